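#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange left_join anti_join
#'   semi_join group_by summarise ungroup bind_rows distinct rename n
#'   row_number across all_of pull if_else slice
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rpois rlnorm setNames weighted.mean
#'   dnorm pnorm optim sd
#' @importFrom utils head
NULL

# Categorical vocabularies shared across the package ------------------------

#' Controlled vocabularies
#'
#' Category levels used throughout the package: planning regions, the five
#' remoteness classes, disease-severity classes, sexes, vital statuses and
#' facility roles.
#'
#' @name vocabularies
#' @keywords internal
NULL

cp_regions <- c("GreaterSydney", "ACT", "RestOfState")
cp_remoteness <- c("MajorCities", "InnerRegional", "OuterRegional",
                   "Remote", "VeryRemote")
cp_severities <- c("Simple", "Moderate", "Complex", "Unknown")
cp_sexes <- c("female", "male", "other")
cp_vital <- c("alive", "deceased")
cp_facility_roles <- c("current_clinic", "candidate", "hospital")

#' Sentinel used for suppressed small counts
#'
#' Masked cells serialize as the string `"masked"` in every output format,
#' never as a number.
#'
#' @return A length-one character string.
#' @export
#' @examples
#' masked_sentinel()
masked_sentinel <- function() "masked"

# days-per-year convention used everywhere a duration becomes "years"
days_per_year <- 365.25

#' Elapsed time in decimal years
#'
#' @param from,to `Date` vectors.
#' @return Numeric years, using a 365.25 days/year convention.
#' @keywords internal
years_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / days_per_year
}

# stop with a classed condition so tests can assert on the class
cp_abort <- function(msg, class) {
  abort(msg, class = c(class, "clinicplan_error"))
}

cp_warn <- function(msg, class) {
  warn(msg, class = c(class, "clinicplan_warning"))
}

# largest-remainder apportionment of n into groups with target fractions;
# guarantees the counts sum to n exactly
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# markdown table from a data frame (all columns coerced to character)
md_table <- function(df) {
  if (nrow(df) == 0) {
    return(paste0("| ", paste(names(df), collapse = " | "), " |\n",
                  "|", paste(rep("---", ncol(df)), collapse = "|"), "|\n",
                  "| ", paste(rep("(none)", ncol(df)), collapse = " | "),
                  " |\n"))
  }
  cells <- vapply(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, body, ""), collapse = "\n")
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
}
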