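#' Small-cell masking policy
#'
#' The public branch of the tool suppresses any geographic patient count
#' below the threshold (default five individuals). Private mode is the
#' identity transform. Zeros are displayed: a zero describes no individual,
#' so it discloses nothing about one.
#'
#' @param threshold Minimum displayable non-zero count (integer, at least 2).
#' @param mode `"private"` (identity) or `"public"` (masking applied).
#' @return A `mask_policy` object.
#' @export
#' @examples
#' mask_policy(mode = "public")
mask_policy <- function(threshold = 5, mode = c("private", "public")) {
  mode <- match.arg(mode)
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 2) {
    cp_abort("mask threshold must be an integer >= 2", "cp_invalid_policy")
  }
  structure(list(threshold = threshold, mode = mode), class = "mask_policy")
}

# a count cell: integer, the sentinel string, or already-masked character.
# Returns character; masked cells hold masked_sentinel().
mask_cell <- function(x, threshold) {
  chr <- as.character(x)
  num <- suppressWarnings(as.numeric(chr))
  masked <- chr == masked_sentinel() |
    (!is.na(num) & num > 0 & num < threshold)
  out <- chr
  out[masked] <- masked_sentinel()
  out
}

cell_is_masked <- function(x) !is.na(x) & x == masked_sentinel()

cell_value <- function(x) suppressWarnings(as.numeric(x))

#' Mask per-area aggregates for public release
#'
#' In public mode every non-zero count below the policy threshold — the
#' area total, each severity count, each diagnosis count, and the
#' lost-to-follow-up count — is replaced by the masked sentinel. Because
#' severity counts sum to the displayed total, suppressing one cell alone
#' would let it be recovered by subtraction; in that case the smallest
#' non-zero unmasked severity sibling is also suppressed (complementary
#' suppression), or the total itself when no such sibling exists. Count
#' columns become character so the sentinel can travel through CSV/JSON;
#' masking is idempotent. Private mode returns the input unchanged.
#'
#' @param aggregates An `area_aggregates` tibble ([aggregate_to_areas()]),
#'   or the already-masked output of this function.
#' @param policy A [mask_policy()].
#' @return The aggregates with count columns as character, masked cells
#'   holding `"masked"`, and `masked` flagging rows touched by suppression.
#' @export
mask_aggregates <- function(aggregates, policy) {
  if (policy$mode == "private") return(aggregates)
  thr <- policy$threshold
  out <- as_tibble(aggregates)

  total <- mask_cell(out$n_patients, thr)
  sev <- lapply(severity_count_cols, function(cl) mask_cell(out[[cl]], thr))
  names(sev) <- severity_count_cols

  for (i in seq_len(nrow(out))) {
    if (cell_is_masked(total[i])) next  # all sub-counts < threshold already
    svals <- vapply(sev, function(col) col[i], character(1))
    m <- cell_is_masked(svals)
    if (sum(m) == 1) {
      # one suppressed severity cell is recoverable from total - siblings
      vals <- cell_value(svals)
      cand <- which(!m & !is.na(vals) & vals > 0)
      if (length(cand)) {
        pick <- cand[which.min(vals[cand])]
        svals[pick] <- masked_sentinel()
      } else {
        total[i] <- masked_sentinel()  # total equals the suppressed cell
      }
      for (cl in severity_count_cols) sev[[cl]][i] <- svals[[cl]]
    }
  }

  out$n_patients <- total
  for (cl in severity_count_cols) out[[cl]] <- sev[[cl]]
  out$n_lost_to_follow_up <- mask_cell(out$n_lost_to_follow_up, thr)
  out$diagnoses <- lapply(out$diagnoses, function(d) {
    d$n <- mask_cell(d$n, thr)
    d
  })
  out$masked <- cell_is_masked(out$n_patients) |
    Reduce(`|`, lapply(sev, cell_is_masked)) |
    cell_is_masked(out$n_lost_to_follow_up) |
    vapply(out$diagnoses, function(d) any(cell_is_masked(d$n)), logical(1))
  class(out) <- unique(c("area_aggregates", class(out)))
  out
}

#' Mask a choropleth layer
#'
#' Patient-count layers are masked cell-by-cell under the policy; drive-time
#' layers carry no patient information and pass through unchanged.
#'
#' @param layer A tibble `area_id`, `value` (or a named vector).
#' @param policy A [mask_policy()].
#' @param kind `"count"` for patient-count layers, `"time"` for drive-time
#'   layers.
#' @return A tibble `area_id`, `value`; for masked count layers `value` is
#'   character with `"masked"` sentinels.
#' @export
mask_layer <- function(layer, policy, kind = c("count", "time")) {
  kind <- match.arg(kind)
  vals <- normalize_layer_values(layer)
  if (policy$mode == "private" || kind == "time") return(vals)
  vals$value <- mask_cell(vals$value, policy$threshold)
  vals
}

#' Scan serialized output for disclosive small counts
#'
#' Returns the patient-count values found in `[1, threshold - 1]` in an
#' artifact destined for public release; a clean artifact returns an empty
#' vector. Methods cover masked aggregates / clinic tables (count columns
#' are those named `n_*`), choropleth GeoJSON text (one named count
#' property), and report/markdown text (cells of count-labelled table
#' columns).
#'
#' @param x The artifact: a data frame, GeoJSON text, or markdown text.
#' @param threshold The masking threshold.
#' @param ... Method-specific arguments.
#' @return Numeric vector of offending values (empty when clean).
#' @export
small_count_violations <- function(x, threshold = 5, ...) {
  UseMethod("small_count_violations")
}

#' @rdname small_count_violations
#' @export
small_count_violations.data.frame <- function(x, threshold = 5, ...) {
  count_cols <- grep("^n_", names(x), value = TRUE)
  vals <- unlist(lapply(count_cols, function(cl) cell_value(as.character(x[[cl]]))),
                 use.names = FALSE)
  if ("diagnoses" %in% names(x)) {
    vals <- c(vals, unlist(lapply(x$diagnoses, function(d) {
      cell_value(as.character(d$n))
    }), use.names = FALSE))
  }
  vals <- vals[!is.na(vals)]
  vals[vals >= 1 & vals < threshold]
}

#' @rdname small_count_violations
#' @param layer_name For GeoJSON text: the count property to inspect.
#' @export
small_count_violations.character <- function(x, threshold = 5,
                                             layer_name = NULL, ...) {
  txt <- if (length(x) == 1 && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  if (!is.null(layer_name)) {
    vals <- read_choropleth(txt, layer_name)$value
    num <- cell_value(vals)
    num <- num[!is.na(num)]
    return(num[num >= 1 & num < threshold])
  }
  scan_markdown_counts(txt, threshold)
}

# headers that mark a markdown table column as a geographic or per-clinic
# patient count (the cells masking applies to); whole-cohort demographic
# tabulations are published unmasked, like the tool's public summary tables
count_header_rx <- paste0(
  "^(n_patients|n_lost_to_follow_up|n_ltf|Patients|ltf|",
  "n_within.*|n_patients_within_threshold|n_ltf_within_threshold)$"
)

scan_markdown_counts <- function(txt, threshold) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  # per-area diagnosis lines render as "- <area>: <label> = <n>; ..."
  viol_dx <- numeric(0)
  for (l in grep("^- .*: .* = ", lines, value = TRUE)) {
    nums <- suppressWarnings(as.numeric(
      regmatches(l, gregexpr("(?<= = )[0-9.]+", l, perl = TRUE))[[1]]
    ))
    viol_dx <- c(viol_dx, nums[!is.na(nums) & nums >= 1 & nums < threshold])
  }
  is_row <- grepl("^\\|.*\\|\\s*$", lines)
  viol <- numeric(0)
  i <- 1
  while (i <= length(lines)) {
    if (is_row[i] && i + 1 <= length(lines) && grepl("^\\|[-| :]+\\|\\s*$", lines[i + 1])) {
      split_row <- function(l) {
        cells <- strsplit(l, "|", fixed = TRUE)[[1]]
        trimws(cells[-1])
      }
      header <- split_row(lines[i])
      count_cols <- which(grepl(count_header_rx, header))
      j <- i + 2
      while (j <= length(lines) && is_row[j]) {
        cells <- split_row(lines[j])
        for (k in count_cols) {
          if (k <= length(cells)) {
            v <- suppressWarnings(as.numeric(cells[k]))
            if (!is.na(v) && v >= 1 && v < threshold) viol <- c(viol, v)
          }
        }
        j <- j + 1
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  c(viol_dx, viol)
}
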