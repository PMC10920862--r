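#' Two-group comparison of a per-animal quantity
#'
#' @param df data.frame with a `group` column and the value column.
#' @param value_col Name of the per-animal value column.
#' @return One-row data.frame: group labels, per-group n and mean, pooled
#'   t-test (t, df, p) and exact Mann-Whitney (U, p) results.
#' @export
group_compare <- function(df, value_col) {
  stopifnot(value_col %in% names(df), "group" %in% names(df))
  g <- unique(df$group)
  if (length(g) != 2)
    stop("group comparison requires exactly 2 groups, got ", length(g),
         call. = FALSE)
  a <- df[[value_col]][df$group == g[1]]
  b <- df[[value_col]][df$group == g[2]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  tt <- students_t(a, b)
  mw <- mann_whitney(a, b)
  data.frame(quantity = value_col, group_a = g[1], group_b = g[2],
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             t = tt$statistic, df = tt$df, p_t = tt$p_two_sided,
             U = mw$statistic, p_mw = mw$p_two_sided,
             stringsAsFactors = FALSE)
}

#' Full group-comparison report
#'
#' Compares the per-animal phase markers (onset, offset, midpoint, peak,
#' alpha) and, when provided, the free-running period and the lights-off
#' latency between the two groups, with both the pooled t-test and the
#' exact Mann-Whitney U test.
#'
#' @param marker_summary Output of [summarize_markers()].
#' @param periods Optional output of [cohort_periods()].
#' @param latencies Optional data.frame with `group` and `latency_min`.
#' @return data.frame, one row per compared quantity (see [group_compare()]).
#' @export
group_report <- function(marker_summary, periods = NULL, latencies = NULL) {
  rows <- lapply(c("onset_zt", "offset_zt", "midpoint_zt", "peak_zt", "alpha_h"),
                 function(v) group_compare(marker_summary, v))
  if (!is.null(periods))
    rows <- c(rows, list(group_compare(periods, "period_h")))
  if (!is.null(latencies))
    rows <- c(rows, list(group_compare(latencies, "latency_min")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-animal lights-off latencies for a cohort
#'
#' @param records List of [actigraphy_record()]s (LD).
#' @param ... Passed to [onset_latency()].
#' @return data.frame: `animal_id`, `group`, `latency_min`, `n_days_used`.
#' @export
cohort_latencies <- function(records, ...) {
  rows <- lapply(records, function(r) {
    ol <- onset_latency(r, ...)
    data.frame(animal_id = r$animal_id, group = r$group,
               latency_min = ol$latency_min, n_days_used = ol$n_days_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
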