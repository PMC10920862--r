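#' Options for phase-marker detection
#'
#' Window lengths for the moving averages and the daily search window, all in
#' hours. Defaults follow the standard crossing method for nocturnal rodents:
#' activity onset is the time at which a short (3-h) centred moving average
#' of activity rises above a long (24-h) one, offset the subsequent fall
#' below, the midpoint halves the cumulative activity over a fixed 16-h span
#' from onset, and the peak is the maximum of a 1-h moving average.
#'
#' @param window_long Long moving-average window, hours (default 24).
#' @param window_onset Short moving-average window, hours (default 3).
#' @param window_peak Peak moving-average window, hours (default 1).
#' @param midpoint_span Span from onset over which cumulative activity is
#'   halved, hours (default 16).
#' @param search_start_zt,search_end_zt Daily crossing search window in ZT
#'   hours (defaults 6 and 30, i.e. ZT6 to ZT6 of the next day, so the
#'   expected nocturnal onset near ZT12 is interior).
#' @param direction `"short_above_long"` (default; onset = short average
#'   rising above the long) or `"long_above_short"` (the inverted reading).
#' @return An object of class `marker_options`.
#' @export
marker_options <- function(window_long = 24, window_onset = 3,
                           window_peak = 1, midpoint_span = 16,
                           search_start_zt = 6, search_end_zt = 30,
                           direction = c("short_above_long", "long_above_short")) {
  direction <- match.arg(direction)
  stopifnot(window_onset < window_long, midpoint_span <= 24,
            window_peak > 0,
            search_end_zt - search_start_zt >= 12,
            search_end_zt > search_start_zt)
  structure(list(window_long = window_long, window_onset = window_onset,
                 window_peak = window_peak, midpoint_span = midpoint_span,
                 search_start_zt = search_start_zt,
                 search_end_zt = search_end_zt, direction = direction),
            class = "marker_options")
}

#' Centred moving average
#'
#' Centred moving average over a window of `window_h` hours. Positions whose
#' full window falls outside the series are `NA` (no partial windows, no
#' wrap-around). For an even number of bins the window is taken with
#' `floor((w - 1) / 2)` bins before the centre and the remainder after.
#'
#' @param x Numeric per-bin series.
#' @param window_h Window length in hours; `window_h * 3600 / bin_seconds`
#'   must be a whole number of bins, at least 1.
#' @param bin_seconds Bin width of `x` in seconds.
#' @return Numeric vector of `length(x)` with `NA` at undefined positions.
#' @export
moving_average <- function(x, window_h, bin_seconds) {
  w_exact <- window_h * 3600 / bin_seconds
  w <- as.integer(round(w_exact))
  if (abs(w_exact - w) > 1e-9 || w < 1L)
    stop("window must be a whole positive number of bins", call. = FALSE)
  n <- length(x)
  if (n < w) stop("series shorter than the moving-average window", call. = FALSE)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, n)
  idx <- (left + 1L):(n - right)
  out[idx] <- (cs[idx + right + 1L] - cs[idx - left]) / w
  out
}

#' Detect per-day activity phase markers
#'
#' For each ZT day whose search window is fully covered by defined moving
#' averages: onset is the start time of the first bin in the window at which
#' the short moving average sits on the active side of the long one after a
#' bin on the other side (first upward crossing); offset is the first
#' subsequent downward crossing. The midpoint is the earliest time at which
#' cumulative activity from onset reaches half the total over
#' `[onset, onset + midpoint_span]`; the peak is the earliest time of the
#' maximum of the short peak-window average within `[onset, offset]`. Times
#' are reported in ZT hours with carry-over (an offset after midnight of the
#' ZT day exceeds 24 rather than wrapping).
#'
#' @param record An [actigraphy_record()] of at least 3 days.
#' @param opts A [marker_options()].
#' @return A data.frame of class `phase_markers` with one row per searched
#'   day: `day_index`, `onset_zt`, `offset_zt`, `midpoint_zt`, `peak_zt`,
#'   `alpha_h`, `valid`. Days with no crossing have `valid = FALSE` and `NA`
#'   markers; a day whose midpoint span runs past the record end has `NA`
#'   midpoint only.
#' @export
detect_markers <- function(record, opts = marker_options()) {
  stopifnot(inherits(record, "actigraphy_record"),
            inherits(opts, "marker_options"))
  bs <- record$bin_seconds
  x <- as.numeric(record$activity)
  ma_long <- moving_average(x, opts$window_long, bs)
  ma_short <- moving_average(x, opts$window_onset, bs)
  ma_peak <- moving_average(x, opts$window_peak, bs)
  sgn <- if (opts$direction == "short_above_long") 1 else -1
  d <- sgn * (ma_short - ma_long)
  u <- record$schedule$anchor_zt + bin_times(record) / 3600  # unwrapped ZT
  defined <- which(!is.na(d))
  if (!length(defined))
    stop("record too short for the long moving-average window", call. = FALSE)
  def_lo <- min(defined); def_hi <- max(defined)
  bin_h <- bs / 3600
  span_bins <- as.integer(round(opts$midpoint_span * 3600 / bs))

  day_lo <- ceiling((u[def_lo] - opts$search_start_zt) / 24)
  day_hi <- floor((u[def_hi] + bin_h - opts$search_end_zt) / 24)
  rows <- list()
  for (dday in seq(day_lo, day_hi, by = 1)) {
    w0 <- opts$search_start_zt + 24 * dday
    w1 <- opts$search_end_zt + 24 * dday
    win <- which(u >= w0 & u < w1)
    if (!length(win) || min(win) < def_lo || max(win) > def_hi) next
    row <- list(day_index = dday, onset_zt = NA_real_, offset_zt = NA_real_,
                midpoint_zt = NA_real_, peak_zt = NA_real_, alpha_h = NA_real_,
                valid = FALSE)
    # first upward crossing: previous bin at or below zero, this bin above
    i0 <- win[1]
    on_i <- NA_integer_
    for (i in win[-1]) {
      if (d[i] > 0 && d[i - 1] <= 0) { on_i <- i; break }
    }
    if (!is.na(on_i)) {
      off_i <- NA_integer_
      j <- on_i + 1L
      while (j <= max(win)) {
        if (d[j] < 0 && d[j - 1] >= 0) { off_i <- j; break }
        j <- j + 1L
      }
      if (!is.na(off_i)) {
        row$onset_zt <- u[on_i] - 24 * dday
        row$offset_zt <- u[off_i] - 24 * dday
        row$alpha_h <- row$offset_zt - row$onset_zt
        row$valid <- TRUE
        # peak: earliest maximum of the peak-window average in [onset, offset]
        pk_rng <- on_i:off_i
        pk_ok <- pk_rng[!is.na(ma_peak[pk_rng])]
        if (length(pk_ok)) {
          pk_i <- pk_ok[which.max(ma_peak[pk_ok])]
          row$peak_zt <- u[pk_i] - 24 * dday
        }
        # midpoint: half of cumulative activity over the fixed span from onset
        end_i <- on_i + span_bins - 1L
        if (end_i <= record$n_bins) {
          cum <- cumsum(x[on_i:end_i])
          half <- cum[length(cum)] / 2
          mid_i <- on_i + which(cum >= half)[1] - 1L
          row$midpoint_zt <- u[mid_i] - 24 * dday
        }
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(day_index = integer(0), onset_zt = numeric(0),
               offset_zt = numeric(0), midpoint_zt = numeric(0),
               peak_zt = numeric(0), alpha_h = numeric(0), valid = logical(0))
  out$animal_id <- rep(record$animal_id, nrow(out))
  out$group <- rep(record$group, nrow(out))
  out <- out[c("animal_id", "group", "day_index", "onset_zt", "offset_zt",
               "midpoint_zt", "peak_zt", "alpha_h", "valid")]
  class(out) <- c("phase_markers", "data.frame")
  out
}

#' Phase markers for a whole cohort
#'
#' @param records List of [actigraphy_record()]s.
#' @param opts A [marker_options()].
#' @return Row-bound [detect_markers()] output for all records.
#' @export
cohort_markers <- function(records, opts = marker_options()) {
  out <- do.call(rbind, lapply(records, detect_markers, opts = opts))
  rownames(out) <- NULL
  out
}

#' Per-animal marker summaries
#'
#' Arithmetic means of each marker across an animal's valid days, on the
#' ZT-with-carry-over scale (offsets past 24 are averaged as-is, never
#' wrapped through 0). Animals are the units of inference for the group
#' tests, so one row per animal is returned. Animals with zero valid days
#' are dropped with a warning.
#'
#' @param markers A `phase_markers` data.frame (e.g. from [cohort_markers()]).
#' @return data.frame with one row per animal: `animal_id`, `group`,
#'   `n_days`, `onset_zt`, `offset_zt`, `midpoint_zt`, `peak_zt`, `alpha_h`.
#' @export
summarize_markers <- function(markers) {
  stopifnot(is.data.frame(markers))
  ids <- unique(markers$animal_id)
  rows <- list()
  for (id in ids) {
    m <- markers[markers$animal_id == id & markers$valid, , drop = FALSE]
    if (!nrow(m)) {
      warning(sprintf("animal %s has no valid marker days; excluded", id),
              call. = FALSE)
      next
    }
    rows[[id]] <- data.frame(
      animal_id = id, group = m$group[1], n_days = nrow(m),
      onset_zt = mean(m$onset_zt), offset_zt = mean(m$offset_zt),
      midpoint_zt = mean(m$midpoint_zt, na.rm = TRUE),
      peak_zt = mean(m$peak_zt, na.rm = TRUE),
      alpha_h = mean(m$alpha_h), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
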