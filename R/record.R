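#' Construct an actigraphy record
#'
#' One animal's equally spaced activity-count and body-temperature series.
#' Activity is complete by construction (a dropped bin is a format error at
#' read time); temperature may carry `NA` for missing samples. Bin `i`
#' (1-based) covers recording time `[(i-1) * bin_seconds, i * bin_seconds)`.
#'
#' @param animal_id Non-empty string.
#' @param group Non-empty group label.
#' @param bin_seconds Bin width in seconds; must divide 86400 so bins tile
#'   the day (default 300, i.e. 5 min).
#' @param activity Integer vector of non-negative counts per bin.
#' @param temperature Numeric vector (degrees C) of the same length;
#'   `NA` = missing sample.
#' @param schedule The [light_schedule()] the animal was recorded under.
#' @param t0_s Recording time of the first bin start (default 0).
#'
#' @return An object of class `actigraphy_record`.
#' @export
actigraphy_record <- function(animal_id, group, activity, temperature = NULL,
                              bin_seconds = 300L,
                              schedule = light_schedule("LD"), t0_s = 0) {
  stopifnot(is.character(animal_id), nzchar(animal_id),
            is.character(group), nzchar(group),
            inherits(schedule, "light_schedule"))
  bin_seconds <- as.integer(bin_seconds)
  if (bin_seconds <= 0L || 86400L %% bin_seconds != 0L)
    stop("bin_seconds must be a positive divisor of 86400", call. = FALSE)
  if (any(is.na(activity)))
    stop("activity must be complete (no NA); missing bins are not representable",
         call. = FALSE)
  if (any(activity < 0) || any(activity != round(activity)))
    stop("activity must be non-negative integers", call. = FALSE)
  activity <- as.integer(round(activity))
  n <- length(activity)
  if (is.null(temperature)) temperature <- rep(NA_real_, n)
  if (length(temperature) != n)
    stop("temperature must have one value per activity bin", call. = FALSE)
  structure(
    list(animal_id = animal_id, group = group, bin_seconds = bin_seconds,
         n_bins = n, activity = activity, temperature = as.numeric(temperature),
         schedule = schedule, t0_s = t0_s),
    class = "actigraphy_record")
}

#' @export
print.actigraphy_record <- function(x, ...) {
  cat(sprintf("<actigraphy_record> %s (%s): %d bins of %ds (%.2f days), %s\n",
              x$animal_id, x$group, x$n_bins, x$bin_seconds,
              x$n_bins * x$bin_seconds / 86400, x$schedule$cycle))
  invisible(x)
}

#' Bin start times of a record
#' @param record An [actigraphy_record()].
#' @return Numeric vector of recording times (seconds) at each bin start.
#' @export
bin_times <- function(record) {
  record$t0_s + (seq_len(record$n_bins) - 1) * record$bin_seconds
}
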