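#' Rebin a record to a coarser grid
#'
#' Activity counts are summed within each coarse bin; temperature is
#' averaged, missing-aware (a coarse bin is missing only when all of its
#' fine bins are missing).
#'
#' @param record An [actigraphy_record()].
#' @param bin_minutes Target bin width in minutes; must be a multiple of the
#'   record's bin width, and the record length a multiple of the ratio.
#' @return An [actigraphy_record()] on the coarser grid.
#' @export
rebin <- function(record, bin_minutes) {
  stopifnot(inherits(record, "actigraphy_record"))
  new_bs <- as.integer(bin_minutes * 60)
  if (new_bs %% record$bin_seconds != 0)
    stop("bin_minutes must be a multiple of the record's bin width", call. = FALSE)
  k <- new_bs %/% record$bin_seconds
  if (k == 1L) return(record)
  if (record$n_bins %% k != 0)
    stop("record length must be a multiple of the rebin ratio", call. = FALSE)
  act <- colSums(matrix(record$activity, nrow = k))
  tm <- matrix(record$temperature, nrow = k)
  temp <- colMeans(tm, na.rm = TRUE)
  temp[colSums(!is.na(tm)) == 0] <- NA_real_
  actigraphy_record(record$animal_id, record$group, act, temp,
                    bin_seconds = new_bs, schedule = record$schedule,
                    t0_s = record$t0_s)
}

#' Daily activity or temperature profile of a group
#'
#' For each animal, each ZT bin is averaged across all complete recording
#' days; the group profile is then the across-animal mean and standard error
#' (sample SD over the square root of the number of animals) of those
#' per-animal values. Animals — not animal-days — are the independent units,
#' so the SEM quantifies between-animal variability.
#'
#' @param records List of [actigraphy_record()]s from one group, sharing bin
#'   width and schedule; at least 2 animals.
#' @param variable `"activity"` or `"temperature"`.
#' @param bin_minutes Profile bin width (a multiple of the record bin width).
#' @return data.frame of class `daily_profile`: `bin_start_zt`, `mean`,
#'   `sem`, `n_animals`, with attributes `variable` and `bin_minutes`.
#' @export
daily_profile <- function(records, variable = c("activity", "temperature"),
                          bin_minutes = 5) {
  variable <- match.arg(variable)
  if (length(records) < 2)
    stop("need at least 2 animals for a group profile (sem undefined)",
         call. = FALSE)
  per_animal <- lapply(records, animal_daily_means, variable = variable,
                       bin_minutes = bin_minutes)
  zt0 <- per_animal[[1]]$bin_start_zt
  for (pa in per_animal)
    if (!isTRUE(all.equal(pa$bin_start_zt, zt0)))
      stop("records must share bin grid and schedule", call. = FALSE)
  mat <- do.call(rbind, lapply(per_animal, `[[`, "mean"))
  out <- data.frame(
    bin_start_zt = zt0,
    mean = colMeans(mat),
    sem = apply(mat, 2, stats::sd) / sqrt(nrow(mat)),
    n_animals = nrow(mat))
  attr(out, "variable") <- variable
  attr(out, "bin_minutes") <- bin_minutes
  class(out) <- c("daily_profile", "data.frame")
  out
}

# One animal's day-averaged profile over the ZT day.
animal_daily_means <- function(record, variable, bin_minutes) {
  rec <- rebin(record, bin_minutes)
  x <- if (variable == "activity") as.numeric(rec$activity) else rec$temperature
  per_day <- as.integer(86400 / rec$bin_seconds)
  n_days <- rec$n_bins %/% per_day
  if (n_days < 1) stop("record shorter than one day", call. = FALSE)
  x <- x[seq_len(n_days * per_day)]  # complete days only
  # bin starts sit on the grid, so rounding (not floor) avoids fp drift
  zt_bin <- as.integer(round(zt_of(bin_times(rec)[seq_len(n_days * per_day)],
                                   rec$schedule) * 3600 / rec$bin_seconds)) %% per_day
  means <- tapply(x, zt_bin, mean, na.rm = TRUE)
  ord <- order(as.integer(names(means)))
  data.frame(bin_start_zt = as.integer(names(means))[ord] * rec$bin_seconds / 3600,
             mean = as.numeric(means)[ord])
}

#' Align records to a light transition
#'
#' For each animal, averages the chosen variable over every occurrence of the
#' event (lights-off or lights-on) across recording days, on a relative time
#' grid. Bin 0 is the first bin after the event instant (the half-open light
#' interval convention: the lights-off instant belongs to the dark phase).
#' Only event occurrences whose full window lies inside the record are used.
#'
#' @param records List of [actigraphy_record()]s under an LD schedule.
#' @param event `"lights_off"` or `"lights_on"`.
#' @param window `c(pre_minutes, post_minutes)`: minutes before and after
#'   the event to cover.
#' @param bin_minutes Relative-grid bin width (a multiple of the record bin).
#' @param variable `"activity"` or `"temperature"`.
#' @return An object of class `response_matrix`: list with `rel_min_start`
#'   (bin start times relative to the event, minutes), `values` (matrix,
#'   one row per animal), `animal_id`, `group`, `event`, `variable`.
#' @export
align_to_transition <- function(records, event = c("lights_off", "lights_on"),
                                window = c(60, 360), bin_minutes = 15,
                                variable = c("activity", "temperature")) {
  event <- match.arg(event)
  variable <- match.arg(variable)
  stopifnot(length(window) == 2, window[1] >= 0, window[2] > 0)
  rows <- list()
  for (record in records) {
    sch <- record$schedule
    if (sch$cycle == "DD" || (!is.na(sch$dd_start_s) && sch$dd_start_s == 0))
      stop("transition alignment requires an LD schedule", call. = FALSE)
    rec <- rebin(record, bin_minutes)
    x <- if (variable == "activity") as.numeric(rec$activity) else rec$temperature
    bs <- rec$bin_seconds
    total_s <- rec$n_bins * bs
    tr <- transitions(sch, rec$t0_s - 1, rec$t0_s + total_s + 1)
    ev_t <- tr$time_s[tr$type == event]
    pre_bins <- as.integer(round(window[1] * 60 / bs))
    post_bins <- as.integer(round(window[2] * 60 / bs))
    if (pre_bins * bs != window[1] * 60 || post_bins * bs != window[2] * 60)
      stop("window must be a whole number of bins", call. = FALSE)
    segs <- list()
    for (e in ev_t) {
      i0 <- (e - rec$t0_s) / bs  # index of first post-event bin, 0-based
      if (abs(i0 - round(i0)) > 1e-9)
        stop("event instant does not align with the bin grid", call. = FALSE)
      i0 <- as.integer(round(i0))
      lo <- i0 - pre_bins + 1L
      hi <- i0 + post_bins
      if (lo < 1L || hi > rec$n_bins) next
      segs[[length(segs) + 1L]] <- x[lo:hi]
    }
    if (!length(segs))
      stop(sprintf("no complete %s window in record %s", event, record$animal_id),
           call. = FALSE)
    m <- do.call(rbind, segs)
    rows[[record$animal_id]] <- colMeans(m, na.rm = TRUE)
  }
  values <- do.call(rbind, rows)
  structure(
    list(rel_min_start = (seq(-pre_bins, post_bins - 1L)) * bin_minutes,
         values = values,
         animal_id = vapply(records, `[[`, "", "animal_id"),
         group = vapply(records, `[[`, "", "group"),
         event = event, variable = variable, bin_minutes = bin_minutes),
    class = "response_matrix")
}

#' Per-bin two-group comparison of response matrices
#'
#' Runs a two-tailed two-sample test on the per-animal values at each
#' relative bin, reporting raw p-values (the uncorrected multiple-t-test
#' presentation) side by side with Holm-adjusted ones. Bins where the
#' statistic is undefined (zero variance in both groups with equal means)
#' are flagged degenerate, not errors.
#'
#' @param matrix_a,matrix_b `response_matrix` objects on the same relative
#'   grid, with at least 2 animals each.
#' @param welch Use Welch's t instead of pooled-variance Student's t.
#' @return data.frame: `rel_min`, `mean_a`, `sem_a`, `mean_b`, `sem_b`, `t`,
#'   `df`, `p_raw`, `p_holm`, `degenerate`.
#' @export
per_bin_compare <- function(matrix_a, matrix_b, welch = FALSE) {
  stopifnot(inherits(matrix_a, "response_matrix"),
            inherits(matrix_b, "response_matrix"),
            identical(matrix_a$rel_min_start, matrix_b$rel_min_start))
  A <- matrix_a$values; B <- matrix_b$values
  stopifnot(nrow(A) >= 2, nrow(B) >= 2)
  nb <- ncol(A)
  res <- data.frame(
    rel_min = matrix_a$rel_min_start,
    mean_a = colMeans(A), sem_a = apply(A, 2, stats::sd) / sqrt(nrow(A)),
    mean_b = colMeans(B), sem_b = apply(B, 2, stats::sd) / sqrt(nrow(B)),
    t = NA_real_, df = NA_real_, p_raw = NA_real_, p_holm = NA_real_,
    degenerate = FALSE)
  for (j in seq_len(nb)) {
    tt <- students_t(A[, j], B[, j], welch = welch)
    res$t[j] <- tt$statistic
    res$df[j] <- tt$df
    res$p_raw[j] <- tt$p_two_sided
    res$degenerate[j] <- tt$degenerate
  }
  res$p_holm <- holm_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

#' Lights-off response latency
#'
#' Operationalises "speed of the activity increase after lights-off" as the
#' time from the lights-off instant to the first bin whose activity reaches
#' `threshold_frac` of that day's dark-phase mean activity, computed per
#' dark phase and averaged per animal. Dark phases with no crossing, or with
#' zero total activity (threshold undefined), are dropped and counted.
#'
#' @param record An [actigraphy_record()] under an LD schedule.
#' @param threshold_frac Fraction of the dark-phase mean (default 0.5).
#' @param bin_minutes Analysis bin width, minutes (default 15).
#' @return List: `latency_min` (mean over days; `NA` if no day yields one),
#'   `per_day_min`, `n_days_used`, `n_days_flagged`.
#' @export
onset_latency <- function(record, threshold_frac = 0.5, bin_minutes = 15) {
  stopifnot(inherits(record, "actigraphy_record"), threshold_frac >= 0)
  sch <- record$schedule
  rec <- rebin(record, bin_minutes)
  bs <- rec$bin_seconds
  total_s <- rec$n_bins * bs
  dark_h <- sch$cycle_length - sch$lights_off_zt
  dark_bins <- as.integer(round(dark_h * 3600 / bs))
  tr <- transitions(sch, rec$t0_s - 1, rec$t0_s + total_s + 1)
  ev_t <- tr$time_s[tr$type == "lights_off"]
  per_day <- numeric(0)
  flagged <- 0L
  for (e in ev_t) {
    i0 <- (e - rec$t0_s) / bs
    if (abs(i0 - round(i0)) > 1e-9) next
    i0 <- as.integer(round(i0)) + 1L          # first dark bin (1-based)
    i1 <- i0 + dark_bins - 1L
    if (i0 < 1L || i1 > rec$n_bins) next      # incomplete dark phase
    dark <- as.numeric(rec$activity[i0:i1])
    if (mean(dark) == 0) { flagged <- flagged + 1L; next }
    hit <- which(dark >= threshold_frac * mean(dark))[1]
    if (is.na(hit)) { flagged <- flagged + 1L; next }
    per_day <- c(per_day, (hit - 1L) * bs / 60)
  }
  if (!length(per_day) && !flagged)
    stop("record contains no complete dark phase", call. = FALSE)
  list(latency_min = if (length(per_day)) mean(per_day) else NA_real_,
       per_day_min = per_day, n_days_used = length(per_day),
       n_days_flagged = flagged)
}
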