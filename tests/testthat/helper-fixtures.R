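# Shared fixtures and independent oracles for the test suite.

# Noiseless square-wave record: activity `high` during ZT12-24, 0 during
# ZT0-12, anchored at ZT0.
square_wave_record <- function(days = 4, high = 10L, bin_seconds = 300L,
                               shift_bins = 0L, scale = 1) {
  per_day <- 86400L %/% bin_seconds
  zt <- (((seq_len(days * per_day) - 1 - shift_bins) * bin_seconds) / 3600) %% 24
  act <- as.integer(round(ifelse(zt >= 12, high * scale, 0)))
  actigraphy_record("sq", "fixture", act, bin_seconds = bin_seconds,
                    schedule = light_schedule("LD"))
}

# Brute-force O(n * w) centred moving average with the same even-window
# convention as the implementation (floor((w-1)/2) bins before the centre).
ma_brute <- function(x, w) {
  n <- length(x)
  left <- (w - 1) %/% 2
  right <- w - 1 - left
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - left; hi <- i + right
    if (lo >= 1 && hi <= n) out[i] <- mean(x[lo:hi])
  }
  out
}

# Exhaustive exact Mann-Whitney oracle: for every assignment of the pooled
# values to the groups, count discordant pairs directly (no rank formula),
# then tally assignments at least as extreme as the observed one.
mw_exact_oracle <- function(a, b) {
  pool <- c(a, b)
  n_a <- length(a); N <- length(pool)
  U_of <- function(av, bv)
    sum(outer(av, bv, function(x, y) (x > y) + 0.5 * (x == y)))
  U_obs <- U_of(a, b)
  mu <- n_a * (N - n_a) / 2
  combos <- utils::combn(N, n_a)
  U_all <- apply(combos, 2, function(ix) U_of(pool[ix], pool[-ix]))
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Naive first-principles marker recomputation (independent of detect_markers
# internals): scan the raw moving-average difference for the day's first
# up-crossing and subsequent down-crossing.
markers_naive <- function(record, opts = marker_options()) {
  bs <- record$bin_seconds
  x <- as.numeric(record$activity)
  d <- ma_brute(x, as.integer(opts$window_onset * 3600 / bs)) -
       ma_brute(x, as.integer(opts$window_long * 3600 / bs))
  u <- record$schedule$anchor_zt + (seq_along(x) - 1) * bs / 3600
  res <- list()
  defined <- which(!is.na(d))
  for (dday in 0:ceiling(max(u) / 24)) {
    w0 <- opts$search_start_zt + 24 * dday
    w1 <- opts$search_end_zt + 24 * dday
    win <- which(u >= w0 & u < w1)
    if (!length(win) || min(win) < min(defined) || max(win) > max(defined)) next
    on_i <- NA; off_i <- NA
    for (i in win[-1]) if (d[i] > 0 && d[i - 1] <= 0) { on_i <- i; break }
    if (!is.na(on_i))
      for (j in (on_i + 1):max(win)) if (d[j] < 0 && d[j - 1] >= 0) { off_i <- j; break }
    res[[length(res) + 1]] <- data.frame(
      day_index = dday,
      onset_zt = if (is.na(on_i)) NA_real_ else u[on_i] - 24 * dday,
      offset_zt = if (is.na(off_i)) NA_real_ else u[off_i] - 24 * dday,
      valid = !is.na(on_i) && !is.na(off_i))
  }
  do.call(rbind, res)
}
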