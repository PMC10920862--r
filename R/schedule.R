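#' Define a lighting schedule
#'
#' A light schedule maps recording time (seconds since the start of the
#' recording) to zeitgeber time (ZT, hours) and light state. ZT0 is the
#' lights-on instant by the standard chronobiology convention; under the
#' default 12:12 light-dark (LD) cycle lights go off at ZT12. A schedule may
#' switch permanently to constant darkness (DD) at `dd_start_s`; the ZT frame
#' keeps ticking at 24 h/day after that point (frozen from the LD anchor), so
#' free-running phases can still be expressed as clock times.
#'
#' @param cycle `"LD"` or `"DD"`. A `"DD"` schedule is dark from `dd_start_s`
#'   (default 0, i.e. the whole recording).
#' @param cycle_length Cycle length in hours (default 24).
#' @param lights_off_zt ZT hour at which lights switch off (default 12);
#'   lights-on is ZT0 by convention.
#' @param anchor_zt ZT hour at recording time 0. A recording started exactly
#'   at lights-on has `anchor_zt = 0`.
#' @param dd_start_s Recording time (seconds) from which lights stay off
#'   permanently; `NA` for a pure LD schedule.
#'
#' @return An object of class `light_schedule`.
#' @examples
#' sch <- light_schedule("LD")
#' zt_of(6 * 3600, sch)     # ZT6
#' light_state(13 * 3600, sch)  # "dark"
#' @export
light_schedule <- function(cycle = c("LD", "DD"), cycle_length = 24,
                           lights_off_zt = 12, anchor_zt = 0,
                           dd_start_s = if (match.arg(cycle) == "DD") 0 else NA_real_) {
  cycle <- match.arg(cycle)
  stopifnot(is.numeric(cycle_length), cycle_length > 0,
            is.numeric(lights_off_zt), lights_off_zt >= 0,
            lights_off_zt < cycle_length,
            is.numeric(anchor_zt), anchor_zt >= 0, anchor_zt < cycle_length)
  if (cycle == "DD" && is.na(dd_start_s)) dd_start_s <- 0
  if (!is.na(dd_start_s) && dd_start_s < 0)
    stop("dd_start_s must be non-negative", call. = FALSE)
  structure(
    list(cycle = cycle, cycle_length = cycle_length,
         lights_off_zt = lights_off_zt, anchor_zt = anchor_zt,
         dd_start_s = dd_start_s),
    class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %s %g:%g, anchor ZT%.3g at t=0%s\n",
              x$cycle, x$lights_off_zt, x$cycle_length - x$lights_off_zt,
              x$anchor_zt,
              if (!is.na(x$dd_start_s)) sprintf(", DD from t=%gs", x$dd_start_s) else ""))
  invisible(x)
}

#' Zeitgeber time of a recording time
#'
#' @param t_s Recording time(s) in seconds since recording start (vectorised).
#' @param schedule A [light_schedule()].
#' @return ZT in hours, in `[0, cycle_length)`. In DD the frame is the frozen
#'   continuation of the LD anchor.
#' @export
zt_of <- function(t_s, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (any(t_s < 0)) stop("recording time must be non-negative", call. = FALSE)
  (schedule$anchor_zt + t_s / 3600) %% schedule$cycle_length
}

#' Light state at a recording time
#'
#' Intervals are half-open: light during ZT `[0, lights_off_zt)`, so the
#' lights-off instant itself belongs to the dark phase. After `dd_start_s`
#' the state is always `"dark"`.
#'
#' @inheritParams zt_of
#' @return Character vector, `"light"` or `"dark"`.
#' @export
light_state <- function(t_s, schedule) {
  zt <- zt_of(t_s, schedule)
  out <- ifelse(zt < schedule$lights_off_zt, "light", "dark")
  if (!is.na(schedule$dd_start_s)) out[t_s >= schedule$dd_start_s] <- "dark"
  out
}

#' Enumerate light transitions in a time span
#'
#' Returns every lights-off and lights-on boundary of the schedule strictly
#' inside the span `(t0_s, t1_s)`, ordered in time (a boundary coinciding
#' with either endpoint is not counted). A DD span (or the portion of the
#' span at or beyond `dd_start_s`) contains no transitions.
#'
#' @param schedule A [light_schedule()].
#' @param t0_s,t1_s Span bounds in recording seconds, `t0_s < t1_s`.
#' @return A data.frame with columns `time_s` and `type`
#'   (`"lights_off"` / `"lights_on"`), possibly zero rows.
#' @export
transitions <- function(schedule, t0_s, t1_s) {
  stopifnot(inherits(schedule, "light_schedule"), t0_s < t1_s)
  empty <- data.frame(time_s = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  hi <- t1_s
  if (!is.na(schedule$dd_start_s)) hi <- min(hi, schedule$dd_start_s)
  if (hi <= t0_s) return(empty)
  cyc_s <- schedule$cycle_length * 3600
  # boundary times solve (anchor + t/3600) == zt_b (mod cycle_length)
  one_kind <- function(zt_b, type) {
    t_first <- ((zt_b - schedule$anchor_zt) %% schedule$cycle_length) * 3600
    k0 <- floor((t0_s - t_first) / cyc_s)
    k1 <- ceiling((hi - t_first) / cyc_s)
    tt <- t_first + (k0:k1) * cyc_s
    tt <- tt[tt > t0_s & tt < hi]  # boundaries strictly inside the span
    if (!length(tt)) return(empty)
    data.frame(time_s = tt, type = rep(type, length(tt)), stringsAsFactors = FALSE)
  }
  out <- rbind(one_kind(0, "lights_on"),
               one_kind(schedule$lights_off_zt, "lights_off"))
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
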