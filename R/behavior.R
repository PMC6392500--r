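#' Velocity trace
#'
#' Uniformly sampled signed crawl speed, body-lengths/s; negative values are
#' backward motion. `NA` marks samples where the tracker lost the worm.
#'
#' @param time s, uniform and increasing.
#' @param signed_speed body-lengths/s (`NA` = untracked).
#' @return an object of class `velocity_trace`.
#' @export
velocity_trace <- function(time, signed_speed) {
  stopifnot(is.numeric(time), is.numeric(signed_speed),
            length(time) == length(signed_speed), length(time) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * mean(dt))
    stop("`time` must be uniformly sampled and increasing", call. = FALSE)
  structure(data.frame(time = time, signed_speed = signed_speed),
            sample_rate = 1 / mean(dt),
            class = c("velocity_trace", "data.frame"))
}

#' Call a tap-evoked reversal from a velocity trace
#'
#' The escape response to a plate tap is a brief reversal: sustained backward
#' motion shortly after the tap. The call is `reversed = TRUE` iff
#' `signed_speed < -back_speed_threshold` continuously for at least
#' `min_back_duration` within `[tap_time, tap_time + window]`; the latency is
#' the first such onset relative to the tap. A tracking gap (`NA` speed)
#' overlapping the window makes the outcome `"untracked"` — such worms are
#' excluded from reversal denominators, never scored as non-reversers.
#'
#' @param v a [velocity_trace()].
#' @param tap_time s.
#' @param window s after the tap searched for a reversal.
#' @param min_back_duration minimum sustained backward motion, s.
#' @param back_speed_threshold body-lengths/s.
#' @param worm_id,tap_index labels carried into the output.
#' @return a `reversal_call`: list with `worm_id`, `tap_index`, `tracked`,
#'   `reversed`, `latency` (s, `NA` unless reversed).
#' @export
call_reversal <- function(v, tap_time, window = 1.0,
                          min_back_duration = 0.2,
                          back_speed_threshold = 0.05,
                          worm_id = NA_character_, tap_index = NA_integer_) {
  stopifnot(inherits(v, "velocity_trace"))
  if (tap_time < min(v$time) || tap_time + window > max(v$time))
    stop("`[tap_time, tap_time + window]` must lie within the trace",
         call. = FALSE)
  in_win <- v$time >= tap_time & v$time <= tap_time + window
  sp <- v$signed_speed[in_win]
  tm <- v$time[in_win]
  out <- list(worm_id = worm_id, tap_index = tap_index, tracked = TRUE,
              reversed = FALSE, latency = NA_real_)
  if (anyNA(sp)) {
    out$tracked <- FALSE
    out$reversed <- NA
    return(structure(out, class = "reversal_call"))
  }
  back <- sp < -back_speed_threshold
  r <- rle(back)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- 1 / attr(v, "sample_rate")
  for (i in seq_along(r$values)) {
    if (r$values[i] && (r$lengths[i] - 1L) * dt >= min_back_duration) {
      out$reversed <- TRUE
      out$latency <- tm[starts[i]] - tap_time
      break
    }
  }
  structure(out, class = "reversal_call")
}

#' @export
print.reversal_call <- function(x, ...) {
  cat(sprintf("<reversal_call> tap %s: %s\n", x$tap_index,
              if (!x$tracked) "untracked"
              else if (x$reversed) sprintf("reversal, latency %.2f s", x$latency)
              else "no reversal"))
  invisible(x)
}

#' Detect body-bend events with hysteresis
#'
#' A bend event fires each time the absolute bend angle crosses above
#' `theta_c` on the side opposite the previous event. Two-threshold
#' hysteresis suppresses chatter: after an event, the angle must fall below
#' `theta_c - hysteresis` (in absolute value) before the next event can fire
#' on either side. Events are strictly time-ordered and side-alternating;
#' the first event may fall on either side. `theta_c = 45` degrees with 10
#' degrees of hysteresis operationalizes a C-shaped bend.
#'
#' @param p a [posture_trace()].
#' @param theta_c bend threshold, degrees (> hysteresis).
#' @param hysteresis reset margin, degrees (> 0).
#' @return data.frame with columns `time` (s) and `side` (+1 / -1).
#' @examples
#' t <- seq(0, 10, by = 0.05)
#' tr <- posture_trace(t, 60 * sin(2 * pi * 0.5 * t))
#' nrow(detect_bends(tr))  # one event per half-cycle
#' @export
detect_bends <- function(p, theta_c = 45, hysteresis = 10) {
  stopifnot(inherits(p, "posture_trace"))
  if (!(theta_c > hysteresis && hysteresis > 0))
    stop("require theta_c > hysteresis > 0", call. = FALSE)
  a <- p$bend_angle
  lo <- theta_c - hysteresis
  # compress samples into runs of a 4-level code before walking the state
  # machine; a trace has far fewer threshold runs than samples
  code <- integer(length(a))
  code[a > theta_c] <- 1L
  code[a < -theta_c] <- -1L
  code[abs(a) < lo & code == 0L] <- 9L   # reset band
  r <- rle(code)
  start <- cumsum(r$lengths) - r$lengths + 1L
  times <- sides <- numeric(length(r$values))
  nev <- 0L
  last_side <- 0   # 0 = no event yet
  armed <- TRUE    # below the reset threshold since the last event
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == 9L) { armed <- TRUE; next }
    if (armed && (v == 1L || v == -1L) && v != last_side) {
      nev <- nev + 1L
      times[nev] <- p$time[start[i]]
      sides[nev] <- v
      last_side <- v
      armed <- FALSE
    }
  }
  data.frame(time = times[seq_len(nev)], side = sides[seq_len(nev)])
}

#' Call swimming-induced paralysis at the assay time point
#'
#' A swimming worm is scored paralyzed at `assay_time` (10 min in the
#' standard assay) when it shows no C-shaped bends for at least
#' `quiet_window` seconds up to that point, i.e. [detect_bends()] fires no
#' event inside `[assay_time - quiet_window, assay_time]`.
#'
#' @param p a [posture_trace()] covering the window.
#' @param assay_time s.
#' @param quiet_window s.
#' @param theta_c,hysteresis bend thresholds, degrees (see [detect_bends()]).
#' @return logical: paralyzed or not.
#' @export
call_paralysis <- function(p, assay_time = 600, quiet_window = 5,
                           theta_c = 45, hysteresis = 10) {
  stopifnot(inherits(p, "posture_trace"))
  if (min(p$time) > assay_time - quiet_window || max(p$time) < assay_time)
    stop("trace must cover [assay_time - quiet_window, assay_time]",
         call. = FALSE)
  ev <- detect_bends(p, theta_c, hysteresis)
  !any(ev$time >= assay_time - quiet_window & ev$time <= assay_time)
}

#' Thrash frequency over an interval
#'
#' One thrash is one full left-right swim cycle, i.e. two alternating bend
#' events, so the frequency is `events / (2 * interval length)`. The standard
#' automated assay scores thrashing over the full 11 min recording.
#'
#' @param p a [posture_trace()].
#' @param interval `c(start, end)` in s; must lie within the trace.
#' @param theta_c,hysteresis bend thresholds, degrees.
#' @return a `thrash_estimate`: list with `frequency_hz`, `n_events`,
#'   `interval`.
#' @export
thrash_frequency <- function(p, interval = c(0, 660), theta_c = 45,
                             hysteresis = 10) {
  stopifnot(inherits(p, "posture_trace"), length(interval) == 2L,
            interval[2] > interval[1])
  if (min(p$time) > interval[1] || max(p$time) < interval[2])
    stop("`interval` must lie within the trace", call. = FALSE)
  ev <- detect_bends(p, theta_c, hysteresis)
  n <- sum(ev$time >= interval[1] & ev$time <= interval[2])
  structure(list(frequency_hz = n / (2 * diff(interval)), n_events = n,
                 interval = interval),
            class = "thrash_estimate")
}

#' @export
print.thrash_estimate <- function(x, ...) {
  cat(sprintf("<thrash_estimate> %.3f Hz (%d bend events over [%g, %g] s)\n",
              x$frequency_hz, x$n_events, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Count body bends in an interval
#'
#' The basal slowing assay counts body bends of animals persisting from 60
#' to 120 s on or off a bacterial lawn; this returns the [detect_bends()]
#' event count in that interval.
#'
#' @inheritParams thrash_frequency
#' @param interval `c(start, end)` in s, default the 60-120 s scoring window.
#' @return integer bend count.
#' @export
count_body_bends <- function(p, interval = c(60, 120), theta_c = 45,
                             hysteresis = 10) {
  stopifnot(inherits(p, "posture_trace"), length(interval) == 2L,
            interval[2] > interval[1])
  if (min(p$time) > interval[1] || max(p$time) < interval[2])
    stop("`interval` must lie within the trace", call. = FALSE)
  ev <- detect_bends(p, theta_c, hysteresis)
  sum(ev$time >= interval[1] & ev$time <= interval[2])
}
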