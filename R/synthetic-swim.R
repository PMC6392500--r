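#' Posture trace
#'
#' Uniformly sampled signed midbody bend-angle series, the substrate for
#' thrash, paralysis and body-bend scoring.
#'
#' @param time sample times, s (uniform; jitter under 1% of the interval).
#' @param bend_angle signed midbody bend angle, degrees.
#' @param sample_rate Hz; inferred from `time` when omitted.
#' @return an object of class `posture_trace` (a data.frame with columns
#'   `time`, `bend_angle` and attribute `sample_rate`).
#' @export
posture_trace <- function(time, bend_angle, sample_rate = NULL) {
  stopifnot(is.numeric(time), is.numeric(bend_angle),
            length(time) == length(bend_angle), length(time) >= 2L)
  if (!all(is.finite(time)) || !all(is.finite(bend_angle)))
    stop("posture trace values must be finite", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * mean(dt))
    stop("`time` must be uniformly sampled and increasing", call. = FALSE)
  if (is.null(sample_rate)) sample_rate <- 1 / mean(dt)
  structure(data.frame(time = time, bend_angle = bend_angle),
            sample_rate = sample_rate,
            class = c("posture_trace", "data.frame"))
}

#' @export
print.posture_trace <- function(x, ...) {
  cat(sprintf("<posture_trace> %d samples @ %g Hz, %.1f s\n",
              nrow(x), attr(x, "sample_rate"), max(x$time) - min(x$time)))
  invisible(x)
}

#' Parameters of a synthetic swim (thrash) recording
#'
#' The bend angle is `amplitude * sin(2*pi*thrash_freq*t)` plus Gaussian
#' noise. If `paralysis_time` is set, the amplitude ramps linearly to zero
#' over `ramp` seconds starting there and stays at zero after (a real worm
#' does not stop discontinuously).
#'
#' @param sample_rate Hz; must exceed `2 * thrash_freq` (Nyquist).
#' @param duration s; the automated swimming-induced-paralysis assay scores
#'   thrashing over 11 min, so use >= 660 s for that endpoint.
#' @param thrash_freq true swim cycle frequency, Hz (one cycle = one full
#'   left-right-left thrash).
#' @param amplitude degrees (> 0).
#' @param paralysis_time onset of paralysis, s, or `NA` for none.
#' @param noise_sd Gaussian angle noise sd, degrees.
#' @param ramp amplitude ramp-down duration at paralysis, s.
#' @return an object of class `swim_params`.
#' @export
swim_params <- function(sample_rate = 20, duration = 660, thrash_freq = 1,
                        amplitude = 60, paralysis_time = NA, noise_sd = 0,
                        ramp = 2) {
  check_pos(sample_rate, "sample_rate"); check_pos(duration, "duration")
  check_pos(thrash_freq, "thrash_freq"); check_pos(amplitude, "amplitude")
  check_pos(noise_sd, "noise_sd", strict = FALSE); check_pos(ramp, "ramp")
  if (sample_rate < 2 * thrash_freq)
    stop("`sample_rate` below the Nyquist rate 2 * thrash_freq: ",
         "the thrash cycle would alias", call. = FALSE)
  if (!is.na(paralysis_time) &&
      (paralysis_time < 0 || paralysis_time > duration))
    stop("`paralysis_time` must lie in [0, duration] (or NA)", call. = FALSE)
  structure(list(sample_rate = sample_rate, duration = duration,
                 thrash_freq = thrash_freq, amplitude = amplitude,
                 paralysis_time = paralysis_time, noise_sd = noise_sd,
                 ramp = ramp),
            class = "swim_params")
}

swim_envelope <- function(params, t) {
  if (is.na(params$paralysis_time)) return(rep(params$amplitude, length(t)))
  frac <- pmin(1, pmax(0, (t - params$paralysis_time) / params$ramp))
  params$amplitude * (1 - frac)
}

#' Simulate swim bend-angle traces with ground truth
#'
#' @param params a [swim_params()], or a list of them (one per worm,
#'   recycled to `n_worms`).
#' @param n_worms number of traces.
#' @param seed integer seed.
#' @return a list of `n_worms` elements, each a list with `trace` (a
#'   [posture_trace()]) and `truth` (`thrash_freq`, `paralysis_time`,
#'   `params`).
#' @examples
#' tr <- gen_swim_traces(swim_params(duration = 30), n_worms = 2, seed = 1)
#' tr[[1]]$trace
#' @export
gen_swim_traces <- function(params, n_worms = 1L, seed) {
  if (inherits(params, "swim_params")) params <- list(params)
  stopifnot(all(vapply(params, inherits, TRUE, "swim_params")))
  params <- rep_len(params, n_worms)
  seeds <- derive_seeds(seed, n_worms)
  lapply(seq_len(n_worms), function(w) {
    p <- params[[w]]
    t <- seq(0, p$duration, by = 1 / p$sample_rate)
    angle <- swim_envelope(p, t) * sin(2 * pi * p$thrash_freq * t)
    if (p$noise_sd > 0) {
      set.seed(seeds[w])
      angle <- angle + stats::rnorm(length(t), 0, p$noise_sd)
    }
    list(trace = posture_trace(t, angle, p$sample_rate),
         truth = list(thrash_freq = p$thrash_freq,
                      paralysis_time = p$paralysis_time, params = p))
  })
}
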