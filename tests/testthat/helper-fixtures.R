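# brute-force oracle for decile background subtraction: full sort, explicit
# decile mean, no shortcuts shared with the implementation
brute_force_F <- function(px, frac = 0.10, literal = FALSE) {
  k <- max(1L, floor(frac * length(px)))
  faint <- sort(px)[seq_len(k)]
  if (literal) sum(px) - sum(faint) else sum(px) - length(px) * mean(faint)
}

# a frame holding one symmetric Gaussian spot (0-based center coordinates)
gaussian_frame <- function(nrow = 41, ncol = 41, center = c(20, 20),
                           sigma = 3, amp = 100, bg = 0) {
  r <- seq_len(nrow) - 1; c <- seq_len(ncol) - 1
  amp * outer(exp(-(r - center[1])^2 / (2 * sigma^2)),
              exp(-(c - center[2])^2 / (2 * sigma^2))) + bg
}

# Wilson interval evaluated from the closed form, written out independently
wilson_oracle <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(center - half, center + half)
}

# sinusoidal posture trace
sine_trace <- function(freq, duration, amplitude = 60, sample_rate = 20,
                       noise_sd = 0, seed = NULL) {
  t <- seq(0, duration, by = 1 / sample_rate)
  a <- amplitude * sin(2 * pi * freq * t)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    a <- a + rnorm(length(t), 0, noise_sd)
  }
  posture_trace(t, a, sample_rate)
}

# dominant frequency by periodogram (FFT), an oracle independent of
# the bend-counting estimator
periodogram_peak <- function(trace) {
  x <- trace$bend_angle - mean(trace$bend_angle)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_len(n) - 1) * attr(trace, "sample_rate") / n
  half <- 2:floor(n / 2)
  fr[half][which.max(sp[half])]
}
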