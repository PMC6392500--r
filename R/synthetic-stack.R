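#' Two-channel fluorescence stack
#'
#' Container for a time-ordered pair of image series (cyan = CFP donor,
#' yellow = YFP acceptor) from a ratiometric recording. Pixel coordinates are
#' 0-based `(row, col)` with pixel centers at integer coordinates.
#'
#' @param cyan,yellow numeric arrays `rows x cols x frames`, intensities >= 0
#'   (arbitrary units / camera counts).
#' @param frame_rate frames per second per channel (> 0).
#' @return an object of class `two_channel_stack`.
#' @export
two_channel_stack <- function(cyan, yellow, frame_rate) {
  stopifnot(is.array(cyan), is.array(yellow), length(dim(cyan)) == 3L,
            identical(dim(cyan), dim(yellow)))
  check_pos(frame_rate, "frame_rate")
  if (min(cyan) < 0 || min(yellow) < 0)
    stop("stack intensities must be non-negative", call. = FALSE)
  structure(list(cyan = cyan, yellow = yellow, frame_rate = frame_rate),
            class = "two_channel_stack")
}

#' @export
print.two_channel_stack <- function(x, ...) {
  d <- dim(x$cyan)
  cat(sprintf("<two_channel_stack> %d x %d px, %d frames @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate))
  invisible(x)
}

#' @export
dim.two_channel_stack <- function(x) dim(x$cyan)

n_frames <- function(stack) dim(stack$cyan)[3]

#' Parameters of a synthetic calcium-imaging recording
#'
#' Describes one cell (a 2-D Gaussian fluorescent spot, sd = `cell_radius`
#' pixels) drifting along `cell_path`, with a single calcium transient that
#' multiplies the true YFP/CFP ratio by `1 + dRR0(t)/100`. The transient has
#' a double-exponential time course (rise then decay) normalized to peak at
#' `transient_peak_dRR0` percent. The acceptor channel receives a fraction
#' `alpha_true` of the donor signal (spectral bleed-through); both channels
#' sit on a uniform background and are corrupted by Poisson shot noise plus
#' Gaussian read noise.
#'
#' @param frame_rate Hz (> 0); recordings in the emulated assay run at 10 Hz.
#' @param duration recording length, s.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param cell_path `frames x 2` matrix of true centroid `(row, col)` in
#'   0-based pixel coordinates, or `NULL` for a stationary cell at the image
#'   center. Convenience: a length-2 numeric `c(d_row, d_col)` is read as a
#'   constant per-frame drift from the center.
#' @param cell_radius Gaussian sd of the spot, pixels.
#' @param baseline_Fc,baseline_Fy peak photons/pixel of the donor (CFP) and
#'   acceptor (YFP) signal at the spot center, before the transient. The
#'   defaults give the photon budget of EM-CCD imaging of a bright cell
#'   body at 10 Hz, where shot noise on the frame-wise ratio is a fraction
#'   of a percent — well below the smallest response amplitudes the assay
#'   resolves.
#' @param transient_onset transient start time, s (within the recording;
#'   defaults to 10 s, or a third of short recordings).
#' @param transient_peak_dRR0 true peak ratio change, percent (0 for a
#'   no-transient null recording).
#' @param rise_tau,decay_tau transient rise and decay time constants, s.
#' @param alpha_true bleed-through fraction of donor signal into the acceptor
#'   channel (0 <= alpha_true < 1).
#' @param bg_level uniform background, photons/pixel.
#' @param read_noise_sd Gaussian read noise sd, photons.
#' @return an object of class `stack_params`.
#' @export
stack_params <- function(frame_rate = 10, duration = 30,
                         image_shape = c(64L, 64L), cell_path = NULL,
                         cell_radius = 3, baseline_Fc = 1000,
                         baseline_Fy = 1000,
                         transient_onset = min(10, duration / 3),
                         transient_peak_dRR0 = 30, rise_tau = 0.5,
                         decay_tau = 3, alpha_true = 0, bg_level = 100,
                         read_noise_sd = 3) {
  check_pos(frame_rate, "frame_rate"); check_pos(duration, "duration")
  check_pos(cell_radius, "cell_radius")
  check_pos(baseline_Fc, "baseline_Fc"); check_pos(baseline_Fy, "baseline_Fy")
  check_pos(rise_tau, "rise_tau"); check_pos(decay_tau, "decay_tau")
  check_pos(bg_level, "bg_level", strict = FALSE)
  check_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
  if (!is.numeric(transient_onset) || transient_onset < 0 ||
      transient_onset > duration)
    stop("`transient_onset` must lie within [0, duration]", call. = FALSE)
  if (!is.numeric(alpha_true) || alpha_true < 0 || alpha_true >= 1)
    stop("`alpha_true` must satisfy 0 <= alpha_true < 1", call. = FALSE)
  if (!is.numeric(transient_peak_dRR0) || !is.finite(transient_peak_dRR0) ||
      transient_peak_dRR0 < 0)
    stop("`transient_peak_dRR0` must be a non-negative percentage",
         call. = FALSE)
  nf <- round(duration * frame_rate)
  center <- (image_shape - 1) / 2
  if (is.null(cell_path)) {
    cell_path <- matrix(rep(center, each = nf), ncol = 2)
  } else if (is.numeric(cell_path) && is.null(dim(cell_path)) &&
             length(cell_path) == 2L) {
    cell_path <- cbind(center[1] + (seq_len(nf) - 1) * cell_path[1],
                       center[2] + (seq_len(nf) - 1) * cell_path[2])
  }
  cell_path <- as.matrix(cell_path)
  if (nrow(cell_path) != nf || ncol(cell_path) != 2L)
    stop("`cell_path` must be a frames x 2 matrix", call. = FALSE)
  margin <- 3 * cell_radius
  if (any(cell_path[, 1] < margin) || any(cell_path[, 1] > image_shape[1] - 1 - margin) ||
      any(cell_path[, 2] < margin) || any(cell_path[, 2] > image_shape[2] - 1 - margin))
    stop("cell leaves the frame: path must keep 3*cell_radius from the border",
         call. = FALSE)
  structure(list(frame_rate = frame_rate, duration = duration,
                 image_shape = as.integer(image_shape), cell_path = cell_path,
                 cell_radius = cell_radius, baseline_Fc = baseline_Fc,
                 baseline_Fy = baseline_Fy, transient_onset = transient_onset,
                 transient_peak_dRR0 = transient_peak_dRR0,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 alpha_true = alpha_true, bg_level = bg_level,
                 read_noise_sd = read_noise_sd, n_frames = nf),
            class = "stack_params")
}

#' True percent ratio change of a synthetic transient
#'
#' Double-exponential waveform `(1 - exp(-s/rise_tau)) * exp(-s/decay_tau)`
#' for time-since-onset `s`, normalized so its analytic maximum equals
#' `transient_peak_dRR0`.
#'
#' @param params a [stack_params()].
#' @param t times, s (default: the frame times).
#' @return percent ratio change at each `t`.
#' @export
transient_dRR0 <- function(params,
                           t = (seq_len(params$n_frames) - 1) / params$frame_rate) {
  s <- t - params$transient_onset
  f <- ifelse(s <= 0, 0,
              (1 - exp(-s / params$rise_tau)) * exp(-s / params$decay_tau))
  s_peak <- params$rise_tau *
    log((params$rise_tau + params$decay_tau) / params$rise_tau)
  f_max <- (1 - exp(-s_peak / params$rise_tau)) *
    exp(-s_peak / params$decay_tau)
  params$transient_peak_dRR0 * f / f_max
}

# Noiseless expected photon images for one frame; the Gaussian spot is
# separable so each frame is an outer product of row and column profiles.
render_frame <- function(params, frame, dRR0) {
  rows <- seq_len(params$image_shape[1]) - 1
  cols <- seq_len(params$image_shape[2]) - 1
  ctr <- params$cell_path[frame, ]
  pr <- exp(-(rows - ctr[1])^2 / (2 * params$cell_radius^2))
  pc <- exp(-(cols - ctr[2])^2 / (2 * params$cell_radius^2))
  spot <- outer(pr, pc)
  cfp_sig <- params$baseline_Fc * spot
  yfp_sig <- params$baseline_Fy * (1 + dRR0 / 100) * spot
  list(cyan = cfp_sig + params$bg_level,
       yellow = yfp_sig + params$alpha_true * cfp_sig + params$bg_level)
}

#' Simulate a two-channel calcium-imaging stack with ground truth
#'
#' Renders the recording described by `params` (see [stack_params()]) and,
#' unless `noiseless = TRUE`, applies per-pixel Poisson shot noise plus
#' Gaussian read noise and rounds to non-negative integer camera counts.
#'
#' @param params a [stack_params()].
#' @param seed integer seed (ignored when `noiseless = TRUE`).
#' @param noiseless set `TRUE` for the exact expected-photon images (used for
#'   validation; values are then non-integer).
#' @return a `synthetic_stack`: list with `stack` (a
#'   [two_channel_stack()]) and `truth` (list: `cell_path`, `dRR0` percent
#'   trace per frame, `alpha_true`, `params`).
#' @examples
#' syn <- gen_image_stack(stack_params(duration = 5), seed = 1)
#' syn$stack
#' @export
gen_image_stack <- function(params, seed = NULL, noiseless = FALSE) {
  stopifnot(inherits(params, "stack_params"))
  nf <- params$n_frames
  dRR0 <- transient_dRR0(params)
  sh <- params$image_shape
  cyan <- array(0, c(sh, nf))
  yellow <- array(0, c(sh, nf))
  for (f in seq_len(nf)) {
    fr <- render_frame(params, f, dRR0[f])
    cyan[, , f] <- fr$cyan
    yellow[, , f] <- fr$yellow
  }
  if (!noiseless) {
    if (is.null(seed)) stop("`seed` is required for a noisy render",
                            call. = FALSE)
    set.seed(derive_seeds(seed, 1L))
    n <- length(cyan)
    cyan <- array(pmax(0, round(stats::rpois(n, cyan) +
                                  stats::rnorm(n, 0, params$read_noise_sd))),
                  dim = c(sh, nf))
    yellow <- array(pmax(0, round(stats::rpois(n, yellow) +
                                    stats::rnorm(n, 0, params$read_noise_sd))),
                    dim = c(sh, nf))
  }
  structure(list(stack = two_channel_stack(cyan, yellow, params$frame_rate),
                 truth = list(cell_path = params$cell_path, dRR0 = dRR0,
                              alpha_true = params$alpha_true,
                              params = params)),
            class = "synthetic_stack")
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat("<synthetic_stack> true peak dRR0 =",
      sprintf("%.1f%%", max(x$truth$dRR0)), "\n")
  print(x$stack)
  invisible(x)
}
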