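#' Rectangular region of interest
#'
#' A rectangle drawn around the cell body, described by its center (0-based
#' `(row, col)`, pixel centers at integer coordinates) and half extents. The
#' pixels of the ROI are all pixels whose integer coordinates lie within the
#' half extents of the center.
#'
#' @param center numeric `(row, col)`.
#' @param half_height,half_width half extents in pixels.
#' @return an object of class `roi`.
#' @export
roi <- function(center, half_height, half_width = half_height) {
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  check_pos(half_height, "half_height"); check_pos(half_width, "half_width")
  structure(list(center = as.numeric(center), half_height = half_height,
                 half_width = half_width), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> center (%.2f, %.2f), half extents %g x %g px\n",
              x$center[1], x$center[2], x$half_height, x$half_width))
  invisible(x)
}

# Integer pixel index ranges of an ROI within an image (1-based for R
# subsetting). Errors if the rectangle leaves the image or holds < min_px
# pixels, so the faintest-decile background sample is never empty.
roi_indices <- function(roi, img_dim, min_px = 10L) {
  r0 <- ceiling(roi$center[1] - roi$half_height)
  r1 <- floor(roi$center[1] + roi$half_height)
  c0 <- ceiling(roi$center[2] - roi$half_width)
  c1 <- floor(roi$center[2] + roi$half_width)
  if (r0 < 0 || c0 < 0 || r1 > img_dim[1] - 1 || c1 > img_dim[2] - 1)
    stop("ROI extends outside the image", call. = FALSE)
  rows <- (r0:r1) + 1L
  cols <- (c0:c1) + 1L
  if (length(rows) * length(cols) < min_px)
    stop(sprintf("ROI holds %d pixels; at least %d required",
                 length(rows) * length(cols), min_px), call. = FALSE)
  list(rows = rows, cols = cols)
}

# Clamp an ROI center so the rectangle stays fully inside the image.
clip_roi_center <- function(center, roi, img_dim) {
  c(min(max(center[1], roi$half_height), img_dim[1] - 1 - roi$half_height),
    min(max(center[2], roi$half_width), img_dim[2] - 1 - roi$half_width))
}

# mean of the k faintest pixel values, k = max(1, floor(frac * N)); partial
# sort keeps this O(N) per frame
faintest_decile_mean <- function(px, frac = 0.10) {
  k <- max(1L, floor(frac * length(px)))
  mean(sort(px, partial = k)[seq_len(k)])
}

#' Background-subtracted ROI fluorescence
#'
#' Fluorescence intensity `F` of one frame's ROI: the difference between the
#' sum of pixel intensities and the faintest 10% of pixels (the background)
#' within the ROI. Under the default scaled interpretation the decile mean is
#' treated as the per-pixel background estimate and removed over the full ROI
#' area: `F = sum(ROI) - N * mean(faintest k)`, `k = max(1, floor(0.10 N))`.
#' `literal = TRUE` instead subtracts only the decile's own sum,
#' `F = sum(ROI) - sum(faintest k)`, for comparability with a strictly
#' literal reading of that rule.
#'
#' `F` can be negative in pathological frames; it is reported, never clipped.
#'
#' @param frame 2-D numeric pixel matrix.
#' @param roi an [roi()].
#' @param bg_fraction fraction of ROI pixels treated as background.
#' @param literal use the literal decile-sum subtraction (see above).
#' @return fluorescence `F`, arbitrary units.
#' @examples
#' fr <- matrix(c(rep(110, 90), rep(10, 10)), 10, 10)
#' roi_fluorescence(fr, roi(c(4.5, 4.5), 4.6))  # 9000
#' @export
roi_fluorescence <- function(frame, roi, bg_fraction = 0.10,
                             literal = FALSE) {
  stopifnot(is.matrix(frame), inherits(roi, "roi"))
  idx <- roi_indices(roi, dim(frame))
  px <- as.vector(frame[idx$rows, idx$cols])
  k <- max(1L, floor(bg_fraction * length(px)))
  faint <- sort(px, partial = k)[seq_len(k)]
  if (literal) sum(px) - sum(faint)
  else sum(px) - length(px) * mean(faint)
}

#' Track an ROI across a recording by center of mass
#'
#' For every frame after the first, the ROI is shifted to the new position of
#' the cell's center of mass: the intensity-weighted centroid of the summed
#' two-channel image, locally background-subtracted with the same
#' faintest-decile rule, computed over the previous frame's ROI. One update
#' per frame (no iteration); ROI dimensions stay constant and the path is
#' clipped so the rectangle never leaves the image.
#'
#' @param stack a [two_channel_stack()].
#' @param initial_roi the [roi()] for frame 1.
#' @param bg_fraction background fraction for the local subtraction.
#' @return an `roi_path`: `frames x 2` matrix of centers `(row, col)` with
#'   attributes `half_height` and `half_width`.
#' @export
track_roi <- function(stack, initial_roi, bg_fraction = 0.10) {
  stopifnot(inherits(stack, "two_channel_stack"), inherits(initial_roi, "roi"))
  nf <- n_frames(stack)
  d <- dim(stack$cyan)[1:2]
  path <- matrix(NA_real_, nf, 2, dimnames = list(NULL, c("row", "col")))
  path[1, ] <- initial_roi$center
  cur <- initial_roi
  roi_indices(cur, d)  # validate for frame 1
  for (f in seq_len(nf)[-1]) {
    idx <- roi_indices(cur, d)
    sub <- stack$cyan[idx$rows, idx$cols, f] +
      stack$yellow[idx$rows, idx$cols, f]
    w <- sub - faintest_decile_mean(as.vector(sub), bg_fraction)
    tot <- sum(w)
    if (tot <= 0)
      stop(sprintf("tracking lost at frame %d: ROI intensity <= 0 after background subtraction", f),
           call. = FALSE)
    rows0 <- idx$rows - 1L  # back to 0-based coordinates
    cols0 <- idx$cols - 1L
    ctr <- c(sum(rowSums(w) * rows0), sum(colSums(w) * cols0)) / tot
    ctr <- clip_roi_center(ctr, cur, d)
    path[f, ] <- ctr
    cur <- roi(ctr, cur$half_height, cur$half_width)
  }
  structure(path, half_height = initial_roi$half_height,
            half_width = initial_roi$half_width,
            class = c("roi_path", "matrix", "array"))
}

#' @export
print.roi_path <- function(x, ...) {
  cat(sprintf("<roi_path> %d frames, half extents %g x %g px\n",
              nrow(x), attr(x, "half_height"), attr(x, "half_width")))
  invisible(x)
}

roi_at <- function(path, frame) {
  roi(path[frame, ], attr(path, "half_height"), attr(path, "half_width"))
}

#' Bleed-through-corrected ratio trace of a tracked cell
#'
#' Per frame, computes background-subtracted `F_cyan` and raw `F_yellow` with
#' [roi_fluorescence()], corrects the acceptor channel for donor
#' bleed-through (`F_yellow - alpha * F_cyan`), and forms the fluorescence
#' ratio `R = F_yellow / F_cyan`. The percent ratio change is taken against
#' `R0`, the average `R` within the first `baseline_window` seconds of
#' recording: `dRR0 = 100 * (R - R0) / R0`. The baseline frame count is
#' `round(baseline_window * frame_rate)` (30 frames at 10 Hz with the
#' default 3 s window).
#'
#' Frames with `F_cyan <= 0` have undefined `R`, propagated as `NA`; a
#' non-positive `F_cyan` inside the baseline, or a non-positive `R0`, is an
#' error because no percent change is defined against such a baseline.
#'
#' @param stack a [two_channel_stack()].
#' @param roi_path an `roi_path` from [track_roi()], or a single [roi()] for
#'   a stationary analysis.
#' @param alpha bleed-through coefficient, `0 <= alpha < 1` (0 = no
#'   correction).
#' @param baseline_window baseline duration, s.
#' @param bg_fraction,literal passed to [roi_fluorescence()].
#' @return a `ratio_trace`: data.frame with columns `time`, `F_cyan`,
#'   `F_yellow` (corrected), `R`, `dRR0`, plus attributes `R0`, `alpha`,
#'   `baseline_frames`, `frame_rate`, `roi_path`.
#' @examples
#' syn <- gen_image_stack(stack_params(duration = 8, transient_onset = 4),
#'                        seed = 1)
#' path <- track_roi(syn$stack, roi(syn$truth$cell_path[1, ], 9))
#' tr <- compute_ratio_trace(syn$stack, path, baseline_window = 3)
#' max(tr$dRR0)
#' @export
compute_ratio_trace <- function(stack, roi_path, alpha = 0,
                                baseline_window = 3,
                                bg_fraction = 0.10, literal = FALSE) {
  stopifnot(inherits(stack, "two_channel_stack"))
  if (inherits(roi_path, "roi")) {
    nf <- n_frames(stack)
    roi_path <- structure(matrix(rep(roi_path$center, each = nf), nf, 2),
                          half_height = roi_path$half_height,
                          half_width = roi_path$half_width,
                          class = c("roi_path", "matrix", "array"))
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("`alpha` must satisfy 0 <= alpha < 1", call. = FALSE)
  nf <- n_frames(stack)
  stopifnot(nrow(roi_path) == nf)
  if (baseline_window > nf / stack$frame_rate)
    stop("`baseline_window` exceeds the recording duration", call. = FALSE)
  fc <- fy <- numeric(nf)
  for (f in seq_len(nf)) {
    r <- roi_at(roi_path, f)
    fc[f] <- roi_fluorescence(stack$cyan[, , f], r, bg_fraction, literal)
    fy[f] <- roi_fluorescence(stack$yellow[, , f], r, bg_fraction, literal)
  }
  fy <- fy - alpha * fc
  R <- ifelse(fc > 0, fy / fc, NA_real_)
  nb <- round(baseline_window * stack$frame_rate)
  if (any(fc[seq_len(nb)] <= 0))
    stop("F_cyan <= 0 within the baseline window: baseline undefined",
         call. = FALSE)
  R0 <- mean(R[seq_len(nb)])
  if (!is.finite(R0) || R0 <= 0)
    stop("degenerate baseline: R0 <= 0", call. = FALSE)
  structure(data.frame(time = (seq_len(nf) - 1) / stack$frame_rate,
                       F_cyan = fc, F_yellow = fy, R = R,
                       dRR0 = 100 * (R - R0) / R0),
            R0 = R0, alpha = alpha, baseline_frames = nb,
            frame_rate = stack$frame_rate, roi_path = roi_path,
            class = c("ratio_trace", "data.frame"))
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("<ratio_trace> %d frames @ %g Hz; R0 = %.4f (first %d frames), alpha = %g\n",
              nrow(x), attr(x, "frame_rate"), attr(x, "R0"),
              attr(x, "baseline_frames"), attr(x, "alpha")))
  cat(sprintf("  dRR0 range [%.2f, %.2f]%%\n",
              min(x$dRR0, na.rm = TRUE), max(x$dRR0, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.ratio_trace <- function(x, ...) {
  graphics::plot(x$time, x$dRR0, type = "l", xlab = "time (s)",
                 ylab = expression(paste(Delta, "R/R0 (%)")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Classify a trace as responder / non-responder to a stimulus
#'
#' The response window runs from stimulus onset to
#' `onset + stimulus_duration + window_after`. The cell is called a responder
#' when the peak percent ratio change inside the window exceeds
#' `max(threshold_k * sigma_baseline, floor_pct)`, where `sigma_baseline` is
#' the standard deviation of `dRR0` over the baseline frames. Stimulus
#' durations follow the assay convention: 1 s for the firm nose press, 3.7 s
#' for the gentle food-mimicking buzz.
#'
#' @param trace a `ratio_trace` from [compute_ratio_trace()].
#' @param stimulus_onset s from recording start (must not precede the end of
#'   the baseline window).
#' @param stimulus_kind `"press"` (1 s) or `"buzz"` (3.7 s).
#' @param threshold_k baseline-sd multiplier of the response threshold.
#' @param floor_pct absolute floor of the threshold, percent.
#' @param window_after extra window after stimulus offset, s.
#' @param smooth_frames width (frames) of the centered moving average
#'   applied to `dRR0` before peak extraction and baseline-sd estimation;
#'   standard low-pass for shot-noise-limited ratio traces. The default
#'   (5 frames = 0.5 s at 10 Hz, about one rise time constant of the
#'   indicator) suppresses frame noise without clipping the transient
#'   peak. Use 1 for the raw trace.
#' @return a `response_call`: list with `responder`, `peak_dRR0`,
#'   `peak_time`, `stimulus_kind`, `stimulus_onset`, `stimulus_duration`,
#'   `response_window`, `sigma_baseline`, `threshold`.
#' @export
call_response <- function(trace, stimulus_onset,
                          stimulus_kind = c("press", "buzz"),
                          threshold_k = 3, floor_pct = 5, window_after = 10,
                          smooth_frames = 5L) {
  stopifnot(inherits(trace, "ratio_trace"))
  stimulus_kind <- match.arg(stimulus_kind)
  stimulus_duration <- switch(stimulus_kind, press = 1.0, buzz = 3.7)
  nb <- attr(trace, "baseline_frames")
  fr <- attr(trace, "frame_rate")
  if (stimulus_onset < nb / fr)
    stop("`stimulus_onset` must not precede the end of the baseline window",
         call. = FALSE)
  w_end <- stimulus_onset + stimulus_duration + window_after
  t_max <- max(trace$time)
  if (w_end > t_max) {
    warning("response window extends past the recording end; clipped",
            call. = FALSE)
    w_end <- t_max
  }
  in_win <- trace$time >= stimulus_onset & trace$time <= w_end
  d <- trace$dRR0
  if (smooth_frames > 1L) {
    sm <- as.numeric(stats::filter(d, rep(1 / smooth_frames, smooth_frames),
                                   sides = 2))
    d <- ifelse(is.na(sm), d, sm)  # edges keep the raw value
  }
  sigma <- stats::sd(d[seq_len(nb)])
  thr <- max(threshold_k * sigma, floor_pct)
  peak <- max(d[in_win], na.rm = TRUE)
  structure(list(responder = peak > thr, peak_dRR0 = peak,
                 peak_time = trace$time[in_win][which.max(trace$dRR0[in_win])],
                 stimulus_kind = stimulus_kind,
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 response_window = c(stimulus_onset, w_end),
                 sigma_baseline = sigma, threshold = thr,
                 threshold_k = threshold_k, floor_pct = floor_pct,
                 smooth_frames = smooth_frames),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("<response_call> %s %s: peak dRR0 = %.2f%% at %.1f s (threshold %.2f%%)\n",
              x$stimulus_kind,
              if (x$responder) "RESPONDER" else "non-responder",
              x$peak_dRR0, x$peak_time, x$threshold))
  invisible(x)
}
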