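test_that("roi_fluorescence matches the brute-force decile oracle", {
  set.seed(101)
  for (i in 1:200) {
    nr <- sample(4:15, 1); nc <- sample(4:15, 1)
    if (nr * nc < 10) next
    frame <- matrix(rexp(nr * nc, 1 / 50), nr, nc)
    r <- roi(c((nr - 1) / 2, (nc - 1) / 2), nr / 2, nc / 2)
    expect_identical(roi_fluorescence(frame, r),
                     brute_force_F(as.vector(frame)))
    expect_identical(roi_fluorescence(frame, r, literal = TRUE),
                     brute_force_F(as.vector(frame), literal = TRUE))
  }
})

test_that("worked 100-pixel example: 90 bright + 10 faint pixels", {
  frame <- matrix(c(rep(110, 90), rep(10, 10)), 10, 10)
  r <- roi(c(4.5, 4.5), 5)
  # k = 10, bg = 10: scaled F = (90*110 + 10*10) - 100*10 = 9000
  expect_equal(roi_fluorescence(frame, r), 9000)
  # literal mode subtracts only the decile's own sum
  expect_equal(roi_fluorescence(frame, r, literal = TRUE),
               (90 * 110 + 10 * 10) - 10 * 10)
})

test_that("uniform and degenerate ROIs behave as the construction dictates", {
  u <- matrix(7, 10, 10)
  expect_equal(roi_fluorescence(u, roi(c(4.5, 4.5), 5)), 0)
  z <- matrix(0, 10, 10)
  expect_equal(roi_fluorescence(z, roi(c(4.5, 4.5), 5)), 0)
  expect_error(roi_fluorescence(u, roi(c(1, 1), 1)), "pixels")
  expect_error(roi_fluorescence(u, roi(c(0, 0), 6)), "outside")
})

test_that("F is invariant to a constant pixel offset", {
  set.seed(5)
  frame <- matrix(rpois(400, 80), 20, 20)
  r <- roi(c(9.5, 9.5), 6)
  f0 <- roi_fluorescence(frame, r)
  expect_equal(roi_fluorescence(frame + 123.4, r), f0, tolerance = 1e-9)
})

test_that("tracking holds a stationary symmetric spot still", {
  frames <- replicate(20, gaussian_frame(), simplify = FALSE)
  cyan <- array(unlist(frames), c(41, 41, 20))
  stack <- two_channel_stack(cyan, cyan, 10)
  path <- track_roi(stack, roi(c(20, 20), 8))
  expect_lt(max(abs(path - 20)), 0.05)
})

test_that("two equal off-center lobes give the geometric midpoint", {
  fr <- gaussian_frame(center = c(20, 15), sigma = 2) +
    gaussian_frame(center = c(20, 25), sigma = 2)
  cyan <- array(rep(fr, 3), c(41, 41, 3))
  stack <- two_channel_stack(cyan, cyan, 10)
  path <- track_roi(stack, roi(c(20, 20), 10))
  expect_lt(max(abs(path[, 1] - 20)), 0.05)
  expect_lt(max(abs(path[, 2] - 20)), 0.05)
})

test_that("tracking recovers a drifting spot and errors on an empty frame", {
  p <- stack_params(duration = 6, image_shape = c(64L, 96L),
                    cell_path = c(0, 0.5), transient_peak_dRR0 = 0)
  syn <- gen_image_stack(p, seed = 21)
  path <- track_roi(syn$stack, roi(syn$truth$cell_path[1, ], 6))
  rms <- sqrt(mean((path - syn$truth$cell_path)^2))
  expect_lt(rms, 0.5)

  dark <- two_channel_stack(array(0, c(20, 20, 3)), array(0, c(20, 20, 3)), 10)
  expect_error(track_roi(dark, roi(c(9.5, 9.5), 5)), "frame 2")
})

test_that("ratio trace reproduces hand-computed bleed-through arithmetic", {
  # ROI = whole 10x10 frame, 90 bright + 10 faint pixels so F is exact:
  # F_cyan = 90*(60-10) = 4500 every frame; raw F_yellow = 90*(v-10)
  mk <- function(v) matrix(c(rep(v, 90), rep(10, 10)), 10, 10)
  cyan <- array(rep(mk(60), 4), c(10, 10, 4))
  # baseline frames: raw Fy = 6750 -> corrected 6750 - 0.5*4500 = 4500, R = 1
  # final frame:     raw Fy = 9000 -> corrected 9000 - 2250 = 6750, R = 1.5
  yellow <- array(c(mk(85), mk(85), mk(85), mk(110)), c(10, 10, 4))
  stack <- two_channel_stack(cyan, yellow, frame_rate = 1)
  tr <- compute_ratio_trace(stack, roi(c(4.5, 4.5), 5), alpha = 0.5,
                            baseline_window = 3)
  expect_equal(tr$F_cyan, rep(4500, 4))
  expect_equal(tr$F_yellow[4], 6750)
  expect_equal(attr(tr, "R0"), 1)
  expect_equal(tr$R[4], 1.5)
  expect_equal(tr$dRR0, c(0, 0, 0, 50))
})

test_that("constant channels give a flat 0% trace and 30 baseline frames at 10 Hz", {
  fr <- gaussian_frame(bg = 5)
  cyan <- array(rep(fr, 40), c(41, 41, 40))
  stack <- two_channel_stack(cyan, 2 * cyan, 10)
  tr <- compute_ratio_trace(stack, roi(c(20, 20), 8), baseline_window = 3)
  expect_equal(attr(tr, "baseline_frames"), 30)
  expect_equal(tr$dRR0, rep(0, 40), tolerance = 1e-10)
})

test_that("R and dRR0 are invariant to a common positive rescaling", {
  p <- stack_params(duration = 5, transient_onset = 2)
  syn <- gen_image_stack(p, noiseless = TRUE)
  r <- roi(syn$truth$cell_path[1, ], 6)
  tr1 <- compute_ratio_trace(syn$stack, r, baseline_window = 1)
  s2 <- two_channel_stack(3.7 * syn$stack$cyan, 3.7 * syn$stack$yellow, 10)
  tr2 <- compute_ratio_trace(s2, r, baseline_window = 1)
  expect_equal(tr2$R, tr1$R, tolerance = 1e-12)
  expect_equal(tr2$dRR0, tr1$dRR0, tolerance = 1e-9)
})

test_that("baseline errors are raised, not silently zeroed", {
  cyan <- array(0, c(10, 10, 5)); cyan[5, 5, ] <- 1
  yellow <- array(1, c(10, 10, 5))
  stack <- two_channel_stack(cyan * 0, yellow, 1)
  expect_error(compute_ratio_trace(stack, roi(c(4.5, 4.5), 5),
                                   baseline_window = 2), "baseline")
  expect_error(compute_ratio_trace(two_channel_stack(cyan, yellow, 1),
                                   roi(c(4.5, 4.5), 5),
                                   baseline_window = 10), "duration")
})

test_that("response calls: flat traces are non-responders, stimuli keep their durations", {
  fr <- gaussian_frame(bg = 2)
  cyan <- array(rep(fr, 200), c(41, 41, 200))
  stack <- two_channel_stack(cyan, cyan, 10)
  tr <- compute_ratio_trace(stack, roi(c(20, 20), 8))
  rc <- call_response(tr, 5, "press")
  expect_false(rc$responder)
  expect_equal(rc$peak_dRR0, 0)
  expect_equal(rc$stimulus_duration, 1.0)
  expect_equal(call_response(tr, 5, "buzz")$stimulus_duration, 3.7)
  expect_warning(call_response(tr, 14, "buzz"), "clipped")
  expect_error(call_response(tr, 1, "press"), "baseline")
})

test_that("a synthetic 30% transient is recovered within 10% relative", {
  p <- stack_params(duration = 25, transient_onset = 10,
                    transient_peak_dRR0 = 30)
  syn <- gen_image_stack(p, seed = 31)
  path <- track_roi(syn$stack, roi(syn$truth$cell_path[1, ], 6))
  tr <- compute_ratio_trace(syn$stack, path)
  rc <- call_response(tr, 10, "buzz")
  expect_true(rc$responder)
  expect_lt(abs(rc$peak_dRR0 - 30) / 30, 0.10)
  expect_lt(rc$sigma_baseline, 2)
})

test_that("matching the generator's bleed-through shrinks the recovered-peak bias", {
  biases <- sapply(1:6, function(s) {
    p <- stack_params(duration = 20, transient_onset = 8,
                      transient_peak_dRR0 = 30, alpha_true = 0.3)
    syn <- gen_image_stack(p, seed = 400 + s)
    r <- roi(syn$truth$cell_path[1, ], 6)
    pk <- function(alpha) {
      tr <- compute_ratio_trace(syn$stack, r, alpha = alpha)
      call_response(tr, 8, "buzz", window_after = 8)$peak_dRR0
    }
    c(matched = pk(0.3) - 30, uncorrected = pk(0) - 30)
  })
  expect_lt(abs(mean(biases["matched", ])), abs(mean(biases["uncorrected", ])))
})
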