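test_that("causal moving average computes partial means of past data only", {
  expect_equal(moving_average(c(0, 4, 8, 12, 16), window = 4),
               c(0, 2, 4, 6, 10))
  expect_equal(moving_average(rep(3, 7), window = 4), rep(3, 7))
  x <- rnorm(10)
  expect_equal(moving_average(x, window = 1), x)
  expect_identical(moving_average(numeric(0), 4), numeric(0))
  expect_error(moving_average(1:5, window = 0), ">= 1")
  # na.rm drops sentinels from the window
  expect_equal(moving_average(c(1, Inf, 3), window = 2, na.rm = TRUE),
               c(1, 1, 3))
})

test_that("moving average is causal: truncation never changes the past", {
  set.seed(301)
  x <- rnorm(40)
  full <- moving_average(x, window = 4)
  for (k in c(3, 17, 33)) {
    expect_identical(moving_average(x[1:k], window = 4), full[1:k])
  }
})

test_that("frame integration averages the trailing window", {
  set.seed(302)
  frames <- replicate(6, matrix(rnorm(64), 8, 8), simplify = FALSE)
  expect_identical(integrate_frames(frames, 1), frames[[6]])
  same <- replicate(4, frames[[1]], simplify = FALSE)
  expect_equal(integrate_frames(same, 4), frames[[1]])
  expect_equal(integrate_frames(frames, 4),
               (frames[[3]] + frames[[4]] + frames[[5]] + frames[[6]]) / 4)
  expect_error(integrate_frames(frames, 7), "n >= 1 frames available")
  bad <- c(frames[1:3], list(matrix(0, 4, 4)))
  expect_error(integrate_frames(bad, 4), "dimensions differ")
  # 4-frame integration halves noise sd
  set.seed(303)
  ratios <- replicate(20, {
    fs <- replicate(4, matrix(rnorm(64 * 64), 64, 64), simplify = FALSE)
    sd(integrate_frames(fs, 4)) / sd(fs[[4]])
  })
  expect_equal(mean(ratios), 0.5, tolerance = 0.02)
})

test_that("a simulated focus ramp yields a unimodal graph peaking near focus", {
  spec <- generate_specimen(512, 512, feature_scale = 1, seed = 99)
  opt <- optics_state(magnification = 8, current = 26)
  acq <- acquisition_params(width = 96, height = 96, sampling = "nearest",
                            psf_scale = 6, seed = 304)
  st <- sem_stream(spec, ramp_trajectory(opt, "defocus", -3, 3, 40), acq)
  g <- evaluate_sweep(st$frames, st$meta$defocus, reduction = 2,
                      window = 4, integration = 1)
  gl <- glance(g)
  expect_false(is.na(gl$peak_tick))
  expect_lt(abs(gl$peak_control), 1)
  # smoothing reduces graph variance
  expect_lte(var(g$samples$snr_smooth), var(g$samples$snr_raw))
})

test_that("a constant-defocus stream gives a flat graph with no peak", {
  spec <- generate_specimen(512, 512, feature_scale = 1, seed = 99)
  opt <- optics_state(defocus = 1, magnification = 8, current = 26)
  acq <- acquisition_params(width = 96, height = 96, sampling = "nearest",
                            psf_scale = 6, seed = 305)
  st <- sem_stream(spec, rep(list(opt), 36), acq)
  g <- evaluate_sweep(st$frames, rep(1, 36), reduction = 2, window = 4)
  expect_true(is.na(g$peak_tick))
})

test_that("a stigmator sweep at best focus peaks near zero astigmatism", {
  spec <- generate_specimen(512, 512, feature_scale = 1, seed = 99)
  opt <- optics_state(magnification = 8, current = 26)
  acq <- acquisition_params(width = 96, height = 96, sampling = "nearest",
                            psf_scale = 6, seed = 306)
  st <- sem_stream(spec, ramp_trajectory(opt, "astig_y", -3, 3, 40), acq)
  g <- evaluate_sweep(st$frames, st$meta$astig_y, reduction = 2, window = 4)
  gl <- glance(g)
  expect_false(is.na(gl$peak_tick))
  expect_lt(abs(gl$peak_control), 1)
})

test_that("sweep outputs are causal for a fixed reduction level", {
  spec <- generate_specimen(512, 512, feature_scale = 1, seed = 99)
  opt <- optics_state(magnification = 8, current = 26)
  acq <- acquisition_params(width = 64, height = 64, sampling = "nearest",
                            psf_scale = 6, seed = 307)
  st <- sem_stream(spec, ramp_trajectory(opt, "defocus", -2, 2, 24), acq)
  full <- evaluate_sweep(st$frames, st$meta$defocus, reduction = 2,
                         window = 4, integration = 2)
  for (k in c(8, 15, 21)) {
    part <- evaluate_sweep(st$frames[1:k], st$meta$defocus[1:k], reduction = 2,
                           window = 4, integration = 2)
    keep <- full$samples$tick <= k
    expect_equal(part$samples[, c("tick", "control", "snr_raw", "snr_smooth")],
                 full$samples[keep, c("tick", "control", "snr_raw", "snr_smooth")])
  }
})

test_that("zero-noise samples are sentinels excluded from peak detection", {
  # identical consecutive frames produce Inf SNR samples
  f <- matrix(seq_len(64), 8, 8)
  frames <- replicate(6, f, simplify = FALSE)
  g <- evaluate_sweep(frames, 1:6, reduction = 0, window = 2)
  expect_true(all(g$samples$status == "zero_noise"))
  expect_true(all(is.infinite(g$samples$snr_raw)))
  expect_true(is.na(g$peak_tick))
})

test_that("just-focus detection accepts clean peaks and rejects noise", {
  mkgraph <- function(raw, window = 1) {
    smooth <- moving_average(raw, window)
    structure(list(samples = tibble::tibble(tick = seq_along(raw),
                                            control = seq_along(raw),
                                            snr_raw = raw, snr_smooth = smooth,
                                            status = "ok"),
                   window = window, integration = 1L, level = 0L,
                   metric = "snr", peak_tick = NA_integer_),
              class = "focus_graph")
  }
  # noiseless unimodal parabola: argmax tick
  x <- seq(-1, 1, length.out = 31)
  g <- mkgraph(1 - x^2)
  expect_identical(detect_just_focus(g), 16L)
  # flat noise-only graph: no prominent peak
  set.seed(308)
  flat_hits <- sapply(1:20, function(i) !is.na(detect_just_focus(mkgraph(rnorm(40)))))
  expect_lte(mean(flat_hits), 0.1)
  # explicit prominence override
  expect_identical(detect_just_focus(g, prominence = 2), NA_integer_)
  # fewer than 3 usable samples: none
  expect_identical(detect_just_focus(mkgraph(c(1, 2))), NA_integer_)
})

test_that("covariance-graph mode tracks the same peak as the SNR mode", {
  spec <- generate_specimen(512, 512, feature_scale = 1, seed = 99)
  opt <- optics_state(magnification = 8, current = 26)
  acq <- acquisition_params(width = 96, height = 96, sampling = "nearest",
                            psf_scale = 6, seed = 309)
  st <- sem_stream(spec, ramp_trajectory(opt, "defocus", -3, 3, 40), acq)
  gc <- evaluate_sweep(st$frames, st$meta$defocus, reduction = 2,
                       window = 4, metric = "cov")
  expect_false(is.na(gc$peak_tick))
  expect_lt(abs(glance(gc)$peak_control), 1)
})

test_that("sufficiency assessment thresholds the stability index", {
  expect_identical(assess_sufficiency(0, 0.5), "insufficient")
  expect_identical(assess_sufficiency(10, 0), "sufficient")
  expect_identical(assess_sufficiency(3.2, 3.2), "sufficient")
  # strong- vs weak-texture fields at identical optics, threshold between
  # their ground-truth indices
  spec_w <- generate_specimen(256, 256, feature_scale = 1,
                              strength_profile = matrix(0.3, 256, 256), seed = 7)
  spec_s <- generate_specimen(256, 256, feature_scale = 1, seed = 7)
  opt <- optics_state(magnification = 4, current = 26)
  acq <- acquisition_params(width = 64, height = 64, sampling = "nearest", seed = 3)
  gt_w <- ground_truth_snr(spec_w, opt, acq)
  gt_s <- ground_truth_snr(spec_s, opt, acq)
  thr <- mean(stability_index(c(gt_w, gt_s), 64 * 64))
  set.seed(310)
  lv_w <- tibble::tibble(index_value = stability_index(
    estimate_snr(render_frame(spec_w, opt, acq), render_frame(spec_w, opt, acq))$snr, 64 * 64))
  lv_s <- tibble::tibble(index_value = stability_index(
    estimate_snr(render_frame(spec_s, opt, acq), render_frame(spec_s, opt, acq))$snr, 64 * 64))
  expect_identical(assess_sufficiency(lv_w, thr), "insufficient")
  expect_identical(assess_sufficiency(lv_s, thr), "sufficient")
})
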