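test_that("blank correction is exact isotope mass balance", {
  expect_equal(correct_blank(10, 20, 1, 0), 200 / 9)        # 22.222...
  expect_equal(correct_blank(10, 20, 0, 0), 20)             # no blank
  expect_equal(correct_blank(10, 20, 1, 20), 20)            # same composition
  expect_error(correct_blank(1, 20, 1, 0), "signal too small")
  expect_error(correct_blank(0.5, 20, 1, 0), "signal too small")
})

test_that("linearity fit recovers an injected amplitude slope", {
  amp <- c(2, 4, 6, 8)
  lin <- fit_linearity(amp, 10 + 0.002 * amp)
  expect_equal(lin$slope, 0.002, tolerance = 1e-12)
  expect_equal(lin$a_ref, 5)
  # two points define the line exactly
  expect_equal(fit_linearity(c(2, 8), c(10.004, 10.016))$slope, 0.002)
  expect_error(fit_linearity(c(5, 5), c(10, 10)), "distinct")
})

test_that("drift fit recovers an injected positional slope", {
  pos <- c(2, 10, 18, 26)
  dr <- fit_drift(pos, 23.8 + 0.01 * pos)
  expect_equal(dr$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit_drift(c(1, 21), c(23.8, 24.0))$slope, 0.01)
  expect_error(fit_drift(c(3, 3), c(23.8, 23.9)), "distinct")
})

test_that("noisy linearity and drift slopes fall within their fit uncertainty", {
  set.seed(31)
  amp <- rep(c(2, 4, 6, 8, 10), 3)
  d <- 10 + 0.02 * amp + rnorm(length(amp), 0, 0.05)
  fit <- lm(d ~ amp)
  ci <- confint(fit)["amp", ]
  est <- fit_linearity(amp, d)$slope
  expect_equal(est, unname(coef(fit)["amp"]))
  expect_true(ci[1] <= 0.02 && 0.02 <= ci[2])
})

test_that("one-point calibration anchors air standards to 23.8 permil", {
  seq0 <- irms_sequence(id = 1:4,
                        kind = c("sample", "standard_air", "standard_air", "sample"),
                        amplitude = c(5, 5, 5, 5),
                        raw_delta = c(30.0, 24.3, 24.3, 10.0),
                        position = 1:4)
  cal <- calibrate_one_point(seq0)
  expect_equal(cal$offset, -0.5)
  expect_equal(cal$delta, c(29.5, 23.8, 23.8, 9.5))
  no_air <- irms_sequence(1:2, c("sample", "sample"), c(5, 5), c(30, 10), 1:2)
  expect_error(calibrate_one_point(no_air), "calibration impossible")
  expect_error(correct_sequence(no_air), "calibration impossible")
})

test_that("the full correction chain is the identity on an artifact-free sequence", {
  truth <- c(35.2, 48.1, 60.0)
  seq0 <- generate_irms_sequence(truth, artifacts = list(),
                                 noise = noise_model(sigma_delta = 0, seed = 1))
  corr <- correct_sequence(seq0)
  smp <- corr$kind == "sample"
  expect_equal(corr$corrected_delta[smp], corr$raw_delta[smp], tolerance = 1e-9)
  expect_equal(corr$corrected_delta[smp], truth, tolerance = 1e-9)
  m <- attr(corr, "correction_model")
  expect_equal(m$calibration_offset, 0, tolerance = 1e-9)
  expect_equal(m$linearity_slope, 0, tolerance = 1e-12)
  expect_equal(m$drift_slope, 0, tolerance = 1e-12)
})

test_that("injected blank, linearity, drift and offset artifacts are inverted", {
  truth <- c(25.1, 40.3, 55.7, 70.2, 82.4)
  art <- list(blank_amplitude = 0.3, blank_delta = 5,
              linearity_slope = 0.02, drift_slope = 0.008,
              calibration_offset = 0.6)
  seq0 <- generate_irms_sequence(truth, artifacts = art,
                                 noise = noise_model(sigma_delta = 0, seed = 2))
  corr <- correct_sequence(seq0)
  smp <- corr$kind == "sample"
  rms <- sqrt(mean((corr$corrected_delta[smp] - truth)^2))
  expect_lt(rms, 0.05)
  # raw deltas are visibly corrupted before correction
  expect_gt(max(abs(seq0$raw_delta[smp] - truth)), 0.2)
})

test_that("a constant shift of all raw deltas is absorbed by the calibration step", {
  set.seed(5)
  truth <- runif(4, 20, 80)
  art <- list(blank_amplitude = 0.2, blank_delta = 3,
              linearity_slope = 0.01, drift_slope = 0.005)
  s1 <- generate_irms_sequence(truth, art, noise_model(sigma_delta = 0, seed = 3))
  s2 <- s1
  s2$raw_delta <- s2$raw_delta + 4.2
  c1 <- correct_sequence(s1)
  c2 <- correct_sequence(s2)
  smp <- c1$kind == "sample"
  expect_equal(c2$corrected_delta[smp], c1$corrected_delta[smp],
               tolerance = 1e-6)
  expect_equal(attr(c2, "correction_model")$calibration_offset,
               attr(c1, "correction_model")$calibration_offset - 4.2,
               tolerance = 1e-6)
})

test_that("IRMS sequence CSV I/O round-trips", {
  seq0 <- generate_irms_sequence(c(30, 50), noise = noise_model(sigma_delta = 0, seed = 4))
  corr <- correct_sequence(seq0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_irms_csv(corr, path)
  back <- read_irms_csv(path)
  expect_s3_class(back, "irms_sequence")
  expect_equal(back$raw_delta, corr$raw_delta)
  expect_equal(utils::read.csv(path)$corrected_delta_permil, corr$corrected_delta)
})

test_that("sequence validation rejects malformed input", {
  expect_error(irms_sequence(1:2, c("sample", "sample"), c(5, 5), c(1, 2),
                             c(1, 1)), "unique|position")
  expect_error(irms_sequence(1:2, c("sample", "blank"), c(0, 0.2), c(1, 2), 1:2),
               "> 0")
})
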