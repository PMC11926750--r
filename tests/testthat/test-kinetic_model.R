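params_demo <- function(rf = 1e-9, k3 = 253 * K2_SINGLET_O2, f_delta = 0.75) {
  kinetic_params(k3 = k3, rf = rf, f_delta = f_delta)
}

test_that("triplet steady state is rf/(kq [O2]) with the expected scalings", {
  p <- params_demo(rf = 1e-9)
  expect_equal(triplet_steady_state(p, 2.7e-4), 3.7037037037e-15,
               tolerance = 1e-9)
  expect_equal(triplet_steady_state(kinetic_params(k3 = p$k3, rf = 2e-9), 2.7e-4),
               2 * triplet_steady_state(p, 2.7e-4))
  expect_equal(triplet_steady_state(p, 2 * 2.7e-4),
               triplet_steady_state(p, 2.7e-4) / 2)
  expect_error(triplet_steady_state(p, 0), "degenerate")
})

test_that("singlet-oxygen steady state obeys its quencher limits", {
  p <- params_demo()
  t_ss <- triplet_steady_state(p, 2.7e-4)
  base <- singlet_oxygen_steady_state(p, t_ss, 2.7e-4, pc = 0)
  k1 <- p$f_delta * p$kq
  expect_equal(base, k1 * t_ss * 2.7e-4 / p$k2)
  # at pc = k2/k3 the denominator doubles
  expect_equal(singlet_oxygen_steady_state(p, t_ss, 2.7e-4, pc = p$k2 / p$k3),
               base / 2)
  # strong-quenching asymptote
  pc_big <- 1e6 * p$k2 / p$k3
  expect_equal(singlet_oxygen_steady_state(p, t_ss, 2.7e-4, pc_big),
               k1 * t_ss * 2.7e-4 / (p$k3 * pc_big), tolerance = 1e-5)
})

test_that("O2 consumption rate saturates at rf*f_delta and is monotone in pc", {
  p <- params_demo(rf = 5e-7 / 0.75)
  expect_equal(o2_consumption_rate(p, 0), 0)
  expect_equal(o2_consumption_rate(p, p$k2 / p$k3), 5e-7 / 2)
  expect_equal(o2_consumption_rate(p, 1e5 * p$k2 / p$k3), 5e-7,
               tolerance = 1e-4)
  pc <- 10^seq(-6, 0, length.out = 30)
  r <- o2_consumption_rate(p, pc)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < p$rf * p$f_delta))
})

test_that("commitment is k3 pc / k2, linear in pc, and matches reported values", {
  expect_equal(commitment(0.25, k3_over_k2 = 480), 120)    # 250 mM FFA
  expect_equal(commitment(0, k3_over_k2 = 480), 0)
  expect_equal(commitment(0.004, k3_over_k2 = 253), 1.0, tolerance = 0.02)
  a <- 7.3; pc <- 0.004
  expect_equal(commitment(a * pc, k3_over_k2 = 253),
               a * commitment(pc, k3_over_k2 = 253))
  p <- params_demo()
  expect_equal(commitment(0.001, p), p$k3 / p$k2 * 0.001)
})

test_that("regime classification follows the probe-to-O2 ratio heuristic", {
  expect_equal(classify_regime(experiment_conditions("His", pc0 = 0.1)), "zero")
  expect_equal(classify_regime(experiment_conditions("His", pc0 = 3.0e-4)), "first")
  expect_equal(classify_regime(experiment_conditions("His", pc0 = 2.7e-4)), "first")
  expect_equal(classify_regime(experiment_conditions("His", pc0 = 8e-4)), "mixed")
  # reported first-order experiments all classify first
  tab <- experiment_table()
  first_entries <- c(3, 4, 12, 13, 16)
  for (i in first_entries) {
    expect_equal(classify_regime(
      experiment_conditions(tab$probe[i], pc0 = tab$pc_mM[i] / 1000)), "first")
  }
  # unambiguous zero-order experiments (probe in >= 5x excess)
  for (i in c(1, 2, 5, 6, 7, 8, 9, 17, 18)) {
    expect_equal(classify_regime(
      experiment_conditions(tab$probe[i], pc0 = tab$pc_mM[i] / 1000)), "zero")
  }
})

test_that("rate fitting recovers zero- and first-order decays", {
  tt <- seq(0, 1000, by = 100)
  o2 <- 2.7e-4 - 0.2e-6 * tt
  fit <- fit_rate(tt, o2, "zero")
  expect_equal(fit$rate, 0.2e-6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  o2e <- 2.7e-4 * exp(-4.3e-4 * tt)
  fite <- fit_rate(tt, o2e, "first")
  expect_equal(fite$rate, 4.3e-4, tolerance = 1e-9)

  # auto picks the better-fitting order
  expect_equal(fit_rate(tt, o2e, "auto")$order, "first")
  expect_equal(fit_rate(tt, o2, "auto")$order, "zero")

  expect_error(fit_rate(c(0, 100, 50), o2[1:3]), "increasing")
  expect_error(fit_rate(tt, o2 - 3e-4, "first"), "> 0")
})

test_that("noisy zero-order rate is recovered within its confidence interval", {
  set.seed(9)
  tt <- seq(0, 900, length.out = 8)
  truth <- 0.21e-6
  cover <- vapply(1:200, function(i) {
    o2 <- 2.7e-4 - truth * tt + rnorm(8, 0, 2e-6)
    fit <- fit_rate(tt, o2, "zero")
    abs(fit$rate - truth) <= fit$ci95
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("zero-order rates regress linearly on the commitment term with slope rf*f_delta", {
  p <- params_demo(rf = 5e-7 / 0.75)
  cc <- c(0.32, 0.10, 0.038, 0.014, 0.12, 0.77 / 10, 0.038, 0.019)
  rates <- o2_consumption_rate(p, cc / (p$k3 / p$k2))
  reg <- rate_commitment_regression(cc, rates)
  expect_equal(reg$slope, 5e-7, tolerance = 1e-9)
  expect_equal(reg$intercept, 0, tolerance = 1e-12)
  expect_gt(reg$r_squared, 0.99)
  expect_error(rate_commitment_regression(1, 1e-7), "2 points")
  expect_error(rate_commitment_regression(c(1, 1), c(1e-7, 1e-7)), "degenerate")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(kinetic_params(k3 = -1, rf = 1e-9), "positive")
  expect_error(kinetic_params(k3 = 1e8, rf = 1e-9, f_delta = 1.2), "f_delta")
  expect_error(experiment_conditions("His", pc0 = 0.1, o2_0 = 0), "o2_0")
  expect_error(experiment_conditions("His", pc0 = -0.1), ">= 0")
})
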