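test_that("fixed-exponent fit equals closed-form linear least squares", {
  set.seed(31)
  for (k in 1:100) {
    p <- random_params()
    n <- sample(8:80, 1)
    g <- default_grid(n, f_min = runif(1, 1, 50), f_max = runif(1, 1e5, 5e6))
    x <- canonical_model_reactance(p, g)
    if (k %% 2 == 0) x <- x + rnorm(n, 0, 0.5)  # half the instances noisy
    sp <- impedance_spectrum(g, resistance = rep(50, n), reactance = x,
                             time_h = 0)
    fit <- fit_fixed_exponents(sp)
    beta <- qr.solve(oracle_design(g$omega), x)
    est <- unlist(fit$params[c("a0", "b0", "c0", "d0")])
    scale <- pmax(abs(beta), 1e-12)
    expect_lt(max(abs(est - beta) / scale), 1e-8)
  }
})

test_that("noiseless coefficients are recovered almost exactly", {
  truth <- canonical_truth()
  fit <- fit_fixed_exponents(noiseless_spectrum(truth))
  for (nm in c("a0", "b0", "c0", "d0"))
    expect_lt(rel_err(fit$params[[nm]], truth[[nm]]), 1e-6)
  expect_lt(fit$residual_ss, 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$negated_report,
               c(a0 = -fit$params$a0, b0 = -fit$params$b0,
                 c0 = -fit$params$c0, d0 = -fit$params$d0))
})

test_that("constant and single-element spectra collapse to one coefficient", {
  g <- default_grid()
  sp <- impedance_spectrum(g, resistance = rep(50, 61),
                           reactance = rep(7, 61), time_h = 0)
  fit <- fit_fixed_exponents(sp)
  expect_equal(fit$params$a0, 7, tolerance = 1e-8)
  expect_lt(abs(fit$params$b0) * max(g$omega^-1.5), 1e-8)
  expect_lt(abs(fit$params$c0) * max(g$omega^-0.5), 1e-8)
  expect_lt(abs(fit$params$d0) * max(g$omega), 1e-8)

  truth <- circuit_params(d0 = 1e-5)
  fit <- fit_fixed_exponents(noiseless_spectrum(truth))
  expect_lt(rel_err(fit$params$d0, 1e-5), 1e-6)
  expect_lt(abs(fit$params$a0), 1e-6)
})

test_that("fit preconditions are enforced", {
  g4 <- frequency_grid(c(10, 100, 1000, 1e4))
  sp4 <- impedance_spectrum(g4, resistance = rep(1, 4),
                            reactance = rep(1, 4), time_h = 0)
  expect_error(fit_fixed_exponents(sp4), "at least 5")
  g6 <- default_grid(6)
  sp6 <- noiseless_spectrum(grid = g6)
  expect_error(fit_free_exponents(sp6), "at least 7")
})

test_that("coefficient error shrinks as the grid is refined", {
  truth <- canonical_truth()
  med_err <- sapply(c(31, 61, 121), function(n) {
    g <- default_grid(n)
    errs <- sapply(1:30, function(s) {
      sp <- simulate_spectrum(truth, g, noise_spec(sigma_abs = 1,
                                                   sigma_rel = 0, seed = s),
                              time_h = 0)
      f <- fit_fixed_exponents(sp)
      rel_err(f$params$b0, truth$b0)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("free-exponent fit recovers the generating exponents", {
  fit <- fit_free_exponents(noiseless_spectrum())
  expect_lt(abs(fit$params$p1 - (-1.5)), 0.01)
  expect_lt(abs(fit$params$p2 - 1), 0.01)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations_used, 50000 * nrow(fit_config()$starts))
})

test_that("free fit drifts to the ideal-capacitor exponent on 1/omega data", {
  g <- default_grid()
  x <- general_model_reactance(list(c(1e3, -1)), 0, g)  # X = -1e3/omega
  sp <- impedance_spectrum(g, resistance = rep(50, 61), reactance = x,
                           time_h = 0)
  fit <- fit_free_exponents(sp)
  expect_lt(abs(fit$params$p1 - (-1)), 0.02)
  expect_lt(fit$residual_ss, 1e-10 * length(g$f))
})

test_that("exponent recovery tightens as the signal-to-noise ratio rises", {
  truth <- canonical_truth()
  g <- default_grid()
  err_at <- function(sigma_rel, s) {
    sp <- simulate_spectrum(truth, g, noise_spec(0, sigma_rel, s),
                            time_h = 0)
    fit <- fit_free_exponents(sp)
    c(p1 = abs(fit$params$p1 - (-1.5)), p2 = abs(fit$params$p2 - 1))
  }
  coarse <- sapply(1:8, function(s) err_at(1e-2, s))
  fine <- sapply(1:8, function(s) err_at(1e-4, s))
  # the low-frequency exponent is the weakly identified direction (the
  # s^p1 and Warburg terms are nearly collinear); its error must shrink
  # with noise, and at very high SNR both exponents are pinned tightly
  expect_lt(median(fine["p1", ] / coarse["p1", ]), 1)
  expect_true(all(fine < 0.01))
})

test_that("fitting is deterministic", {
  sp <- simulate_spectrum(canonical_truth(), default_grid(),
                          noise_spec(0.5, 0.01, 99), time_h = 0)
  expect_identical(fit_fixed_exponents(sp), fit_fixed_exponents(sp))
  expect_identical(fit_free_exponents(sp), fit_free_exponents(sp))
})

test_that("replicate summaries average the per-reactor fits", {
  sp <- noiseless_spectrum()
  single <- fit_fixed_exponents(sp)

  out <- fit_replicates(list(sp, sp, sp))
  expect_equal(out$n_reactors, 3)
  for (nm in c("a0", "b0", "c0", "d0")) {
    expect_equal(out[[paste0(nm, "_mean")]], single$params[[nm]])
    expect_equal(out[[paste0(nm, "_std")]], 0)
  }

  out1 <- fit_replicates(sp)
  expect_equal(out1$n_reactors, 1)
  expect_equal(out1$b0_mean, single$params$b0)
  expect_equal(out1$b0_std, 0)

  sp2 <- noiseless_spectrum(condition = "with_pb")
  expect_error(fit_replicates(list(sp, sp2)), "mixed conditions")
})

test_that("noisy replicate means land within the Monte-Carlo spread", {
  truth <- canonical_truth()
  g <- default_grid()
  # Monte-Carlo oracle: sd of a single-fit b0 under this noise level
  mc <- sapply(1:200, function(s) {
    sp <- simulate_spectrum(truth, g, noise_spec(0, 0.02, 1000 + s),
                            time_h = 0)
    fit_fixed_exponents(sp)$params$b0
  })
  sd_b0 <- sd(mc)
  reps <- lapply(1:3, function(r)
    simulate_spectrum(truth, g, noise_spec(0, 0.02, r), time_h = 0,
                      reactor_id = paste0("R", r)))
  out <- fit_replicates(reps)
  expect_lt(abs(out$b0_mean - truth$b0), 3 * sd_b0 / sqrt(3))
})

test_that("the time-course table has one row per condition and hour", {
  cfg <- experiment_config(times = 1:10, noise_sigma_rel = 0,
                           growth_jitter_sd = 0, seed = 5)
  dir <- withr::local_tempdir()
  res <- simulate_experiment(cfg, dir)
  tc <- fit_timecourse(res$spectra)
  expect_equal(nrow(tc), 20)
  expect_equal(as.integer(table(tc$condition)), c(10L, 10L))
  fits <- attr(tc, "fits")
  expect_equal(nrow(fits), 60)

  # noiseless monotone linkage: replicate-mean -b0 strictly decreasing
  # while the culture grows
  for (cond in c("with_pb", "without_pb")) {
    nb <- -tc$b0_mean[tc$condition == cond]
    expect_true(all(diff(nb) < 0))
  }

  one <- Filter(function(s) s$time_h == 1, res$spectra)
  tc1 <- fit_timecourse(one)
  expect_equal(nrow(tc1), 2)
})
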