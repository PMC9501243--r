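test_that("growth profiles have the intended shapes", {
  flat <- growth_model_spec("rise_plateau", initial_log_cfu = 6,
                            growth_rate = 0, capacity = 9)
  expect_equal(simulate_growth(flat, 0:10)$log_cfu, rep(6, 11))

  rp <- growth_model_spec("rise_plateau", initial_log_cfu = 6,
                          growth_rate = 0.5, capacity = 9)
  g <- simulate_growth(rp, 0:24)
  expect_true(all(diff(g$log_cfu) >= 0))
  expect_lte(max(g$log_cfu), 9)

  rd <- growth_model_spec("rise_decline", initial_log_cfu = 6,
                          growth_rate = 0.6, capacity = 9, peak_time_h = 9,
                          decline_rate = 0.15)
  s <- simulate_growth(rd, 1:14)
  expect_equal(s$time_h[which.max(s$log_cfu)], 9)
  # exactly one local maximum
  sg <- sign(diff(s$log_cfu))
  expect_equal(sum(diff(sg) < 0), 1)
})

test_that("rise increments match the growth rate far below capacity", {
  spec <- growth_model_spec("rise_plateau", initial_log_cfu = 2,
                            growth_rate = 0.5, capacity = 200)
  g <- simulate_growth(spec, 0:3)
  inc <- diff(g$log_cfu)
  expect_true(all(abs(inc - 0.5) / 0.5 < 0.01))
  # oracle: forward-Euler integration of dL/dt = r (K - L) / (K - n0)
  L <- 2; dt <- 1e-4
  for (i in seq_len(3 / dt)) L <- L + dt * 0.5 * (200 - L) / 198
  expect_equal(g$log_cfu[4], L, tolerance = 1e-3)
})

test_that("Pb depletion steps down with growth and clamps at the floor", {
  g <- growth_series(0:2, c(6, 7, 8))
  none <- pb_depletion_spec(80, uptake_rate = 0, floor_mg_l = 5)
  expect_equal(simulate_pb(none, g)$pb_mg_per_l, rep(80, 3))

  big <- pb_depletion_spec(80, uptake_rate = 50, floor_mg_l = 5)
  out <- simulate_pb(big, g)$pb_mg_per_l
  expect_equal(out, c(80, 5, 5))
  expect_true(all(out >= 5))

  # hand-computed step sequence: C(t+1) = C(t) - 2 * log_cfu(t)
  mid <- pb_depletion_spec(80, uptake_rate = 2, floor_mg_l = 5)
  expect_equal(simulate_pb(mid, g)$pb_mg_per_l, c(80, 68, 54))
})

test_that("Pb series are always non-increasing and above the floor", {
  set.seed(51)
  for (k in 1:20) {
    spec <- pb_depletion_spec(80, uptake_rate = runif(1, 0, 10),
                              floor_mg_l = runif(1, 0, 20))
    g <- growth_series(0:10, cumsum(c(6, runif(10, 0, 0.5))))
    out <- simulate_pb(spec, g)$pb_mg_per_l
    expect_true(all(diff(out) <= 0))
    expect_true(all(out >= spec$floor_mg_l - 1e-12))
  }
})

test_that("the linkage maps CFU counts onto circuit parameters", {
  lk <- linkage_model(b0 = c(-10, 2))
  g <- growth_series(0:1, c(4, 4))
  p <- params_from_growth(lk, g, "without_pb")
  expect_equal(-p[[1]]$b0, 10 - 2 * 4)

  # zero-slope linkage: constant parameters over time
  lk0 <- linkage_model(a0 = c(1, 0), b0 = c(-5, 0), c0 = c(-2, 0),
                       d0 = c(1e-5, 0))
  g2 <- growth_series(0:3, c(5, 6, 7, 8))
  p2 <- params_from_growth(lk0, g2, "without_pb")
  expect_equal(unique(vapply(p2, `[[`, 0, "b0")), -5)

  # default preset: with-Pb |b0| exceeds without-Pb by >= 10x at every time
  lk <- linkage_model()
  g3 <- simulate_growth(growth_model_spec(), 1:10)
  pw <- params_from_growth(lk, g3, "with_pb")
  po <- params_from_growth(lk, g3, "without_pb")
  ratio <- abs(vapply(pw, `[[`, 0, "b0")) / abs(vapply(po, `[[`, 0, "b0"))
  expect_true(all(ratio >= 10))
  # -b0 strictly monotone in log CFU for the growing culture
  expect_true(all(diff(-vapply(po, `[[`, 0, "b0")) < 0))
})

test_that("spectrum simulation is noiseless at sigma 0 and seed-stable", {
  p <- canonical_truth()
  g <- default_grid()
  sp0 <- simulate_spectrum(p, g, noise_spec(0, 0, 1), time_h = 0)
  expect_equal(sp0$reactance, canonical_model_reactance(p, g))
  expect_equal(sp0$resistance, rep(50, 61))

  a <- simulate_spectrum(p, g, noise_spec(0.5, 0.01, 7), time_h = 0)
  b <- simulate_spectrum(p, g, noise_spec(0.5, 0.01, 7), time_h = 0)
  expect_identical(a$reactance, b$reactance)
  c <- simulate_spectrum(p, g, noise_spec(0.5, 0.01, 8), time_h = 0)
  expect_false(identical(a$reactance, c$reactance))
})

test_that("absolute noise has the configured standard deviation", {
  p <- circuit_params(a0 = 5)
  g <- frequency_grid(10^seq(1, 6, length.out = 10000))
  sp <- simulate_spectrum(p, g, noise_spec(sigma_abs = 1, sigma_rel = 0,
                                           seed = 3), time_h = 0)
  eps <- sp$reactance - canonical_model_reactance(p, g)
  expect_lt(abs(sd(eps) - 1), 0.03)
})

test_that("a simulated experiment has the full factorial shape", {
  cfg <- experiment_config(seed = 2)
  dir <- withr::local_tempdir()
  res <- simulate_experiment(cfg, dir)
  df <- read.csv(res$paths$spectra)
  expect_equal(nrow(df), 2 * 3 * 10 * 61)
  expect_setequal(unique(df$condition), c("with_pb", "without_pb"))
  growth <- read.csv(res$paths$growth)
  expect_equal(nrow(growth), 2 * 3 * 10)
  pb <- read.csv(res$paths$pb)
  expect_equal(nrow(pb), 3 * 10)  # Pb tracked in the with-Pb arm
  truth <- jsonlite::fromJSON(res$paths$truth)
  expect_equal(truth$seed, 2)
  expect_length(truth$true_params$b0, 60)
})

test_that("identical seeds give byte-identical datasets", {
  cfg <- experiment_config(seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_experiment(cfg, d1)
  r2 <- simulate_experiment(cfg, d2)
  for (f in c("spectra", "growth", "pb", "truth"))
    expect_identical(readLines(r1$paths[[f]]), readLines(r2$paths[[f]]))
})

test_that("stock and dosing arithmetic reproduce the preparation figures", {
  stock <- stock_concentration(1.6, pb_fraction_lead_nitrate(), 0.1)
  expect_equal(signif(stock, 2), 10000)
  expect_equal(stock, 1.6 * 207.2 / 331.21 * 1e4, tolerance = 1e-4)
  expect_equal(stock_concentration(1, 1, 1), 1000)
  expect_equal(stock_concentration(0, 0.5, 1), 0)
  expect_error(stock_concentration(1, 0.5, 0), "volume")

  expect_equal(dilution_concentration(0.8, 10000, 100), 80)
  expect_equal(dilution_concentration(0, 10000, 100), 0)
  expect_equal(dilution_concentration(1, 1000, 1000), 1)
  expect_error(dilution_concentration(1, 1000, 0), "volume")
})
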