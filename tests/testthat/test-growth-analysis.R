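test_that("plate-count arithmetic gives log10 CFU per mL", {
  expect_equal(log_cfu_from_plate(43, 1e-6, 0.1), log10(4.3e8))
  expect_equal(log_cfu_from_plate(1, 1, 1), 0)
  # zero colonies: finite below-detection sentinel, under the 1-colony value
  zero <- log_cfu_from_plate(0, 1e-6, 0.1)
  expect_true(is.finite(zero))
  expect_lt(zero, log_cfu_from_plate(1, 1e-6, 0.1))
  expect_error(log_cfu_from_plate(-1, 1e-6), "negative")
  expect_error(log_cfu_from_plate(2, 2), "dilution")
})

test_that("plate-count arithmetic is monotone in count and dilution", {
  counts <- c(1, 5, 20, 100, 400)
  expect_true(all(diff(log_cfu_from_plate(counts, 1e-5)) > 0))
  dils <- 10^-(7:4)
  expect_true(all(diff(log_cfu_from_plate(50, dils)) < 0))
})

test_that("exponential window selection honours manual and auto modes", {
  gs <- growth_series(0:9, 6 + 0.3 * (0:9))
  expect_equal(exponential_window(gs, "manual", window = c(0, 6)), c(0, 6))
  # uniform slope: auto spans the whole series
  expect_equal(exponential_window(gs, "auto"), c(0, 9))

  # rise then decline with a peak at 9 h: auto ends at the last pre-peak
  # sample; brute-force slope-scan oracle alongside
  spec <- growth_model_spec("rise_decline", initial_log_cfu = 6,
                            growth_rate = 0.6, capacity = 9,
                            peak_time_h = 9, decline_rate = 0.2)
  rd <- simulate_growth(spec, 1:12)
  win <- exponential_window(rd, "auto", frac = 0.5)
  slopes <- diff(rd$log_cfu) / diff(rd$time_h)
  ok <- slopes >= 0.5 * max(slopes)
  runs <- rle(ok)
  stopifnot(any(runs$values))
  ends <- cumsum(runs$lengths)
  best <- which(runs$values)[which.max(runs$lengths[which(runs$values)])]
  oracle <- c(rd$time_h[ends[best] - runs$lengths[best] + 1],
              rd$time_h[ends[best] + 1])
  expect_equal(win, oracle)
  expect_lte(win[2], 9)  # never extends past the CFU peak

  expect_error(exponential_window(growth_series(1:2, c(1, 2)), "auto"),
               "at least 3")
})

test_that("supercapacitance-CFU regression reproduces an exact line", {
  lc <- c(6, 6.4, 6.9, 7.2, 7.6, 8)
  ft <- data.frame(time_h = 1:6, b0_mean = -(10 - 2 * lc))
  gs <- growth_series(1:6, lc)
  r <- correlate_supercap_cfu(ft, gs, window = c(0, 6))
  expect_equal(r$slope, -2, tolerance = 1e-12)
  expect_equal(r$intercept, 10, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$n, 6)

  # shuffle invariance
  perm <- c(4, 1, 6, 3, 2, 5)
  r2 <- correlate_supercap_cfu(ft[perm, ], gs, window = c(0, 6))
  expect_equal(r2$slope, r$slope)
  expect_equal(r2$r_squared, r$r_squared)

  expect_error(correlate_supercap_cfu(ft[1, , drop = FALSE], gs, c(0, 6)),
               "fewer than 2")
  flat <- growth_series(1:6, rep(7, 6))
  expect_error(correlate_supercap_cfu(ft, flat, c(0, 6)), "constant")
})

test_that("noisy regression recovers the linkage slope", {
  beta <- -2e3
  lc <- c(6.2, 6.6, 7.0, 7.3, 7.6, 7.8)
  level <- 3.2e4 + beta * lc
  set.seed(41)
  slopes <- replicate(500, {
    y <- level + rnorm(6, 0, 0.02 * mean(abs(level)))
    ft <- data.frame(time_h = 1:6, b0_mean = -y)
    r <- correlate_supercap_cfu(ft, growth_series(1:6, lc), c(0, 6))
    r$slope
  })
  # Monte-Carlo oracle: the estimator is unbiased, so the mean of 500
  # draws is within 3 standard errors of the generating slope
  expect_lt(abs(mean(slopes) - beta), 3 * sd(slopes) / sqrt(500))
  # and with beta < 0 the recovered sign is negative in >= 95% of draws
  expect_gte(mean(slopes < 0), 0.95)
})

test_that("Pb presence classification thresholds the log magnitude", {
  out <- classify_pb_presence(c(1e-3, 1e-6),
                              c("pb_present", "pb_absent"),
                              query = 1e-4)
  expect_equal(out$labels, "pb_present")
  expect_equal(out$log10_threshold, -4.5)
  # query exactly on the threshold: pb_absent by convention
  tie <- classify_pb_presence(c(1e-3, 1e-6), c("pb_present", "pb_absent"),
                              query = 10^-4.5)
  expect_equal(tie$labels, "pb_absent")
  expect_error(classify_pb_presence(c(1, 2), c("pb_present", "pb_present"),
                                    1),
               "both classes")
})

test_that("classification separates non-overlapping training magnitudes", {
  set.seed(42)
  for (k in 1:20) {
    hi <- 10^runif(6, -3.4, -3)   # pb_present class
    lo <- 10^runif(6, -6, -5.6)   # pb_absent class
    train <- c(hi, lo)
    labs <- rep(c("pb_present", "pb_absent"), each = 6)
    out <- classify_pb_presence(train, labs, query = train)
    expect_equal(out$labels, labs)
    # scale monotonicity: larger query can never flip present -> absent
    q <- sort(10^runif(10, -7, -2))
    lab_idx <- match(classify_pb_presence(train, labs, q)$labels,
                     c("pb_absent", "pb_present"))
    expect_true(all(diff(lab_idx) >= 0))
  }
})

test_that("growth and Pb CSV readers validate their schemas", {
  gpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,reactor_id,condition,colony_count,dilution_factor",
               "1,R1,with_pb,40,1e-06",
               "2,R1,with_pb,90,1e-06"), gpath)
  gl <- read_growth(gpath, plated_volume_ml = 0.1)
  expect_length(gl, 1)
  expect_equal(gl[[1]]$log_cfu, log_cfu_from_plate(c(40, 90), 1e-6, 0.1))

  writeLines(c("time_h,reactor_id,condition,log_cfu",
               "1,R1,without_pb,6.5"), gpath)
  expect_equal(read_growth(gpath)[[1]]$log_cfu, 6.5)

  writeLines("time_h,reactor_id", gpath)
  expect_error(read_growth(gpath), "missing columns")

  ppath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,reactor_id,pb_mg_per_l", "1,R1,-3"), ppath)
  expect_error(read_pb(ppath), "negative")
  writeLines(c("time_h,reactor_id,pb_mg_per_l", "1,R1,80", "2,R1,60"), ppath)
  expect_equal(read_pb(ppath)$pb_mg_per_l, c(80, 60))
})
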