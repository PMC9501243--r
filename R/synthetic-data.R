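# In-silico experiment generator with known ground truth.
#
# Emulates the batch-reactor study design: three replicate reactors per
# condition (with / without 80 mg/L initial Pb(II)), hourly sampling over a
# 10 h horizon, 61-point 10 Hz-1 MHz sweeps. Two growth presets mirror the
# organisms studied: a rise-then-plateau profile (K. pneumoniae-like,
# logistic in log-CFU space) and a rise-then-decline profile
# (P. bifermentans-like, peak near 9 h followed by linear decline). Circuit
# parameters are linked to the CFU count by per-coefficient affine maps
# during growth, with a multiplicative with-Pb offset on |b0| and |c0|
# reproducing the orders-of-magnitude class separation seen with dissolved
# Pb(II). Every generator is a pure function of (spec, seed).

#' Growth-curve specification
#'
#' @param profile `"rise_plateau"` (saturating rise in log-CFU space,
#'   levelling off at the carrying capacity) or `"rise_decline"` (same rise,
#'   then linear decline after `peak_time_h`).
#' @param initial_log_cfu Starting CFU count (log10 CFU/mL).
#' @param growth_rate Exponential-phase rate in log10 units per hour.
#' @param capacity Carrying capacity (log10 CFU/mL).
#' @param peak_time_h Peak time in hours (`rise_decline` only).
#' @param decline_rate Post-peak decline in log10 units per hour.
#' @return A list of class `growth_model_spec`.
#' @export
growth_model_spec <- function(profile = c("rise_plateau", "rise_decline"),
                              initial_log_cfu = 6, growth_rate = 0.5,
                              capacity = 9, peak_time_h = 9,
                              decline_rate = 0.15) {
  profile <- match.arg(profile)
  stopifnot(growth_rate >= 0, decline_rate >= 0,
            capacity >= initial_log_cfu)
  structure(list(profile = profile, initial_log_cfu = initial_log_cfu,
                 growth_rate = growth_rate, capacity = capacity,
                 peak_time_h = peak_time_h, decline_rate = decline_rate),
            class = "growth_model_spec")
}

# Saturating growth in log-CFU space: dL/dt = r * (K - L) / (K - n0), so the
# curve leaves the inoculum at slope r (log10 units per hour, the
# exponential-phase rate) and relaxes smoothly onto the carrying capacity.
# Closed form: L(t) = K - (K - n0) * exp(-r * t / (K - n0)).
rise_log_cfu <- function(spec, t) {
  n0 <- spec$initial_log_cfu
  K <- spec$capacity
  r <- spec$growth_rate
  if (r == 0 || K == n0) return(rep(n0, length(t)))
  K - (K - n0) * exp(-r * t / (K - n0))
}

#' Simulate a growth series
#'
#' Deterministic evaluation of a [growth_model_spec()] at the requested
#' times. `rise_plateau` rises in log-CFU space at slope `growth_rate`
#' while far below capacity (exponential phase is linear in log counts) and
#' saturates smoothly at the carrying capacity; `rise_decline` follows the
#' same rise up to `peak_time_h`, then declines linearly.
#'
#' @param spec A [growth_model_spec()].
#' @param times Sample times in hours, ascending.
#' @param reactor_id,condition Metadata for the returned series.
#' @return A [growth_series()].
#' @export
simulate_growth <- function(spec, times, reactor_id = "R1",
                            condition = "without_pb") {
  stopifnot(inherits(spec, "growth_model_spec"))
  if (any(diff(times) <= 0)) stop("times must be strictly ascending")
  lc <- rise_log_cfu(spec, times)
  if (spec$profile == "rise_decline") {
    peak_val <- rise_log_cfu(spec, spec$peak_time_h)
    after <- times > spec$peak_time_h
    lc[after] <- peak_val - spec$decline_rate * (times[after] - spec$peak_time_h)
  }
  growth_series(times, lc, reactor_id, condition)
}

#' Pb(II) depletion specification
#'
#' First-order-style stepwise uptake with a floor: at each step the
#' concentration drops in proportion to the current CFU count and never
#' falls below `floor_mg_l`.
#'
#' @param initial_mg_l Initial Pb(II) concentration (default 80 mg/L, the
#'   nominal reactor dose).
#' @param uptake_rate mg/L removed per hour per log10-CFU unit.
#' @param floor_mg_l Residual concentration floor.
#' @return A list of class `pb_depletion_spec`.
#' @export
pb_depletion_spec <- function(initial_mg_l = 80, uptake_rate = 1,
                              floor_mg_l = 5) {
  stopifnot(initial_mg_l >= 0, uptake_rate >= 0,
            floor_mg_l >= 0, floor_mg_l <= initial_mg_l)
  structure(list(initial_mg_l = initial_mg_l, uptake_rate = uptake_rate,
                 floor_mg_l = floor_mg_l),
            class = "pb_depletion_spec")
}

#' Simulate residual Pb(II) concentrations
#'
#' `C(t + dt) = max(floor, C(t) - uptake * log_cfu(t) * dt)` on the growth
#' series' time base. Deterministic; the output is non-increasing and never
#' below the floor.
#'
#' @param spec A [pb_depletion_spec()].
#' @param growth A [growth_series()] supplying times and CFU counts.
#' @return A data.frame with `time_h`, `reactor_id`, `pb_mg_per_l`.
#' @export
simulate_pb <- function(spec, growth) {
  stopifnot(inherits(spec, "pb_depletion_spec"),
            inherits(growth, "growth_series"))
  t <- growth$time_h
  conc <- numeric(length(t))
  conc[1] <- spec$initial_mg_l
  if (length(t) > 1) {
    for (i in seq_len(length(t) - 1)) {
      drop <- spec$uptake_rate * growth$log_cfu[i] * (t[i + 1] - t[i])
      conc[i + 1] <- max(spec$floor_mg_l, conc[i] - drop)
    }
  }
  data.frame(time_h = t, reactor_id = growth$reactor_id[1],
             pb_mg_per_l = conc)
}

#' Linkage from CFU count to circuit parameters
#'
#' Per-coefficient affine maps `coef = intercept + slope * log_cfu` applied
#' during growth, plus multiplicative with-Pb offsets on b0 and c0 (the
#' coefficients whose magnitudes separate the two conditions by an order of
#' magnitude or more). The default b0 map is strictly monotone: `-b0`
#' decreases as the CFU count rises.
#'
#' @param a0,b0,c0,d0 Numeric `c(intercept, slope)` pairs mapping log CFU to
#'   each coefficient.
#' @param pb_multiplier_b0,pb_multiplier_c0 Factors applied to b0 and c0
#'   under the `with_pb` condition.
#' @return A list of class `linkage_model`.
#' @export
linkage_model <- function(a0 = c(-2, -0.3),
                          b0 = c(-3.2e4, 2.0e3),
                          c0 = c(-800, 40),
                          d0 = c(2e-5, 0),
                          pb_multiplier_b0 = 30,
                          pb_multiplier_c0 = 30) {
  maps <- list(a0 = a0, b0 = b0, c0 = c0, d0 = d0)
  stopifnot(all(vapply(maps, length, 0L) == 2),
            pb_multiplier_b0 > 0, pb_multiplier_c0 > 0)
  structure(c(maps, list(pb_multiplier_b0 = pb_multiplier_b0,
                         pb_multiplier_c0 = pb_multiplier_c0)),
            class = "linkage_model")
}

#' Ground-truth slope of -b0 against log CFU
#'
#' The linkage's generating slope for the `-b0` vs CFU regression that
#' [correlate_supercap_cfu()] estimates, i.e. `-slope(b0)` times the with-Pb
#' multiplier when applicable.
#'
#' @param linkage A [linkage_model()].
#' @param condition `"with_pb"` or `"without_pb"`.
#' @return The slope (coefficient units per log10 CFU).
#' @export
linkage_neg_b0_slope <- function(linkage, condition = "without_pb") {
  stopifnot(inherits(linkage, "linkage_model"))
  mult <- if (condition == "with_pb") linkage$pb_multiplier_b0 else 1
  -linkage$b0[2] * mult
}

#' Circuit parameters along a growth series
#'
#' Evaluates the linkage at every time point of a growth series, applying
#' the with-Pb offsets when the condition requires it.
#'
#' @param linkage A [linkage_model()].
#' @param growth A [growth_series()].
#' @param condition `"with_pb"` or `"without_pb"`.
#' @param p1,p2 Exponents stored in the returned parameter sets.
#' @return A list of [circuit_params()], one per time point, with the
#'   series times as attribute `"time_h"`.
#' @export
params_from_growth <- function(linkage, growth,
                               condition = c("without_pb", "with_pb"),
                               p1 = -1.5, p2 = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(linkage, "linkage_model"),
            inherits(growth, "growth_series"))
  mb <- if (condition == "with_pb") linkage$pb_multiplier_b0 else 1
  mc <- if (condition == "with_pb") linkage$pb_multiplier_c0 else 1
  out <- lapply(growth$log_cfu, function(lc) {
    circuit_params(a0 = linkage$a0[1] + linkage$a0[2] * lc,
                   b0 = (linkage$b0[1] + linkage$b0[2] * lc) * mb,
                   c0 = (linkage$c0[1] + linkage$c0[2] * lc) * mc,
                   d0 = linkage$d0[1] + linkage$d0[2] * lc,
                   p1 = p1, p2 = p2)
  })
  attr(out, "time_h") <- growth$time_h
  out
}

#' Reactance noise specification
#'
#' Additive Gaussian noise on the simulated reactance:
#' `X_obs = X + eps_abs + eps_rel * |X|` with independent draws
#' `eps_abs ~ N(0, sigma_abs)` and `eps_rel ~ N(0, sigma_rel)`. Identical
#' seeds give identical draws.
#'
#' @param sigma_abs Absolute noise sd in ohm.
#' @param sigma_rel Relative noise sd as a fraction of |X| (0.01 is an SNR
#'   of 100).
#' @param seed Integer RNG seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_abs = 0, sigma_rel = 0.01, seed = 1L) {
  stopifnot(sigma_abs >= 0, sigma_rel >= 0)
  structure(list(sigma_abs = sigma_abs, sigma_rel = sigma_rel,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

#' Simulate a noisy impedance sweep from known circuit parameters
#'
#' Forward-evaluates the canonical reactance model on the grid and adds the
#' configured noise. The real channel is filled with a constant series
#' (solution) resistance so Nyquist plots are drawable; the fitted quantity
#' is the reactance only. The generating parameters are retained as
#' attribute `"truth"`.
#'
#' @param params A [circuit_params()] ground truth.
#' @param grid A [frequency_grid()].
#' @param noise A [noise_spec()].
#' @param series_resistance Constant real-part stub in ohm (default 50).
#' @param reactor_id,time_h,condition Spectrum metadata.
#' @return An [impedance_spectrum()] with attribute `"truth"`.
#' @export
simulate_spectrum <- function(params, grid, noise = noise_spec(),
                              series_resistance = 50,
                              reactor_id = "R1", time_h = NA_real_,
                              condition = "without_pb") {
  stopifnot(inherits(noise, "noise_spec"))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  x <- canonical_model_reactance(params, grid)
  n <- length(x)
  eps <- with_seed(noise$seed, {
    ea <- if (noise$sigma_abs > 0) stats::rnorm(n, 0, noise$sigma_abs) else numeric(n)
    er <- if (noise$sigma_rel > 0) stats::rnorm(n, 0, noise$sigma_rel) else numeric(n)
    ea + er * abs(x)
  })
  sp <- impedance_spectrum(grid, resistance = rep(series_resistance, n),
                           reactance = x + eps, reactor_id = reactor_id,
                           time_h = time_h, condition = condition)
  attr(sp, "truth") <- params
  sp
}

#' Full-experiment configuration
#'
#' @param preset `"kpneumoniae_like"` (rise-plateau growth, slow sustained
#'   Pb uptake) or `"pbifermentans_like"` (rise-decline growth with a 9 h
#'   peak, fast early Pb uptake).
#' @param times Sampling times in hours (default hourly, 1-10 h).
#' @param n_reactors Replicate reactors per condition (default 3).
#' @param conditions Conditions to simulate.
#' @param grid Frequency grid (default 61 points, 10 Hz-1 MHz).
#' @param linkage A [linkage_model()].
#' @param noise_sigma_rel,noise_sigma_abs Reactance noise levels.
#' @param growth_jitter_sd Per-reactor sd of the initial CFU count (log10
#'   units), giving replicate-to-replicate spread.
#' @param series_resistance Real-channel stub (ohm).
#' @param seed Master RNG seed; every stream is derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("kpneumoniae_like",
                                         "pbifermentans_like"),
                              times = 1:10, n_reactors = 3,
                              conditions = c("with_pb", "without_pb"),
                              grid = default_grid(),
                              linkage = linkage_model(),
                              noise_sigma_rel = 0.01, noise_sigma_abs = 0,
                              growth_jitter_sd = 0.05,
                              series_resistance = 50,
                              seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(all(conditions %in% c("with_pb", "without_pb")),
            n_reactors >= 1)
  growth <- switch(preset,
    kpneumoniae_like = growth_model_spec("rise_plateau", initial_log_cfu = 6,
                                         growth_rate = 0.5, capacity = 9),
    pbifermentans_like = growth_model_spec("rise_decline",
                                           initial_log_cfu = 6,
                                           growth_rate = 0.6, capacity = 9,
                                           peak_time_h = 9,
                                           decline_rate = 0.15))
  pb <- switch(preset,
    kpneumoniae_like = pb_depletion_spec(80, uptake_rate = 1, floor_mg_l = 5),
    pbifermentans_like = pb_depletion_spec(80, uptake_rate = 1.6,
                                           floor_mg_l = 5))
  structure(list(preset = preset, times = times, n_reactors = n_reactors,
                 conditions = conditions, grid = grid,
                 growth_spec = growth, pb_spec = pb, linkage = linkage,
                 noise_sigma_rel = noise_sigma_rel,
                 noise_sigma_abs = noise_sigma_abs,
                 growth_jitter_sd = growth_jitter_sd,
                 series_resistance = series_resistance,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# deterministic sub-seed per (condition, reactor, time) stream, < 2^31
derive_seed <- function(seed, cond_i, reactor_i, time_i = 0L) {
  (as.integer(seed) * 7919L + cond_i * 104729L + reactor_i * 1299709L +
     time_i * 15485863L) %% 2147483629L
}

#' Simulate a complete in-silico experiment
#'
#' Generates growth curves, Pb(II) depletion, linked circuit-parameter
#' trajectories and noisy sweeps for every (condition, reactor, time), and
#' writes them in the exact CSV dialects the pipeline reads, plus a truth
#' JSON holding every generating parameter. Byte-identical for identical
#' (config, seed).
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths (`spectra`, `growth`,
#'   `pb`, `truth`) and the in-memory objects.
#' @export
simulate_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)

  spectra <- list(); growth_rows <- list(); pb_rows <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    for (ri in seq_len(config$n_reactors)) {
      rid <- paste0("R", ri)
      gspec <- config$growth_spec
      jitter <- with_seed(derive_seed(config$seed, ci, ri),
                          stats::rnorm(1, 0, config$growth_jitter_sd))
      gspec$initial_log_cfu <- gspec$initial_log_cfu + jitter
      g <- simulate_growth(gspec, config$times, rid, cond)
      growth_rows[[length(growth_rows) + 1L]] <-
        data.frame(time_h = g$time_h, reactor_id = rid, condition = cond,
                   log_cfu = g$log_cfu)
      if (cond == "with_pb")
        pb_rows[[length(pb_rows) + 1L]] <- simulate_pb(config$pb_spec, g)
      plist <- params_from_growth(config$linkage, g, cond)
      for (ti in seq_along(config$times)) {
        sp <- simulate_spectrum(
          plist[[ti]], config$grid,
          noise_spec(config$noise_sigma_abs, config$noise_sigma_rel,
                     derive_seed(config$seed, ci, ri, ti)),
          series_resistance = config$series_resistance,
          reactor_id = rid, time_h = config$times[ti], condition = cond)
        spectra[[length(spectra) + 1L]] <- sp
      }
    }
  }

  paths <- list(spectra = file.path(out_dir, "spectra.csv"),
                growth = file.path(out_dir, "growth.csv"),
                pb = file.path(out_dir, "pb.csv"),
                truth = file.path(out_dir, "truth.json"))
  write_spectra(spectra, paths$spectra)
  utils::write.csv(do.call(rbind, growth_rows), paths$growth,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, pb_rows), paths$pb,
                   row.names = FALSE, quote = FALSE)

  truth <- list(
    preset = config$preset, seed = config$seed, times = config$times,
    n_reactors = config$n_reactors, conditions = config$conditions,
    growth_spec = unclass(config$growth_spec),
    pb_spec = unclass(config$pb_spec),
    linkage = unclass(config$linkage),
    noise = list(sigma_abs = config$noise_sigma_abs,
                 sigma_rel = config$noise_sigma_rel),
    growth_jitter_sd = config$growth_jitter_sd,
    series_resistance = config$series_resistance,
    exponents = list(p1 = -1.5, pW = -0.5, p2 = 1),
    neg_b0_slope = list(
      with_pb = linkage_neg_b0_slope(config$linkage, "with_pb"),
      without_pb = linkage_neg_b0_slope(config$linkage, "without_pb")),
    true_params = lapply(seq_along(spectra), function(i) {
      sp <- spectra[[i]]
      tp <- attr(sp, "truth")
      c(list(condition = sp$condition, reactor_id = sp$reactor_id,
             time_h = sp$time_h), unclass(tp))
    }))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, spectra = spectra,
                 growth = do.call(rbind, growth_rows),
                 pb = do.call(rbind, pb_rows), truth = truth))
}

#' Stock concentration from dissolved mass
#'
#' `mass_g * mass_fraction * 1000 / volume_l`, in mg/L of the element of
#' interest. For lead nitrate the Pb mass fraction is 207.2 / 331.2 (atomic
#' masses Pb 207.2, N 14.007, O 15.999), so 1.6 g in 100 mL gives
#' ~10,000 mg/L Pb(II) (2 significant figures).
#'
#' @param mass_g Dissolved mass in grams.
#' @param mass_fraction Mass fraction of the element in the compound,
#'   in (0, 1].
#' @param volume_l Solution volume in litres.
#' @return Concentration in mg/L.
#' @export
stock_concentration <- function(mass_g, mass_fraction, volume_l) {
  stopifnot(mass_g >= 0, mass_fraction > 0, mass_fraction <= 1)
  if (volume_l <= 0) stop("volume must be positive")
  mass_g * mass_fraction * 1000 / volume_l
}

#' Pb mass fraction of lead nitrate
#'
#' 207.2 / (207.2 + 2 * (14.007 + 3 * 15.999)).
#' @return The dimensionless mass fraction (~0.6256).
#' @export
pb_fraction_lead_nitrate <- function() {
  207.2 / (207.2 + 2 * (14.007 + 3 * 15.999))
}

#' Nominal concentration after dosing a reactor from stock
#'
#' `v_add_ml * c_stock_mg_l / v_reactor_ml`; the added volume is not
#' counted in the denominator, matching the nominal dosing arithmetic
#' (0.8 mL of 10,000 mg/L stock into 100 mL gives 80 mg/L).
#'
#' @param v_add_ml Added stock volume (mL).
#' @param c_stock_mg_l Stock concentration (mg/L).
#' @param v_reactor_ml Reactor volume (mL).
#' @return Concentration in mg/L.
#' @export
dilution_concentration <- function(v_add_ml, c_stock_mg_l, v_reactor_ml) {
  stopifnot(v_add_ml >= 0, c_stock_mg_l >= 0)
  if (v_reactor_ml <= 0) stop("reactor volume must be positive")
  v_add_ml * c_stock_mg_l / v_reactor_ml
}
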