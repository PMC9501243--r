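# Least-squares estimation of the equivalent-circuit parameters from
# measured reactance.
#
# Two stages mirror the modelling workflow:
#   * fixed-exponent stage: with p1, p2 pinned the model is LINEAR in
#     (a0, b0, c0, d0), so the fit is an exact weighted linear least-squares
#     solve (QR with column scaling; the raw design spans ~14 orders of
#     magnitude between the omega^-1.5 and omega columns).
#   * free-exponent stage: p1 < 0 and p2 > 0 are released (the Warburg
#     exponent stays at -0.5) and estimated by variable projection — the
#     optimizer searches only (p1, p2) and the coefficients are recovered by
#     the linear solve at each candidate pair. This has the same optimum as
#     a joint 6-parameter nonlinear fit but a far better-conditioned search
#     space, and it is deterministic: a fixed multi-start list, no RNG.

#' Fit configuration
#'
#' Collects the tunable settings of the fitting stage. Unknown names are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param p1,p2 Fixed-stage exponents (defaults -1.5 and +1).
#' @param pW Warburg exponent, held fixed in both stages (default -0.5).
#' @param weighting Residual weighting: `"none"` (unweighted squared
#'   reactance residual, the default), `"inv_abs_x"` (1/|X|) or
#'   `"inv_abs_z"` (1/|Z|).
#' @param max_iterations Iteration cap per optimizer start (default 50000).
#' @param bounds_p1,bounds_p2 Free-stage box bounds.
#' @param starts Matrix of free-stage starting points, one `(p1, p2)` row
#'   per start; the default is `c(-1.5, 1)` plus four fixed perturbations.
#' @param fix_d0_zero Hold the inductance d0 at zero (useful for data where
#'   the wire-inductance term is negligible). Default `FALSE`: freezing d0
#'   at a nonzero value is never done — it can prevent the optimizer from
#'   reaching a solution.
#' @return A list of class `eis_fit_config`.
#' @export
fit_config <- function(p1 = -1.5, p2 = 1, pW = -0.5,
                       weighting = c("none", "inv_abs_x", "inv_abs_z"),
                       max_iterations = 50000,
                       bounds_p1 = c(-3, -0.01), bounds_p2 = c(0.01, 2),
                       starts = NULL, fix_d0_zero = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(p1 < 0, p2 > 0, pW < 0, max_iterations >= 1,
            bounds_p1[1] < bounds_p1[2], bounds_p2[1] < bounds_p2[2])
  if (is.null(starts)) {
    starts <- rbind(c(p1, p2),
                    c(-1.0, 0.5), c(-2.0, 1.5), c(-0.7, 1.2), c(-2.5, 0.8))
  }
  starts <- as.matrix(starts)
  if (ncol(starts) != 2) stop("starts must have two columns (p1, p2)")
  structure(list(p1 = p1, p2 = p2, pW = pW, weighting = weighting,
                 max_iterations = as.integer(max_iterations),
                 bounds_p1 = bounds_p1, bounds_p2 = bounds_p2,
                 starts = starts, fix_d0_zero = isTRUE(fix_d0_zero)),
            class = "eis_fit_config")
}

reactance_design <- function(omega, p1, pW, p2, fix_d0_zero = FALSE) {
  cols <- cbind(a0 = rep(1, length(omega)),
                b0 = omega^p1 * sin(p1 * pi / 2),
                c0 = omega^pW * sin(pW * pi / 2),
                d0 = omega^p2 * sin(p2 * pi / 2))
  if (fix_d0_zero) cols <- cols[, 1:3, drop = FALSE]
  cols
}

residual_weights <- function(spectrum, weighting) {
  switch(weighting,
         none = rep(1, length(spectrum$reactance)),
         inv_abs_x = 1 / pmax(abs(spectrum$reactance), .Machine$double.eps),
         inv_abs_z = 1 / pmax(sqrt(spectrum$resistance^2 +
                                   spectrum$reactance^2),
                              .Machine$double.eps))
}

# Weighted linear LS with column equilibration; returns coefficients
# (rank-deficient columns -> 0), residual sum of squares and rank.
scaled_lls <- function(X, y, w = NULL) {
  if (!is.null(w)) {
    sw <- sqrt(w)
    X <- X * sw
    y <- y * sw
  }
  nrm <- sqrt(colSums(X^2))
  keep <- nrm > 0
  beta <- numeric(ncol(X))
  if (any(keep)) {
    Xs <- sweep(X[, keep, drop = FALSE], 2, nrm[keep], "/")
    qrx <- qr(Xs)
    bs <- qr.coef(qrx, y)
    bs[is.na(bs)] <- 0
    beta[keep] <- bs / nrm[keep]
  } else {
    qrx <- list(rank = 0L)
  }
  res <- y - X %*% beta
  list(coef = beta, rss = sum(res^2), rank = qrx$rank)
}

new_fit_result <- function(params, residual_ss, n_points, n_iter, converged) {
  structure(list(params = params,
                 residual_ss = residual_ss,
                 n_points = n_points,
                 n_iterations_used = n_iter,
                 converged = converged,
                 negated_report = c(a0 = -params$a0, b0 = -params$b0,
                                    c0 = -params$c0, d0 = -params$d0)),
            class = "eis_fit")
}

#' @export
print.eis_fit <- function(x, ...) {
  cat(sprintf("<eis_fit> %s, RSS = %.4g ohm^2 over %d points\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual_ss, x$n_points))
  print(x$params)
  invisible(x)
}

#' Fixed-exponent equivalent-circuit fit
#'
#' Estimates `(a0, b0, c0, d0)` by minimising the (optionally weighted) sum
#' of squared reactance residuals with the exponents held fixed. The model
#' is linear in the coefficients, so the solution is the exact linear
#' least-squares estimate on the design
#' `[1, omega^p1*sin(p1*pi/2), omega^pW*sin(pW*pi/2), omega^p2*sin(p2*pi/2)]`.
#'
#' @param spectrum An [impedance_spectrum()] with at least 5 frequencies.
#' @param config A [fit_config()].
#' @return An object of class `eis_fit`: `params` ([circuit_params()]),
#'   `residual_ss` (ohm^2), `n_points`, `n_iterations_used`, `converged`,
#'   and `negated_report` — the tuple `(-a0, -b0, -c0, -d0)` in the sign
#'   convention used for plotting parameter time-courses.
#' @export
fit_fixed_exponents <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(config, "eis_fit_config"))
  n <- length(spectrum$grid$f)
  if (n < 5) stop("need at least 5 frequency points to fit 4 coefficients")
  X <- reactance_design(spectrum$grid$omega, config$p1, config$pW, config$p2,
                        config$fix_d0_zero)
  sol <- scaled_lls(X, spectrum$reactance,
                    residual_weights(spectrum, config$weighting))
  if (sol$rank < ncol(X))
    stop("rank-deficient design: frequencies do not separate the model terms")
  cf <- sol$coef
  if (config$fix_d0_zero) cf <- c(cf, 0)
  params <- circuit_params(a0 = cf[1], b0 = cf[2], c0 = cf[3], d0 = cf[4],
                           p1 = config$p1, p2 = config$p2)
  new_fit_result(params, sol$rss, n, n_iter = 1L, converged = TRUE)
}

#' Free-exponent equivalent-circuit fit
#'
#' Releases the exponents `p1 < 0` and `p2 > 0` (Warburg stays at `pW`) and
#' minimises the same reactance residual over all six parameters. The
#' search uses variable projection: a bounded quasi-Newton optimisation
#' over `(p1, p2)` (L-BFGS-B, iteration cap per start) in which the four
#' coefficients are profiled out by the exact linear solve. A fixed
#' multi-start list guards against local minima; the result is
#' deterministic. If no start converges the best-effort parameters are
#' returned with `converged = FALSE` rather than an error.
#'
#' @param spectrum An [impedance_spectrum()] with at least 7 frequencies.
#' @param config A [fit_config()]; `bounds_p1`, `bounds_p2` and `starts`
#'   control the search.
#' @return An `eis_fit` (see [fit_fixed_exponents()]) whose `params` carry
#'   the fitted exponents.
#' @export
fit_free_exponents <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(config, "eis_fit_config"))
  n <- length(spectrum$grid$f)
  if (n < 7) stop("need at least 7 frequency points for the free-exponent fit")
  w <- residual_weights(spectrum, config$weighting)
  omega <- spectrum$grid$omega
  y <- spectrum$reactance

  objective <- function(p) {
    X <- reactance_design(omega, p[1], config$pW, p[2], config$fix_d0_zero)
    scaled_lls(X, y, w)$rss
  }

  lower <- c(config$bounds_p1[1], config$bounds_p2[1])
  upper <- c(config$bounds_p1[2], config$bounds_p2[2])
  starts <- config$starts
  starts[, 1] <- pmin(pmax(starts[, 1], lower[1]), upper[1])
  starts[, 2] <- pmin(pmax(starts[, 2], lower[2]), upper[2])

  best <- NULL
  total_iter <- 0L
  any_conv <- FALSE
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[k, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = config$max_iterations,
                                  factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    total_iter <- total_iter + as.integer(fit$counts[1])
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    # every start failed outright: fall back to the fixed-exponent solution
    p <- c(config$p1, config$p2)
    best <- list(par = p, value = objective(p))
  }

  p1 <- best$par[1]; p2 <- best$par[2]
  X <- reactance_design(omega, p1, config$pW, p2, config$fix_d0_zero)
  sol <- scaled_lls(X, y, w)
  cf <- sol$coef
  if (config$fix_d0_zero) cf <- c(cf, 0)
  params <- circuit_params(a0 = cf[1], b0 = cf[2], c0 = cf[3], d0 = cf[4],
                           p1 = p1, p2 = p2)
  new_fit_result(params, sol$rss, n,
                 n_iter = min(total_iter, config$max_iterations * nrow(starts)),
                 converged = any_conv)
}

#' Replicate-averaged circuit parameters at one time point
#'
#' Fits each reactor's spectrum independently (fixed-exponent stage) and
#' summarises the coefficients across reactors by their mean and sample
#' standard deviation (`sd`, denominator n-1; 0 when a single reactor is
#' supplied). All spectra must share one condition and one sample time.
#'
#' @param spectra A list of [impedance_spectrum()] objects (>= 1), one per
#'   reactor.
#' @param config A [fit_config()].
#' @return A one-row data.frame with columns `condition`, `time_h`,
#'   `n_reactors`, `<coef>_mean` and `<coef>_std` for a0..d0, and
#'   `residual_ss_mean`.
#' @export
fit_replicates <- function(spectra, config = fit_config()) {
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  conds <- vapply(spectra, `[[`, "", "condition")
  times <- vapply(spectra, `[[`, 0, "time_h")
  if (length(unique(conds)) > 1)
    stop("mixed conditions in one replicate group: ",
         paste(unique(conds), collapse = ", "))
  if (length(unique(times)) > 1)
    stop("mixed sample times in one replicate group")
  fits <- lapply(spectra, fit_fixed_exponents, config = config)
  coefs <- t(vapply(fits, function(f)
    unlist(f$params[c("a0", "b0", "c0", "d0")]), numeric(4)))
  m <- colMeans(coefs)
  s <- if (nrow(coefs) > 1) apply(coefs, 2, stats::sd) else rep(0, 4)
  out <- data.frame(condition = conds[1], time_h = times[1],
                    n_reactors = length(spectra))
  for (i in seq_along(m)) {
    nm <- names(m)[i]
    out[[paste0(nm, "_mean")]] <- m[[i]]
    out[[paste0(nm, "_std")]] <- s[[i]]
  }
  out$residual_ss_mean <- mean(vapply(fits, `[[`, 0, "residual_ss"))
  out
}

#' Parameter time-course across a whole experiment
#'
#' Groups spectra by (condition, time), fits every reactor, and returns one
#' replicate summary row per group, ordered by condition then time. The
#' per-reactor fits are attached as attribute `"fits"` (a data.frame with
#' one row per reactor and time).
#'
#' @param spectra A list of [impedance_spectrum()] objects covering the
#'   experiment (e.g. from [read_spectra()]).
#' @param config A [fit_config()].
#' @return A data.frame of replicate summaries (see [fit_replicates()]).
#' @export
fit_timecourse <- function(spectra, config = fit_config()) {
  stopifnot(length(spectra) >= 1)
  key <- paste(vapply(spectra, `[[`, "", "condition"),
               vapply(spectra, `[[`, 0, "time_h"), sep = "@")
  groups <- split(spectra, key)
  rows <- list(); fit_rows <- list()
  for (g in groups) {
    rows[[length(rows) + 1L]] <- fit_replicates(g, config)
    for (sp in g) {
      f <- fit_fixed_exponents(sp, config)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        condition = sp$condition, reactor_id = sp$reactor_id,
        time_h = sp$time_h,
        a0 = f$params$a0, b0 = f$params$b0, c0 = f$params$c0,
        d0 = f$params$d0, residual_ss = f$residual_ss,
        n_points = f$n_points)
    }
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$condition, summary$time_h), , drop = FALSE]
  rownames(summary) <- NULL
  fits <- do.call(rbind, fit_rows)
  fits <- fits[order(fits$condition, fits$reactor_id, fits$time_h), ,
               drop = FALSE]
  rownames(fits) <- NULL
  attr(summary, "fits") <- fits
  summary
}
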