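# CFU arithmetic, exponential-window selection, supercapacitance-vs-CFU
# correlation, and Pb-presence classification.
#
# "CFU count" throughout means log10(CFU/mL). The correlation step regresses
# the replicate-mean supercapacitor magnitude -b0 (y) on the CFU count (x)
# inside the exponential growth window, where the relation is approximately
# linear; outside that window only qualitative trends hold.

#' log10(CFU/mL) from a plate count
#'
#' Standard spread-plate arithmetic:
#' `log10(count / (dilution_factor * plated_volume_ml))`. A zero colony
#' count is below the detection limit of the dilution; it is reported as
#' the count-of-one concentration minus 1 log (a finite sentinel), never
#' as -Inf.
#'
#' @param colony_count Non-negative integer count of colonies.
#' @param dilution_factor Dilution of the plated sample in (0, 1]
#'   (e.g. 1e-6 for a 10^-6 dilution).
#' @param plated_volume_ml Plated volume in mL (default 0.1, the common
#'   spread-plate volume).
#' @return log10(CFU/mL), vectorised over the inputs.
#' @examples
#' log_cfu_from_plate(43, 1e-6)  # 43 colonies at 10^-6: ~8.63
#' @export
log_cfu_from_plate <- function(colony_count, dilution_factor,
                               plated_volume_ml = 0.1) {
  if (any(colony_count < 0)) stop("negative colony count")
  if (any(colony_count != round(colony_count)))
    stop("colony count must be an integer")
  if (any(dilution_factor <= 0 | dilution_factor > 1))
    stop("dilution factor must be in (0, 1]")
  if (any(plated_volume_ml <= 0)) stop("plated volume must be positive")
  detection <- log10(1 / (dilution_factor * plated_volume_ml)) - 1
  out <- ifelse(colony_count == 0, detection,
                log10(colony_count / (dilution_factor * plated_volume_ml)))
  as.numeric(out)
}

#' One reactor's growth series
#'
#' @param time_h Sample times in hours, strictly ascending.
#' @param log_cfu log10(CFU/mL) at each time, finite.
#' @param reactor_id,condition Grouping metadata.
#' @return An object of class `growth_series` (a data.frame).
#' @export
growth_series <- function(time_h, log_cfu, reactor_id = "R1",
                          condition = "without_pb") {
  stopifnot(length(time_h) == length(log_cfu))
  if (any(!is.finite(time_h)) || any(!is.finite(log_cfu)))
    stop("non-finite growth data")
  if (any(diff(time_h) <= 0)) stop("times must be strictly ascending")
  structure(data.frame(time_h = as.numeric(time_h),
                       log_cfu = as.numeric(log_cfu),
                       reactor_id = reactor_id,
                       condition = match.arg(condition,
                                             c("with_pb", "without_pb"))),
            class = c("growth_series", "data.frame"))
}

#' Exponential growth window of a growth series
#'
#' Two modes. `"manual"` returns the configured window unchanged — the
#' hands-on choice when the phase boundaries are known (e.g. the first
#' hours up to 6 h for a K. pneumoniae-like run). `"auto"` scans per-step
#' slopes of log CFU and returns the maximal contiguous run of steps whose
#' slope exceeds `frac` times the maximum observed slope; for a
#' rise-then-decline curve this ends at the last pre-peak sample.
#'
#' @param series A [growth_series()] with at least 3 points.
#' @param mode `"manual"` or `"auto"`.
#' @param window Numeric `c(t_start, t_end)` for manual mode.
#' @param frac Auto mode slope threshold as a fraction of the maximum
#'   per-step slope (default 0.5).
#' @return Numeric `c(t_start, t_end)` in hours.
#' @export
exponential_window <- function(series, mode = c("manual", "auto"),
                               window = c(0, 6), frac = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "growth_series"))
  if (nrow(series) < 3) stop("need at least 3 points to locate a growth window")
  if (mode == "manual") {
    stopifnot(length(window) == 2, window[1] < window[2])
    return(as.numeric(window))
  }
  slopes <- diff(series$log_cfu) / diff(series$time_h)
  ok <- slopes >= frac * max(slopes)
  # longest contiguous TRUE run (first one on ties)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  c(series$time_h[starts[best]], series$time_h[ends[best] + 1])
}

#' Correlate the extracted supercapacitance with CFU counts
#'
#' Ordinary least-squares line of the replicate-mean `-b0` (y) against
#' log10(CFU/mL) (x), restricted to time points inside the exponential
#' window. Fit times are matched to CFU sample times by nearest neighbour
#' within `match_tol_h`. For a K. pneumoniae-like culture the slope is
#' negative: `-b0` falls as the cells proliferate.
#'
#' @param fit_table A time-course summary with columns `time_h` and
#'   `b0_mean` (one condition; see [fit_timecourse()]). When `b0_std` and
#'   `n_reactors` columns are present, the replicate spread is propagated
#'   through the OLS slope formula to give the slope standard error
#'   (`slope_se`); otherwise the residual-based SE is used.
#' @param growth A [growth_series()] (replicate-mean CFU counts).
#' @param window Numeric `c(t_start, t_end)` hours (inclusive).
#' @param match_tol_h Maximum |fit time - CFU time| for a match (default
#'   0.5 h).
#' @return A list of class `supercap_correlation`: `slope`, `intercept`,
#'   `r_squared`, `n`, `window`, `slope_se`, and the matched points as a
#'   data.frame.
#' @export
correlate_supercap_cfu <- function(fit_table, growth, window,
                                   match_tol_h = 0.5) {
  stopifnot(is.data.frame(fit_table), all(c("time_h", "b0_mean") %in%
                                          names(fit_table)),
            inherits(growth, "growth_series"), length(window) == 2)
  ft <- fit_table[fit_table$time_h >= window[1] &
                  fit_table$time_h <= window[2], , drop = FALSE]
  if (length(unique(ft$time_h)) != nrow(ft))
    stop("fit_table must contain a single condition (duplicate time points)")
  has_spread <- all(c("b0_std", "n_reactors") %in% names(ft))
  matched <- lapply(seq_len(nrow(ft)), function(i) {
    d <- abs(growth$time_h - ft$time_h[i])
    j <- which.min(d)
    if (d[j] <= match_tol_h)
      data.frame(time_h = ft$time_h[i], neg_b0 = -ft$b0_mean[i],
                 log_cfu = growth$log_cfu[j],
                 sd_y = if (has_spread)
                          ft$b0_std[i] / sqrt(ft$n_reactors[i])
                        else NA_real_)
    else NULL
  })
  pts <- do.call(rbind, matched)
  if (is.null(pts) || nrow(pts) < 2)
    stop("fewer than 2 matched time points inside the window")
  if (stats::var(pts$log_cfu) == 0)
    stop("log CFU is constant inside the window: slope undefined")
  fit <- stats::lm(neg_b0 ~ log_cfu, data = pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$neg_b0 - mean(pts$neg_b0))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  # slope SE: propagate the per-point measurement sd through the OLS slope
  # weights c_i = (x_i - xbar)/Sxx when replicate spread is available (it
  # has more pooled degrees of freedom than the n-2 residual estimate);
  # otherwise fall back to the residual-based SE.
  sxx <- sum((pts$log_cfu - mean(pts$log_cfu))^2)
  se_resid <- sqrt(ss_res / (nrow(pts) - 2) / sxx)
  se <- if (!anyNA(pts$sd_y) && any(pts$sd_y > 0)) {
    xc <- pts$log_cfu - mean(pts$log_cfu)
    # pool the per-point variances: each b0_std has only n_reactors - 1
    # degrees of freedom, so the pooled estimate is far more stable
    sqrt(mean(pts$sd_y^2) * sum((xc / sum(xc^2))^2))
  } else se_resid
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = nrow(pts),
                 window = as.numeric(window),
                 points = pts,
                 slope_se = se),
            class = "supercap_correlation")
}

#' @export
print.supercap_correlation <- function(x, ...) {
  cat(sprintf(
    "<supercap_correlation> -b0 = %.4g %+.4g * logCFU  (R^2 = %.3f, n = %d, window %g-%g h)\n",
    x$intercept, x$slope, x$r_squared, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Classify Pb(II) presence from the supercapacitor magnitude
#'
#' With and without dissolved Pb(II) the magnitude of the supercapacitor
#' coefficient `|b0|` differs by orders of magnitude, so a simple magnitude
#' threshold separates the two states. The threshold is the midpoint of
#' the two class means of `log10|b0|`; a query above it is called
#' `pb_present`, and a query exactly on it is called `pb_absent` (tie goes
#' to the smaller-magnitude class). The classifier is monotone in the
#' query magnitude.
#'
#' @param b0_magnitudes Numeric training magnitudes `|b0|` (> 0).
#' @param labels Character vector, `"pb_present"` / `"pb_absent"` (or
#'   logical, `TRUE` = Pb present); both classes must be represented.
#' @param query Numeric `|b0|` values to classify (> 0).
#' @return A list: `labels` (classification of `query`),
#'   `log10_threshold`, `threshold`.
#' @export
classify_pb_presence <- function(b0_magnitudes, labels, query) {
  if (is.logical(labels))
    labels <- ifelse(labels, "pb_present", "pb_absent")
  stopifnot(length(b0_magnitudes) == length(labels),
            all(labels %in% c("pb_present", "pb_absent")))
  if (any(b0_magnitudes <= 0) || any(query <= 0))
    stop("magnitudes must be positive")
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes")
  lg <- log10(b0_magnitudes)
  m_with <- mean(lg[labels == "pb_present"])
  m_without <- mean(lg[labels == "pb_absent"])
  if (m_with <= m_without)
    stop("pb_present class must have the larger mean log magnitude")
  thr <- (m_with + m_without) / 2
  list(labels = ifelse(log10(query) > thr, "pb_present", "pb_absent"),
       log10_threshold = thr,
       threshold = 10^thr)
}

#' Read growth tables
#'
#' Accepts either direct CFU counts (`log_cfu` column) or plate counts
#' (`colony_count`, `dilution_factor` columns, converted through
#' [log_cfu_from_plate()]). Required metadata: `time_h`, `reactor_id`,
#' `condition`.
#'
#' @param path CSV path.
#' @param plated_volume_ml Passed to [log_cfu_from_plate()] when counts are
#'   given.
#' @return A list of [growth_series()], one per (condition, reactor).
#' @export
read_growth <- function(path, plated_volume_ml = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "reactor_id", "condition")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  if (!"log_cfu" %in% names(df)) {
    if (!all(c("colony_count", "dilution_factor") %in% names(df)))
      stop("growth file needs either log_cfu or colony_count + dilution_factor")
    df$log_cfu <- log_cfu_from_plate(df$colony_count, df$dilution_factor,
                                     plated_volume_ml)
  }
  groups <- split(df, interaction(df$condition, df$reactor_id, drop = TRUE))
  out <- lapply(groups, function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    growth_series(g$time_h, g$log_cfu, g$reactor_id[1], g$condition[1])
  })
  names(out) <- NULL
  out
}

#' Read residual Pb(II) tables
#'
#' @param path CSV with columns `time_h`, `reactor_id`, `pb_mg_per_l`.
#' @return A data.frame, times ascending within reactor; concentrations
#'   must be non-negative.
#' @export
read_pb <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "reactor_id", "pb_mg_per_l")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  if (any(df$pb_mg_per_l < 0)) stop("negative Pb(II) concentration")
  df[order(df$reactor_id, df$time_h), , drop = FALSE]
}

#' Mean CFU count across replicate reactors
#'
#' @param series_list A list of [growth_series()] sharing one condition.
#' @return A single [growth_series()] with `reactor_id = "mean"`.
#' @export
mean_growth <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  conds <- vapply(series_list, function(s) s$condition[1], "")
  if (length(unique(conds)) > 1) stop("mixed conditions")
  df <- do.call(rbind, lapply(series_list, as.data.frame))
  agg <- stats::aggregate(log_cfu ~ time_h, df, mean)
  agg <- agg[order(agg$time_h), ]
  growth_series(agg$time_h, agg$log_cfu, "mean", conds[1])
}
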