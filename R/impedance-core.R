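# Data model and I/O for electrochemical impedance sweeps.
#
# Conventions used throughout the package:
#   * frequencies in Hz, impedances in ohm, phase in degrees on the
#     interval (-180, 180], sample times in hours;
#   * capacitive reactance is stored negative; Nyquist plots use -X so the
#     trace sits in the first quadrant;
#   * spectra CSV files are long-format with explicit reactor_id, time_h and
#     condition columns so replicate grouping never depends on file layout.

DEG_PER_RAD <- 180 / pi

#' Logarithmic frequency grid for an impedance sweep
#'
#' Constructs and validates the frequency axis of an EIS sweep. Frequencies
#' must be strictly positive, strictly ascending and free of duplicates.
#' Angular frequencies `omega = 2*pi*f` (rad/s) are carried alongside.
#'
#' @param frequencies Numeric vector of frequencies in Hz.
#' @return An object of class `frequency_grid`: a list with elements
#'   `f` (Hz) and `omega` (rad/s).
#' @examples
#' g <- frequency_grid(c(10, 100, 1000))
#' g$omega / g$f  # all 2*pi
#' @export
frequency_grid <- function(frequencies) {
  f <- as.numeric(frequencies)
  if (length(f) == 0) stop("frequency grid is empty")
  if (any(!is.finite(f))) stop("non-finite frequency in grid")
  if (any(f <= 0)) stop("frequencies must be strictly positive")
  if (any(diff(f) == 0)) stop("duplicate frequency in grid")
  if (any(diff(f) < 0)) stop("frequencies must be strictly ascending")
  structure(list(f = f, omega = 2 * pi * f), class = "frequency_grid")
}

#' Default log-spaced sweep grid
#'
#' Log-spaced points between two frequency bounds; the defaults span the
#' 10 Hz to 1 MHz band of the measurement device with 61 points
#' (12 points per decade), enough to resolve all four model terms.
#'
#' @param n Number of points.
#' @param f_min,f_max Sweep bounds in Hz.
#' @return A [frequency_grid()].
#' @export
default_grid <- function(n = 61, f_min = 10, f_max = 1e6) {
  stopifnot(n >= 2, f_min > 0, f_max > f_min)
  frequency_grid(10^seq(log10(f_min), log10(f_max), length.out = n))
}

#' @export
length.frequency_grid <- function(x) length(x$f)

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d points, %.6g Hz to %.6g Hz\n",
              length(x$f), min(x$f), max(x$f)))
  invisible(x)
}

wrap_phase_deg <- function(phase_deg) {
  # wrap to (-180, 180]
  p <- (phase_deg + 180) %% 360 - 180
  p[p == -180] <- 180
  p
}

#' Impedance from simultaneous voltage and current phasors
#'
#' Ohm's-law division of complex phasors: `|Z| = |V| / |I|` and
#' `angle(Z) = angle(V) - angle(I)`, with the phase wrapped to (-180, 180]
#' degrees. A zero-magnitude current signals an unmeasurable impedance and
#' is rejected.
#'
#' @param voltage Complex voltage phasor (V).
#' @param current Complex current phasor (A); must be nonzero.
#' @return A list with `magnitude` (ohm) and `phase` (degrees).
#' @examples
#' compute_impedance(1 + 0i, 0.5 + 0i)  # 2 ohm, 0 degrees
#' @export
compute_impedance <- function(voltage, current) {
  v <- as.complex(voltage)
  i <- as.complex(current)
  stopifnot(length(v) == 1, length(i) == 1)
  if (!is.finite(Mod(v)) || !is.finite(Mod(i))) stop("non-finite phasor")
  if (Mod(i) == 0) stop("zero current: impedance is unmeasurable")
  list(magnitude = Mod(v) / Mod(i),
       phase = wrap_phase_deg((Arg(v) - Arg(i)) * DEG_PER_RAD))
}

#' Polar to rectangular impedance conversion
#'
#' `R = |Z| cos(theta)`, `X = |Z| sin(theta)` with theta in degrees.
#'
#' @param magnitude Impedance magnitude in ohm (vectorised).
#' @param phase_deg Phase in degrees.
#' @return A list with `resistance` and `reactance`, both in ohm.
#' @seealso [rect_to_polar()]
#' @export
polar_to_rect <- function(magnitude, phase_deg) {
  stopifnot(length(magnitude) == length(phase_deg))
  if (any(magnitude < 0, na.rm = TRUE)) stop("negative impedance magnitude")
  th <- phase_deg / DEG_PER_RAD
  list(resistance = magnitude * cos(th), reactance = magnitude * sin(th))
}

#' Rectangular to polar impedance conversion
#'
#' Inverse of [polar_to_rect()]; recovers the input to better than 1e-9
#' relative. Phase is reported in (-180, 180] degrees.
#'
#' @param resistance,reactance Ohm (vectorised).
#' @return A list with `magnitude` (ohm) and `phase` (degrees).
#' @export
rect_to_polar <- function(resistance, reactance) {
  stopifnot(length(resistance) == length(reactance))
  z <- complex(real = resistance, imaginary = reactance)
  list(magnitude = Mod(z), phase = wrap_phase_deg(Arg(z) * DEG_PER_RAD))
}

#' One impedance sweep with reactor metadata
#'
#' Bundles a frequency grid with rectangular-form readings and the grouping
#' metadata used for replicate averaging. Readings may be supplied in
#' rectangular (`resistance`, `reactance`) or polar (`magnitude`,
#' `phase_deg`) form; polar input is converted on construction.
#'
#' @param grid A [frequency_grid()] (or numeric frequencies in Hz).
#' @param resistance,reactance Ohm, one value per frequency.
#' @param magnitude,phase_deg Polar alternative to the rectangular pair.
#' @param reactor_id Reactor label (e.g. `"R1"`).
#' @param time_h Sample time in hours.
#' @param condition `"with_pb"` or `"without_pb"`.
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(grid, resistance = NULL, reactance = NULL,
                               magnitude = NULL, phase_deg = NULL,
                               reactor_id = "R1", time_h = NA_real_,
                               condition = "without_pb") {
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  if (is.null(resistance) != is.null(reactance))
    stop("resistance and reactance must be supplied together")
  if (is.null(resistance)) {
    if (is.null(magnitude) || is.null(phase_deg))
      stop("supply either (resistance, reactance) or (magnitude, phase_deg)")
    rect <- polar_to_rect(magnitude, phase_deg)
    resistance <- rect$resistance
    reactance <- rect$reactance
  }
  n <- length(grid$f)
  if (length(resistance) != n || length(reactance) != n)
    stop("readings and frequency grid differ in length")
  if (any(!is.finite(resistance)) || any(!is.finite(reactance)))
    stop("non-finite impedance reading")
  condition <- match.arg(condition, c("with_pb", "without_pb"))
  structure(list(grid = grid,
                 resistance = as.numeric(resistance),
                 reactance = as.numeric(reactance),
                 reactor_id = as.character(reactor_id),
                 time_h = as.numeric(time_h),
                 condition = condition),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("<impedance_spectrum> reactor %s, t = %s h, %s, %d frequencies\n",
              x$reactor_id, format(x$time_h), x$condition, length(x$grid$f)))
  invisible(x)
}

#' Nyquist-plot coordinates of a spectrum
#'
#' Returns one `(resistance, -reactance)` pair per frequency, ordered by
#' ascending frequency. Negating the reactance puts capacitive sweeps in the
#' first quadrant, the usual Nyquist convention.
#'
#' @param spectrum An [impedance_spectrum()].
#' @return A data.frame with columns `frequency_hz`, `resistance`,
#'   `neg_reactance`.
#' @export
nyquist_points <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  data.frame(frequency_hz = spectrum$grid$f,
             resistance = spectrum$resistance,
             neg_reactance = -spectrum$reactance)
}

.spectra_cols <- list(
  polar = c("frequency_hz", "z_mag_ohm", "z_phase_deg"),
  rect  = c("frequency_hz", "z_real_ohm", "z_imag_ohm"))
.meta_cols <- c("reactor_id", "time_h", "condition")

#' Read impedance sweeps from a long-format CSV file
#'
#' The file must carry the metadata columns `reactor_id`, `time_h`,
#' `condition` plus either the polar columns (`frequency_hz`, `z_mag_ohm`,
#' `z_phase_deg`) or the rectangular columns (`frequency_hz`, `z_real_ohm`,
#' `z_imag_ohm`). Rows are grouped into one spectrum per
#' (reactor, time, condition); within each group frequencies must be
#' strictly ascending with no duplicates and all values finite.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default, inferred from column names), `"polar"`
#'   or `"rect"`.
#' @return A list of [impedance_spectrum()] objects, ordered by condition,
#'   reactor, then time.
#' @export
read_spectra <- function(path, dialect = c("auto", "polar", "rect")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "auto") {
    dialect <- if (all(.spectra_cols$polar %in% names(df))) "polar"
               else if (all(.spectra_cols$rect %in% names(df))) "rect"
               else stop("cannot infer dialect: no complete polar or rect column set in ",
                         path)
  }
  need <- c(.spectra_cols[[dialect]], .meta_cols)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  val_cols <- setdiff(.spectra_cols[[dialect]], "frequency_hz")
  for (cc in c("frequency_hz", val_cols, "time_h"))
    if (any(!is.finite(df[[cc]])))
      stop("non-finite values in column ", cc)
  key <- interaction(df$condition, df$reactor_id, df$time_h, drop = TRUE)
  groups <- split(df, key)
  ord <- order(vapply(groups, function(g) g$condition[1], ""),
               vapply(groups, function(g) g$reactor_id[1], ""),
               vapply(groups, function(g) g$time_h[1], 0))
  spectra <- lapply(groups[ord], function(g) {
    g <- g[order(g$frequency_hz), , drop = FALSE]
    if (anyDuplicated(g$frequency_hz))
      stop("duplicate frequency within sweep (reactor ", g$reactor_id[1],
           ", t = ", g$time_h[1], " h)")
    grid <- frequency_grid(g$frequency_hz)
    if (dialect == "polar")
      impedance_spectrum(grid, magnitude = g$z_mag_ohm,
                         phase_deg = g$z_phase_deg,
                         reactor_id = g$reactor_id[1], time_h = g$time_h[1],
                         condition = g$condition[1])
    else
      impedance_spectrum(grid, resistance = g$z_real_ohm,
                         reactance = g$z_imag_ohm,
                         reactor_id = g$reactor_id[1], time_h = g$time_h[1],
                         condition = g$condition[1])
  })
  names(spectra) <- NULL
  spectra
}

#' Write impedance sweeps to a long-format CSV file
#'
#' Inverse of [read_spectra()]: writing then reading reproduces the spectra
#' up to float formatting (values are written with 15 significant digits).
#'
#' @param spectra A list of [impedance_spectrum()] objects (or a single one).
#' @param path Output CSV path.
#' @param dialect `"rect"` (default) or `"polar"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, dialect = c("rect", "polar")) {
  dialect <- match.arg(dialect)
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(sp) {
    base <- data.frame(reactor_id = sp$reactor_id, time_h = sp$time_h,
                       condition = sp$condition,
                       frequency_hz = sp$grid$f)
    if (dialect == "rect") {
      base$z_real_ohm <- sp$resistance
      base$z_imag_ohm <- sp$reactance
    } else {
      pol <- rect_to_polar(sp$resistance, sp$reactance)
      base$z_mag_ohm <- pol$magnitude
      base$z_phase_deg <- pol$phase
    }
    base
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = NA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
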