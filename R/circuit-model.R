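# The Laplace-domain equivalent-circuit reactance model.
#
# The fitted model is a sum of fractional-order elements evaluated at
# s = j*omega on the principal branch, (j*omega)^p = omega^p * exp(j*p*pi/2),
# so each term contributes reactance coeff * omega^p * sin(p*pi/2) and a
# constant phase of p*90 degrees:
#
#   X(omega) = a0 + b0*omega^p1*sin(p1*pi/2)
#                 + c0*omega^-0.5*sin(-pi/4) + d0*omega^p2*sin(p2*pi/2)
#
# With the canonical exponents p1 = -1.5 (fractional supercapacitor) and
# p2 = +1 (series wire inductance) this reduces to
#   X(omega) = a0 - (b0/sqrt(2))*omega^-1.5 - (c0/sqrt(2))*omega^-0.5
#                 + d0*omega.
# The constant a0 enters the reactance directly as a constant reactive
# offset. The omega^-0.5 term is the diffusion (Warburg) element and is
# never freed. Note on units: b0 multiplies s^-1.5, so it is not a
# capacitance in Farad in the SI sense; it is stored as a raw coefficient
# with pseudo-units ohm*(rad/s)^1.5.

#' Equivalent-circuit parameter set
#'
#' The six quantities of the reactance model: four element magnitudes and
#' two free exponents. `a0` is a constant reactive offset (ohm); `b0`
#' multiplies the fractional-supercapacitor term `s^p1`; `c0` multiplies the
#' Warburg diffusion term `s^-0.5`; `d0` is the series inductance (H)
#' multiplying `s^p2`. Coefficients may take any sign; `p1` must be
#' negative and `p2` positive.
#'
#' @param a0,b0,c0,d0 Element magnitudes (see Details).
#' @param p1 Low-frequency fractional exponent, `< 0` (default -1.5).
#' @param p2 High-frequency exponent, `> 0` (default +1).
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(a0 = 0, b0 = 0, c0 = 0, d0 = 0,
                           p1 = -1.5, p2 = 1) {
  vals <- c(a0 = a0, b0 = b0, c0 = c0, d0 = d0, p1 = p1, p2 = p2)
  if (any(!is.finite(vals))) stop("non-finite circuit parameter")
  if (p1 >= 0) stop("exponent p1 must be negative")
  if (p2 <= 0) stop("exponent p2 must be positive")
  structure(as.list(vals), class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf(
    "<circuit_params> a0 = %.6g, b0 = %.6g, c0 = %.6g, d0 = %.6g (p1 = %g, p2 = %g)\n",
    x$a0, x$b0, x$c0, x$d0, x$p1, x$p2))
  invisible(x)
}

#' Serialize circuit parameters to/from JSON
#'
#' A flat JSON object with keys `a0, b0, c0, d0, p1, p2`.
#'
#' @param params A [circuit_params()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `params_to_json`: JSON string or `path`;
#'   `params_from_json`: a [circuit_params()].
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "circuit_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname params_to_json
#' @param json JSON string or file path to read.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(circuit_params, x[c("a0", "b0", "c0", "d0", "p1", "p2")])
}

omega_of <- function(grid) {
  if (inherits(grid, "frequency_grid")) grid$omega else 2 * pi * as.numeric(grid)
}

#' Reactance of a general sum of fractional-order terms
#'
#' Evaluates `X(omega) = a0 + sum_k coeff_k * omega^(e_k) * sin(e_k*pi/2)`,
#' the imaginary part of `a0 + sum_k coeff_k * (j*omega)^(e_k)` on the
#' principal branch, with `a0` counted directly as a constant reactive
#' offset.
#'
#' @param terms A list of `c(coefficient, exponent)` pairs (possibly empty),
#'   or a 2-column matrix with one term per row.
#' @param a0 Constant reactive offset (ohm).
#' @param grid A [frequency_grid()] or numeric frequencies in Hz.
#' @return Numeric reactance in ohm, one value per frequency.
#' @examples
#' # ideal capacitor of 1 F: term (1, -1); X = -1/omega
#' general_model_reactance(list(c(1, -1)), 0, 1 / (2 * pi))  # omega = 1
#' @export
general_model_reactance <- function(terms, a0, grid) {
  w <- omega_of(grid)
  if (any(w <= 0)) stop("angular frequency must be positive")
  if (is.matrix(terms)) terms <- asplit(terms, 1)
  x <- rep(as.numeric(a0), length(w))
  for (tm in terms) {
    if (length(tm) != 2 || any(!is.finite(tm))) stop("malformed term")
    x <- x + tm[1] * w^tm[2] * sin(tm[2] * pi / 2)
  }
  x
}

#' Reactance of the canonical fixed-structure model
#'
#' The four-element model with the Warburg exponent pinned at -0.5:
#' `X = a0 + b0*omega^p1*sin(p1*pi/2) + c0*omega^-0.5*sin(-pi/4) +
#' d0*omega^p2*sin(p2*pi/2)`. With the default exponents (`p1 = -1.5`,
#' `p2 = 1`) this is
#' `X = a0 - (b0/sqrt(2))*omega^-1.5 - (c0/sqrt(2))*omega^-0.5 + d0*omega`.
#'
#' @param params A [circuit_params()] object.
#' @param grid A [frequency_grid()] or numeric frequencies in Hz.
#' @return Numeric reactance in ohm, one value per frequency.
#' @export
canonical_model_reactance <- function(params, grid) {
  stopifnot(inherits(params, "circuit_params"))
  general_model_reactance(
    list(c(params$b0, params$p1), c(params$c0, -0.5), c(params$d0, params$p2)),
    params$a0, grid)
}

#' Complex impedance of a Warburg diffusion element
#'
#' `Z_W(omega) = A_W * omega^-0.5 * (1 - j)`: magnitude
#' `sqrt(2)*A_W*omega^-0.5` and a constant phase of -45 degrees at every
#' frequency, the diffusion signature that appears as a 45-degree straight
#' line on a Nyquist plot.
#'
#' @param A_W Warburg coefficient, `>= 0` (ohm*(rad/s)^0.5 scale).
#' @param grid A [frequency_grid()] or numeric frequencies in Hz.
#' @return Complex impedance, one value per frequency.
#' @export
warburg_impedance <- function(A_W, grid) {
  if (!is.finite(A_W) || A_W < 0) stop("Warburg coefficient must be >= 0")
  w <- omega_of(grid)
  if (any(w <= 0)) stop("angular frequency must be positive")
  A_W * w^-0.5 * complex(real = 1, imaginary = -1)
}
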