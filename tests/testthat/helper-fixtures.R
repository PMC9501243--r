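# Shared fixtures: all synthetic, built in code at test time.

canonical_truth <- function() {
  circuit_params(a0 = 5, b0 = -2e4, c0 = -500, d0 = 2e-5)
}

noiseless_spectrum <- function(params = canonical_truth(),
                               grid = default_grid(), time_h = 1,
                               reactor_id = "R1", condition = "without_pb") {
  x <- canonical_model_reactance(params, grid)
  impedance_spectrum(grid, resistance = rep(50, length(grid$f)),
                     reactance = x, reactor_id = reactor_id,
                     time_h = time_h, condition = condition)
}

# explicit fixed-exponent design matrix, the closed-form linear LS oracle
oracle_design <- function(omega, p1 = -1.5, pW = -0.5, p2 = 1) {
  cbind(1, omega^p1 * sin(p1 * pi / 2), omega^pW * sin(pW * pi / 2),
        omega^p2 * sin(p2 * pi / 2))
}

random_params <- function() {
  circuit_params(a0 = stats::runif(1, -10, 10),
                 b0 = stats::runif(1, -5e4, 5e4),
                 c0 = stats::runif(1, -2e3, 2e3),
                 d0 = stats::runif(1, -5e-5, 5e-5))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
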