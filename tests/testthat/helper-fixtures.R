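# Shared fixtures: toy cost landscapes with grid-scan oracles, and a cheap
# pacing protocol for AP-level tests.

# Deterministic quadratic two-drug landscape with an interior optimum.
toy_quadratic_context <- function(center = c(A = 3, B = 1),
                                  scale = c(A = 0.1, B = 1)) {
  objective_context(function(doses) {
    d <- c(A = 0, B = 0)
    d[names(doses)] <- doses
    sum(scale * (d[names(center)] - center)^2)
  })
}

# 1-D brute-force oracle: best dose on an n-point grid over [0, bound].
grid_scan_1d <- function(fn, bound, n = 1001) {
  doses <- seq(0, bound, length.out = n)
  costs <- vapply(doses, fn, numeric(1))
  list(dose = doses[which.min(costs)], cost = min(costs),
       step = bound / (n - 1))
}

# 2-D brute-force oracle on an n x n grid over [0, b1] x [0, b2].
grid_scan_2d <- function(fn, bounds, n = 101) {
  g1 <- seq(0, bounds[1], length.out = n)
  g2 <- seq(0, bounds[2], length.out = n)
  costs <- outer(g1, g2, Vectorize(function(a, b) fn(c(a, b))))
  idx <- arrayInd(which.min(costs), dim(costs))
  list(dose = c(g1[idx[1]], g2[idx[2]]), cost = min(costs),
       step = bounds / (n - 1))
}

# Fast protocol for AP-level tests: coarser output grid and fewer beats
# than the analysis default, sufficient for qualitative assertions.
fast_protocol <- function(n_prebeats = 40, dt_output = 0.1)
  pacing_protocol(n_prebeats = n_prebeats, dt_output = dt_output)

surrogate_model_path <- function()
  system.file("extdata", "surrogate_model.yaml", package = "aprepair")
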