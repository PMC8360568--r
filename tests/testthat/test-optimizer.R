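test_that("dose bound modes reproduce their defining formulas", {
  lib <- default_drug_library()
  b_min <- dose_bounds(lib, "min-ec50")
  expect_equal(b_min[["quinidine"]], 8.14)      # smallest EC50 across targets
  expect_equal(b_min[["veratridine"]], 0.426)
  b_half <- dose_bounds(lib, "half-min-ec50")
  expect_equal(as.numeric(b_half), as.numeric(b_min) / 2)
  # 95% saturation cap: EC50 * 19^(1/H); veratridine (H = 2) caps at 1.857 uM
  b_sat <- dose_bounds(lib, "saturation-cap")
  expect_equal(b_sat[["veratridine"]], 0.426 * 19^(1 / 2), tolerance = 1e-12)
  expect_equal(b_sat[["quinidine"]], 8.14 * 19, tolerance = 1e-12)
  expect_error(dose_bounds(lib, "explicit"), "named")
  expect_error(dose_bounds(lib, "explicit",
                           bounds = c(quinidine = 1)), "missing")
})

test_that("the single-dose search matches a 1001-point brute-force scan", {
  landscapes <- list(
    function(d) (d - 3.2)^2 + 0.5,          # interior optimum
    function(d) (d - 20)^2,                 # optimum at the bound
    function(d) d * 0.1 + 1,                # monotone: optimum at zero
    function(d) sin(d) + d / 5 + 1.2        # mildly multimodal
  )
  bound <- 10
  for (fn in landscapes) {
    ctx <- objective_context(function(doses) fn(unname(doses[1])))
    drug <- drug_profile("toy", list(I_Kr = hill_effect(1, 1, -1)))
    res <- optimize_single(drug, bound, ctx)
    oracle <- grid_scan_1d(fn, bound)
    expect_lte(res$cost, oracle$cost + 1e-6)
    expect_lt(abs(res$doses[[1]] - oracle$dose), oracle$step + 1e-9)
    # round-trip: reported cost is the objective at the reported dose
    expect_equal(res$cost, fn(res$doses[[1]]), tolerance = 1e-12)
  }
  drug <- drug_profile("toy", list(I_Kr = hill_effect(1, 1, -1)))
  ctx <- objective_context(function(doses) 1)
  # a drug with no effect on the cost settles at dose zero
  res0 <- optimize_single(drug, bound, ctx)
  expect_identical(unname(res0$doses), 0)
  expect_error(optimize_single(drug, 0, ctx), "positive")
})

test_that("the two-dose search matches a 101 x 101 brute-force scan", {
  ctx <- toy_quadratic_context(center = c(A = 3, B = 1),
                               scale = c(A = 0.1, B = 1))
  profiles <- list(drug_profile("A", list(I_Kr = hill_effect(1, 1, -1))),
                   drug_profile("B", list(I_Na = hill_effect(1, 1, -1))))
  bounds <- dose_bounds(profiles, "explicit", bounds = c(A = 10, B = 10))
  inc <- optimize_incremental(profiles, bounds, ctx, max_drugs = 2)
  oracle <- grid_scan_2d(function(d) ctx$objective(c(A = d[1], B = d[2])),
                         c(10, 10))
  # the local search stops at a 1e-4 cost spread; allow that on top of the
  # grid-scan optimum
  expect_lte(inc[[2]]$cost, oracle$cost + 5e-4)
  got <- inc[[2]]$doses[c("A", "B")]
  expect_true(all(abs(got - oracle$dose) < oracle$step + 1e-9))
})

test_that("incremental continuation is monotone and absorbs null drugs", {
  # drug C has no influence on the cost at all
  ctx <- toy_quadratic_context(center = c(A = 3, B = 1))
  profiles <- list(drug_profile("A", list(I_Kr = hill_effect(1, 1, -1))),
                   drug_profile("B", list(I_Na = hill_effect(1, 1, -1))),
                   drug_profile("C", list(I_f = hill_effect(1, 1, -1))))
  bounds <- dose_bounds(profiles, "explicit",
                        bounds = c(A = 10, B = 10, C = 10))
  inc <- optimize_incremental(profiles, bounds, ctx, max_drugs = 3)
  costs <- vapply(inc, `[[`, numeric(1), "cost")
  expect_true(all(diff(costs) <= 1e-12))
  # the null drug is pruned to dose zero at essentially unchanged cost
  expect_lt(abs(inc[[3]]$cost - inc[[2]]$cost), 1e-4)
  expect_identical(inc[[3]]$doses[["C"]], 0)
  # every reported dose respects its bound
  for (r in inc)
    expect_true(all(r$doses <= unclass(bounds)[names(r$doses)] + 1e-9))
})

test_that("the pairwise scan is symmetric with single-drug optima on the diagonal", {
  ctx <- toy_quadratic_context(center = c(A = 3, B = 1))
  profiles <- list(drug_profile("A", list(I_Kr = hill_effect(1, 1, -1))),
                   drug_profile("B", list(I_Na = hill_effect(1, 1, -1))),
                   drug_profile("C", list(I_f = hill_effect(1, 1, -1))))
  bounds <- dose_bounds(profiles, "explicit",
                        bounds = c(A = 10, B = 10, C = 10))
  scan <- pairwise_scan(profiles, bounds, ctx)
  M <- scan$cost_matrix
  expect_identical(M, t(M))
  # pairing adds a degree of freedom: off-diagonal <= both diagonals
  for (i in 1:2) for (j in (i + 1):3)
    expect_lte(M[i, j], min(M[i, i], M[j, j]) + 1e-8)
  # the null drug C adds nothing: its pairings equal the partner's optimum
  expect_equal(M["A", "C"], M["A", "A"], tolerance = 1e-6)
  expect_equal(M["B", "C"], M["B", "B"], tolerance = 1e-6)
  # the best pair solves the separable problem
  oracle <- grid_scan_2d(function(d) ctx$objective(c(A = d[1], B = d[2])),
                         c(10, 10))
  expect_lte(scan$best$cost, oracle$cost + 5e-4)
})
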