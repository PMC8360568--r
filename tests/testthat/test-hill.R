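test_that("eta has the Hill-model fixed points and limits", {
  cases <- list(
    hill_effect(8.14, 1, -1),
    hill_effect(15.77, 0.6, -1),
    hill_effect(0.426, 2, 1.8),
    hill_effect(0.05, 1.7, 1.8),
    hill_effect(168.4, 1.09, -0.311)
  )
  for (e in cases) {
    ec50 <- 1 / e$eps
    expect_identical(eta(e, 0), 0)
    expect_equal(eta(e, ec50), e$emax / 2, tolerance = 1e-12)
    # saturating limit: within 1e-6 relative of E once (eps * D)^H = 1e6
    d_sat <- ec50 * 1e6^(1 / e$hill)
    expect_lt(abs(eta(e, d_sat) - e$emax) / abs(e$emax), 1.1e-6)
    # monotone towards E, bounded by E
    d <- ec50 * 10^seq(-3, 3, by = 0.5)
    et <- eta(e, d)
    expect_true(all(diff(abs(et)) > 0))
    expect_true(all(abs(et) < abs(e$emax)))
  }
})

test_that("single-drug percent changes reproduce the published dose table", {
  lib <- default_drug_library()
  pct <- function(drug, dose, current)
    round_half_away(100 * eta(lib[[drug]]$effects[[current]], dose), 1)
  # optimal single doses and their per-current effects
  expect_equal(pct("veratridine", 1.86, "I_NaL"), 171.0)
  expect_equal(pct("quinidine", 29.3, "I_Na"), -27.4)
  # the published doses are themselves rounded to three figures, so a few
  # table cells wobble in the last printed decimal when recomputed
  expect_lt(abs(pct("quinidine", 29.3, "I_Kr") - -78.2), 0.2)
  expect_equal(pct("quinidine", 29.3, "I_CaL"), -16.1)
  expect_equal(pct("ivabradine", 67.7, "I_f"), -61.7)
  expect_equal(pct("ivabradine", 67.7, "I_Kr"), -84.3)
  expect_equal(pct("ivabradine", 67.7, "I_Na"), -44.0)
  expect_equal(pct("disopyramide", 142, "I_Kr"), -78.9)
  expect_equal(pct("disopyramide", 142, "I_CaL"), -9.4)
  expect_equal(pct("disopyramide", 142, "I_Na"), -14.1)
  expect_equal(pct("amiodarone", 0.0338, "I_Kr"), -24.6)
  expect_equal(pct("propafenone", 0.0752, "I_Kr"), -14.5)
  expect_equal(pct("mexiletine", 65.3, "I_Na"), -24.5)
  expect_lt(abs(pct("BAY K 8644", 0.0475, "I_CaL") - 86.2), 0.2)
  # two-drug combination row
  expect_equal(pct("disopyramide", 3.03, "I_Kr"), -27.1)
})

test_that("saturation_fraction matches the published max-%-of-E entries", {
  lib <- default_drug_library()
  expect_identical(saturation_fraction(lib$veratridine$effects$I_NaL, 0), 0)
  pct_sat <- function(effect, dose)
    round_half_away(100 * saturation_fraction(effect, dose))
  expect_identical(pct_sat(lib$veratridine$effects$I_NaL, 1.86), 95)
  expect_identical(pct_sat(lib$disopyramide$effects$I_Kr, 7.77), 40)
  expect_identical(pct_sat(lib$disopyramide$effects$I_Kr, 142), 79)
  expect_identical(pct_sat(lib$quinidine$effects$I_Kr, 29.3), 78)
})

test_that("combined_factor multiplies independent drug effects", {
  lib <- default_drug_library()
  five <- c(disopyramide = 7.77, quinidine = 3.84, ivabradine = 4.32,
            veratridine = 0.211, `BAY K 8644` = 0.00883)
  f_kr <- combined_factor(lib, five, "I_Kr")
  expect_equal(round_half_away(100 * (f_kr - 1), 1), -69.4)
  expect_equal(round_half_away(100 * (combined_factor(lib, five, "I_CaL") - 1), 1),
               5.7)
  expect_equal(round_half_away(100 * (combined_factor(lib, five, "I_Na") - 1), 1),
               -10.2)
  expect_equal(round_half_away(100 * (combined_factor(lib, five, "I_f") - 1), 1),
               -9.3)

  # permutation invariance (exact product)
  perm <- five[c(4, 2, 5, 1, 3)]
  expect_identical(combined_factor(lib, perm, "I_Kr"), f_kr)
  # sequential application equals the joint factor
  seq_f <- 1
  for (drug in names(five))
    seq_f <- seq_f * combined_factor(lib[drug], five[drug], "I_Kr")
  expect_equal(seq_f, f_kr, tolerance = 1e-12)
  # zero doses contribute nothing
  expect_identical(combined_factor(lib, c(quinidine = 0), "I_Kr"), 1)
  expect_identical(combined_factor(lib, numeric(0), "I_Kr"), 1)
})

test_that("combination factors respect blocker/agonist bounds and monotonicity", {
  lib <- default_drug_library()
  blockers <- c(quinidine = 5, ivabradine = 3, disopyramide = 10)
  agonist <- c(veratridine = 0.5)
  for (cur in c("I_Kr", "I_Na", "I_CaL")) {
    f <- combined_factor(lib, blockers, cur)
    expect_gt(f, 0)
    expect_lte(f, 1)
  }
  expect_gte(combined_factor(lib, agonist, "I_NaL"), 1)
  # monotone in each blocker dose
  f1 <- combined_factor(lib, c(quinidine = 5), "I_Kr")
  f2 <- combined_factor(lib, c(quinidine = 10), "I_Kr")
  expect_lt(f2, f1)
})

test_that("percent_change_table reports all requested currents exactly", {
  lib <- default_drug_library()
  tab <- percent_change_table(lib, c(quinidine = 29.3),
                              currents = c("I_Kr", "I_CaL", "I_Na", "I_NaL", "I_f"))
  expect_equal(tab$percent_change[tab$current == "I_Na"], -27.4, tolerance = 2e-3)
  expect_identical(tab$percent_change[tab$current == "I_NaL"], 0)
  expect_identical(tab$percent_change[tab$current == "I_f"], 0)
  empty <- percent_change_table(lib, stats::setNames(numeric(0), character(0)),
                                currents = c("I_Kr", "I_Na"))
  expect_true(all(empty$percent_change == 0))
})

test_that("drug-effect validation rejects out-of-range parameters", {
  expect_error(hill_effect(-1, 1, -1), "ec50")
  expect_error(hill_effect(10, 0, -1), "hill")
  expect_error(hill_effect(10, 1, -1.2), "emax")
  expect_error(hill_effect(10, 1, 0), "emax")
  e <- hill_effect(10, 1, -1)
  expect_error(eta(e, -0.1), "doses")
  expect_error(combined_factor(default_drug_library(), c(nosuch = 1), "I_Kr"),
               "unknown drug")
  expect_error(drug_profile("empty", list()), "non-empty")
})
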