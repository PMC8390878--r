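p_ref <- hb_params(K_R = 240, K_T = 3.5, L = 75000)

test_that("partition function matches its closed form and limits", {
  expect_equal(partition_function(p_ref, 0), 1 + 75000)
  # direct polynomial evaluation at x = 1/240 mM
  expect_equal(partition_function(p_ref, 1 / 240),
               2^4 + 75000 * (1 + 3.5 / 240)^4)
  expect_error(partition_function(p_ref, -1e-6), "nonnegative")
  # single-state limit: tiny L leaves only the R term
  pR <- hb_params(240, 3.5, 1e-300)
  expect_equal(partition_function(pR, 0.01), (1 + 240 * 0.01)^4,
               tolerance = 1e-12)
})

test_that("drug-extended partition function reduces correctly", {
  drug <- drug_affinities(K_RX = 170, K_TX = 0.08, L = 75000)
  x <- runif(20, 0, 0.3)
  expect_equal(partition_function_drug(p_ref, drug, x, 0),
               partition_function(p_ref, x))
  expect_equal(partition_function_drug(p_ref, drug, 0, 0.2),
               (1 + 170 * 0.2) + 75000 * (1 + 0.08 * 0.2))
  expect_equal(partition_function_drug(p_ref, drug, 1 / 240, 0.2),
               35 * 16 + 75000 * 1.016 * (1 + 3.5 / 240)^4)
})

test_that("fractional saturation is the closed-form mean ligation / 4", {
  y <- fractional_saturation(p_ref, 1 / 240)
  expect_equal(y, (8 + 75000 * (3.5 / 240) * (1 + 3.5 / 240)^3) /
                 (16 + 75000 * (1 + 3.5 / 240)^4))
  expect_equal(round(y, 3), 0.014)
  expect_equal(fractional_saturation(p_ref, 0), 0)
  expect_gt(fractional_saturation(p_ref, 1e6), 0.99999)
})

test_that("saturation is monotone in oxygen and bounded, with and without drug", {
  drug <- drug_affinities(170, 0.08, 75000)
  x <- exp(seq(log(1e-6), log(10), length.out = 300))
  for (X in c(0, 0.012, 0.2)) {
    y <- fractional_saturation(p_ref, x, drug, X)
    expect_true(all(diff(y) >= -1e-14))
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("species probabilities are normalized partition-function terms", {
  drug <- drug_affinities(170, 0.08, 75000)
  pr0 <- species_probabilities(p_ref, drug, 0, 0)
  expect_equal(unname(pr0["R0"]), 1 / (1 + 75000))
  expect_equal(unname(pr0["T0"]), 75000 / (1 + 75000))
  expect_equal(sum(pr0 != 0), 2)
  for (x in c(0, 0.01, 0.3)) for (X in c(0, 0.2)) {
    pr <- species_probabilities(p_ref, drug, x, X)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
  # zero-oxygen drug-bound/free ratio is the mass-action occupancy ratio
  pr <- species_probabilities(p_ref, drug, 0, 0.2)
  expect_equal(unname(pr["T0X"] / pr["T0"]), 0.08 * 0.2)
})

test_that("p50 agrees with an independent root finder and the two pure limits", {
  # pure-conformation p50s implied by the unit conversion
  expect_equal(round(p50(hb_params(240, 3.5, 1e-12)), 1), 2.3)
  expect_equal(p50(hb_params(240, 3.5, 1e12)), 160, tolerance = 1e-3)
  # full model vs an independent uniroot oracle on the same saturation
  p <- hb_params(240, 3.5, 75000)
  oracle <- uniroot(function(P)
    fractional_saturation(p, p$alpha * P) - 0.5, c(1e-3, 1e4),
    tol = 1e-8)$root
  expect_equal(p50(p), oracle, tolerance = 1e-2)
  # order of magnitude of the drug-free red-cell measurement (~37 torr);
  # exact agreement is buffer dependent and not expected
  expect_gt(p50(hb_params(240, 3.5, 1e5)), 10)
  expect_lt(p50(hb_params(240, 3.5, 1e5)), 100)
})

test_that("Hill coefficient is cooperative and the drug left-shifts the midpoint", {
  p <- hb_params(240, 3.5, 1e5)
  drug <- drug_affinities(170, 0.08, 1e5)
  nH <- hill_coefficient(p)
  expect_gt(nH, 1); expect_lte(nH, 4)
  # saturating drug: still a two-state cooperative isotherm (the switch
  # remains inside the binding window), but strongly left-shifted
  nH_drug <- hill_coefficient(p, drug, X = 1)
  expect_gt(nH_drug, 1); expect_lte(nH_drug, 4)
  expect_lt(p50(p, drug, X = 1), p50(p) / 3)
  # zero drug reduces to the drug-free slope
  expect_equal(hill_coefficient(p, drug, X = 0), nH)
})

test_that("occupancy formulas reproduce the closed-form reference values", {
  expect_equal(equilibrium_drug_occupancy(0.06, 0.2), 0.012 / 1.012)
  expect_equal(round(equilibrium_drug_occupancy(0.06, 0.2), 2), 0.01)
  expect_equal(equilibrium_drug_occupancy(170, 0), 0)
  expect_equal(equilibrium_drug_occupancy(170, 0.2), 34 / 35)
  # depletion-corrected occupancy: quadratic root vs reference value
  expect_equal(round(depleted_occupancy(1 / 0.006, 0.0216, 0.012), 1), 0.4)
  expect_equal(depleted_occupancy(100, 0.02, 0), 0)
  # stoichiometric limit: all ligand bound when K -> Inf and X < R
  expect_equal(depleted_occupancy(1e12, 0.0216, 0.012), 0.012 / 0.0216,
               tolerance = 1e-6)
  # no-depletion limit recovers the simple isotherm
  expect_equal(depleted_occupancy(1 / 0.006, 1e-9, 0.012),
               equilibrium_drug_occupancy(1 / 0.006, 0.012),
               tolerance = 1e-4)
})

test_that("pseudo-first-order half-time and its scaling", {
  expect_equal(pseudo_first_order_half_time(0.02, 0.2), log(2) / 0.004)
  expect_equal(pseudo_first_order_half_time(0.02, 0.4),
               pseudo_first_order_half_time(0.02, 0.2) / 2)
  expect_error(pseudo_first_order_half_time(0, 0.2), "positive")
})

test_that("linkage fixes the drug-bound allosteric constant", {
  expect_equal(linkage_LX(70000, 0.06, 210), 20)
  expect_equal(linkage_LX(1234, 0.5, 0.5), 1234)
  expect_equal(linkage_LX(70000, 0.06, 420), 10)
})

test_that("true equilibrium curve: no-drug identity, left shift, bounded depletion", {
  p <- hb_params(240, 3.5, 1e5)
  drug <- drug_affinities(170, 0.08, 1e5)
  P <- exp(seq(log(1), log(160), length.out = 60))
  free <- true_equilibrium_curve(p, drug, 0, pressures = P)
  expect_equal(free$saturation, fractional_saturation(p, p$alpha * P))
  with_drug <- true_equilibrium_curve(p, drug, 0.2, pressures = P)
  # drug raises affinity: saturation above drug-free at every pressure
  expect_true(all(with_drug$saturation >= free$saturation - 1e-12))
  p50_free <- approx(free$saturation, free$pO2_torr, 0.5)$y
  p50_drug <- approx(with_drug$saturation, with_drug$pO2_torr, 0.5)$y
  expect_lt(p50_drug, p50_free)
  # bound drug never exceeds the hemoglobin-site capacity of the cells
  bound <- 0.2 - with_drug$X_free_mM
  expect_true(all(bound >= -1e-12))
  expect_true(all(bound <= 5.4 * 0.004 + 1e-9))
})

test_that("delivery delta behaves monotonically", {
  p <- hb_params(240, 3.5, 1e5)
  drug <- drug_affinities(170, 0.08, 1e5)
  free <- true_equilibrium_curve(p, drug, 0)
  shifted <- true_equilibrium_curve(p, drug, 0.2)
  expect_equal(delivery_delta(free, 70, 70), 0)
  d_free <- delivery_delta(free, 100, 30)
  expect_gt(d_free, delivery_delta(shifted, 100, 30))
  expect_gt(d_free, 0.3)  # cooperative curve unloads substantially
})

test_that("parameter constructors enforce their invariants", {
  expect_error(hb_params(3.5, 240, 1e5), "K_R > K_T")
  expect_error(hb_params(240, 3.5, -1), "positive")
  expect_error(drug_affinities(0.08, 170, 1e5), "K_RX > K_TX")
  expect_error(suspension_config(volume_fraction = 1.2), "0,1")
})
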