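set_mid <- canonical_parameters("table1_mid")

test_that("rate constructor closes every thermodynamic cycle", {
  r <- set_mid$rates
  p <- set_mid$params
  expect_equal(r$kbR / r$kdR, p$K_R)
  expect_equal(r$kbT / r$kdT, p$K_T)
  expect_equal(r$kRT / r$kTR, p$L * p$c^(0:4))
  expect_equal(r$kRTX / r$kTRX, r$drug$L_X * p$c^(0:4))
  expect_equal(r$kRbX / r$kRdX, r$drug$K_RX)
  expect_equal(r$kTbX / r$kTdX, r$drug$K_TX)
  # the faster member of each quaternary pair is pinned (subsecond)
  expect_true(all(abs(pmax(r$kRT, r$kTR) - 1e4) < 1e-6))
})

test_that("right-hand side conserves tetramer and matches the state template", {
  r <- set_mid$rates
  st <- equilibrium_state(set_mid$params, r$drug, 0.05, 0.1, 5.4)
  d <- ode_rhs(st, 0.03, 0.05, r)
  expect_lt(abs(sum(d)), 1e-10 * max(abs(d)))
  # term-by-term audit: all mass in R0X at zero oxygen and zero free drug
  st2 <- setNames(rep(0, 20), species_names()); st2["R0X"] <- 1
  d2 <- ode_rhs(st2, 0, 0, r)
  expect_equal(unname(d2["R0X"]), -(r$kRdX + r$kRTX[1]))
  expect_equal(unname(d2["R0"]), r$kRdX)
  expect_equal(unname(d2["T0X"]), r$kRTX[1])
  expect_equal(sum(d2 != 0), 3)
  # stationarity at the partition-function equilibrium
  deq <- ode_rhs(equilibrium_state(set_mid$params, r$drug, 0.03, 0.05, 5.4),
                 0.03, 0.05, r)
  expect_lt(max(abs(deq)) / 5.4, 1e-6)
})

test_that("compiled integrator agrees with the pure-R right-hand side", {
  r <- set_mid$rates
  st0 <- equilibrium_state(set_mid$params, r$drug, 0, 0, 5.4)
  times <- seq(0, 50, by = 5)
  x_fix <- 0.02; X_fix <- 0.15
  compiled <- simulate_kinetics(st0, r, times, x_fix, X_total = X_fix,
                                mass_balance = FALSE)
  ref <- deSolve::lsoda(unname(st0), times, function(t, y, p) {
    names(y) <- species_names()
    list(unname(ode_rhs(pmax(y, 0), x_fix, X_fix, r)))
  }, NULL, rtol = 1e-10, atol = 1e-14)
  expect_equal(unname(compiled[, -1]), unname(ref[, -1]), tolerance = 1e-6)
})

test_that("long-time simulation relaxes to the partition-function equilibrium", {
  r <- set_mid$rates
  st0 <- equilibrium_state(set_mid$params, r$drug, 0.01, 0.01, 5.4)
  for (cond in list(c(0.005, 0.2), c(0.27, 0.012))) {
    out <- simulate_kinetics(st0, r, c(0, 10^(0:5), 2e5), cond[1],
                             X_total = cond[2], mass_balance = FALSE)
    fin <- out[nrow(out), -1]
    eq <- equilibrium_state(set_mid$params, r$drug, cond[1], cond[2], 5.4)
    sel <- eq / 5.4 > 1e-9
    expect_lt(max(abs(fin[sel] - eq[sel]) / eq[sel]), 1e-4)
    expect_lt(abs(sum(fin) - 5.4) / 5.4, 1e-8)
  }
})

test_that("stationary state stays stationary and saturation readout is exact", {
  r <- set_mid$rates
  x <- 0.05
  eq <- equilibrium_state(set_mid$params, r$drug, x, 0, 5.4)
  out <- simulate_kinetics(eq, r, seq(0, 1000, 100), x, X_total = 0,
                           mass_balance = FALSE)
  expect_lt(max(abs(out[nrow(out), -1] - eq)) / 5.4, 1e-9)
  # saturation readouts
  st <- setNames(rep(0, 20), species_names())
  st["R4"] <- 2; expect_equal(saturation_of_state(st), 1)
  st["R4"] <- 0; st["T0"] <- 3; expect_equal(saturation_of_state(st), 0)
  st["T0"] <- 1; st["R4"] <- 1; expect_equal(saturation_of_state(st), 0.5)
  # consistency with the closed-form equilibrium saturation
  expect_equal(saturation_of_state(eq),
               fractional_saturation(set_mid$params, x, r$drug, 0))
})

test_that("a drug step relaxes the R pool at the pseudo-first-order rate", {
  r <- set_mid$rates
  x_hi <- 2  # far above the switch: <1% T, so the R pool is clean
  st0 <- equilibrium_state(set_mid$params, r$drug, x_hi, 0, 5.4)
  X <- 0.2
  k_exp <- r$kRbX * X + r$kRdX
  times <- seq(0, 2000, by = 5)
  out <- simulate_kinetics(st0, r, times, x_hi, X_total = X,
                           mass_balance = FALSE)
  bound_frac <- rowSums(out[, paste0("R", 0:4, "X")]) / rowSums(out[, -1])
  eq_frac <- bound_frac[length(bound_frac)]
  t_half <- approx(bound_frac / eq_frac, times, xout = 0.5,
                   ties = "ordered")$y
  expect_equal(t_half, log(2) / k_exp, tolerance = 0.05)
})

test_that("bimolecular relaxation half-time: limits and monotonicity", {
  # pseudo-first-order limit at large ligand excess, no dissociation
  expect_equal(bimolecular_relaxation_half_time(0.02, 0, 1e-6, 0.2),
               log(2) / (0.02 * 0.2), tolerance = 1e-3)
  # slower binding at the same affinity lengthens the half-time
  t1 <- bimolecular_relaxation_half_time(0.02, 1.2e-4, 0.0216, 0.012)
  t2 <- bimolecular_relaxation_half_time(0.01, 0.6e-4, 0.0216, 0.012)
  expect_gt(t2, t1)
  expect_error(bimolecular_relaxation_half_time(-1, 0, 1, 1), "invalid")
})

test_that("simulation rejects invalid input", {
  r <- set_mid$rates
  st0 <- equilibrium_state(set_mid$params, r$drug, 0, 0, 5.4)
  expect_error(simulate_kinetics(st0 - 1, r, 0:10, 0.1), "negative")
  expect_error(simulate_kinetics(st0, r, c(0, 0, 1), 0.1), "increasing")
})
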