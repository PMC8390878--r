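test_that("canonical sets encode the documented constants", {
  mid <- canonical_parameters("table1_mid")
  expect_equal(mid$params$L, 117500)
  expect_equal(mid$rates$kRbX, 0.025)
  expect_equal(mid$rates$drug$K_RX, 0.025 / 1.5e-4)
  lx <- canonical_parameters("table1_LX20")
  # the constructed set has exact linkage L^X = 20
  expect_equal(lx$rates$drug$L_X, 20)
  expect_equal(lx$rates$drug$K_RX, 210)
  expect_equal(lx$rates$drug$K_TX, 0.06)
  free <- canonical_parameters("drug_free")
  expect_equal(free$params$L, 1e5)
  expect_error(canonical_parameters("bogus"))
})

test_that("dataset generation is deterministic for a fixed seed", {
  d1 <- generate_dataset("drug_free", 0, intervals_min = 2,
                         noise_sd = 0.01, seed = 42, dt_out = 20)
  d2 <- generate_dataset("drug_free", 0, intervals_min = 2,
                         noise_sd = 0.01, seed = 42, dt_out = 20)
  expect_identical(d1$curves, d2$curves)
  d3 <- generate_dataset("drug_free", 0, intervals_min = 2,
                         noise_sd = 0.01, seed = 43, dt_out = 20)
  expect_false(identical(d1$curves$disso1$saturation_reported,
                         d3$curves$disso1$saturation_reported))
  # noise is additive on the reported channel only
  expect_equal(d1$curves$disso1$saturation_true,
               d3$curves$disso1$saturation_true)
})

test_that("written datasets round-trip through the CSV/manifest format", {
  dir <- tempfile("synthds")
  on.exit(unlink(dir, recursive = TRUE))
  generate_dataset("drug_free", 0, intervals_min = 2, noise_sd = 0,
                   seed = 7, dir = dir, dt_out = 20)
  files <- list.files(dir)
  expect_setequal(files, c("0_dissociation1.csv", "0_association1.csv",
                           "manifest.json"))
  ds <- read_dataset(dir)
  expect_setequal(names(ds$curves), c("disso1", "assoc1"))
  expect_equal(ds$manifest$set, "drug_free")
  expect_equal(ds$manifest$seed, 7)
  expect_equal(ds$manifest$params$L, 1e5)
  # byte-identical regeneration
  dir2 <- tempfile("synthds2")
  on.exit(unlink(dir2, recursive = TRUE), add = TRUE)
  generate_dataset("drug_free", 0, intervals_min = 2, noise_sd = 0,
                   seed = 7, dir = dir2, dt_out = 20)
  for (f in c("0_dissociation1.csv", "0_association1.csv"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("noise-free drug-free curves track the equilibrium isotherm", {
  res <- run_drug_free()
  p <- res$set$params
  # slow ramps and holds: last-cycle curves sit on the equilibrium curve
  for (nm in c("disso3", "assoc3")) {
    cr <- res$run$curves[[nm]]
    y_eq <- fractional_saturation(p, p$alpha * cr$pO2_torr)
    expect_lt(max(abs(cr$saturation_true - y_eq)), 1e-3)
  }
  # and dissociation/association pairs coincide (no drug, no hysteresis)
  expect_lt(phase_spread(res$run, "dissociation", "saturation_true"), 1e-3)
  expect_lt(phase_spread(res$run, "association", "saturation_true"), 1e-3)
})

test_that("a low drug dose produces a biphasic dissociation curve", {
  res <- run_12uM()
  # two separated components: the shifted (drug-bound) and unshifted pools
  expect_gte(n_derivative_peaks(res$run$curves$disso1), 2)
  # drug-free curves are monophasic by the same detector
  free <- run_drug_free()
  expect_equal(n_derivative_peaks(free$run$curves$disso1), 1)
  expect_equal(n_derivative_peaks(free$run$curves$assoc3), 1)
})

test_that("hysteresis grows with drug dose and cooperativity collapses", {
  r200 <- run_200uM(); r12 <- run_12uM()
  gap <- function(run, cyc) {
    grid <- exp(seq(log(3), log(120), length.out = 50))
    di <- interp_sorted(run$curves[[paste0("disso", cyc)]]$pO2_torr,
                        run$curves[[paste0("disso", cyc)]]$saturation_true,
                        grid)
    as_ <- interp_sorted(run$curves[[paste0("assoc", cyc)]]$pO2_torr,
                         run$curves[[paste0("assoc", cyc)]]$saturation_true,
                         grid)
    mean(abs(di - as_))
  }
  expect_gt(gap(r200$run, 1), gap(r12$run, 1))
  expect_gt(gap(r200$run, 1), 0.05)
  # saturated drug leaves residual saturation at the lowest pressure
  expect_gt(min(r200$run$curves$disso3$saturation_true), 0.02)
  # reported dissociation curve of the drugged sample is non-cooperative:
  # log-odds Hill slope at half saturation well below the drug-free value
  hill_of <- function(curve) {
    sel <- curve$saturation_reported > 0.02 & curve$saturation_reported < 0.98
    y <- curve$saturation_reported[sel]; P <- curve$pO2_torr[sel]
    fit <- lm(log(y / (1 - y)) ~ log(P))
    unname(coef(fit)[2])
  }
  expect_lt(hill_of(r200$run$curves$disso3), 1.5)
  expect_gt(hill_of(run_drug_free()$run$curves$disso3), 2)
})
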