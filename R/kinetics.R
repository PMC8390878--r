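#' Mass-action rate set for the 20-state kinetic model
#'
#' Builds the full rate set for the two-conformation, 0-4-oxygen,
#' drug-free/drug-bound state space. Every reverse rate is forced by its
#' forward rate and the corresponding equilibrium constant, so each
#' thermodynamic cycle closes by construction:
#' \itemize{
#'   \item oxygen: kdR = kbR / K_R, kdT = kbT / K_T (per-heme rates);
#'   \item quaternary: k_i(R->T)/k_i(T->R) = L c^i drug-free and L^X c^i
#'     drug-bound, with c = K_T/K_R; the larger member of each pair is set
#'     to \code{k_quaternary} and the partner scaled by the ratio, which
#'     caps stiffness while keeping every transition subsecond;
#'   \item drug: K_RX = kRbX / kRdX and K_TX = kTbX / kTdX are taken from
#'     the four supplied rate coefficients.
#' }
#' The oxygen on-rates default to literature-typical per-heme magnitudes;
#' they only need to be fast relative to the minutes-scale pressure
#' protocols, and are configurable.
#'
#' @param params An \code{hb_params} object.
#' @param kRbX,kRdX Drug binding (per mM per s) and dissociation (per s)
#'   rates for the R conformation.
#' @param kTbX,kTdX Same for the T conformation.
#' @param kbR,kbT Per-heme oxygen binding rates, per mM per s.
#' @param k_quaternary Magnitude assigned to the faster member of each
#'   quaternary rate pair, per s.
#' @return An object of class \code{kinetic_rates} carrying all rates plus
#'   the derived \code{drug_affinities}.
#' @export
kinetic_rates <- function(params, kRbX, kRdX, kTbX, kTdX,
                          kbR = 3.3e4, kbT = 3e3, k_quaternary = 1e4) {
  stopifnot(inherits(params, "hb_params"))
  if (any(c(kRbX, kRdX, kTbX, kTdX, kbR, kbT, k_quaternary) <= 0))
    stop("all rates must be positive")
  K_RX <- kRbX / kRdX
  K_TX <- kTbX / kTdX
  drug <- drug_affinities(K_RX, K_TX, params$L)
  qpair <- function(ratio) {
    # forward = R->T (or RX->TX); forward/backward = ratio
    if (ratio >= 1) c(fwd = k_quaternary, bwd = k_quaternary / ratio)
    else            c(fwd = k_quaternary * ratio, bwd = k_quaternary)
  }
  i <- 0:4
  qf  <- t(vapply(params$L      * params$c^i, qpair, numeric(2)))
  qfx <- t(vapply(drug$L_X      * params$c^i, qpair, numeric(2)))
  structure(list(
    params = params, drug = drug,
    kbR = kbR, kdR = kbR / params$K_R,
    kbT = kbT, kdT = kbT / params$K_T,
    kRbX = kRbX, kRdX = kRdX, kTbX = kTbX, kTdX = kTdX,
    kRT = qf[, "fwd"], kTR = qf[, "bwd"],
    kRTX = qfx[, "fwd"], kTRX = qfx[, "bwd"]
  ), class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("20-state kinetic rate set\n")
  cat(sprintf("  oxygen:  kbR = %g, kdR = %g, kbT = %g, kdT = %g\n",
              x$kbR, x$kdR, x$kbT, x$kdT))
  cat(sprintf("  drug:    kRbX = %g, kRdX = %g (K_RX = %g /mM)\n",
              x$kRbX, x$kRdX, x$drug$K_RX))
  cat(sprintf("           kTbX = %g, kTdX = %g (K_TX = %g /mM)\n",
              x$kTbX, x$kTdX, x$drug$K_TX))
  cat(sprintf("  linkage: L = %g, L^X = %g\n", x$params$L, x$drug$L_X))
  invisible(x)
}

# flat parameter vector handed to the compiled right-hand side
rates_to_parms <- function(rates, X_parm, vf, mass_balance) {
  c(rates$kbR, rates$kdR, rates$kbT, rates$kdT,
    rates$kRbX, rates$kRdX, rates$kTbX, rates$kTdX,
    rates$kRT, rates$kTR, rates$kRTX, rates$kTRX,
    X_parm, vf, as.numeric(mass_balance))
}

#' Time derivatives of the 20 species (reference implementation)
#'
#' Pure-R mass-action right-hand side, mirroring the per-state template: for
#' a state with i oxygens bound, oxygen binds into the (i+1) state with
#' statistical factor (4 - i) and dissociates from it with factor i;
#' quaternary exchange couples same-ligation, same-drug partners; drug
#' binding couples each drug-free state to its drug-bound twin at rate
#' k_bind * [species] * X. Used as the independent check of the compiled
#' integrator backend.
#'
#' @param state Named vector of the 20 species concentrations (mM tetramer),
#'   canonical order (see \code{species_probabilities}).
#' @param x Free oxygen concentration, mM.
#' @param X Free drug concentration, mM.
#' @param rates A \code{kinetic_rates} object.
#' @return Named vector of d(concentration)/dt, per s; sums to zero.
#' @export
ode_rhs <- function(state, x, X, rates) {
  if (any(state < 0)) stop("negative concentrations")
  y <- matrix(state, nrow = 5)  # columns: R, T, RX, TX; rows ligation 0..4
  d <- matrix(0, 5, 4)
  kb <- c(rates$kbR, rates$kbT, rates$kbR, rates$kbT)
  kd <- c(rates$kdR, rates$kdT, rates$kdR, rates$kdT)
  for (col in 1:4) {
    for (i in 0:4) {
      r <- i + 1
      acc <- 0
      if (i < 4) acc <- acc - (4 - i) * kb[col] * y[r, col] * x +
                          (i + 1) * kd[col] * y[r + 1, col]
      if (i > 0) acc <- acc + (4 - i + 1) * kb[col] * y[r - 1, col] * x -
                          i * kd[col] * y[r, col]
      d[r, col] <- d[r, col] + acc
    }
  }
  for (i in 0:4) {  # quaternary exchange R<->T within each drug block
    r <- i + 1
    flow <- rates$kRT[r] * y[r, 1] - rates$kTR[r] * y[r, 2]
    d[r, 1] <- d[r, 1] - flow; d[r, 2] <- d[r, 2] + flow
    flowX <- rates$kRTX[r] * y[r, 3] - rates$kTRX[r] * y[r, 4]
    d[r, 3] <- d[r, 3] - flowX; d[r, 4] <- d[r, 4] + flowX
  }
  for (i in 0:4) {  # drug binding/dissociation
    r <- i + 1
    bR <- rates$kRbX * y[r, 1] * X - rates$kRdX * y[r, 3]
    d[r, 1] <- d[r, 1] - bR; d[r, 3] <- d[r, 3] + bR
    bT <- rates$kTbX * y[r, 2] * X - rates$kTdX * y[r, 4]
    d[r, 2] <- d[r, 2] - bT; d[r, 4] <- d[r, 4] + bT
  }
  out <- as.vector(d)
  names(out) <- species_names()
  out
}

#' Equilibrium concentrations of the 20 species
#'
#' Concentrations proportional to the terms of the drug-extended partition
#' function at fixed free oxygen and drug, scaled to the total tetramer
#' concentration. Identical (by shared definition) to
#' \code{species_probabilities} times \code{total_hb}.
#'
#' @param params An \code{hb_params} object.
#' @param drug A \code{drug_affinities} object.
#' @param x Free oxygen concentration, mM.
#' @param X Free drug concentration, mM.
#' @param total_hb Total tetramer concentration, mM.
#' @return Named vector of 20 concentrations, mM.
#' @export
equilibrium_state <- function(params, drug, x, X, total_hb) {
  total_hb * species_probabilities(params, drug, x, X)
}

#' Fractional saturation of a concentration state
#'
#' Mean ligation over all species divided by 4:
#' sum(i * [species_i]) / (4 * sum([species])).
#'
#' @param state Vector (or matrix with 20 columns) of species concentrations
#'   in canonical order.
#' @return Saturation in [0,1].
#' @export
saturation_of_state <- function(state) {
  lig <- species_ligation()
  if (is.matrix(state)) {
    tot <- rowSums(state)
    if (any(tot <= 0)) stop("total concentration must be positive")
    as.vector(state %*% lig) / (4 * tot)
  } else {
    tot <- sum(state)
    if (tot <= 0) stop("total concentration must be positive")
    sum(lig * state) / (4 * tot)
  }
}

#' Integrate the 20-state kinetic model
#'
#' Stiff implicit integration (deSolve::lsoda, compiled right-hand side) of
#' the coupled mass-action system along a time-dependent oxygen drive.
#' Free oxygen x(t) is supplied as a forcing series (Henry's-law
#' equilibration with the gas phase is instantaneous); free drug is either
#' held fixed or co-solved from the suspension mass balance
#' X = X_total - vf * (drug-bound hemoglobin) at every step.
#'
#' @param state0 Named vector of 20 initial concentrations, mM.
#' @param rates A \code{kinetic_rates} object.
#' @param times Output time grid, s (monotone increasing from 0).
#' @param x_forcing Either a scalar (constant x, mM) or a two-column matrix
#'   (time_s, x_mM) interpolated linearly by the integrator.
#' @param X_total Total suspension drug (mM) when \code{mass_balance = TRUE},
#'   otherwise the fixed free drug concentration.
#' @param volume_fraction Red-cell volume fraction (mass balance only).
#' @param mass_balance Co-solve free drug from conservation? Default TRUE.
#' @param rtol,atol Integrator tolerances. The defaults keep the total
#'   tetramer drift below 1e-8 relative without any concentration clipping.
#' @return Matrix of class \code{deSolve}: time plus the 20 species columns.
#' @export
simulate_kinetics <- function(state0, rates, times, x_forcing,
                              X_total = 0, volume_fraction = 0.004,
                              mass_balance = TRUE,
                              rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(rates, "kinetic_rates"), length(state0) == 20)
  if (any(state0 < 0)) stop("negative initial concentrations")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (length(x_forcing) == 1) {
    forc <- cbind(range(times), rep(x_forcing, 2))
  } else {
    forc <- as.matrix(x_forcing)
  }
  parms <- rates_to_parms(rates, X_total, volume_fraction, mass_balance)
  out <- deSolve::lsoda(
    y = unname(state0), times = times, func = "mwc_derivs", parms = parms,
    dllname = "mwcdrug", initfunc = "mwc_initmod",
    forcings = list(forc), initforc = "mwc_initforc",
    rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  colnames(out) <- c("time", species_names())
  out
}

# free drug implied by a species state under suspension mass balance
free_drug_of_state <- function(state_row, X_total, volume_fraction) {
  bound <- sum(state_row[11:20])
  X_total - volume_fraction * bound
}

#' Bimolecular binding relaxation half-time with depletion
#'
#' Integrates the full bimolecular rate equation
#' d[RX]/dt = k_bind (R_t - [RX]) (X_t - [RX]) - k_diss [RX]
#' from [RX] = 0 and returns the time at which the complex reaches half its
#' equilibrium concentration. When neither species is in excess the
#' pseudo-first-order expression underestimates this time substantially.
#'
#' @param k_bind Binding rate, per mM per s.
#' @param k_diss Dissociation rate, per s (0 allowed).
#' @param R_total Total receptor, mM.
#' @param X_total Total ligand, mM.
#' @return Half-time, seconds.
#' @examples
#' bimolecular_relaxation_half_time(0.02, 1.2e-4, 0.0216, 0.012)  # ~1200 s
#' @export
bimolecular_relaxation_half_time <- function(k_bind, k_diss, R_total, X_total) {
  if (k_bind <= 0 || R_total <= 0 || X_total <= 0 || k_diss < 0)
    stop("invalid inputs")
  # equilibrium complex: smaller root of the binding quadratic
  Kd <- k_diss / k_bind
  b <- R_total + X_total + Kd
  eq <- (b - sqrt(b^2 - 4 * R_total * X_total)) / 2
  target <- eq / 2
  rhs <- function(t, y, p) {
    list(k_bind * (R_total - y[1]) * (X_total - y[1]) - k_diss * y[1])
  }
  # crude timescale to bracket the crossing
  t_scale <- 1 / (k_bind * (R_total + X_total) + k_diss)
  t_end <- 200 * t_scale
  for (rep in 1:10) {
    times <- seq(0, t_end, length.out = 4000)
    sol <- deSolve::lsoda(c(RX = 0), times, rhs, NULL,
                          rtol = 1e-10, atol = 1e-14)
    if (max(sol[, 2]) >= target) {
      idx <- which(sol[, 2] >= target)[1]
      # linear interpolation between bracketing grid points
      t1 <- sol[idx - 1, 1]; t2 <- sol[idx, 1]
      v1 <- sol[idx - 1, 2]; v2 <- sol[idx, 2]
      return(unname(t1 + (target - v1) / (v2 - v1) * (t2 - t1)))
    }
    t_end <- t_end * 10
  }
  stop("half-equilibrium level not reached: nonconvergence")
}
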