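#' MWC binding partition function (drug-free)
#'
#' Q(x) = (1 + K_R x)^4 + L (1 + K_T x)^4, the two-state binding polynomial
#' for a tetramer whose R and T conformations each bind oxygen
#' noncooperatively.
#'
#' @param params An \code{hb_params} object.
#' @param x Free oxygen concentration, mM (vectorised, >= 0).
#' @return Q, same length as \code{x}; Q >= 1 + L.
#' @export
partition_function <- function(params, x) {
  stopifnot(inherits(params, "hb_params"))
  if (any(x < 0)) stop("x must be nonnegative")
  (1 + params$K_R * x)^4 + params$L * (1 + params$K_T * x)^4
}

#' MWC partition function with one drug site per tetramer
#'
#' Q^X(x, X) = (1 + K_RX X)(1 + K_R x)^4 + L (1 + K_TX X)(1 + K_T x)^4.
#' The drug binds one site on either quaternary conformation and leaves the
#' oxygen affinity of each conformation unchanged, so the drug factor
#' multiplies each conformational term. Reduces to Q when X = 0.
#'
#' @param params An \code{hb_params} object.
#' @param drug A \code{drug_affinities} object.
#' @param x Free oxygen concentration, mM (>= 0, vectorised).
#' @param X Free drug concentration, mM (>= 0).
#' @return Q^X.
#' @export
partition_function_drug <- function(params, drug, x, X) {
  stopifnot(inherits(params, "hb_params"), inherits(drug, "drug_affinities"))
  if (any(x < 0) || any(X < 0)) stop("x and X must be nonnegative")
  (1 + drug$K_RX * X) * (1 + params$K_R * x)^4 +
    params$L * (1 + drug$K_TX * X) * (1 + params$K_T * x)^4
}

#' Equilibrium fractional saturation with oxygen
#'
#' Mean number of bound oxygens per tetramer divided by 4, computed from the
#' explicit term sums of the binding polynomial (closed form, not symbolic
#' differentiation): monotone nondecreasing in x, bounded in [0,1].
#'
#' @param params An \code{hb_params} object.
#' @param x Free oxygen concentration, mM (vectorised).
#' @param drug Optional \code{drug_affinities}; required when X > 0.
#' @param X Free drug concentration, mM (default 0).
#' @return Fractional saturation y in [0,1].
#' @examples
#' p <- hb_params(240, 3.5, 75000)
#' fractional_saturation(p, x = 1/240)  # about 0.014
#' @export
fractional_saturation <- function(params, x, drug = NULL, X = 0) {
  stopifnot(inherits(params, "hb_params"))
  if (any(x < 0)) stop("x must be nonnegative")
  if (X > 0 && is.null(drug)) stop("drug affinities required when X > 0")
  fR <- if (is.null(drug)) 1 else 1 + drug$K_RX * X
  fT <- if (is.null(drug)) 1 else 1 + drug$K_TX * X
  aR <- params$K_R * x
  aT <- params$K_T * x
  num <- fR * aR * (1 + aR)^3 + params$L * fT * aT * (1 + aT)^3
  den <- fR * (1 + aR)^4 + params$L * fT * (1 + aT)^4
  num / den
}

#' Equilibrium probabilities of the 20 kinetic species
#'
#' One probability per (conformation, ligation, drug occupancy) state, in the
#' canonical species order R0..R4, T0..T4, R0X..R4X, T0X..T4X: each term of
#' Q^X divided by Q^X. Sums to 1 exactly.
#'
#' @param params An \code{hb_params} object.
#' @param drug A \code{drug_affinities} object (use K_TX, K_RX ~ 0 bounds via
#'   X = 0 for the drug-free case).
#' @param x Free oxygen concentration, mM (scalar).
#' @param X Free drug concentration, mM (scalar).
#' @return Named numeric vector of 20 probabilities.
#' @export
species_probabilities <- function(params, drug, x, X) {
  stopifnot(inherits(params, "hb_params"), inherits(drug, "drug_affinities"),
            length(x) == 1, length(X) == 1)
  if (x < 0 || X < 0) stop("x and X must be nonnegative")
  binom <- choose(4, 0:4)
  wR <- binom * (params$K_R * x)^(0:4)
  wT <- params$L * binom * (params$K_T * x)^(0:4)
  w <- c(wR, wT, drug$K_RX * X * wR, drug$K_TX * X * wT)
  names(w) <- species_names()
  w / sum(w)
}

#' Half-saturation oxygen pressure (p50)
#'
#' Solves fractional_saturation(x) = 1/2 by bisection on log pressure in
#' [1e-3, 1e4] torr, to an absolute tolerance of 0.01 torr, and converts the
#' root to torr through the Henry's-law solubility.
#'
#' @param params An \code{hb_params} object.
#' @param drug Optional \code{drug_affinities}.
#' @param X Free drug concentration, mM.
#' @return p50 in torr.
#' @examples
#' # pure-R limit: L -> 0 recovers p50 = 1/(K_R * alpha) = 2.3 torr
#' @export
p50 <- function(params, drug = NULL, X = 0) {
  f <- function(P) fractional_saturation(params, params$alpha * P, drug, X) - 0.5
  lo <- 1e-3; hi <- 1e4
  if (f(lo) > 0 || f(hi) < 0)
    stop("saturation does not cross 0.5 inside [1e-3, 1e4] torr")
  while (hi - lo > 0.01) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Hill coefficient at half saturation
#'
#' Finite-difference slope of log(y/(1-y)) against log pressure, evaluated at
#' p50. Between 1 (noncooperative) and 4 (maximal for a tetramer).
#'
#' @inheritParams p50
#' @param h Relative finite-difference step on pressure.
#' @return Hill coefficient n_H.
#' @export
hill_coefficient <- function(params, drug = NULL, X = 0, h = 1e-3) {
  P <- p50(params, drug, X)
  lo <- P * (1 - h); hi <- P * (1 + h)
  ylo <- fractional_saturation(params, params$alpha * lo, drug, X)
  yhi <- fractional_saturation(params, params$alpha * hi, drug, X)
  (log(yhi / (1 - yhi)) - log(ylo / (1 - ylo))) / (log(hi) - log(lo))
}

#' Equilibrium fractional occupancy of a single binding site
#'
#' Simple-isotherm occupancy K X / (1 + K X) at fixed free ligand, e.g. the
#' drug-bound fraction of the T conformation when free drug is not depleted.
#'
#' @param K_assoc Association constant, per mM.
#' @param X_free Free ligand concentration, mM.
#' @return Occupancy in [0, 1).
#' @examples
#' equilibrium_drug_occupancy(0.06, 0.2)  # ~0.012, i.e. ~0.01
#' @export
equilibrium_drug_occupancy <- function(K_assoc, X_free) {
  if (K_assoc <= 0) stop("K_assoc must be positive")
  if (any(X_free < 0)) stop("X_free must be nonnegative")
  K_assoc * X_free / (1 + K_assoc * X_free)
}

#' Binding occupancy with ligand depletion
#'
#' Fraction of receptor R bound at equilibrium when the ligand is not in
#' excess: the smaller root of the binding quadratic
#' [RX]^2 - [RX](R_t + X_t + 1/K) + R_t X_t = 0, divided by R_t.
#'
#' @param K_assoc Association constant, per mM.
#' @param R_total Total receptor concentration, mM.
#' @param X_total Total ligand concentration, mM.
#' @return Bound fraction of R, in [0,1].
#' @examples
#' depleted_occupancy(1/0.006, 0.0216, 0.012)  # ~0.38
#' @export
depleted_occupancy <- function(K_assoc, R_total, X_total) {
  if (K_assoc <= 0 || R_total <= 0) stop("K_assoc and R_total must be positive")
  if (X_total < 0) stop("X_total must be nonnegative")
  if (X_total == 0) return(0)
  b <- R_total + X_total + 1 / K_assoc
  disc <- b^2 - 4 * R_total * X_total
  if (disc < 0) stop("negative discriminant: inconsistent inputs")
  RX <- (b - sqrt(disc)) / 2
  RX / R_total
}

#' Pseudo-first-order binding half-time
#'
#' ln 2 / (k_bind * X): the half-time of complex formation when ligand is in
#' large excess so its concentration is effectively constant.
#'
#' @param k_bind Bimolecular binding rate, per mM per s.
#' @param X Ligand concentration, mM.
#' @return Half-time, seconds.
#' @examples
#' pseudo_first_order_half_time(0.02, 0.2)  # 173 s
#' @export
pseudo_first_order_half_time <- function(k_bind, X) {
  if (k_bind <= 0 || X <= 0) stop("k_bind and X must be positive")
  log(2) / (k_bind * X)
}

#' True equilibrium binding curve in the presence of drug
#'
#' The curve that would be measured if drug binding and dissociation were
#' instantaneous: at every pressure the free drug concentration is solved
#' self-consistently against the suspension mass balance
#' X_free = X_total - vf * hb * (drug-bound fraction), by damped fixed-point
#' iteration (tolerance 1e-9 mM), and the saturation evaluated from the
#' drug-extended partition function.
#'
#' @param params An \code{hb_params} object.
#' @param drug A \code{drug_affinities} object.
#' @param X_total Total drug in the suspension, mM.
#' @param cell_hb_mM Hemoglobin tetramer concentration inside cells, mM.
#' @param volume_fraction Red-cell volume fraction.
#' @param pressures Ascending oxygen pressures, torr.
#' @return A data frame (class \code{hb_curve}) with columns pO2_torr, x_mM,
#'   saturation, X_free_mM.
#' @export
true_equilibrium_curve <- function(params, drug, X_total,
                                   cell_hb_mM = 5.4, volume_fraction = 0.004,
                                   pressures = exp(seq(log(0.5), log(160),
                                                       length.out = 200))) {
  stopifnot(inherits(params, "hb_params"))
  if (is.unsorted(pressures)) stop("pressures must be ascending")
  xs <- params$alpha * pressures
  sat <- numeric(length(xs)); Xf <- numeric(length(xs))
  for (i in seq_along(xs)) {
    x <- xs[i]
    X <- X_total
    if (X_total > 0) {
      for (iter in 1:500) {
        fR <- (1 + params$K_R * x)^4
        fT <- params$L * (1 + params$K_T * x)^4
        occ <- (drug$K_RX * X * fR + drug$K_TX * X * fT) /
          ((1 + drug$K_RX * X) * fR + (1 + drug$K_TX * X) * fT)
        Xnew <- X_total - volume_fraction * cell_hb_mM * occ
        Xnew <- max(Xnew, 0)
        Xupd <- 0.5 * X + 0.5 * Xnew   # damped
        if (abs(Xupd - X) < 1e-9) { X <- Xupd; break }
        X <- Xupd
        if (iter == 500) stop("free-drug fixed point did not converge")
      }
    }
    Xf[i] <- X
    sat[i] <- if (X_total > 0) fractional_saturation(params, x, drug, X)
              else fractional_saturation(params, x)
  }
  structure(data.frame(pO2_torr = pressures, x_mM = xs, saturation = sat,
                       X_free_mM = Xf),
            class = c("hb_curve", "data.frame"))
}

#' Arteriovenous saturation difference from a binding curve
#'
#' y(P_arterial) - y(P_venous), interpolated from a curve of saturation
#' against pressure. A proxy for the oxygen delivered per pass between two
#' fixed pressures; a right-shifted curve gives a larger delta.
#'
#' @param curve Data frame with columns pO2_torr and saturation.
#' @param P_arterial Arterial oxygen pressure, torr.
#' @param P_venous Venous oxygen pressure, torr (< P_arterial).
#' @return Saturation difference.
#' @export
delivery_delta <- function(curve, P_arterial, P_venous) {
  if (P_arterial < P_venous) stop("require P_arterial >= P_venous")
  f <- stats::approxfun(curve$pO2_torr, curve$saturation, rule = 2)
  f(P_arterial) - f(P_venous)
}
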