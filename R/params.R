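#' Oxygen solubility used for pressure <-> concentration conversion
#'
#' Henry's-law proportionality between the oxygen partial pressure in the gas
#' phase and the free dissolved oxygen concentration inside the red cell,
#' in mM per torr. The default is derived from the paired reference values
#' K_T = 3.5 /mM and p50(T) = 160 torr, i.e. alpha = (1/3.5)/160 = 1/560
#' mM/torr. The independent K_R = 240 /mM and p50(R) = 2.3 torr pairing
#' implies 1.81e-3, about 1.5% higher; the K_T-derived value is used
#' throughout.
#'
#' @return Oxygen solubility in mM per torr.
#' @export
default_alpha <- function() 1 / 560

#' Allosteric (MWC) equilibrium parameters for hemoglobin-oxygen binding
#'
#' Constructs the parameter set of the two-state allosteric model: oxygen
#' association constants for the high-affinity R and low-affinity T quaternary
#' conformations, the allosteric constant L = [T0]/[R0] at zero oxygen, and
#' the Henry's-law solubility used to convert gas pressure to dissolved
#' oxygen concentration.
#'
#' @param K_R Oxygen association constant for R, per mM.
#' @param K_T Oxygen association constant for T, per mM. Must satisfy
#'   0 < K_T < K_R.
#' @param L Allosteric constant [T0]/[R0], dimensionless, > 0.
#' @param alpha Oxygen solubility, mM per torr.
#' @return An object of class \code{hb_params}.
#' @examples
#' p <- hb_params(K_R = 240, K_T = 3.5, L = 1e5)
#' p$c  # K_T/K_R, the affinity ratio governing the quaternary ladder
#' @export
hb_params <- function(K_R, K_T, L, alpha = default_alpha()) {
  stopifnot(is.numeric(K_R), is.numeric(K_T), is.numeric(L), is.numeric(alpha))
  if (!(K_R > K_T && K_T > 0)) stop("require K_R > K_T > 0")
  if (L <= 0) stop("L must be positive")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(K_R = K_R, K_T = K_T, L = L, alpha = alpha, c = K_T / K_R),
            class = "hb_params")
}

#' @export
print.hb_params <- function(x, ...) {
  cat("MWC allosteric parameters\n")
  cat(sprintf("  K_R = %g /mM   K_T = %g /mM   (c = K_T/K_R = %.4g)\n",
              x$K_R, x$K_T, x$c))
  cat(sprintf("  L   = %g      alpha = %.4g mM/torr\n", x$L, x$alpha))
  invisible(x)
}

#' Drug binding affinities for the two quaternary conformations
#'
#' Association constants of a quaternary-state-selective affinity modifier
#' (one binding site per tetramer) for the R and T conformations. The
#' drug-bound allosteric constant L^X is never free: it is derived through
#' the thermodynamic linkage L^X = L * K_TX / K_RX, which closes the
#' drug/conformation cycle (detailed balance).
#'
#' @param K_RX Drug association constant for R, per mM.
#' @param K_TX Drug association constant for T, per mM. Must satisfy
#'   0 < K_TX < K_RX (R-selective drug).
#' @param L Allosteric constant of the drug-free protein (used to derive L^X).
#' @return An object of class \code{drug_affinities} with fields
#'   \code{K_RX}, \code{K_TX}, \code{L_X}.
#' @export
drug_affinities <- function(K_RX, K_TX, L) {
  stopifnot(is.numeric(K_RX), is.numeric(K_TX), is.numeric(L))
  if (!(K_RX > K_TX && K_TX > 0)) stop("require K_RX > K_TX > 0")
  if (L <= 0) stop("L must be positive")
  structure(list(K_RX = K_RX, K_TX = K_TX, L_X = linkage_LX(L, K_TX, K_RX)),
            class = "drug_affinities")
}

#' @export
print.drug_affinities <- function(x, ...) {
  cat(sprintf("Drug affinities: K_RX = %g /mM, K_TX = %g /mM, L^X = %g\n",
              x$K_RX, x$K_TX, x$L_X))
  invisible(x)
}

#' Drug-bound allosteric constant from thermodynamic linkage
#'
#' L^X = L * K_TX / K_RX. This is the only admissible value of the
#' drug-bound quaternary equilibrium constant: any other choice breaks
#' detailed balance around the four-state cycle R <-> T, R-X <-> T-X.
#'
#' @param L Drug-free allosteric constant.
#' @param K_TX Drug association constant for T, per mM.
#' @param K_RX Drug association constant for R, per mM.
#' @return L^X, dimensionless.
#' @examples
#' linkage_LX(70000, 0.06, 210)  # 20
#' @export
linkage_LX <- function(L, K_TX, K_RX) {
  if (any(c(L, K_TX, K_RX) <= 0)) stop("inputs must be positive")
  L * K_TX / K_RX
}

#' Red-cell suspension configuration
#'
#' Describes the dilute red-cell suspension in the measuring cuvette:
#' hemoglobin tetramer concentration inside the cells, red-cell volume
#' fraction of the suspension, and total drug concentration referred to the
#' whole suspension volume.
#'
#' @param hb_mM Hemoglobin tetramer concentration inside red cells, mM.
#' @param volume_fraction Red-cell volume fraction of the suspension, in (0,1).
#' @param drug_total_mM Total drug concentration in the suspension, mM.
#' @param temperature Label only (the model is isothermal).
#' @return An object of class \code{suspension_config}.
#' @export
suspension_config <- function(hb_mM = 5.4, volume_fraction = 0.004,
                              drug_total_mM = 0, temperature = "37C") {
  stopifnot(hb_mM >= 0, drug_total_mM >= 0)
  if (!(volume_fraction > 0 && volume_fraction < 1))
    stop("volume_fraction must be in (0,1)")
  structure(list(hb_mM = hb_mM, volume_fraction = volume_fraction,
                 drug_total_mM = drug_total_mM, temperature = temperature),
            class = "suspension_config")
}

#' Canonical ordering of the 20 kinetic species
#'
#' Conformation (R then T), ligation 0..4, then the drug-bound block in the
#' same order: R0..R4, T0..T4, R0X..R4X, T0X..T4X. State vectors, trajectory
#' columns and right-hand-side outputs all follow this ordering.
#'
#' @return Character vector of the 20 species names.
#' @export
species_names <- function() {
  c(paste0("R", 0:4), paste0("T", 0:4),
    paste0("R", 0:4, "X"), paste0("T", 0:4, "X"))
}

# ligation count of each species in canonical order
species_ligation <- function() rep(c(0:4, 0:4), 2)
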