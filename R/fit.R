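#' Chi-square misfit between observed and model curves
#'
#' Sum over all matching curves of ((observed - model)/sigma)^2 on the
#' reported-saturation scale. Model curves are interpolated in time to the
#' observed sample points; curves are matched by phase and cycle.
#'
#' @param observed List of curve data frames (time_s, phase, cycle,
#'   saturation_reported), or a single curve.
#' @param model Same structure, from a simulated run.
#' @param sigma Measurement noise s.d. in saturation units.
#' @return Chi-square value (>= 0).
#' @export
chi_square <- function(observed, model, sigma = 0.005) {
  if (is.data.frame(observed)) observed <- list(observed)
  if (is.data.frame(model)) model <- list(model)
  key <- function(cr) paste0(cr$phase[1], cr$cycle[1])
  mkeys <- vapply(model, key, "")
  total <- 0
  for (obs in observed) {
    m <- model[[match(key(obs), mkeys)]]
    if (is.null(m)) stop("no model curve matching ", key(obs))
    pred <- stats::approx(m$time_s, m$saturation_reported,
                          xout = obs$time_s, rule = 2)$y
    total <- total + sum(((obs$saturation_reported - pred) / sigma)^2)
  }
  total
}

# Nelder-Mead in log10 space with soft box penalty; restarted with a fresh
# simplex at the previous optimum until the value stops improving (degenerate
# simplices are the usual NM failure mode on narrow valleys)
nm_logsearch <- function(objective, theta0, lower, upper, control,
                        max_rounds = 4) {
  pen_obj <- function(th) {
    pen <- sum(pmax(th - upper, 0)^2 + pmax(lower - th, 0)^2) * 1e6
    objective(pmin(pmax(th, lower), upper)) + pen
  }
  settled <- FALSE
  fit <- stats::optim(theta0, pen_obj, method = "Nelder-Mead",
                      control = control)
  for (r in seq_len(max_rounds - 1)) {
    prev <- fit$value
    fit <- stats::optim(fit$par, pen_obj, method = "Nelder-Mead",
                        control = control)
    if (prev - fit$value < 1e-6 * (abs(prev) + 1e-12)) { settled <- TRUE; break }
  }
  list(par = pmin(pmax(fit$par, lower), upper), value = fit$value,
       convergence = if (settled || fit$convergence == 0) 0L else 1L)
}

new_mwc_fit <- function(type, estimates, chi_sq, replicates, fixed, sigma,
                        fitted_curves, observed) {
  # parameter spread across replicates that reached a comparable minimum
  ok <- is.finite(replicates$chi_sq) &
    replicates$chi_sq <= 2 * min(replicates$chi_sq) + 1e-6
  ranges <- sapply(names(estimates), function(p) {
    if (p %in% names(replicates)) range(replicates[[p]][ok])
    else c(NA_real_, NA_real_)
  })
  rownames(ranges) <- c("min", "max")
  structure(list(type = type, estimates = estimates, chi_sq = chi_sq,
                 replicates = replicates, ranges = ranges, fixed = fixed,
                 sigma = sigma, fitted_curves = fitted_curves,
                 observed = observed),
            class = "mwc_fit")
}

#' Fit the three allosteric constants to drug-free binding curves
#'
#' Chi-square fit of the equilibrium two-state model (K_R, K_T, L) to
#' reported (instrument-normalized) drug-free saturation curves. Each trial
#' model curve is evaluated at the observed pressures and normalized by its
#' own extremes, exactly as the instrument reports. Derivative-free
#' Nelder-Mead search in log space from multiple log-uniform starting points
#' inside broad bounds (K_R in [50, 1000], K_T in [0.5, 20] /mM,
#' L in [1e3, 1e7]).
#'
#' @param curves List of drug-free curve data frames (pO2_torr, time_s,
#'   phase, cycle, saturation_reported).
#' @param init Optional named initial values (K_R, K_T, L); used as an
#'   additional starting point.
#' @param n_starts Number of random starting points.
#' @param seed RNG seed for the starting points.
#' @param sigma Noise s.d. for the chi-square.
#' @param alpha Oxygen solubility, mM/torr.
#' @return An object of class \code{mwc_fit}.
#' @export
fit_allosteric <- function(curves, init = NULL, n_starts = 8, seed = 1,
                           sigma = 0.005, alpha = default_alpha()) {
  if (length(curves) < 1) stop("need at least one curve")
  lower <- log10(c(50, 0.5, 1e3)); upper <- log10(c(1000, 20, 1e7))
  model_curves <- function(K_R, K_T, L) {
    p <- hb_params(K_R, K_T, L, alpha)
    lapply(curves, function(obs) {
      y <- fractional_saturation(p, alpha * obs$pO2_torr)
      cr <- data.frame(time_s = obs$time_s, pO2_torr = obs$pO2_torr,
                       saturation_true = y, phase = obs$phase,
                       cycle = obs$cycle)
      instrument_normalize(cr)
    })
  }
  objective <- function(th) {
    v <- 10^th
    if (v[1] <= v[2]) return(1e12)   # enforce K_R > K_T
    chi_square(curves, model_curves(v[1], v[2], v[3]), sigma)
  }
  rng <- local({set.seed(seed); function(n) stats::runif(n)})
  starts <- lapply(seq_len(n_starts), function(i)
    lower + (upper - lower) * rng(3))
  if (!is.null(init)) starts <- c(list(log10(unname(
    init[c("K_R", "K_T", "L")]))), starts)
  reps <- data.frame()
  best <- NULL
  for (s in starts) {
    fit <- nm_logsearch(objective, s, lower, upper,
                        control = list(maxit = 500, reltol = 1e-10))
    v <- 10^fit$par
    reps <- rbind(reps, data.frame(K_R = v[1], K_T = v[2], L = v[3],
                                   chi_sq = fit$value,
                                   converged = fit$convergence == 0))
    if (is.null(best) || fit$value < best$value ||
        (fit$value == best$value && sum(fit$par^2) < sum(best$par^2)))
      best <- fit
  }
  v <- 10^best$par
  est <- c(K_R = v[1], K_T = v[2], L = v[3])
  new_mwc_fit("allosteric", est, best$value, reps,
              fixed = list(alpha = alpha), sigma = sigma,
              fitted_curves = model_curves(v[1], v[2], v[3]),
              observed = curves)
}

#' Fit the four drug rate coefficients to drug-present curves
#'
#' Joint chi-square fit of the drug binding/dissociation rates for R and T
#' (kRbX, kRdX, kTbX, kTdX) to dissociation and association curves at one or
#' more drug concentrations, with the allosteric constants held fixed (they
#' come from the drug-free fit). Every objective evaluation re-simulates the
#' full 20-state kinetic model through the complete pressure protocol at
#' each concentration. Derivative-free Nelder-Mead in log space; hard search
#' bounds are [1e-7, 10] in each rate's unit, with starting points drawn
#' log-uniformly from a physically motivated sub-box (binding 1e-4 to 1
#' /mM/s, dissociation 1e-6 to 1e-2 /s, the magnitudes compatible with the
#' minutes-to-hours hysteresis the curves display). The derived affinities
#' K_RX, K_TX and the linkage L^X are reported alongside the rates. Ties in
#' chi-square break to the smallest log-L2 parameter norm; deterministic for
#' a fixed seed.
#'
#' @param datasets List of datasets, each a list with elements \code{curves}
#'   (as from \code{generate_dataset}), \code{drug_conc_mM},
#'   \code{intervals_min} (defaults to c(0.7, 28, 56)).
#' @param params Fixed \code{hb_params} (from the drug-free stage).
#' @param init Optional named initial rates (kRbX, kRdX, kTbX, kTdX),
#'   used as an additional starting point.
#' @param n_starts Number of random multi-start points (>= 1).
#' @param seed RNG seed for the starting points.
#' @param sigma Noise s.d. for the chi-square.
#' @param thin Use every \code{thin}-th observed sample in the objective.
#' @param control \code{optim} control for each Nelder-Mead round.
#' @param rtol,atol Integrator tolerances during fitting (looser than the
#'   reporting defaults; the objective is noise-limited well above this).
#' @param hb_mM,volume_fraction Suspension constants.
#' @return An object of class \code{mwc_fit}; \code{estimates} carries the
#'   four rates plus derived K_RX, K_TX and L_X.
#' @export
fit_drug_kinetics <- function(datasets, params, init = NULL, n_starts = 5,
                              seed = 1, sigma = 0.005, thin = 5,
                              control = list(maxit = 150, reltol = 1e-5),
                              rtol = 1e-5, atol = 1e-9,
                              hb_mM = 5.4, volume_fraction = 0.004) {
  stopifnot(inherits(params, "hb_params"), length(datasets) >= 1)
  lower <- rep(log10(1e-7), 4); upper <- rep(log10(10), 4)
  # pre-thin the observations once
  obs_sets <- lapply(datasets, function(d) {
    lapply(d$curves, function(cr) cr[seq(1, nrow(cr), by = thin), ])
  })
  sim_curves <- function(rates, d) {
    program <- standard_protocol(
      length(d$intervals_min %||% c(0.7, 28, 56)),
      d$intervals_min %||% c(0.7, 28, 56),
      include_incubation = d$drug_conc_mM > 0)
    cfg <- suspension_config(hb_mM, volume_fraction, d$drug_conc_mM)
    run_experiment(params, rates, cfg, program, dt_out = 4, dt_force = 2,
                   rtol = rtol, atol = atol)$curves
  }
  objective <- function(th) {
    v <- 10^th
    # R-selectivity: project a K_TX >= K_RX trial back inside the feasible
    # region and add a smooth penalty, so the search keeps a gradient
    pen <- 0
    gap <- log10(v[3] / v[4]) - log10(v[1] / v[2])   # log10(K_TX/K_RX)
    if (gap > -0.3) {
      pen <- 1e4 * (gap + 0.3)^2
      v[3] <- v[4] * (v[1] / v[2]) * 10^(-0.3)
    }
    val <- try({
      rates <- kinetic_rates(params, v[1], v[2], v[3], v[4])
      total <- 0
      for (i in seq_along(datasets))
        total <- total + chi_square(obs_sets[[i]],
                                    sim_curves(rates, datasets[[i]]), sigma)
      total
    }, silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e12 else val + pen
  }
  set.seed(seed)
  # screening stage: score log-uniform candidates from the physically
  # plausible sub-box, then polish the best ones with Nelder-Mead
  slo <- log10(c(1e-4, 1e-6, 1e-4, 1e-6))
  shi <- log10(c(1, 1e-2, 1, 1e-2))
  n_screen <- max(4 * n_starts, 20)
  cand <- t(replicate(n_screen, slo + (shi - slo) * stats::runif(4)))
  scores <- apply(cand, 1, objective)
  starts <- lapply(order(scores)[seq_len(n_starts)], function(i) cand[i, ])
  if (!is.null(init)) starts <- c(list(log10(unname(
    init[c("kRbX", "kRdX", "kTbX", "kTdX")]))), starts)
  reps <- data.frame()
  best <- NULL
  for (s in starts) {
    fit <- nm_logsearch(objective, s, lower, upper, control = control)
    v <- 10^fit$par
    reps <- rbind(reps, data.frame(
      kRbX = v[1], kRdX = v[2], kTbX = v[3], kTdX = v[4],
      K_RX = v[1] / v[2], K_TX = v[3] / v[4],
      L_X = linkage_LX(params$L, v[3] / v[4], v[1] / v[2]),
      chi_sq = fit$value, converged = fit$convergence == 0))
    if (is.null(best) || fit$value < best$value ||
        (fit$value == best$value && sum(fit$par^2) < sum(best$par^2)))
      best <- fit
  }
  v <- 10^best$par
  est <- c(kRbX = v[1], kRdX = v[2], kTbX = v[3], kTdX = v[4],
           K_RX = v[1] / v[2], K_TX = v[3] / v[4],
           L_X = linkage_LX(params$L, v[3] / v[4], v[1] / v[2]))
  rates <- kinetic_rates(params, v[1], v[2], v[3], v[4])
  fitted <- lapply(datasets, function(d) sim_curves(rates, d))
  new_mwc_fit("drug_kinetics", est, best$value, reps,
              fixed = list(K_R = params$K_R, K_T = params$K_T, L = params$L,
                           alpha = params$alpha),
              sigma = sigma, fitted_curves = fitted, observed = obs_sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mwc_fit <- function(x, ...) {
  cat(sprintf("MWC %s fit: chi-square = %.4g (%d starts, %d converged)\n",
              x$type, x$chi_sq, nrow(x$replicates),
              sum(x$replicates$converged)))
  print(signif(x$estimates, 4))
  invisible(x)
}

#' @export
summary.mwc_fit <- function(object, ...) {
  cat(sprintf("MWC %s fit\n", object$type))
  cat(sprintf("  chi-square: %.6g  (sigma = %g saturation units)\n",
              object$chi_sq, object$sigma))
  cat("  estimates and multi-start replicate ranges:\n")
  tab <- data.frame(estimate = object$estimates,
                    min = object$ranges["min", names(object$estimates)],
                    max = object$ranges["max", names(object$estimates)])
  print(signif(as.matrix(tab), 4))
  if (length(object$fixed)) {
    cat("  fixed: ")
    cat(paste(names(object$fixed), signif(unlist(object$fixed), 4),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.mwc_fit <- function(object, ...) object$estimates

#' Model curves at the fitted parameters
#'
#' @param object An \code{mwc_fit}.
#' @param ... Unused.
#' @return The list of fitted model curves evaluated at the observed grids.
#' @export
predict.mwc_fit <- function(object, ...) object$fitted_curves

#' @export
residuals.mwc_fit <- function(object, ...) {
  obs <- object$observed; fit <- object$fitted_curves
  if (object$type == "allosteric") { obs <- list(obs); fit <- list(fit) }
  unlist(lapply(seq_along(obs), function(i) {
    key <- function(cr) paste0(cr$phase[1], cr$cycle[1])
    fkeys <- vapply(fit[[i]], key, "")
    unlist(lapply(obs[[i]], function(o) {
      m <- fit[[i]][[match(key(o), fkeys)]]
      o$saturation_reported -
        stats::approx(m$time_s, m$saturation_reported, xout = o$time_s,
                      rule = 2)$y
    }))
  }))
}
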