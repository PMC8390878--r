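#' Piecewise oxygen-pressure program
#'
#' Low-level constructor for a pressure schedule: an ordered set of segments
#' each with start/end pressure (torr), duration (s), interpolation shape
#' ("log" = linear in log pressure, "linear"), phase label and cycle index.
#'
#' @param phase Character vector: "incubation", "dissociation", "hold" or
#'   "association".
#' @param cycle Integer cycle index (0 for incubation).
#' @param P_start,P_end Segment pressures, torr.
#' @param duration_s Segment durations, s (> 0).
#' @param shape "log" or "linear" per segment.
#' @return Data frame of class \code{pressure_program} with a t_start_s
#'   column of cumulative segment start times.
#' @export
pressure_program <- function(phase, cycle, P_start, P_end, duration_s,
                             shape = "log") {
  if (any(duration_s <= 0)) stop("durations must be positive")
  if (any(P_start <= 0) || any(P_end <= 0)) stop("pressures must be positive")
  if (!all(phase %in% c("incubation", "dissociation", "hold", "association")))
    stop("unknown phase label")
  df <- data.frame(phase = phase, cycle = cycle, P_start = P_start,
                   P_end = P_end, duration_s = duration_s,
                   shape = rep_len(shape, length(phase)))
  df$t_start_s <- cumsum(c(0, df$duration_s[-nrow(df)]))
  structure(df, class = c("pressure_program", "data.frame"))
}

#' Standard paired dissociation/association protocol
#'
#' The canonical instrument run: an optional 60 min incubation hold at room
#' air (150 torr, during which the drug equilibrates with the cells),
#' followed per cycle by a dissociation ramp 150 -> 2 torr over 8 min, a
#' hold at 2 torr for the stated interval, and an association ramp
#' 2 -> 150 torr over 12 min. Ramps default to linear in log pressure.
#'
#' @param n_cycles Number of dissociation/association pairs.
#' @param intervals_min Waiting time at low pressure after each dissociation
#'   ramp, minutes; length must equal \code{n_cycles}.
#' @param include_incubation Prepend the 60 min pre-incubation hold?
#' @param P_high,P_low Operating pressures, torr (room air ~150; lowest
#'   achieved ~2).
#' @param dissoc_min,assoc_min Ramp durations, minutes.
#' @param incubation_min Incubation duration, minutes.
#' @param shape Ramp shape, "log" (default) or "linear".
#' @return A \code{pressure_program}.
#' @examples
#' standard_protocol(3, c(0.7, 28, 56))       # 200 uM-style schedule
#' standard_protocol(3, c(0.7, 28, 60))       # drug-free-style schedule
#' @export
standard_protocol <- function(n_cycles = 3, intervals_min = c(0.7, 28, 56),
                              include_incubation = TRUE,
                              P_high = 150, P_low = 2,
                              dissoc_min = 8, assoc_min = 12,
                              incubation_min = 60, shape = "log") {
  if (length(intervals_min) == 0) stop("intervals_min must be nonempty")
  if (length(intervals_min) != n_cycles)
    stop("intervals_min must have one entry per cycle")
  if (any(intervals_min < 0)) stop("intervals_min must be nonnegative")
  phase <- character(0); cyc <- integer(0)
  Ps <- numeric(0); Pe <- numeric(0); dur <- numeric(0); shp <- character(0)
  add <- function(ph, k, p1, p2, mins, s) {
    phase <<- c(phase, ph); cyc <<- c(cyc, k)
    Ps <<- c(Ps, p1); Pe <<- c(Pe, p2); dur <<- c(dur, mins * 60)
    shp <<- c(shp, s)
  }
  if (include_incubation)
    add("incubation", 0L, P_high, P_high, incubation_min, "linear")
  for (k in seq_len(n_cycles)) {
    add("dissociation", k, P_high, P_low, dissoc_min, shape)
    if (intervals_min[k] > 0)
      add("hold", k, P_low, P_low, intervals_min[k], "linear")
    add("association", k, P_low, P_high, assoc_min, shape)
  }
  pressure_program(phase, cyc, Ps, Pe, dur, shp)
}

#' Oxygen pressure at given protocol times
#'
#' @param program A \code{pressure_program}.
#' @param t Times, s, within [0, total duration].
#' @return Pressures, torr.
#' @export
program_pressure <- function(program, t) {
  ends <- program$t_start_s + program$duration_s
  total <- ends[nrow(program)]
  if (any(t < 0 | t > total + 1e-9)) stop("time outside program")
  idx <- findInterval(pmin(t, total - 1e-12), program$t_start_s)
  frac <- (t - program$t_start_s[idx]) / program$duration_s[idx]
  frac <- pmin(pmax(frac, 0), 1)
  P <- ifelse(program$shape[idx] == "log",
              program$P_start[idx] *
                (program$P_end[idx] / program$P_start[idx])^frac,
              program$P_start[idx] +
                frac * (program$P_end[idx] - program$P_start[idx]))
  P
}

#' Free drug concentration from suspension mass balance
#'
#' Drug partitions instantaneously across the red-cell membrane, so the free
#' concentration is the same inside and outside the cells; conservation then
#' gives X_free = X_total - vf * bound, with bound expressed per unit cell
#' volume.
#'
#' @param config A \code{suspension_config}.
#' @param bound_mM Drug bound to hemoglobin, mM of cell volume.
#' @return Free drug concentration, mM.
#' @export
drug_mass_balance <- function(config, bound_mM) {
  stopifnot(inherits(config, "suspension_config"))
  if (bound_mM > config$hb_mM + 1e-12)
    stop("bound drug exceeds hemoglobin concentration")
  X <- config$drug_total_mM - config$volume_fraction * bound_mM
  if (X < -1e-12)
    stop("negative free drug: inconsistent state (depletion-dominated ",
         "regimes must be co-solved with binding)")
  max(X, 0)
}

#' Run a simulated instrument experiment
#'
#' Integrates the 20-state kinetic model along a pressure program with
#' x(t) = alpha * P(t) (instantaneous gas/liquid oxygen equilibration) and
#' free drug co-solved from the suspension mass balance at every step,
#' starting from the drug-free equilibrium at the initial pressure. The
#' trajectory is sliced into one curve record per dissociation and
#' association segment, and each curve is put through the instrument's
#' min-max saturation normalization.
#'
#' @param params An \code{hb_params} object.
#' @param rates A \code{kinetic_rates} object.
#' @param config A \code{suspension_config}.
#' @param program A \code{pressure_program}.
#' @param dt_out Output grid spacing, s.
#' @param dt_force Forcing-series spacing for x(t), s.
#' @param rtol,atol Integrator tolerances.
#' @return List of class \code{hemox_run}: \code{curves} (list of curve data
#'   frames with time_s, pO2_torr, saturation_true, saturation_reported,
#'   phase, cycle) and \code{trajectory} (full species time course with
#'   free-drug and saturation columns).
#' @export
run_experiment <- function(params, rates, config, program,
                           dt_out = 2, dt_force = 1,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "hb_params"), inherits(rates, "kinetic_rates"),
            inherits(config, "suspension_config"),
            inherits(program, "pressure_program"))
  total <- sum(program$duration_s)
  tf <- seq(0, total, by = dt_force)
  if (tf[length(tf)] < total) tf <- c(tf, total)
  forc <- cbind(tf, params$alpha * program_pressure(program, tf))
  bounds <- sort(unique(c(program$t_start_s,
                          program$t_start_s + program$duration_s)))
  times <- sort(unique(c(seq(0, total, by = dt_out), bounds, total)))
  x0 <- params$alpha * program$P_start[1]
  state0 <- equilibrium_state(params, rates$drug, x0, 0, config$hb_mM)
  out <- simulate_kinetics(state0, rates, times, forc,
                           X_total = config$drug_total_mM,
                           volume_fraction = config$volume_fraction,
                           mass_balance = TRUE, rtol = rtol, atol = atol)
  species <- out[, species_names(), drop = FALSE]
  traj <- data.frame(
    time_s = out[, "time"],
    pO2_torr = program_pressure(program, out[, "time"]),
    X_free_mM = config$drug_total_mM -
      config$volume_fraction * rowSums(species[, 11:20, drop = FALSE]),
    species, check.names = FALSE)
  traj$saturation <- saturation_of_state(as.matrix(species))
  class(traj) <- c("hb_trajectory", "data.frame")

  curves <- list()
  for (s in seq_len(nrow(program))) {
    if (!program$phase[s] %in% c("dissociation", "association")) next
    t0 <- program$t_start_s[s]; t1 <- t0 + program$duration_s[s]
    sel <- traj$time_s >= t0 - 1e-9 & traj$time_s <= t1 + 1e-9
    cr <- data.frame(time_s = traj$time_s[sel], pO2_torr = traj$pO2_torr[sel],
                     saturation_true = traj$saturation[sel],
                     phase = program$phase[s], cycle = program$cycle[s])
    cr <- instrument_normalize(cr)
    curves[[paste0(substr(program$phase[s], 1, 5), program$cycle[s])]] <- cr
  }
  structure(list(curves = curves, trajectory = traj,
                 params = params, rates = rates, config = config,
                 program = program),
            class = "hemox_run")
}

#' Apply the instrument's min-max saturation normalization
#'
#' The instrument reports saturation assuming 100% at the highest pressure of
#' the run (room air) and 0% at the lowest achieved pressure:
#' reported = (y - y_low) / (y_high - y_low), clamped to [0,1]. For
#' high-affinity samples whose true saturation at ~2 torr is far from zero
#' this distorts the curve; the transform is invertible given the model's
#' true extremes.
#'
#' @param curve Data frame with pO2_torr and saturation_true columns.
#' @return The curve with a saturation_reported column added.
#' @export
instrument_normalize <- function(curve) {
  ylo <- curve$saturation_true[which.min(curve$pO2_torr)]
  yhi <- curve$saturation_true[which.max(curve$pO2_torr)]
  if (abs(yhi - ylo) < 1e-12) stop("constant curve cannot be normalized")
  curve$saturation_reported <-
    pmin(pmax((curve$saturation_true - ylo) / (yhi - ylo), 0), 1)
  curve
}

#' @export
print.hemox_run <- function(x, ...) {
  cat(sprintf("Simulated instrument run: %d curves, %.1f min total, %g mM drug\n",
              length(x$curves), sum(x$program$duration_s) / 60,
              x$config$drug_total_mM))
  for (nm in names(x$curves)) {
    cr <- x$curves[[nm]]
    cat(sprintf("  %-14s cycle %d  t = %6.1f-%6.1f min  y(true) %.3f -> %.3f\n",
                cr$phase[1], cr$cycle[1], min(cr$time_s) / 60,
                max(cr$time_s) / 60,
                cr$saturation_true[1], cr$saturation_true[nrow(cr)]))
  }
  invisible(x)
}

#' @export
plot.hemox_run <- function(x, ...) {
  traj <- x$trajectory
  graphics::plot(traj$time_s / 60, traj$saturation, type = "l",
                 xlab = "experimental time (min)",
                 ylab = "fractional saturation", ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
plot.hb_trajectory <- function(x, what = c("saturation", "conformations"),
                               ...) {
  what <- match.arg(what)
  if (what == "saturation") {
    graphics::plot(x$time_s / 60, x$saturation, type = "l",
                   xlab = "time (min)", ylab = "fractional saturation",
                   ylim = c(0, 1), ...)
  } else {
    tot <- rowSums(as.matrix(x[, species_names()]))
    pops <- cbind(R  = rowSums(x[, paste0("R", 0:4)]) / tot,
                  T  = rowSums(x[, paste0("T", 0:4)]) / tot,
                  RX = rowSums(x[, paste0("R", 0:4, "X")]) / tot,
                  TX = rowSums(x[, paste0("T", 0:4, "X")]) / tot)
    graphics::matplot(x$time_s / 60, pops, type = "l", lty = 1,
                      xlab = "time (min)", ylab = "population fraction", ...)
    graphics::legend("topright", colnames(pops), col = 1:4, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Conformational population fractions along a trajectory
#'
#' Fractions of the total tetramer pool in drug-free R, drug-free T,
#' drug-bound R and drug-bound T at each time point.
#'
#' @param traj An \code{hb_trajectory}.
#' @return Data frame with time_s, R, T, RX, TX columns (fractions).
#' @export
conformation_populations <- function(traj) {
  m <- as.matrix(traj[, species_names()])
  tot <- rowSums(m)
  data.frame(time_s = traj$time_s,
             R  = rowSums(m[, 1:5, drop = FALSE]) / tot,
             T  = rowSums(m[, 6:10, drop = FALSE]) / tot,
             RX = rowSums(m[, 11:15, drop = FALSE]) / tot,
             TX = rowSums(m[, 16:20, drop = FALSE]) / tot)
}
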