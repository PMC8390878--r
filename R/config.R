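#' Read and validate a run configuration
#'
#' Loads a JSON run configuration and validates it against the accepted
#' schema; unknown keys are rejected so unit mistakes surface immediately
#' (all physical quantities carry unit suffixes in their key names).
#'
#' Accepted keys: \code{set} (canonical parameter-set name),
#' \code{drug_conc_mM} (scalar or vector), \code{intervals_min},
#' \code{noise_sd}, \code{seed}, \code{out_dir}, \code{dt_out_s},
#' \code{n_starts}, \code{pressures_torr}.
#'
#' @param path Path to a JSON file, or a named list already in memory.
#' @return Validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else as.list(path)
  allowed <- c("set", "drug_conc_mM", "intervals_min", "noise_sd", "seed",
               "out_dir", "dt_out_s", "n_starts", "pressures_torr")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(set = "table1_mid", drug_conc_mM = 0.2,
                   intervals_min = c(0.7, 28, 56), noise_sd = 0.005,
                   seed = 1, out_dir = ".", dt_out_s = 2, n_starts = 5,
                   pressures_torr = exp(seq(log(0.5), log(160),
                                            length.out = 200)))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$set %in% c("table1_mid", "table1_LX20", "drug_free"))
    stop("unknown parameter set: ", cfg$set)
  if (any(cfg$drug_conc_mM < 0) || cfg$noise_sd < 0)
    stop("concentrations and noise_sd must be nonnegative")
  if (cfg$seed != as.integer(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "run_config")
}

#' Export equilibrium binding curves
#'
#' Writes the drug-free equilibrium curve and, when drug is present, the
#' true equilibrium curve (instantaneous drug exchange) over the configured
#' pressure grid, as CSV with columns pO2_torr, x_mM, saturation (six
#' decimal places).
#'
#' @param config A \code{run_config} (or path/list accepted by
#'   \code{read_run_config}).
#' @return Invisibly, the list of written file paths.
#' @export
cli_equilibrium <- function(config) {
  cfg <- read_run_config(config)
  set <- canonical_parameters(cfg$set)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_curve <- function(curve, file) {
    df <- data.frame(pO2_torr = round(curve$pO2_torr, 6),
                     x_mM = round(curve$x_mM, 6),
                     saturation = round(curve$saturation, 6))
    utils::write.csv(df, file, row.names = FALSE)
    file
  }
  P <- cfg$pressures_torr
  free <- data.frame(pO2_torr = P, x_mM = set$params$alpha * P,
                     saturation = fractional_saturation(
                       set$params, set$params$alpha * P))
  paths <- write_curve(free, file.path(cfg$out_dir, "equilibrium_drug_free.csv"))
  for (X in cfg$drug_conc_mM[cfg$drug_conc_mM > 0]) {
    eq <- true_equilibrium_curve(set$params, set$rates$drug, X,
                                 set$config$hb_mM,
                                 set$config$volume_fraction, P)
    paths <- c(paths, write_curve(eq, file.path(
      cfg$out_dir, sprintf("equilibrium_drug_%s_mM.csv", format(X)))))
  }
  invisible(paths)
}

#' Generate synthetic datasets from a configuration
#'
#' Runs the synthetic-data generator for each configured drug concentration,
#' writing curve CSVs and manifests under \code{out_dir}.
#'
#' @inheritParams cli_equilibrium
#' @return Invisibly, the list of dataset directories written.
#' @export
cli_simulate <- function(config) {
  cfg <- read_run_config(config)
  dirs <- character(0)
  for (X in cfg$drug_conc_mM) {
    d <- file.path(cfg$out_dir, sprintf("dataset_%s_mM", format(X)))
    generate_dataset(cfg$set, X, cfg$intervals_min, cfg$noise_sd,
                     seed = cfg$seed, dir = d, dt_out = cfg$dt_out_s)
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}

#' Fit model parameters to a dataset directory tree
#'
#' Runs the drug-free allosteric fit (if a zero-concentration dataset is
#' present) and then the four-rate drug-kinetics fit over all drug-present
#' datasets, writing the fit result as JSON plus a fit-vs-data CSV.
#'
#' @inheritParams cli_equilibrium
#' @param dataset_dirs Directories written by \code{cli_simulate}.
#' @return Invisibly, a list with the \code{mwc_fit} objects.
#' @export
cli_fit <- function(config, dataset_dirs) {
  cfg <- read_run_config(config)
  missing <- dataset_dirs[!dir.exists(dataset_dirs)]
  if (length(missing)) stop("dataset not found: ", paste(missing, collapse = ", "))
  sets <- lapply(dataset_dirs, read_dataset)
  concs <- vapply(sets, function(s) s$manifest$drug_conc_mM, 0)
  allo <- NULL
  if (any(concs == 0)) {
    allo <- fit_allosteric(sets[[which(concs == 0)[1]]]$curves,
                           n_starts = cfg$n_starts, seed = cfg$seed,
                           sigma = max(cfg$noise_sd, 1e-3))
    params <- hb_params(allo$estimates["K_R"], allo$estimates["K_T"],
                        allo$estimates["L"])
  } else {
    set <- canonical_parameters(cfg$set)
    params <- set$params
  }
  kin <- NULL
  if (any(concs > 0)) {
    dsets <- lapply(which(concs > 0), function(i)
      list(curves = sets[[i]]$curves, drug_conc_mM = concs[i],
           intervals_min = sets[[i]]$manifest$intervals_min))
    kin <- fit_drug_kinetics(dsets, params, n_starts = cfg$n_starts,
                             seed = cfg$seed,
                             sigma = max(cfg$noise_sd, 1e-3))
  }
  out <- list()
  for (f in list(allosteric = allo, drug_kinetics = kin)) {
    if (is.null(f)) next
    out[[f$type]] <- f
    jsonlite::write_json(
      list(type = f$type, estimates = as.list(f$estimates),
           chi_sq = f$chi_sq, seed = cfg$seed,
           ranges = as.data.frame(t(f$ranges)),
           replicates = f$replicates, fixed = f$fixed),
      file.path(cfg$out_dir, paste0("fit_", f$type, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Export conformational population tables
#'
#' Simulates the configured protocol at each drug concentration and writes
#' species-vs-time and conformation-vs-saturation tables (one CSV each).
#'
#' @inheritParams cli_equilibrium
#' @return Invisibly, written file paths.
#' @export
cli_populations <- function(config) {
  cfg <- read_run_config(config)
  set <- canonical_parameters(cfg$set)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (X in cfg$drug_conc_mM) {
    program <- standard_protocol(length(cfg$intervals_min),
                                 cfg$intervals_min,
                                 include_incubation = X > 0)
    config2 <- suspension_config(set$config$hb_mM,
                                 set$config$volume_fraction, X)
    run <- run_experiment(set$params, set$rates, config2, program,
                          dt_out = cfg$dt_out_s)
    traj <- run$trajectory
    f1 <- file.path(cfg$out_dir, sprintf("trajectory_%s_mM.csv", format(X)))
    num <- vapply(traj, is.numeric, TRUE)
    traj[num] <- lapply(traj[num], function(v) round(v, 6))
    utils::write.csv(traj, f1, row.names = FALSE)
    pops <- conformation_populations(run$trajectory)
    pops$saturation <- run$trajectory$saturation
    f2 <- file.path(cfg$out_dir, sprintf("populations_%s_mM.csv", format(X)))
    utils::write.csv(round(pops, 6), f2, row.names = FALSE)
    paths <- c(paths, f1, f2)
  }
  invisible(paths)
}
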