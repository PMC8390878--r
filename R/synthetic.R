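#' Canonical parameter sets
#'
#' Named parameter sets used throughout the package and its tests:
#' \describe{
#'   \item{table1_mid}{Midpoints of the reported ranges of every fitted
#'     constant: L = 117500, K_R = 240, K_T = 3.5 /mM; kRbX = 0.025,
#'     kRdX = 1.5e-4 (K_RX ~ 167 /mM), kTbX = 4.5e-5, kTdX = 6e-4
#'     (K_TX = 0.075 /mM).}
#'   \item{table1_LX20}{A constructed generating set with L = 70000,
#'     kRbX = 0.021, kRdX = 1e-4 (K_RX = 210), kTbX = 4.5e-5,
#'     kTdX = 7.5e-4 (K_TX = 0.06), chosen so the linkage-derived
#'     drug-bound allosteric constant is exactly L^X = 20. L sits just
#'     below the reported 75000-160000 range; the set is synthetic by
#'     design.}
#'   \item{drug_free}{K_R = 240, K_T = 3.5, L = 1e5, with nominal mid-range
#'     drug rates that are inert at zero drug.}
#' }
#'
#' @param name One of "table1_mid", "table1_LX20", "drug_free".
#' @return List of class \code{canonical_set} with elements \code{name},
#'   \code{params} (\code{hb_params}), \code{rates} (\code{kinetic_rates}),
#'   \code{config} (\code{suspension_config}, zero drug) and \code{note}.
#' @export
canonical_parameters <- function(name = c("table1_mid", "table1_LX20",
                                          "drug_free")) {
  name <- match.arg(name)
  spec <- switch(name,
    table1_mid = list(L = (75000 + 160000) / 2, kRbX = 0.025, kRdX = 1.5e-4,
                      kTbX = 4.5e-5, kTdX = 6e-4,
                      note = "midpoints of the reported parameter ranges"),
    table1_LX20 = list(L = 70000, kRbX = 0.021, kRdX = 1e-4,
                       kTbX = 4.5e-5, kTdX = 7.5e-4,
                       note = "constructed so that L * K_TX / K_RX = 20 exactly"),
    drug_free = list(L = 1e5, kRbX = 0.025, kRdX = 1.5e-4,
                     kTbX = 4.5e-5, kTdX = 6e-4,
                     note = "drug-free reference set (drug rates inert at X = 0)"))
  params <- hb_params(K_R = 240, K_T = 3.5, L = spec$L)
  rates <- kinetic_rates(params, spec$kRbX, spec$kRdX, spec$kTbX, spec$kTdX)
  structure(list(name = name, params = params, rates = rates,
                 config = suspension_config(5.4, 0.004, 0),
                 note = spec$note),
            class = "canonical_set")
}

#' @export
print.canonical_set <- function(x, ...) {
  cat(sprintf("Canonical parameter set '%s' (%s)\n", x$name, x$note))
  print(x$params); print(x$rates)
  invisible(x)
}

#' Generate a synthetic instrument dataset
#'
#' Simulates a full paired dissociation/association experiment at the given
#' total drug concentration, applies the instrument's min-max normalization,
#' adds i.i.d. Gaussian noise to the reported saturation, and (optionally)
#' writes one CSV per curve plus a JSON manifest recording the parameters
#' and seed. Bit-reproducible for a fixed seed.
#'
#' @param set A \code{canonical_set} (or a name accepted by
#'   \code{canonical_parameters}).
#' @param drug_conc_mM Total drug in the suspension, mM.
#' @param intervals_min Low-pressure waiting intervals, minutes (one per
#'   cycle); defaults to the three-cycle schedule 0.7, 28, 56 min.
#' @param noise_sd Gaussian noise s.d. on reported saturation (0 = none).
#' @param seed RNG seed, recorded in the manifest.
#' @param dir Output directory (created if needed); NULL for in-memory only.
#' @param dt_out Sampling interval of the saturation record, s.
#' @param ... Passed to \code{run_experiment} (e.g. integrator tolerances).
#' @return Invisibly, a list with \code{curves} (list of curve data frames
#'   with noisy saturation_reported), \code{run} (the noise-free
#'   \code{hemox_run}) and \code{manifest}.
#' @export
generate_dataset <- function(set, drug_conc_mM, intervals_min = c(0.7, 28, 56),
                             noise_sd = 0.005, seed = 1, dir = NULL,
                             dt_out = 2, ...) {
  if (is.character(set)) set <- canonical_parameters(set)
  stopifnot(inherits(set, "canonical_set"), noise_sd >= 0)
  program <- standard_protocol(length(intervals_min), intervals_min,
                               include_incubation = drug_conc_mM > 0)
  config <- suspension_config(set$config$hb_mM, set$config$volume_fraction,
                              drug_conc_mM)
  run <- run_experiment(set$params, set$rates, config, program,
                        dt_out = dt_out, ...)
  curves <- run$curves
  set.seed(seed)
  for (nm in names(curves)) {
    n <- nrow(curves[[nm]])
    curves[[nm]]$saturation_reported <-
      curves[[nm]]$saturation_reported + stats::rnorm(n, 0, noise_sd)
  }
  manifest <- list(
    set = set$name, drug_conc_mM = drug_conc_mM,
    intervals_min = intervals_min, noise_sd = noise_sd, seed = seed,
    dt_out_s = dt_out,
    params = list(K_R = set$params$K_R, K_T = set$params$K_T,
                  L = set$params$L, alpha = set$params$alpha),
    drug_rates = list(kRbX = set$rates$kRbX, kRdX = set$rates$kRdX,
                      kTbX = set$rates$kTbX, kTdX = set$rates$kTdX),
    suspension = list(hb_mM = config$hb_mM,
                      volume_fraction = config$volume_fraction))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(curves)) {
      cr <- curves[[nm]]
      num <- c("pO2_torr", "saturation_true", "saturation_reported")
      cr[num] <- lapply(cr[num], function(v) round(v, 6))
      utils::write.csv(cr, file.path(dir,
        paste0(format(drug_conc_mM), "_", cr$phase[1], cr$cycle[1], ".csv")),
        row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(curves = curves, run = run, manifest = manifest,
                 program = program, config = config))
}

#' Read a synthetic dataset from disk
#'
#' @param dir Directory written by \code{generate_dataset}.
#' @return List with \code{curves} and \code{manifest}.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), character(0))
  curves <- list()
  for (f in files) {
    cr <- utils::read.csv(file.path(dir, f))
    curves[[paste0(substr(cr$phase[1], 1, 5), cr$cycle[1])]] <- cr
  }
  list(curves = curves, manifest = manifest)
}
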