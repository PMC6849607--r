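# End-to-end orchestration: simulate -> fit growth -> fit Monod -> fit
# Arrhenius -> predict (both modes) -> evaluate, with one global seed
# expanded into per-stage substreams so any stage can be rerun
# independently and reproduce its outputs exactly.

#' Pipeline configuration
#'
#' Collects every tunable of the synthetic replication pipeline with
#' defaults matching the factorial study design. All temperatures are
#' Celsius, nutrient concentrations umol L^-1.
#'
#' @param output_dir directory for all CSV artifacts.
#' @param n_species panel size for the synthetic species pool.
#' @param trait_ranges see [default_trait_ranges()].
#' @param monoculture,competition [experiment_design()] objects.
#' @param sigma_log10,misclassification_rate see [noise_model()].
#' @param depletion simulate nutrient drawdown in competition trials.
#' @param n_starts_buchanan,n_starts_monod multi-start counts for the two
#'   nonlinear fits.
#' @param otr_C operational temperature range for the Arrhenius fits.
#' @param T_ref_C reference temperature (inside the OTR).
#' @param evaluation_day census day used for scoring.
#' @param drop_threshold low-density drop cutoff, cells mL^-1.
#' @param bootstrap_B bootstrap resamples for p-values.
#' @param seed global seed; each stage derives its own substream.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "thermocompete-run",
                            n_species = 6,
                            trait_ranges = default_trait_ranges(),
                            monoculture = monoculture_design(),
                            competition = competition_design(),
                            sigma_log10 = 0.05,
                            misclassification_rate = 0,
                            depletion = FALSE,
                            n_starts_buchanan = 1000,
                            n_starts_monod = 200,
                            otr_C = c(15, 25),
                            T_ref_C = 15,
                            evaluation_day = 14,
                            drop_threshold = 500,
                            bootstrap_B = 10000,
                            seed = 1L) {
  if (otr_C[1] >= otr_C[2]) stopf("OTR must satisfy low < high")
  if (T_ref_C < otr_C[1] || T_ref_C > otr_C[2])
    stopf("T_ref_C must lie inside the OTR")
  structure(list(output_dir = output_dir, n_species = n_species,
                 trait_ranges = trait_ranges, monoculture = monoculture,
                 competition = competition, sigma_log10 = sigma_log10,
                 misclassification_rate = misclassification_rate,
                 depletion = depletion,
                 n_starts_buchanan = n_starts_buchanan,
                 n_starts_monod = n_starts_monod, otr_C = otr_C,
                 T_ref_C = T_ref_C, evaluation_day = evaluation_day,
                 drop_threshold = drop_threshold, bootstrap_B = bootstrap_B,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [pipeline_config()] may appear in the file; design grids
#' are given as nested maps with the [experiment_design()] field names.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (d in c("monoculture", "competition"))
    if (!is.null(raw[[d]])) raw[[d]] <- do.call(experiment_design, raw[[d]])
  if (!is.null(raw$trait_ranges))
    raw$trait_ranges <- lapply(raw$trait_ranges, as.numeric)
  if (!is.null(raw$otr_C)) raw$otr_C <- as.numeric(raw$otr_C)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic replication pipeline
#'
#' Executes simulate, fit-growth, fit-monod, fit-arrhenius, predict (both
#' the nutrient-explicit and nutrient-saturated modes) and evaluate, writing
#' every artifact as CSV into `config$output_dir` together with a run
#' manifest (seeds and row counts). Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress (default `TRUE`).
#' @return invisibly, a list with all in-memory artifacts: `panel`,
#'   `growth_curves`, `competition_counts`, `growth_fits`, `monod_fits`,
#'   `traits`, `predictions_R`, `predictions_Rinf`, `evaluation`
#'   (rbind of both modes' [evaluation_table()] rows), `reversals_R`,
#'   `reversals_Rinf`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)
  noise <- noise_model(config$sigma_log10, config$misclassification_rate)

  say("[simulate] sampling %d-species panel", config$n_species)
  panel <- sample_species_panel(config$n_species, config$trait_ranges,
                                seed = substream_seed(config$seed, 1))
  growth_curves <- simulate_monoculture_experiment(
    panel, config$monoculture, noise, seed = substream_seed(config$seed, 2))
  competition_counts <- simulate_competition_experiment(
    panel, config$competition, noise, depletion = config$depletion,
    seed = substream_seed(config$seed, 3))
  write_dataset(panel, out_path("true_traits.csv"))
  write_dataset(growth_curves, out_path("growth_curves.csv"))
  write_dataset(competition_counts, out_path("competition_counts.csv"))
  say("[simulate] %d monoculture rows, %d competition rows",
      nrow(growth_curves), nrow(competition_counts))

  say("[fit-growth] fitting %d curves",
      nrow(unique(growth_curves[, 1:4])))
  growth_fits <- fit_growth_rates(growth_curves,
                                  n_starts = config$n_starts_buchanan,
                                  seed = substream_seed(config$seed, 4))
  write_dataset(growth_fits, out_path("growth_fits.csv"))
  say("[fit-growth] %d fits, %d failed-growth, %d non-converged",
      nrow(growth_fits), sum(growth_fits$failed), sum(!growth_fits$converged))

  monod_fits <- fit_monod_curves(growth_fits,
                                 n_starts = config$n_starts_monod,
                                 seed = substream_seed(config$seed, 5))
  write_dataset(monod_fits, out_path("monod_fits.csv"))
  say("[fit-monod] %d fits, %d flagged", nrow(monod_fits),
      sum(monod_fits$flagged))

  traits <- fit_metabolic_traits(monod_fits, otr_C = config$otr_C,
                                 T_ref_C = config$T_ref_C)
  write_dataset(traits, out_path("metabolic_traits.csv"))
  say("[fit-arrhenius] traits for %d species", nrow(traits))

  horizon <- config$evaluation_day
  predictions_R <- prediction_grid(traits,
                                   config$competition$temperatures_C,
                                   config$competition$phosphate_umol_L,
                                   t_days = horizon, mode = "R")
  predictions_Rinf <- prediction_grid(traits,
                                      config$competition$temperatures_C,
                                      t_days = horizon, mode = "Rinf")
  write_dataset(rbind(predictions_R, predictions_Rinf),
                out_path("predictions.csv"))
  say("[predict] %d + %d predictions",
      nrow(predictions_R), nrow(predictions_Rinf))

  obs <- drop_low_density(competition_counts, config$drop_threshold)
  ev <- list()
  rev <- list()
  for (mode in c("R", "Rinf")) {
    preds <- if (mode == "R") predictions_R else predictions_Rinf
    ev[[mode]] <- evaluation_table(preds, obs, day = config$evaluation_day,
                                   B = config$bootstrap_B,
                                   seed = substream_seed(config$seed, 6))
    rev[[mode]] <- count_reversals(obs, preds, day = config$evaluation_day)
  }
  evaluation <- rbind(ev$R, ev$Rinf)
  write_dataset(evaluation, out_path("evaluation_summary.csv"))
  write_dataset(rbind(rev$R, rev$Rinf), out_path("reversals.csv"))
  comparison <- compare_predictions(predictions_R, obs,
                                    day = config$evaluation_day)
  write_dataset(comparison, out_path("comparison.csv"))
  say("[evaluate] proportion correct (full, R): %.3f | (full, Rinf): %.3f",
      ev$R$proportion_correct[1], ev$Rinf$proportion_correct[1])

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("thermocompete")),
    n_species = config$n_species,
    rows = list(growth_curves = nrow(growth_curves),
                competition_counts = nrow(competition_counts),
                growth_fits = nrow(growth_fits),
                monod_fits = nrow(monod_fits),
                predictions = nrow(predictions_R) + nrow(predictions_Rinf)),
    dropped_replicates = attr(obs, "n_dropped"))
  yaml::write_yaml(manifest, out_path("manifest.yaml"))

  invisible(list(panel = panel, growth_curves = growth_curves,
                 competition_counts = competition_counts,
                 growth_fits = growth_fits, monod_fits = monod_fits,
                 traits = traits, predictions_R = predictions_R,
                 predictions_Rinf = predictions_Rinf,
                 evaluation = evaluation, reversals_R = rev$R,
                 reversals_Rinf = rev$Rinf, manifest = manifest))
}
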