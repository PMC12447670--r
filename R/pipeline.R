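#' Simulate a cohort and write it to disk
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (required: simulation must be reproducible).
#' @param config A [simulation_config()].
#' @return Named vector of written paths, invisibly.
#' @export
run_simulate <- function(out_dir, seed, config = simulation_config()) {
  sim <- simulate_cohort(config, seed)
  paths <- write_simulated_cohort(sim, out_dir)
  message("simulated ", nrow(sim$dataset$covariates), " participants, ",
          length(sim$dataset$measures), " measures -> ", out_dir)
  invisible(paths)
}

#' Load, filter and run detection; write the shifts table
#'
#' Applies the eligibility filters, detects sudden gains and losses on every
#' retained series, and writes `shifts.csv` and `exclusions.csv` under
#' `out_dir`.
#'
#' @param scores_csv,covariates_csv,measure_config Input paths, see
#'   [load_cohort()].
#' @param out_dir Output directory.
#' @param eligibility An [eligibility_config()].
#' @param detection A [detection_config()].
#' @return Invisibly, a list with the eligible `dataset`, `shifts` and
#'   `exclusions`.
#' @export
run_detect <- function(scores_csv, covariates_csv, measure_config, out_dir,
                       eligibility = eligibility_config(),
                       detection = detection_config()) {
  dataset <- load_cohort(scores_csv, covariates_csv, measure_config)
  elig <- apply_eligibility(dataset, eligibility)
  shifts <- detect_cohort(elig$dataset, detection)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(shifts, file.path(out_dir, "shifts.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(elig$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE, na = "")
  message(nrow(elig$exclusions), " exclusions; ",
          nrow(shifts), " shifts detected across ",
          length(elig$dataset$measures), " measures")
  invisible(list(dataset = elig$dataset, shifts = shifts,
                 exclusions = elig$exclusions))
}

#' Summarise detected shifts; write the summary tables
#'
#' Writes `summary_gains.csv`, `summary_losses.csv`, the pooled per
#' participant `gain_counts.csv`, and a per-measure around-gain
#' `trajectory_profiles.csv`.
#'
#' @param dataset Eligible [cohort_dataset()].
#' @param shifts Tibble from [detect_cohort()].
#' @param out_dir Output directory.
#' @return Invisibly, the list of summary tables.
#' @export
run_summarize <- function(dataset, shifts, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gains <- flatten_summary(summarize_cohort(dataset, shifts, "gain"))
  losses <- flatten_summary(summarize_cohort(dataset, shifts, "loss"))
  dist <- gain_count_distribution(shifts, dataset)
  prof <- dplyr::bind_rows(lapply(names(dataset$measures), function(m) {
    p <- trajectory_profile(dataset, shifts, m)
    if (nrow(p)) p$measure <- m
    p
  }))
  utils::write.csv(gains, file.path(out_dir, "summary_gains.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(losses, file.path(out_dir, "summary_losses.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(dist$bands, file.path(out_dir, "gain_counts.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(prof, file.path(out_dir, "trajectory_profiles.csv"),
                   row.names = FALSE, na = "")
  invisible(list(gains = gains, losses = losses, distribution = dist,
                 profiles = prof))
}

#' Fit the association models; write the effects table
#'
#' @param dataset Eligible [cohort_dataset()].
#' @param shifts Tibble from [detect_cohort()].
#' @param out_dir Output directory.
#' @return Invisibly, the effects tibble (see [associate_cohort()]).
#' @export
run_associate <- function(dataset, shifts, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  effects <- associate_cohort(dataset, shifts)
  utils::write.csv(effects, file.path(out_dir, "effects.csv"),
                   row.names = FALSE, na = "")
  invisible(effects)
}

#' Run the full pipeline end-to-end
#'
#' simulate (optional) -> eligibility + detection -> summaries ->
#' association models, writing every artifact under `out_dir`.
#'
#' @param scores_csv,covariates_csv,measure_config Input paths; omit all
#'   three and supply `seed` to run on a freshly simulated cohort (written
#'   to `out_dir/simulated/`).
#' @param out_dir Output directory.
#' @param seed Seed for simulation when no inputs are given.
#' @param eligibility An [eligibility_config()].
#' @param detection A [detection_config()].
#' @param sim_config A [simulation_config()] for the simulate step.
#' @return Invisibly, a list with `dataset`, `shifts`, `exclusions`,
#'   `summaries` and `effects`.
#' @export
run_all <- function(out_dir, scores_csv = NULL, covariates_csv = NULL,
                    measure_config = NULL, seed = NULL,
                    eligibility = eligibility_config(),
                    detection = detection_config(),
                    sim_config = simulation_config()) {
  if (is.null(scores_csv)) {
    if (is.null(seed)) stop("supply either input paths or a seed to simulate")
    paths <- run_simulate(file.path(out_dir, "simulated"), seed, sim_config)
    scores_csv <- paths[["scores"]]
    covariates_csv <- paths[["covariates"]]
    measure_config <- paths[["measures"]]
  }
  det <- run_detect(scores_csv, covariates_csv, measure_config, out_dir,
                    eligibility, detection)
  summaries <- run_summarize(det$dataset, det$shifts, out_dir)
  effects <- run_associate(det$dataset, det$shifts, out_dir)
  invisible(list(dataset = det$dataset, shifts = det$shifts,
                 exclusions = det$exclusions, summaries = summaries,
                 effects = effects))
}
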