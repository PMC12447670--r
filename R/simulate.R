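#' Simulated measure definition
#'
#' Couples a [measure_spec()] with the baseline score distribution and
#' recording granularity used when generating trajectories.
#'
#' @param spec A [measure_spec()].
#' @param baseline_mean,baseline_sd Baseline (session-1) score distribution
#'   in scale points.
#' @param granularity Recording step of the scale: 1 for whole-number ordinal
#'   scales, 0.1 for the fractional mean-of-goals scale.
#' @return A list of class `sim_measure`.
#' @export
sim_measure <- function(spec, baseline_mean, baseline_sd, granularity = 1) {
  stopifnot(inherits(spec, "measure_spec"),
            baseline_sd > 0, granularity > 0)
  structure(list(spec = spec, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, granularity = granularity),
            class = "sim_measure")
}

#' Default simulated measure set
#'
#' Three measures spanning the structures the analysis must handle: a
#' fractional higher-better goal-based outcome (1--10, recorded to 0.1), a
#' whole-number lower-better disruptive-behaviour scale (0--20), and a
#' lower-better SDQ-style session-by-session scale (0--20).
#'
#' @return List of [sim_measure()] objects.
#' @export
default_sim_measures <- function() {
  list(
    sim_measure(
      measure_spec("gbo_mean", "higher_better", 1, 10,
                   criterion1_cutoff = 2),
      baseline_mean = 3.5, baseline_sd = 1.2, granularity = 0.1),
    sim_measure(
      measure_spec("disruptive_behaviour", "lower_better", 0, 20,
                   criterion1_cutoff = 3),
      baseline_mean = 13, baseline_sd = 3, granularity = 1),
    sim_measure(
      measure_spec("sdq_sxs", "lower_better", 0, 20,
                   criterion1_cutoff = 3),
      baseline_mean = 11, baseline_sd = 3.5, granularity = 1))
}

#' Simulation configuration
#'
#' Defines a synthetic therapy cohort with the statistical structure the
#' sudden-gains analysis assumes: bounded session-by-session trajectories in
#' both scale orientations, instantaneous planted step-change improvements
#' with a noise-suppressed plateau around the step, covariate-driven gain
#' probability on the log-odds scale, missing-completely-at-random session
#' gaps, and a follow-up outcome linked to gain status. Defaults emulate a
#' paediatric modular-CBT trial cohort: ~150 participants, 10--28 mostly
#' weekly sessions, covariate prevalences around one half, and planted gains
#' in roughly 40% of series.
#'
#' @param n_participants Cohort size; default 150.
#' @param sessions Length-2 integer range; each participant's total session
#'   count is drawn uniformly from it. Minimum must be >= 6 so the default
#'   eligibility filter is passable.
#' @param measures List of [sim_measure()] definitions.
#' @param trend_slope Gradual improvement per session, in points (applied in
#'   each measure's improvement direction); default 0.05.
#' @param noise_sd Session-to-session noise SD in points; default 1.
#' @param missing_rate MCAR probability that an individual session response
#'   is missing; default 0.15.
#' @param gain_model List with `intercept` and named `coefficients` on the
#'   log-odds of planting a gain; recognised covariate names are `sex`,
#'   `age_group`, `ethnicity_white`, `asd`, `intellectual_disability`,
#'   `caregiver_employed`, `primary_disorder_disruptive`, `total_sessions`.
#' @param gain_magnitude Length-2 `(mean, sd)` of the planted step size in
#'   points; the realised magnitude is truncated below at the measure's
#'   criterion-one cutoff.
#' @param gain_session_range Length-2 range of the planted pregain session N
#'   (clamped inside each series so the stability windows exist).
#' @param plateau_length Sessions on each side of the step whose noise is
#'   suppressed (the stable plateau that makes a planted step a *sudden*
#'   gain); default 3.
#' @param outcome_model List controlling the follow-up outcome:
#'   `followup = list(intercept, gain, baseline_sdq, noise_sd,
#'   missing_rate)`; optionally `final = list(intercept, gain, noise_sd)` to
#'   generate the end-of-treatment score from a linear model instead of the
#'   last observed session score.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 150L,
                              sessions = c(10L, 28L),
                              measures = default_sim_measures(),
                              trend_slope = 0.05,
                              noise_sd = 1,
                              missing_rate = 0.15,
                              gain_model = list(
                                intercept = -2.5,
                                coefficients = c(intellectual_disability = 0.5,
                                                 ethnicity_white = 0.7,
                                                 caregiver_employed = 0.4,
                                                 total_sessions = 0.06)),
                              gain_magnitude = c(4, 1),
                              gain_session_range = c(3L, 10L),
                              plateau_length = 3L,
                              outcome_model = list(
                                followup = list(intercept = 9, gain = -1.5,
                                                baseline_sdq = 0.45,
                                                noise_sd = 5,
                                                missing_rate = 0.1))) {
  stopifnot(n_participants >= 1, length(sessions) == 2L,
            length(gain_magnitude) == 2L, length(gain_session_range) == 2L)
  if (sessions[1] < 6L) {
    stop("sessions minimum must be >= 6 (the default eligibility threshold)")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be a probability")
  }
  for (m in measures) {
    span <- m$spec$scale_max - m$spec$scale_min
    if (gain_magnitude[1] > span) {
      stop("infeasible config: mean gain magnitude ", gain_magnitude[1],
           " exceeds the span of measure '", m$spec$name, "' (", span, ")")
    }
    if (gain_magnitude[1] < m$spec$criterion1_cutoff) {
      stop("infeasible config: mean gain magnitude below the cutoff of ",
           "measure '", m$spec$name, "'")
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 sessions = as.integer(sessions),
                 measures = measures, trend_slope = trend_slope,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 gain_model = gain_model, gain_magnitude = gain_magnitude,
                 gain_session_range = as.integer(gain_session_range),
                 plateau_length = as.integer(plateau_length),
                 outcome_model = outcome_model),
            class = "simulation_config")
}

round_to <- function(x, g) round(x / g) * g
clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# covariate draws; prevalences mirror a paediatric LTC therapy cohort
simulate_covariates <- function(n, sessions) {
  tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = rbinom(n, 1, 0.49),
    age_group = rbinom(n, 1, 0.463),           # 1 = >= 11 years
    ethnicity_white = rbinom(n, 1, 0.748),
    asd = rbinom(n, 1, 0.245),
    intellectual_disability = rbinom(n, 1, 0.415),
    caregiver_employed = rbinom(n, 1, 0.619),
    primary_disorder = ifelse(rbinom(n, 1, 0.578) == 1,
                              "disruptive_behaviour",
                              "anxiety_or_depression"),
    total_sessions = sample(seq.int(sessions[1], sessions[2]), n,
                            replace = TRUE),
    baseline_sdq_total = round(clamp(rnorm(n, 18, 6), 0, 40)))
}

#' Generate a synthetic cohort
#'
#' Draws covariates, plants step-change gains under the logistic gain model,
#' generates bounded rounded trajectories
#' `clamp(baseline + trend*t + step*[t >= N+1] + noise)`, applies MCAR
#' missingness, and links the 6-month follow-up outcome to gain status.
#' Identical `(config, seed)` pairs give identical output.
#'
#' The returned truth table flags each planted gain as `detectable` when,
#' after missingness, both step anchor sessions are observed and each
#' stability window retains at least two observed scores -- gains whose
#' anchoring data were lost cannot be identified by any method that refuses
#' to impute.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return List with `dataset` (a [cohort_dataset()]) and `truth` (tibble
#'   `participant_id`, `measure`, `gain_planted`, `planted_session`,
#'   `planted_magnitude`, `detectable`).
#' @export
simulate_cohort <- function(config = simulation_config(), seed) {
  stopifnot(inherits(config, "simulation_config"),
            is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  n <- config$n_participants
  cov <- simulate_covariates(n, config$sessions)

  # log-odds of planting a gain, from the covariate model
  gm <- config$gain_model
  eta <- rep(gm$intercept, n)
  for (nm in names(gm$coefficients)) {
    val <- switch(nm,
      primary_disorder_disruptive =
        as.numeric(cov$primary_disorder == "disruptive_behaviour"),
      cov[[nm]])
    if (is.null(val)) stop("gain model names unknown covariate: ", nm)
    eta <- eta + gm$coefficients[[nm]] * val
  }
  p_gain <- stats::plogis(eta)

  scores <- list()
  truth <- list()
  pre_cols <- list()
  fin_cols <- list()
  for (m in config$measures) {
    sp <- m$spec
    dir_sign <- if (sp$direction == "lower_better") -1 else 1
    baseline <- rnorm(n, m$baseline_mean, m$baseline_sd)
    planted <- rbinom(n, 1, p_gain) == 1
    t_i <- cov$total_sessions
    lo <- pmax(2L, config$gain_session_range[1])
    hi_each <- pmin(config$gain_session_range[2], t_i - 3L)
    planted_session <- ifelse(planted & hi_each >= lo,
                              lo + floor(runif(n) * (hi_each - lo + 1L)),
                              NA_integer_)
    planted <- planted & !is.na(planted_session)
    mag <- pmax(sp$criterion1_cutoff,
                rnorm(n, config$gain_magnitude[1], config$gain_magnitude[2]))
    mag <- round_to(mag, m$granularity)
    mag[!planted] <- NA_real_

    y_all <- vector("list", n)
    detectable <- rep(NA, n)
    pre_adm <- numeric(n)
    fin <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      t_max <- t_i[i]
      t_seq <- seq_len(t_max)
      noise <- rnorm(t_max, 0, config$noise_sd)
      if (planted[i]) {
        np <- planted_session[i]
        plateau <- seq.int(np + 1L - config$plateau_length,
                           np + config$plateau_length)
        noise[t_seq %in% plateau] <- 0
        step <- dir_sign * mag[i] * (t_seq >= np + 1L)
      } else {
        step <- 0
      }
      y <- baseline[i] + dir_sign * config$trend_slope * (t_seq - 1) +
        step + noise
      y <- round_to(clamp(y, sp$scale_min, sp$scale_max), m$granularity)
      miss <- runif(t_max) < config$missing_rate
      y[miss] <- NA_real_
      if (planted[i]) {
        np <- planted_session[i]
        pre_w <- y[seq.int(max(1L, np - 2L), np)]
        post_w <- y[seq.int(np + 1L, min(t_max, np + 3L))]
        detectable[i] <- !is.na(y[np]) && !is.na(y[np + 1L]) &&
          sum(!is.na(pre_w)) >= 2L && sum(!is.na(post_w)) >= 2L
      } else {
        detectable[i] <- FALSE
      }
      y_all[[i]] <- y
      pre_adm[i] <- round_to(
        clamp(baseline[i] + rnorm(1, 0, config$noise_sd),
              sp$scale_min, sp$scale_max), m$granularity)
      obs <- y[!is.na(y)]
      fin[i] <- if (length(obs)) obs[[length(obs)]] else NA_real_
    }
    scores[[sp$name]] <- tibble::tibble(
      participant_id = rep(cov$participant_id, t_i),
      measure = sp$name,
      session = sequence(t_i),
      score = unlist(y_all))
    om_final <- config$outcome_model$final
    if (!is.null(om_final)) {
      fin <- om_final$intercept + om_final$gain * as.numeric(planted) +
        rnorm(n, 0, om_final$noise_sd)
    }
    pre_cols[[paste0("pretreatment_", sp$name)]] <- pre_adm
    fin_cols[[paste0("final_", sp$name)]] <- fin
    truth[[sp$name]] <- tibble::tibble(
      participant_id = cov$participant_id, measure = sp$name,
      gain_planted = planted,
      planted_session = as.integer(planted_session),
      planted_magnitude = mag,
      detectable = detectable)
  }

  truth <- dplyr::bind_rows(truth)
  any_gain <- dplyr::summarise(
    dplyr::group_by(truth, .data$participant_id),
    any_gain = any(.data$gain_planted), .groups = "drop")
  any_gain <- any_gain$any_gain[match(cov$participant_id,
                                      any_gain$participant_id)]
  fu <- config$outcome_model$followup
  if (!is.null(fu)) {
    sdq6 <- fu$intercept + fu$gain * as.numeric(any_gain) +
      fu$baseline_sdq * cov$baseline_sdq_total + rnorm(n, 0, fu$noise_sd)
    sdq6 <- round(clamp(sdq6, 0, 40))
    sdq6[runif(n) < (fu$missing_rate %||% 0)] <- NA_real_
    cov$sdq_total_6m <- sdq6
  }
  cov <- dplyr::bind_cols(cov, tibble::as_tibble(pre_cols),
                          tibble::as_tibble(fin_cols))

  measures <- lapply(config$measures, `[[`, "spec")
  names(measures) <- vapply(measures, `[[`, character(1), "name")
  dataset <- cohort_dataset(measures, cov, dplyr::bind_rows(scores))
  list(dataset = dataset, truth = truth)
}

#' Recovery of planted gains by the detector
#'
#' Matches detected gains against the generator's truth table: a planted
#' gain is recovered when a detected gain on the same series has a pregain
#' session within `tolerance` sessions of the planted one; a detected gain
#' is matched when it corresponds to some planted gain under the same rule.
#'
#' Two recalls are reported: `recall` over all planted gains, and
#' `recall_detectable` over planted gains whose anchoring sessions and
#' stability windows survived missingness (see [simulate_cohort()]) -- the
#' appropriate denominator for judging the detector itself, since no
#' imputation-free method can recover a gain whose anchor scores are gone.
#'
#' @param shifts Tibble from [detect_cohort()] on the generated cohort.
#' @param truth Truth tibble from [simulate_cohort()].
#' @param tolerance Session slack for matching; default 0 (exact).
#' @return List: `recall`, `recall_detectable`, `precision` (NA when nothing
#'   was detected), and the underlying counts.
#' @export
evaluate_recovery <- function(shifts, truth, tolerance = 0L) {
  g <- shifts[shifts$kind == "gain", ]
  planted <- truth[truth$gain_planted, ]
  recovered <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    cand <- g[g$participant_id == planted$participant_id[i] &
                g$measure == planted$measure[i], ]
    recovered[i] <- any(abs(cand$pregain_session -
                              planted$planted_session[i]) <= tolerance)
  }
  matched <- logical(nrow(g))
  for (j in seq_len(nrow(g))) {
    cand <- planted[planted$participant_id == g$participant_id[j] &
                      planted$measure == g$measure[j], ]
    matched[j] <- any(abs(g$pregain_session[j] -
                            cand$planted_session) <= tolerance)
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(recall = rate(sum(recovered), nrow(planted)),
       recall_detectable = rate(sum(recovered & planted$detectable),
                                sum(planted$detectable)),
       precision = rate(sum(matched), nrow(g)),
       n_planted = nrow(planted),
       n_detectable = sum(planted$detectable),
       n_recovered = sum(recovered),
       n_detected = nrow(g))
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the files [load_cohort()] reads (scores CSV, covariates
#' CSV, measure config JSON) plus the planted-truth CSV.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_simulated_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(scores = file.path(dir, "scores.csv"),
             covariates = file.path(dir, "covariates.csv"),
             measures = file.path(dir, "measures.json"),
             truth = file.path(dir, "truth.csv"))
  write_cohort(sim$dataset, paths[["scores"]], paths[["covariates"]],
               paths[["measures"]])
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE, na = "")
  paths
}
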