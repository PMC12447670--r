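#' Assemble a cohort dataset
#'
#' The central container for one analysis: the measure definitions, one row of
#' covariates per participant, and the long score table. Scores are stored in
#' long format (`participant_id`, `measure`, `session`, `score`) with 1-based
#' consecutive session indices; sessions a participant skipped are kept as
#' explicit `NA` rows rather than renumbered, because the detection windows
#' depend on the true spacing of sessions.
#'
#' @param measures Named list of [measure_spec()] objects.
#' @param covariates Data frame, one row per participant. Must contain
#'   `participant_id`; the association models additionally expect `sex`,
#'   `age_group`, `ethnicity_white`, `asd`, `intellectual_disability`,
#'   `caregiver_employed`, `primary_disorder`, `total_sessions`, and
#'   per-measure `pretreatment_<measure>` / `final_<measure>` columns plus
#'   `baseline_sdq_total` / `sdq_total_6m` for the follow-up model.
#' @param scores Data frame with columns `participant_id`, `measure`,
#'   `session`, `score` (`NA` = missing response).
#'
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(measures, covariates, scores) {
  stopifnot(is.list(measures), length(measures) >= 1L)
  if (is.null(names(measures)) || any(!nzchar(names(measures)))) {
    names(measures) <- vapply(measures, `[[`, character(1), "name")
  }
  covariates <- tibble::as_tibble(covariates)
  scores <- tibble::as_tibble(scores)
  req <- c("participant_id", "measure", "session", "score")
  if (!all(req %in% names(scores))) {
    stop("scores table must have columns ", paste(req, collapse = ", "))
  }
  if (!"participant_id" %in% names(covariates)) {
    stop("covariates table must have a participant_id column")
  }
  covariates$participant_id <- as.character(covariates$participant_id)
  scores$participant_id <- as.character(scores$participant_id)
  scores$session <- as.integer(scores$session)
  scores$score <- as.numeric(scores$score)

  if (anyDuplicated(covariates$participant_id)) {
    stop("duplicate participant ids in covariates: ",
         paste(unique(covariates$participant_id[
           duplicated(covariates$participant_id)]), collapse = ", "))
  }
  unknown <- setdiff(unique(scores$measure), names(measures))
  if (length(unknown)) {
    stop("scores reference measures absent from the configuration: ",
         paste(unknown, collapse = ", "))
  }
  orphan <- setdiff(unique(scores$participant_id), covariates$participant_id)
  if (length(orphan)) {
    stop("scores reference participants absent from covariates: ",
         paste(orphan, collapse = ", "))
  }
  key <- paste(scores$participant_id, scores$measure, scores$session)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, measure, session) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(scores$session < 1L, na.rm = TRUE)) {
    stop("session indices must be 1-based positive integers")
  }
  # bounds check, naming the offending row
  for (m in unique(scores$measure)) {
    sp <- measures[[m]]
    rows <- which(scores$measure == m & !is.na(scores$score) &
                    (scores$score < sp$scale_min | scores$score > sp$scale_max))
    if (length(rows)) {
      r <- rows[1]
      stop(sprintf(
        "score %g outside [%g, %g] for measure '%s' (participant %s, session %d)",
        scores$score[r], sp$scale_min, sp$scale_max, m,
        scores$participant_id[r], scores$session[r]))
    }
  }

  # densify: every series spans sessions 1..T (T = largest listed index),
  # gaps as NA rows, in consecutive session order
  scores <- scores[order(scores$participant_id, scores$measure,
                         scores$session), ]
  skey <- paste(scores$participant_id, scores$measure, sep = "\r")
  first <- !duplicated(skey)
  t_max <- as.integer(tapply(scores$session, factor(skey, levels = skey[first]),
                             max))
  full <- tibble::tibble(
    participant_id = rep(scores$participant_id[first], t_max),
    measure = rep(scores$measure[first], t_max),
    session = sequence(t_max))
  scores <- dplyr::left_join(
    full, scores[c("participant_id", "measure", "session", "score")],
    by = c("participant_id", "measure", "session"))

  structure(list(measures = measures, covariates = covariates,
                 scores = scores),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset> %d participants, %d measures, %d score rows (%d observed)\n",
    nrow(x$covariates), length(x$measures), nrow(x$scores),
    sum(!is.na(x$scores$score))))
  invisible(x)
}

#' Load a cohort from CSV + measure configuration
#'
#' @param scores_csv CSV with columns `participant_id,measure,session,score`;
#'   an empty `score` cell is a missing response.
#' @param covariates_csv CSV with one row per participant; booleans coded 0/1.
#' @param measure_config JSON/YAML measure configuration, see
#'   [read_measure_config()].
#' @return A validated [cohort_dataset()].
#' @export
load_cohort <- function(scores_csv, covariates_csv, measure_config) {
  for (p in c(scores_csv, covariates_csv)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  measures <- if (is.list(measure_config) && !is.character(measure_config)) {
    measure_config
  } else {
    read_measure_config(measure_config)
  }
  scores <- utils::read.csv(scores_csv, stringsAsFactors = FALSE,
                            colClasses = c(participant_id = "character"))
  covars <- utils::read.csv(covariates_csv, stringsAsFactors = FALSE,
                            colClasses = c(participant_id = "character"))
  cohort_dataset(measures, covars, scores)
}

#' Write a cohort back to CSV
#'
#' Serialises the score and covariate tables in the same layout
#' [load_cohort()] reads, so that ingestion and serialisation round-trip.
#'
#' @param dataset A [cohort_dataset()].
#' @param scores_csv,covariates_csv Output paths.
#' @param measure_config Optional path to also write the measure configuration.
#' @return Invisibly, the dataset.
#' @export
write_cohort <- function(dataset, scores_csv, covariates_csv,
                         measure_config = NULL) {
  utils::write.csv(dataset$scores, scores_csv, row.names = FALSE, na = "")
  utils::write.csv(dataset$covariates, covariates_csv, row.names = FALSE,
                   na = "")
  if (!is.null(measure_config)) {
    write_measure_config(dataset$measures, measure_config)
  }
  invisible(dataset)
}

#' Extract one participant's score trajectory
#'
#' @param dataset A [cohort_dataset()].
#' @param participant_id,measure Identify the series.
#' @return Numeric vector indexed 1..T (`NA` = missing session), or a
#'   zero-length vector when the participant never responded on the measure.
#' @export
get_series <- function(dataset, participant_id, measure) {
  d <- dataset$scores[dataset$scores$participant_id == participant_id &
                        dataset$scores$measure == measure, ]
  if (!nrow(d)) return(numeric(0))
  out <- d$score[order(d$session)]
  names(out) <- sort(d$session)
  out
}

#' Eligibility configuration
#'
#' The trial-style analysis-population filters: participants must have
#' received at least `min_sessions` therapy sessions; a series contributes to
#' a measure only with at least `min_responses_per_measure` observed scores
#' (">1 response"); a measure is analysed only when retained by at least
#' `min_participants_per_measure` participants (">20 participants").
#'
#' @param min_sessions Minimum sessions received; default 6.
#' @param min_responses_per_measure Minimum observed scores per series;
#'   default 2.
#' @param min_participants_per_measure Minimum participants per measure;
#'   default 21.
#' @return An object of class `eligibility_config`.
#' @export
eligibility_config <- function(min_sessions = 6L,
                               min_responses_per_measure = 2L,
                               min_participants_per_measure = 21L) {
  vals <- c(min_sessions, min_responses_per_measure,
            min_participants_per_measure)
  if (any(!is.finite(vals)) || any(vals < 1) || any(vals != round(vals))) {
    stop("eligibility thresholds must be positive integers")
  }
  structure(list(min_sessions = as.integer(min_sessions),
                 min_responses_per_measure = as.integer(min_responses_per_measure),
                 min_participants_per_measure = as.integer(min_participants_per_measure)),
            class = "eligibility_config")
}

#' Apply the eligibility filters
#'
#' Excludes, in order: participants flagged in an optional `withdrew`
#' covariate column (withdrawal of consent); participants with
#' `total_sessions < min_sessions`; series with fewer observed responses than
#' `min_responses_per_measure`; and finally whole measures retained by fewer
#' than `min_participants_per_measure` participants. Every exclusion is
#' logged with its reason. The operation is idempotent.
#'
#' @param dataset A [cohort_dataset()].
#' @param config An [eligibility_config()].
#' @return A list with elements `dataset` (the filtered [cohort_dataset()])
#'   and `exclusions` (tibble `participant_id`, `measure`, `reason`;
#'   `measure` is `NA` for participant-level exclusions).
#' @export
apply_eligibility <- function(dataset, config = eligibility_config()) {
  stopifnot(inherits(dataset, "cohort_dataset"),
            inherits(config, "eligibility_config"))
  cov <- dataset$covariates
  log <- tibble::tibble(participant_id = character(0),
                        measure = character(0), reason = character(0))

  if ("withdrew" %in% names(cov)) {
    out <- cov$participant_id[!is.na(cov$withdrew) & cov$withdrew == 1]
    if (length(out)) {
      log <- dplyr::bind_rows(log, tibble::tibble(
        participant_id = out, measure = NA_character_,
        reason = "withdrew consent"))
      cov <- cov[!cov$participant_id %in% out, ]
    }
  }
  if (!"total_sessions" %in% names(cov)) {
    stop("covariates must contain total_sessions to apply eligibility")
  }
  few <- cov$participant_id[!is.na(cov$total_sessions) &
                              cov$total_sessions < config$min_sessions]
  if (length(few)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      participant_id = few, measure = NA_character_,
      reason = "fewer than minimum sessions"))
    cov <- cov[!cov$participant_id %in% few, ]
  }

  sc <- dataset$scores[dataset$scores$participant_id %in% cov$participant_id, ]

  # series-level: >1 observed response required on the measure
  obs <- dplyr::summarise(
    dplyr::group_by(sc, .data$participant_id, .data$measure),
    n_obs = sum(!is.na(.data$score)), .groups = "drop")
  thin <- obs[obs$n_obs < config$min_responses_per_measure, ]
  if (nrow(thin)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      participant_id = thin$participant_id, measure = thin$measure,
      reason = "fewer than minimum responses on measure"))
    drop_key <- paste(thin$participant_id, thin$measure)
    sc <- sc[!paste(sc$participant_id, sc$measure) %in% drop_key, ]
  }

  # measure-level: retained by > min-1 participants
  per_measure <- table(unique(sc[c("participant_id", "measure")])$measure)
  small <- names(per_measure)[per_measure < config$min_participants_per_measure]
  small <- union(small,
                 setdiff(names(dataset$measures), names(per_measure)))
  if (length(small)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      participant_id = NA_character_, measure = small,
      reason = "measure below minimum participants"))
    sc <- sc[!sc$measure %in% small, ]
  }
  measures <- dataset$measures[setdiff(names(dataset$measures), small)]
  if (!length(measures)) {
    measures <- dataset$measures[0]
  }

  out <- structure(list(measures = measures, covariates = cov, scores = sc),
                   class = "cohort_dataset")
  list(dataset = out, exclusions = log)
}
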