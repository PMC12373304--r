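# Synthetic OMOP-style EHR generator with planted phenotype clusters.
#
# All dates are integer day offsets from a fixed epoch (day 0 = Jan 1 of the
# epoch year); intervals are closed on both ends unless stated otherwise.
# Latent phenotype labels are returned separately and never written into the
# feature tables, so the analysis pipeline cannot leak them.

EPOCH_YEAR <- 2000L

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generator calls are deterministic without disturbing
#' the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic EHR generator
#'
#' Bundles and validates every tunable of the generator. The defaults define
#' the package's standard synthetic benchmark: 15 numeric measurement
#' features, 10 binary CCS diagnosis categories, 4 planted phenotypes, a flat
#' per-window observation probability of 0.5, unit observation noise and a
#' 2-fold presence boost in the sampling window immediately preceding
#' treatment start (mimicking the pre-treatment documentation spike seen in
#' real EHR cohorts).
#'
#' @param n_patients number of patients to simulate.
#' @param n_meas_features number of numeric measurement features.
#' @param n_ccs_features number of binary CCS diagnosis categories.
#' @param k_phenotypes number of planted phenotype clusters.
#' @param base_presence per-feature probability that a measurement feature is
#'   observed in any one 30-day sampling window; scalar or vector of length
#'   `n_meas_features`, values in `[0, 1]`.
#' @param pre_index_spike multiplicative boost applied to `base_presence` in
#'   the window nearest treatment start (days -35 to -5); the boosted
#'   probability is capped at 1.
#' @param noise_sd standard deviation of the observation noise, z-units.
#' @param seed integer seed; identical configurations produce byte-identical
#'   tables.
#' @param p_second_session probability a patient has a second, later
#'   treatment session.
#' @param p_split_record probability a session is realized as two abutting
#'   same-ingredient exposure records with a gap of at most 40 days.
#' @param p_subset_record probability a two-ingredient session carries an
#'   extra short record with a proper subset of its ingredients.
#' @param p_addon_record probability a session carries an extra short record
#'   adding a new ingredient within 40 days of session start.
#' @param p_isolated_oaom probability a patient additionally has one short
#'   (<30 day) isolated off-label record far from any session.
#' @param session_length_range inclusive range of planted session lengths in
#'   days; the default keeps all planted sessions in the medium/long
#'   (>= 112 day) exposure class.
#' @param gender_p_female probability of female gender.
#' @param trend_slope_sd standard deviation of per-feature latent drift per
#'   30-day step (z-units/step) when drawing default phenotypes; 0 disables
#'   drift.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_patients,
                         n_meas_features = 15L,
                         n_ccs_features = 10L,
                         k_phenotypes = 4L,
                         base_presence = 0.5,
                         pre_index_spike = 2,
                         noise_sd = 1,
                         seed = 1L,
                         p_second_session = 0.25,
                         p_split_record = 0.5,
                         p_subset_record = 0.15,
                         p_addon_record = 0.15,
                         p_isolated_oaom = 0.15,
                         session_length_range = c(120L, 400L),
                         gender_p_female = 0.64,
                         trend_slope_sd = 0) {
  stopifnot(length(n_patients) == 1L, n_patients >= 0L)
  if (n_meas_features < 1L || n_ccs_features < 1L || k_phenotypes < 1L)
    stop("invalid synth config: feature and phenotype counts must be positive")
  if (length(base_presence) == 1L)
    base_presence <- rep(base_presence, n_meas_features)
  if (length(base_presence) != n_meas_features)
    stop("invalid synth config: base_presence must be scalar or length n_meas_features")
  probs <- c(base_presence, gender_p_female, p_second_session, p_split_record,
             p_subset_record, p_addon_record, p_isolated_oaom)
  if (any(probs < 0 | probs > 1))
    stop("invalid synth config: probabilities must lie in [0, 1]")
  if (noise_sd < 0 || pre_index_spike < 0)
    stop("invalid synth config: noise_sd and pre_index_spike must be non-negative")
  if (length(session_length_range) != 2L ||
      session_length_range[1] > session_length_range[2] ||
      session_length_range[1] < 1L)
    stop("invalid synth config: bad session_length_range")
  cfg <- list(n_patients = as.integer(n_patients),
              n_meas_features = as.integer(n_meas_features),
              n_ccs_features = as.integer(n_ccs_features),
              k_phenotypes = as.integer(k_phenotypes),
              base_presence = as.numeric(base_presence),
              pre_index_spike = as.numeric(pre_index_spike),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed),
              p_second_session = p_second_session,
              p_split_record = p_split_record,
              p_subset_record = p_subset_record,
              p_addon_record = p_addon_record,
              p_isolated_oaom = p_isolated_oaom,
              session_length_range = as.integer(session_length_range),
              gender_p_female = gender_p_female,
              trend_slope_sd = as.numeric(trend_slope_sd))
  class(cfg) <- "synth_config"
  cfg
}

#' Default planted phenotype specifications
#'
#' Draws `k_phenotypes` latent phenotypes. Each phenotype has a vector of
#' per-measurement-feature latent means at +/- `separation` z-units (random
#' sign pattern, distinct across phenotypes), CCS category prevalences of
#' either `prev_high` or `prev_low` (random pattern), and optional linear
#' drift per 30-day step.
#'
#' @param config a [synth_config()].
#' @param separation absolute latent mean per measurement feature, z-units.
#' @param prev_high,prev_low CCS prevalence for the high/low pattern entries.
#' @return list of phenotype specs, each with `label`, `meas_means`,
#'   `ccs_prevalence`, `trend_slopes`.
#' @export
default_phenotypes <- function(config, separation = 2,
                               prev_high = 0.8, prev_low = 0.1) {
  stopifnot(inherits(config, "synth_config"))
  K <- config$k_phenotypes
  with_seed(config$seed * 7L + 11L, {
    seen <- character(0)
    out <- vector("list", K)
    for (k in seq_len(K)) {
      repeat {
        s <- sample(c(-1, 1), config$n_meas_features, replace = TRUE)
        key <- paste(s, collapse = ",")
        if (!key %in% seen) { seen <- c(seen, key); break }
      }
      cbits <- sample(c(TRUE, FALSE), config$n_ccs_features, replace = TRUE)
      out[[k]] <- list(
        label = k,
        meas_means = s * separation,
        ccs_prevalence = ifelse(cbits, prev_high, prev_low),
        trend_slopes = if (config$trend_slope_sd > 0)
          stats::rnorm(config$n_meas_features, 0, config$trend_slope_sd)
        else rep(0, config$n_meas_features))
    }
    out
  })
}

validate_phenotypes <- function(phenotypes, config) {
  if (length(phenotypes) != config$k_phenotypes)
    stop("invalid config: number of phenotype specs (", length(phenotypes),
         ") does not match k_phenotypes (", config$k_phenotypes, ")")
  for (ph in phenotypes) {
    if (length(ph$meas_means) != config$n_meas_features ||
        length(ph$ccs_prevalence) != config$n_ccs_features ||
        length(ph$trend_slopes) != config$n_meas_features)
      stop("invalid phenotype spec: feature count mismatch")
    if (any(ph$ccs_prevalence < 0 | ph$ccs_prevalence > 1))
      stop("invalid phenotype spec: prevalence outside [0, 1]")
    if (any(!is.finite(ph$meas_means)))
      stop("invalid phenotype spec: non-finite measurement mean")
  }
  invisible(TRUE)
}

#' Generate the synthetic patient population
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `person_id`, `gender` ("F"/"M"),
#'   `birth_year`, `race`. Categorical draws follow the configured gender
#'   probability and a fixed race distribution typical of a large US
#'   outpatient obesity cohort.
#' @export
gen_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  if (n < 0L) stop("invalid config: n_patients must be non-negative")
  races <- c("White", "Black or African American", "Asian", "Others", "Unknown")
  race_p <- c(0.39, 0.27, 0.033, 0.004, 0.303)
  with_seed(config$seed * 7L + 1L, {
    data.frame(
      person_id = seq_len(n),
      gender = if (n) sample(c("F", "M"), n, replace = TRUE,
                             prob = c(config$gender_p_female,
                                      1 - config$gender_p_female)) else character(0),
      birth_year = if (n) sample(1940:1995, n, replace = TRUE) else integer(0),
      race = if (n) sample(races, n, replace = TRUE, prob = race_p) else character(0),
      stringsAsFactors = FALSE)
  })
}

F_AOM_INGREDIENTS <- c("phentermine", "semaglutide", "liraglutide",
                       "naltrexone", "orlistat", "tirzepatide", "topiramate_f")
O_AOM_INGREDIENTS <- c("metformin", "topiramate", "zonisamide",
                       "canagliflozin", "lisdexamfetamine")

ing_key <- function(x) paste(sort(unique(x)), collapse = "+")
ing_split <- function(key) strsplit(key, "+", fixed = TRUE)[[1]]

#' Generate raw drug-exposure records with planted treatment sessions
#'
#' Each patient receives one or two planted treatment sessions; each session
#' is realized as one to three raw exposure records that exercise the
#' session-merge rules (same-ingredient continuation with a gap of at most
#' 40 days, short proper-subset records, short add-on records within 40 days
#' of session start). Some patients additionally carry an isolated short
#' off-label record that the off-label filter should remove.
#'
#' @param persons output of [gen_population()]; must be non-empty.
#' @param config a [synth_config()].
#' @return data.frame of exposure records with columns `record_id`,
#'   `person_id`, `ingredients` (sorted "+"-joined set key), `start_day`,
#'   `end_day`, `is_off_label`. The planted session truth is attached as
#'   attribute `"planted_sessions"` (a data.frame `person_id`, `session_idx`,
#'   `start_day`, `end_day`) for evaluation only.
#' @export
gen_exposures <- function(persons, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(persons) == 0L) stop("gen_exposures: persons must be non-empty")
  with_seed(config$seed * 7L + 2L, {
    recs <- list(); planted <- list(); rid <- 0L
    lr <- config$session_length_range
    for (i in seq_len(nrow(persons))) {
      pid <- persons$person_id[i]
      n_sess <- 1L + stats::rbinom(1L, 1L, config$p_second_session)
      a <- sample(500:1500, 1L)
      for (s in seq_len(n_sess)) {
        L <- sample(lr[1]:lr[2], 1L)
        end <- a + L - 1L
        base_two <- stats::runif(1) < config$p_subset_record
        base_ing <- if (base_two) sample(F_AOM_INGREDIENTS, 2L)
                    else sample(F_AOM_INGREDIENTS, 1L)
        split <- stats::runif(1) < config$p_split_record && L > 90L
        if (split) {
          cut <- a + sample(30:(L - 60L), 1L)
          start2 <- cut + sample(0:40, 1L)  # gap = start2 - cut, within rule 1
          recs[[length(recs) + 1L]] <- data.frame(
            person_id = pid, ingredients = ing_key(base_ing),
            start_day = c(a, start2), end_day = c(cut, end),
            is_off_label = FALSE, stringsAsFactors = FALSE)
        } else {
          recs[[length(recs) + 1L]] <- data.frame(
            person_id = pid, ingredients = ing_key(base_ing),
            start_day = a, end_day = end,
            is_off_label = FALSE, stringsAsFactors = FALSE)
        }
        if (base_two) {
          # short proper-subset record inside the session span (merge rule 2)
          ssub <- a + sample(10:60, 1L)
          recs[[length(recs) + 1L]] <- data.frame(
            person_id = pid, ingredients = ing_key(base_ing[1]),
            start_day = ssub, end_day = min(ssub + sample(5:39, 1L), end),
            is_off_label = FALSE, stringsAsFactors = FALSE)
        }
        if (!split && stats::runif(1) < config$p_addon_record) {
          # short record adding a new ingredient within 40 d of session start
          # (merge rule 3); only for unsplit sessions — once the ingredient
          # union grows, a later long same-base record could no longer rejoin
          new_ing <- sample(setdiff(F_AOM_INGREDIENTS, base_ing), 1L)
          sadd <- a + sample(0:40, 1L)
          recs[[length(recs) + 1L]] <- data.frame(
            person_id = pid, ingredients = new_ing,
            start_day = sadd, end_day = min(sadd + sample(5:39, 1L), end),
            is_off_label = FALSE, stringsAsFactors = FALSE)
        }
        planted[[length(planted) + 1L]] <- data.frame(
          person_id = pid, session_idx = s, start_day = a, end_day = end)
        a <- end + sample(100:300, 1L)  # gap > 40 d: next session never merges
      }
      if (stats::runif(1) < config$p_isolated_oaom) {
        s0 <- planted[[length(planted) - n_sess + 1L]]$start_day
        siso <- s0 - sample(150:250, 1L)
        recs[[length(recs) + 1L]] <- data.frame(
          person_id = pid, ingredients = sample(O_AOM_INGREDIENTS, 1L),
          start_day = siso, end_day = siso + sample(4:24, 1L),
          is_off_label = TRUE, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, recs)
    out <- out[order(out$person_id, out$start_day, out$end_day), ]
    out$record_id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out <- out[, c("record_id", "person_id", "ingredients",
                   "start_day", "end_day", "is_off_label")]
    attr(out, "planted_sessions") <- do.call(rbind, planted)
    out
  })
}

#' Generate sparse longitudinal measurements and diagnoses
#'
#' For every planted session, draws per-window measurement observations on
#' the 13-point/30-day sampling grid preceding the session start, with values
#' `phenotype mean + drift * step + Gaussian noise` and per-window presence
#' probability `base_presence` (boosted by `pre_index_spike` in the window
#' nearest treatment start). CCS diagnoses are emitted, for categories active
#' under the phenotype's prevalence, at random days within the pre-treatment
#' year.
#'
#' @param persons output of [gen_population()].
#' @param phenotype_assignment integer vector, one phenotype label per
#'   patient (parallel to `persons`).
#' @param config a [synth_config()].
#' @param sessions planted sessions table (attribute of [gen_exposures()]
#'   output, or any data.frame with `person_id`, `session_idx`, `start_day`).
#' @param phenotypes list of phenotype specs, e.g. [default_phenotypes()].
#' @return list with `measurements` (person_id, feature_id, value, day),
#'   `diagnoses` (person_id, ccs_id, day) and `latent_labels` (person_id,
#'   session_idx, phenotype) — the labels are for evaluation only.
#' @export
gen_clinical_events <- function(persons, phenotype_assignment, config,
                                sessions, phenotypes = default_phenotypes(config)) {
  stopifnot(inherits(config, "synth_config"))
  validate_phenotypes(phenotypes, config)
  if (length(phenotype_assignment) != nrow(persons))
    stop("invalid config: phenotype_assignment length must equal number of persons")
  if (!all(phenotype_assignment %in% seq_along(phenotypes)))
    stop("invalid config: phenotype_assignment refers to unknown phenotype")
  with_seed(config$seed * 7L + 3L, {
    meas <- list(); diag <- list(); labels <- list()
    Dm <- config$n_meas_features; Dc <- config$n_ccs_features
    for (j in seq_len(nrow(sessions))) {
      pid <- sessions$person_id[j]
      a <- sessions$start_day[j]
      ph <- phenotypes[[phenotype_assignment[match(pid, persons$person_id)]]]
      pts <- a - 5L - 30L * (0:12)          # newest first
      for (k in 0:12) {
        p <- pmin(1, config$base_presence *
                       if (k == 0L) config$pre_index_spike else 1)
        obs <- which(stats::runif(Dm) < p)
        if (length(obs)) {
          step <- 12L - k                   # 0 at oldest point, 12 at newest
          meas[[length(meas) + 1L]] <- data.frame(
            person_id = pid,
            feature_id = paste0("meas_", obs),
            value = ph$meas_means[obs] + ph$trend_slopes[obs] * step +
              stats::rnorm(length(obs), 0, config$noise_sd),
            day = pts[k + 1L] - sample(0:29, length(obs), replace = TRUE))
        }
      }
      active <- which(stats::runif(Dc) < ph$ccs_prevalence)
      for (cc in active) {
        nd <- sample(1:3, 1L)
        diag[[length(diag) + 1L]] <- data.frame(
          person_id = pid, ccs_id = paste0("ccs_", cc),
          day = sample((a - 364L):(a - 6L), nd, replace = TRUE))
      }
      labels[[length(labels) + 1L]] <- data.frame(
        person_id = pid, session_idx = sessions$session_idx[j],
        phenotype = ph$label)
    }
    bind0 <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
    list(
      measurements = bind0(meas, data.frame(person_id = integer(0),
        feature_id = character(0), value = numeric(0), day = integer(0))),
      diagnoses = bind0(diag, data.frame(person_id = integer(0),
        ccs_id = character(0), day = integer(0))),
      latent_labels = bind0(labels, data.frame(person_id = integer(0),
        session_idx = integer(0), phenotype = integer(0))))
  })
}

#' Age in years at a given study day
#' @param day integer day offset from the epoch.
#' @param birth_year calendar birth year.
#' @return age in (fractional) years.
#' @export
age_at_day <- function(day, birth_year) EPOCH_YEAR + day / 365.25 - birth_year

#' Generate candidate normal-BMI control periods
#'
#' Emits one candidate control period per patient in the pool (patients with
#' no obesity/overweight diagnosis and no BMI above 25), anchored at a normal
#' BMI measurement date drawn near the case periods' anchor dates, carrying
#' the gender and age-at-anchor fields the matcher needs.
#'
#' @param case_periods data.frame with at least `index_day` (anchor days the
#'   controls should be drawn near).
#' @param persons_pool data.frame of control-pool patients (`person_id`,
#'   `gender`, `birth_year`).
#' @param config a [synth_config()].
#' @param date_jitter max absolute day offset of a control anchor from a
#'   randomly chosen case anchor.
#' @return data.frame `control_id`, `person_id`, `gender`, `anchor_day`,
#'   `age_at_anchor`; empty (with a warning) when the pool is empty.
#' @export
gen_controls <- function(case_periods, persons_pool, config, date_jitter = 365L) {
  stopifnot(inherits(config, "synth_config"))
  empty <- data.frame(control_id = integer(0), person_id = integer(0),
                      gender = character(0), anchor_day = integer(0),
                      age_at_anchor = numeric(0), stringsAsFactors = FALSE)
  if (is.null(persons_pool) || nrow(persons_pool) == 0L) {
    warning("gen_controls: empty control pool; no candidates emitted")
    return(empty)
  }
  with_seed(config$seed * 7L + 4L, {
    n <- nrow(persons_pool)
    anchors <- sample(case_periods$index_day, n, replace = TRUE) +
      sample((-date_jitter):date_jitter, n, replace = TRUE)
    data.frame(control_id = seq_len(n),
               person_id = persons_pool$person_id,
               gender = persons_pool$gender,
               anchor_day = as.integer(anchors),
               age_at_anchor = age_at_day(anchors, persons_pool$birth_year),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic EHR study
#'
#' Convenience wrapper running population, phenotype assignment, exposures
#' and clinical events under one configuration.
#'
#' @param config a [synth_config()].
#' @param phenotypes optional phenotype spec list; defaults to
#'   [default_phenotypes()].
#' @return list with `persons`, `drug_exposure`, `measurements`, `diagnoses`,
#'   `latent_labels`, `planted_sessions`, `phenotype_assignment`, `config`.
#' @export
simulate_ehr <- function(config, phenotypes = default_phenotypes(config)) {
  persons <- gen_population(config)
  assignment <- with_seed(config$seed * 7L + 5L,
    sample(seq_along(phenotypes), nrow(persons), replace = TRUE))
  exposures <- gen_exposures(persons, config)
  planted <- attr(exposures, "planted_sessions")
  ev <- gen_clinical_events(persons, assignment, config, planted, phenotypes)
  list(persons = persons,
       drug_exposure = exposures,
       measurements = ev$measurements,
       diagnoses = ev$diagnoses,
       latent_labels = ev$latent_labels,
       planted_sessions = planted,
       phenotype_assignment = assignment,
       config = config)
}

#' Write a simulated study to OMOP-style CSV files
#'
#' @param sim output of [simulate_ehr()].
#' @param dir output directory (created if needed). Latent labels are written
#'   to a separate `labels.csv`, never into the feature tables.
#' @return invisibly, the vector of file paths written.
#' @export
write_ehr_csv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(person = "person.csv", drug_exposure = "drug_exposure.csv",
             measurement = "measurement.csv", condition = "condition.csv",
             labels = "labels.csv")
  tabs <- list(sim$persons, sim$drug_exposure, sim$measurements,
               sim$diagnoses, sim$latent_labels)
  paths <- file.path(dir, files)
  for (i in seq_along(tabs))
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE)
  invisible(paths)
}
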