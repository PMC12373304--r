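test_that("population generation is deterministic, validated, and calibrated", {
  expect_error(synth_config(n_patients = 10, k_phenotypes = 0),
               "positive")
  expect_error(synth_config(n_patients = 10, base_presence = 1.5),
               "\\[0, 1\\]")

  cfg0 <- synth_config(n_patients = 0)
  expect_equal(nrow(gen_population(cfg0)), 0L)

  cfg <- synth_config(n_patients = 100, seed = 1)
  expect_identical(gen_population(cfg), gen_population(cfg))

  # observed gender fraction within 3 binomial SDs of the configured rate
  cfgN <- synth_config(n_patients = 10000, gender_p_female = 0.64, seed = 2)
  p <- mean(gen_population(cfgN)$gender == "F")
  expect_lt(abs(p - 0.64), 3 * sqrt(0.64 * 0.36 / 10000))
})

test_that("exposure generation is deterministic and plants recoverable sessions", {
  cfg <- synth_config(n_patients = 25, seed = 7)
  persons <- gen_population(cfg)
  e1 <- gen_exposures(persons, cfg)
  e2 <- gen_exposures(persons, cfg)
  expect_identical(e1, e2)
  expect_true(all(e1$end_day >= e1$start_day))
  expect_error(gen_exposures(persons[0, ], cfg), "non-empty")

  # with no session breaks and no stray records, one session per patient
  cfg1 <- synth_config(n_patients = 20, seed = 3, p_second_session = 0,
                       p_isolated_oaom = 0)
  ex <- gen_exposures(gen_population(cfg1), cfg1)
  sess <- build_sessions(ex)
  expect_equal(nrow(sess), 20L)

  # planted sessions are recovered exactly by the cohort stage, several seeds
  for (sd in 1:3) {
    cfg2 <- synth_config(n_patients = 30, seed = sd)
    ex2 <- gen_exposures(gen_population(cfg2), cfg2)
    got <- select_medium_long(build_sessions(filter_oaom_records(ex2)))
    planted <- attr(ex2, "planted_sessions")
    expect_identical(
      sort(paste(got$person_id, got$start_day, got$end_day)),
      sort(paste(planted$person_id, planted$start_day, planted$end_day)))
  }

  # forced removal: only isolated short off-label records -> filter drops all
  iso <- recs(rec(1, "metformin", 100, 119, is_off_label = TRUE),
              rec(2, "topiramate", 300, 310, is_off_label = TRUE))
  expect_equal(nrow(filter_oaom_records(iso)), 0L)
})

test_that("clinical events carry the planted phenotype structure", {
  cfg <- synth_config(n_patients = 40, seed = 5, noise_sd = 0,
                      p_second_session = 0)
  persons <- gen_population(cfg)
  ph <- default_phenotypes(cfg, separation = 3)
  expect_error(
    gen_clinical_events(persons, rep(1L, 3), cfg,
                        data.frame(person_id = 1, session_idx = 1,
                                   start_day = 1000),
                        ph),
    "length")

  sessions <- data.frame(person_id = persons$person_id, session_idx = 1L,
                         start_day = 1000L)
  asg <- rep(1L, nrow(persons))
  ev <- gen_clinical_events(persons, asg, cfg, sessions, ph)
  # degenerate noise: every observed value equals the phenotype mean
  for (d in 1:3) {
    f <- paste0("meas_", d)
    vals <- ev$measurements$value[ev$measurements$feature_id == f]
    expect_true(all(abs(vals - ph[[1]]$meas_means[d]) < 1e-12))
  }
  # labels are returned but never appear in the feature tables
  expect_false("phenotype" %in% names(ev$measurements))
  expect_false("phenotype" %in% names(ev$diagnoses))

  # two phenotypes 6 z-units apart are separable by a t-test on raw values
  cfg2 <- synth_config(n_patients = 200, seed = 6, k_phenotypes = 2,
                       p_second_session = 0)
  ph2 <- list(list(label = 1, meas_means = rep(3, 15),
                   ccs_prevalence = rep(0.5, 10), trend_slopes = rep(0, 15)),
              list(label = 2, meas_means = rep(-3, 15),
                   ccs_prevalence = rep(0.5, 10), trend_slopes = rep(0, 15)))
  persons2 <- gen_population(cfg2)
  asg2 <- rep(1:2, length.out = 200)
  sess2 <- data.frame(person_id = persons2$person_id, session_idx = 1L,
                      start_day = 1000L)
  ev2 <- gen_clinical_events(persons2, asg2, cfg2, sess2, ph2)
  m <- ev2$measurements[ev2$measurements$feature_id == "meas_1", ]
  g <- asg2[match(m$person_id, persons2$person_id)]
  expect_lt(t.test(m$value[g == 1], m$value[g == 2])$p.value, 1e-6)
})

test_that("full observation yields an all-ones measurement mask", {
  cfg <- synth_config(n_patients = 3, seed = 9, base_presence = 1,
                      p_second_session = 0, p_isolated_oaom = 0)
  sim <- simulate_ehr(cfg)
  periods <- derive_pre_aom_periods(
    select_medium_long(build_sessions(sim$drug_exposure)))
  fl <- list(meas = paste0("meas_", 1:15), ccs = paste0("ccs_", 1:10))
  nz <- fit_normalizer(periods, sim$measurements, fl$meas)
  tt <- extract_temporal_tensor(periods[1, ], sim$measurements,
                                sim$diagnoses, fl, nz)
  expect_true(all(tt$M[, tt$meas_channels] == 1))
})

test_that("per-feature presence rate is calibrated to base_presence", {
  cfg <- synth_config(n_patients = 150, seed = 11, base_presence = 0.4,
                      pre_index_spike = 1, p_second_session = 0,
                      p_isolated_oaom = 0)
  sim <- simulate_ehr(cfg)
  periods <- derive_pre_aom_periods(
    select_medium_long(build_sessions(sim$drug_exposure)))
  fl <- list(meas = paste0("meas_", 1:15), ccs = paste0("ccs_", 1:10))
  nz <- fit_normalizer(periods, sim$measurements, fl$meas)
  ts <- build_tensor_set(periods, sim$measurements, sim$diagnoses, fl, nz)
  n_cells <- prod(dim(ts$M)[1:2])
  for (d in sample(seq_along(fl$meas), 5)) {
    rate <- mean(ts$M[, , d])
    expect_lt(abs(rate - 0.4), 3 * sqrt(0.4 * 0.6 / n_cells))
  }
})

test_that("control candidates support forced match and forced non-match", {
  cfg <- synth_config(n_patients = 10, seed = 13)
  cases <- data.frame(period_id = 1:10, gender = rep(c("F", "M"), 5),
                      age_at_index = 40, index_day = 1000L)
  pool <- data.frame(person_id = 101:110, gender = cases$gender,
                     birth_year = 2000 - cases$age_at_index)
  # exact demographic copies anchored at the case day -> all matched
  cand <- data.frame(control_id = 1:10, person_id = pool$person_id,
                     gender = cases$gender, anchor_day = 1000L,
                     age_at_anchor = cases$age_at_index)
  mp <- match_controls(cases, cand, seed = 1)
  expect_equal(nrow(mp), 10L)
  # whole pool aged +5 years -> nothing matches under the +/- 1 year rule
  cand5 <- cand
  cand5$age_at_anchor <- cand5$age_at_anchor + 5
  expect_equal(nrow(match_controls(cases, cand5, seed = 1)), 0L)
  # determinism and empty-pool warning
  g1 <- gen_controls(cases, pool, cfg)
  g2 <- gen_controls(cases, pool, cfg)
  expect_identical(g1, g2)
  expect_warning(empty <- gen_controls(cases, pool[0, ], cfg), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("simulated tables are identical under one seed and written as CSV", {
  cfg <- synth_config(n_patients = 8, seed = 21)
  s1 <- simulate_ehr(cfg)
  s2 <- simulate_ehr(cfg)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$diagnoses, s2$diagnoses)
  d <- withr::local_tempdir()
  paths <- write_ehr_csv(s1, d)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(d, "labels.csv"))
  expect_equal(nrow(back), nrow(s1$latent_labels))
})

test_that("a GMM on raw per-period feature means recovers planted labels", {
  # oracle check on the generator, independent of the autoencoder
  cfg <- synth_config(n_patients = 120, seed = 17, p_second_session = 0,
                      p_isolated_oaom = 0)
  sim <- simulate_ehr(cfg)
  periods <- derive_pre_aom_periods(
    select_medium_long(build_sessions(sim$drug_exposure)))
  fl <- list(meas = paste0("meas_", 1:15), ccs = paste0("ccs_", 1:10))
  nz <- fit_normalizer(periods, sim$measurements, fl$meas)
  ts <- build_tensor_set(periods, sim$measurements, sim$diagnoses, fl, nz)
  means <- t(vapply(seq_len(dim(ts$X)[1]), function(i) {
    Xi <- ts$X[i, , ts$meas_channels]
    Mi <- ts$M[i, , ts$meas_channels]
    colSums(Xi * Mi) / pmax(colSums(Mi), 1)
  }, numeric(15)))
  planted <- sim$latent_labels$phenotype[
    match(periods$person_id, sim$latent_labels$person_id)]
  gmm <- fit_gmm(means, k_range = 2:6, seed = 1)
  ari <- mclust::adjustedRandIndex(assign_clusters(gmm), planted)
  expect_gte(ari, 0.9)
})
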