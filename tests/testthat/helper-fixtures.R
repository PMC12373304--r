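# Shared fixtures built in code.

# one exposure record as a one-row data.frame
rec <- function(person_id, ingredients, start_day, end_day,
                is_off_label = FALSE) {
  data.frame(person_id = person_id,
             ingredients = paste(sort(ingredients), collapse = "+"),
             start_day = as.integer(start_day), end_day = as.integer(end_day),
             is_off_label = is_off_label, stringsAsFactors = FALSE)
}

recs <- function(...) {
  out <- do.call(rbind, list(...))
  out <- out[order(out$person_id, out$start_day, out$end_day), ]
  out$record_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# independent brute-force transcription of the three session-merge rules,
# written as a plain record-by-record loop against the open session's
# ingredient union, start and latest end
oracle_sessions <- function(records, gap_days = 40) {
  split_ing <- function(s) strsplit(s, "+", fixed = TRUE)[[1]]
  sessions <- list()
  for (i in seq_len(nrow(records))) {
    ings <- split_ing(records$ingredients[i])
    st <- records$start_day[i]; en <- records$end_day[i]
    len <- en - st + 1
    joined <- FALSE
    if (length(sessions)) {
      s <- sessions[[length(sessions)]]
      same_person <- s$person == records$person_id[i]
      r1 <- setequal(ings, s$ings) && (st - s$end) <= gap_days
      r2 <- all(ings %in% s$ings) && !setequal(ings, s$ings) &&
        len <= gap_days && (st - s$end) <= gap_days
      r3 <- length(setdiff(ings, s$ings)) > 0 &&
        (st - s$start) <= gap_days && len <= gap_days
      if (same_person && (r1 || r2 || r3)) {
        s$ings <- union(s$ings, ings)
        s$end <- max(s$end, en)
        s$n <- s$n + 1L
        sessions[[length(sessions)]] <- s
        joined <- TRUE
      }
    }
    if (!joined)
      sessions[[length(sessions) + 1]] <-
        list(person = records$person_id[i], ings = ings, start = st,
             end = en, n = 1L)
  }
  do.call(rbind, lapply(sessions, function(s) data.frame(
    person_id = s$person, start_day = as.integer(s$start),
    end_day = as.integer(s$end), n_records = s$n,
    ingredients = paste(sort(s$ings), collapse = "+"))))
}

# minimal period + event fixture: one patient, session starting at `start`
tiny_period <- function(start = 1000L, person_id = 1L, period_id = 1L) {
  data.frame(period_id = period_id, session_id = period_id,
             person_id = person_id, window_start = start - 365L,
             window_end = start, index_day = start - 4L)
}

meas_tab <- function(person_id, feature_id, value, day) {
  data.frame(person_id = person_id, feature_id = feature_id,
             value = value, day = as.integer(day), stringsAsFactors = FALSE)
}

diag_tab <- function(person_id = integer(0), ccs_id = character(0),
                     day = integer(0)) {
  data.frame(person_id = person_id, ccs_id = ccs_id, day = as.integer(day),
             stringsAsFactors = FALSE)
}

# identity-ish normalizer for constructed z-scale fixtures
unit_normalizer <- function(feature_ids) {
  structure(list(feature_ids = feature_ids,
                 mean = stats::setNames(rep(0, length(feature_ids)), feature_ids),
                 sd = stats::setNames(rep(1, length(feature_ids)), feature_ids),
                 xtilde = stats::setNames(rep(0, length(feature_ids)), feature_ids),
                 dropped = character(0)),
            class = "normalizer")
}

# random tensor batch with consistent M/Delta/Xlast, for model tests
random_tensor_set <- function(n, T_, D, presence = 0.6, x_mean = rep(0, D),
                              seed = 1) {
  set.seed(seed)
  M <- array(rbinom(n * T_ * D, 1, presence), c(n, T_, D))
  X <- array(rnorm(n * T_ * D), c(n, T_, D)) * M
  Delta <- array(0, c(n, T_, D))
  Xlast <- array(0, c(n, T_, D))
  for (i in seq_len(n)) for (d in seq_len(D)) {
    last <- x_mean[d]; dl <- 0
    for (t in seq_len(T_)) {
      if (t > 1) dl <- if (M[i, t - 1, d] == 1) 1 else dl + 1
      Delta[i, t, d] <- dl
      Xlast[i, t, d] <- last
      if (M[i, t, d] == 1) last <- X[i, t, d]
    }
  }
  list(X = X, M = M, Delta = Delta, Xlast = Xlast, x_mean = x_mean,
       period_id = seq_len(n), person_id = seq_len(n))
}
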