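# Cohort construction: off-label record filtering, treatment-session
# merging, medium/long exposure selection, pre-treatment periods and
# normal-BMI control matching.
#
# A treatment session is a continuous period of exposure to generally the
# same active ingredients. Relative to the open session (whose reference
# state is the union of member ingredient sets, the session start day and
# the latest member end day), a new record B joins iff:
#   rule 1: identical ingredient set AND start_B - session_end <= gap_days;
#   rule 2: proper subset of the session's ingredients AND record length
#           <= gap_days AND start_B - session_end <= gap_days;
#   rule 3: adds at least one new ingredient AND start_B - session_start
#           <= gap_days AND record length <= gap_days.
# Otherwise B opens a new session. Overlapping/abutting records (gap <= 0)
# always satisfy the gap condition.

rec_len <- function(start_day, end_day) end_day - start_day + 1L

#' Filter short isolated off-label exposure records
#'
#' Off-label (O-AOM) ingredients are often prescribed briefly for unrelated
#' indications. A record is removed when it is off-label, shorter than
#' `min_days`, and has no other record of the same ingredient set whose span
#' comes within `neighbor_days` of its own span. All other records pass
#' through unchanged.
#'
#' @param records exposure record data.frame (`person_id`, `ingredients`,
#'   `start_day`, `end_day`, `is_off_label`), sorted per patient.
#' @param min_days length threshold in days (default 30).
#' @param neighbor_days neighborhood in days within which a same-ingredient
#'   record rescues a short record (default 30).
#' @return the filtered data.frame.
#' @export
filter_oaom_records <- function(records, min_days = 30L, neighbor_days = 30L) {
  if (nrow(records) == 0L) return(records)
  keep <- rep(TRUE, nrow(records))
  short_ol <- records$is_off_label &
    rec_len(records$start_day, records$end_day) < min_days
  for (i in which(short_ol)) {
    same <- which(records$person_id == records$person_id[i] &
                  records$ingredients == records$ingredients[i] &
                  seq_len(nrow(records)) != i)
    if (length(same) == 0L) { keep[i] <- FALSE; next }
    # distance between closed spans; 0 when they overlap
    d <- pmax(records$start_day[same] - records$end_day[i],
              records$start_day[i] - records$end_day[same], 0L)
    if (!any(d <= neighbor_days)) keep[i] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

session_join_rule <- function(rec_ings, rec_start, rec_end,
                              sess_ings, sess_start, sess_end, gap_days) {
  len <- rec_len(rec_start, rec_end)
  gap_end <- rec_start - sess_end
  if (setequal(rec_ings, sess_ings) && gap_end <= gap_days) return(1L)
  if (all(rec_ings %in% sess_ings) && !setequal(rec_ings, sess_ings) &&
      len <= gap_days && gap_end <= gap_days) return(2L)
  if (any(!rec_ings %in% sess_ings) &&
      (rec_start - sess_start) <= gap_days && len <= gap_days) return(3L)
  0L
}

#' Merge exposure records into treatment sessions
#'
#' Greedy chronological merge of one patient's (or many patients') exposure
#' records into continuous treatment sessions under the three gap-based join
#' rules (see the package vignette). Records must be sorted by `person_id`
#' then `start_day`.
#'
#' @param records exposure record data.frame.
#' @param gap_days maximum allowed gap (and short-record length) in days,
#'   default 40.
#' @return data.frame of sessions: `session_id`, `person_id`, `start_day`,
#'   `end_day`, `exposure_length_days`, `ingredients` (union key),
#'   `n_records`, plus a `member_records` list-column of record ids.
#' @export
build_sessions <- function(records, gap_days = 40L) {
  empty <- data.frame(session_id = integer(0), person_id = integer(0),
                      start_day = integer(0), end_day = integer(0),
                      exposure_length_days = integer(0),
                      ingredients = character(0), n_records = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) { empty$member_records <- list(); return(empty) }
  ord <- order(records$person_id, records$start_day, records$end_day)
  if (!identical(ord, seq_len(nrow(records))))
    stop("build_sessions: records must be sorted by person_id, start_day")
  if (is.null(records$record_id)) records$record_id <- seq_len(nrow(records))
  sessions <- list()
  for (pid in unique(records$person_id)) {
    rr <- records[records$person_id == pid, , drop = FALSE]
    sess <- NULL
    flush <- function(s) {
      sessions[[length(sessions) + 1L]] <<- data.frame(
        person_id = pid, start_day = s$start, end_day = s$end,
        exposure_length_days = rec_len(s$start, s$end),
        ingredients = ing_key(s$ings), n_records = length(s$members),
        members = I(list(s$members)), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(rr))) {
      ings <- ing_split(rr$ingredients[i])
      if (is.null(sess)) {
        sess <- list(ings = ings, start = rr$start_day[i], end = rr$end_day[i],
                     members = rr$record_id[i])
        next
      }
      rule <- session_join_rule(ings, rr$start_day[i], rr$end_day[i],
                                sess$ings, sess$start, sess$end, gap_days)
      if (rule > 0L) {
        sess$ings <- union(sess$ings, ings)
        sess$end <- max(sess$end, rr$end_day[i])
        sess$members <- c(sess$members, rr$record_id[i])
      } else {
        flush(sess)
        sess <- list(ings = ings, start = rr$start_day[i], end = rr$end_day[i],
                     members = rr$record_id[i])
      }
    }
    flush(sess)
  }
  out <- do.call(rbind, sessions)
  out$session_id <- seq_len(nrow(out))
  member_records <- out$members
  out$members <- NULL
  out <- out[, c("session_id", "person_id", "start_day", "end_day",
                 "exposure_length_days", "ingredients", "n_records")]
  out$member_records <- member_records
  rownames(out) <- NULL
  out
}

#' Select sessions with medium-to-long exposure
#'
#' @param sessions output of [build_sessions()].
#' @param min_days exposure-length threshold, default 112 days.
#' @param strict_gt if `TRUE` require strictly greater than `min_days`;
#'   default keeps sessions with `exposure_length_days >= min_days`.
#' @return the filtered session data.frame (no mutation).
#' @export
select_medium_long <- function(sessions, min_days = 112L, strict_gt = FALSE) {
  keep <- if (strict_gt) sessions$exposure_length_days > min_days
          else sessions$exposure_length_days >= min_days
  out <- sessions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive pre-treatment observation periods
#'
#' One 365-day pre-treatment window per session: `[start_day - 365,
#' start_day)`, with the index day 4 days before treatment initiation (a
#' lead time for final pre-treatment assessments).
#'
#' @param sessions selected session data.frame.
#' @return data.frame `period_id`, `session_id`, `person_id`,
#'   `window_start`, `window_end` (exclusive, equals the session start),
#'   `index_day`.
#' @export
derive_pre_aom_periods <- function(sessions) {
  data.frame(period_id = seq_len(nrow(sessions)),
             session_id = sessions$session_id,
             person_id = sessions$person_id,
             window_start = sessions$start_day - 365L,
             window_end = sessions$start_day,
             index_day = sessions$start_day - 4L)
}

#' Match case periods to normal-BMI control periods
#'
#' Greedy 1:1 matching without replacement: cases are shuffled by `seed`,
#' and each case takes the unused candidate of identical gender whose
#' age-at-anchor differs by at most `max_age_diff` years and whose anchor
#' date differs by at most `max_date_diff` days, preferring the smallest age
#' difference (ties broken by candidate id).
#'
#' @param case_periods data.frame with `period_id`, `gender`,
#'   `age_at_index`, `index_day`.
#' @param control_candidates output of [gen_controls()].
#' @param seed integer seed for the case shuffle.
#' @param max_age_diff maximum |age difference| in years (default 1).
#' @param max_date_diff maximum |anchor date difference| in days (default 365).
#' @return data.frame of matched pairs (`case_period_id`,
#'   `control_period_id`, `gender`, `age_diff_years`, `date_diff_days`);
#'   unmatched case ids are attached as attribute `"unmatched"`; the seed is
#'   recorded as attribute `"seed"`.
#' @export
match_controls <- function(case_periods, control_candidates, seed = 1L,
                           max_age_diff = 1, max_date_diff = 365L) {
  pairs <- list()
  used <- logical(nrow(control_candidates))
  order_cases <- with_seed(seed, sample(seq_len(nrow(case_periods))))
  unmatched <- integer(0)
  for (i in order_cases) {
    ok <- !used &
      control_candidates$gender == case_periods$gender[i] &
      abs(control_candidates$age_at_anchor - case_periods$age_at_index[i]) <= max_age_diff &
      abs(control_candidates$anchor_day - case_periods$index_day[i]) <= max_date_diff
    if (!any(ok)) { unmatched <- c(unmatched, case_periods$period_id[i]); next }
    cand <- which(ok)
    adiff <- abs(control_candidates$age_at_anchor[cand] - case_periods$age_at_index[i])
    j <- cand[order(adiff, control_candidates$control_id[cand])][1L]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_period_id = case_periods$period_id[i],
      control_period_id = control_candidates$control_id[j],
      gender = case_periods$gender[i],
      age_diff_years = control_candidates$age_at_anchor[j] - case_periods$age_at_index[i],
      date_diff_days = control_candidates$anchor_day[j] - case_periods$index_day[i])
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_period_id = integer(0), control_period_id = integer(0),
               gender = character(0), age_diff_years = numeric(0),
               date_diff_days = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmatched") <- sort(unmatched)
  attr(out, "seed") <- seed
  out
}
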