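#' Classify a task attempt as passed, working or failed
#'
#' A task is passed at accuracy >= 90%, failed below 40%, and working in
#' between (40% inclusive, 90% exclusive).
#'
#' @param accuracy fraction correct, in `[0, 1]` (vectorized).
#' @return character vector: `"passed"`, `"working"` or `"failed"`.
#' @examples
#' classify_task(c(0.90, 0.40, 0.10))
#' @export
classify_task <- function(accuracy) {
  if (!is.numeric(accuracy) || anyNA(accuracy) ||
      any(accuracy < 0 | accuracy > 1)) {
    stop_invalid("accuracy must be in [0, 1]")
  }
  ifelse(accuracy >= 0.90, "passed",
         ifelse(accuracy < 0.40, "failed", "working"))
}

#' Normalized domain score for one session
#'
#' Summarizes the difficulty level a patient operated at during a session.
#' Repeated attempts at the same rank are pooled by mean accuracy before
#' classification. The score is the average of two endpoints, divided by
#' the domain's total number of task levels `L`:
#' \itemize{
#'   \item `hi` — the highest rank passed or working;
#'   \item `lo` — the lowest rank working or failed.
#' }
#' An endpoint whose own status is working or failed is shifted down one
#' rank (floor 0), because the highest level actually passed at that point
#' is the previous task in the progression order. When a session has no
#' working/failed task, both endpoints are the highest passed rank,
#' unadjusted; when it has no passed/working task, both endpoints are the
#' lowest failed rank, adjusted.
#'
#' @param task_rank integer ranks practiced (>= 1, <= L).
#' @param accuracy accuracies aligned with `task_rank`.
#' @param L total number of task levels in the domain.
#' @return the session score, a fraction in `[0, 1]`.
#' @examples
#' session_domain_score(c(8, 9), c(0.92, 0.55), L = 20)  # 0.40
#' session_domain_score(c(5, 6), c(0.93, 0.30), L = 20)  # 0.25
#' @export
session_domain_score <- function(task_rank, accuracy, L) {
  L <- check_count(L, "L", lower = 1)
  if (length(task_rank) == 0) stop_invalid("session has no tasks")
  if (length(task_rank) != length(accuracy)) {
    stop_invalid("task_rank and accuracy must align")
  }
  if (any(task_rank < 1) || any(task_rank != as.integer(task_rank))) {
    stop_invalid("task_rank must be positive integers")
  }
  if (any(task_rank > L)) {
    stop_invalid("task_rank exceeds the domain's ", L, " levels")
  }
  # pool repeated ranks by mean accuracy, then classify per rank
  acc <- tapply(accuracy, task_rank, mean)
  ranks <- as.integer(names(acc))
  status <- classify_task(as.numeric(acc))

  adj <- function(r, s) if (s == "passed") r else max(r - 1L, 0L)
  hi_set <- ranks[status %in% c("passed", "working")]
  lo_set <- ranks[status %in% c("working", "failed")]
  if (length(hi_set) > 0 && length(lo_set) > 0) {
    hi <- max(hi_set); lo <- min(lo_set)
    hi_adj <- adj(hi, status[ranks == hi])
    lo_adj <- adj(lo, status[ranks == lo])
  } else if (length(hi_set) > 0) {        # everything passed
    hi_adj <- lo_adj <- max(hi_set)
  } else {                                # everything failed
    lo_adj <- hi_adj <- max(min(lo_set) - 1L, 0L)
  }
  mean(c(hi_adj, lo_adj)) / L
}

#' Weekly domain scores from a session log
#'
#' Groups events into sessions (all events of one patient x domain on one
#' calendar day), scores each session with [session_domain_score()], bins
#' days into 7-day weeks anchored at each patient's first-ever active day,
#' and averages session scores within each patient x domain x week. Weeks
#' without sessions produce no row. Practice time is summed into hours per
#' week.
#'
#' @param events data.frame with columns `patient_id`, `domain_id`, `day`
#'   (integer day index or a Date), `task_rank`, `accuracy`, `minutes`.
#' @param catalogs named list of task catalogs covering every `domain_id`
#'   present.
#' @param window optional mapping from calendar week to analysis week, as
#'   returned by [analysis_window()]; when supplied only window weeks are
#'   kept and `week` is the 0..9 analysis index, otherwise `week` is the
#'   patient-relative calendar week.
#' @return data.frame: `patient_id`, `domain_id`, `week`, `score`,
#'   `n_sessions`, `hours`.
#' @export
weekly_scores <- function(events, catalogs, window = NULL) {
  need <- c("patient_id", "domain_id", "day", "task_rank", "accuracy", "minutes")
  if (!all(need %in% names(events))) {
    stop_invalid("events must have columns: ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(unique(events$domain_id), names(catalogs))
  if (length(unknown) > 0) {
    stop_invalid("events reference unknown domain(s): ",
                 paste(unknown, collapse = ", "))
  }
  if (nrow(events) == 0) {
    return(data.frame(patient_id = character(), domain_id = character(),
                      week = integer(), score = numeric(),
                      n_sessions = integer(), hours = numeric()))
  }
  day <- if (inherits(events$day, "Date")) as.integer(events$day) else
    as.integer(events$day)
  first_day <- tapply(day, events$patient_id, min)
  week_cal <- (day - as.integer(first_day[as.character(events$patient_id)])) %/% 7L

  key <- paste(events$patient_id, events$domain_id, day, sep = "\r")
  session_score <- vapply(split(seq_len(nrow(events)), key), function(idx) {
    L <- catalog_L(catalogs[[events$domain_id[idx[1]]]])
    session_domain_score(events$task_rank[idx], events$accuracy[idx], L)
  }, numeric(1))
  first_of <- vapply(split(seq_len(nrow(events)), key), `[`, integer(1), 1L)
  minutes <- vapply(split(events$minutes, key), sum, numeric(1))

  sess <- data.frame(
    patient_id = events$patient_id[first_of],
    domain_id = events$domain_id[first_of],
    week = week_cal[first_of],
    score = session_score, minutes = minutes,
    stringsAsFactors = FALSE, row.names = NULL)

  gkey <- paste(sess$patient_id, sess$domain_id, sess$week, sep = "\r")
  idx1 <- vapply(split(seq_len(nrow(sess)), gkey), `[`, integer(1), 1L)
  out <- data.frame(
    patient_id = sess$patient_id[idx1],
    domain_id = sess$domain_id[idx1],
    week = sess$week[idx1],
    score = as.numeric(tapply(sess$score, gkey, mean)),
    n_sessions = as.integer(tapply(sess$score, gkey, length)),
    hours = as.numeric(tapply(sess$minutes, gkey, sum)) / 60,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(window)) {
    m <- match(out$week, window)
    out <- out[!is.na(m), , drop = FALSE]
    out$week <- match(out$week, window) - 1L
  }
  out <- out[order(out$patient_id, out$domain_id, out$week), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Baseline (week-0) score per patient x domain
#'
#' The week-0 score indexes initial severity and is attached as a fixed
#' covariate to every row of that patient x domain in the analysis table.
#'
#' @param weekly a table from [weekly_scores()] with analysis week indices.
#' @return data.frame `patient_id`, `domain_id`, `baseline`.
#' @export
baseline_score <- function(weekly) {
  w0 <- weekly[weekly$week == 0L, c("patient_id", "domain_id", "score")]
  units <- unique(weekly[, c("patient_id", "domain_id")])
  if (nrow(w0) < nrow(units)) {
    miss <- nrow(units) - nrow(w0)
    stop_invalid(miss, " patient-domain unit(s) lack a week-0 score")
  }
  names(w0)[3] <- "baseline"
  rownames(w0) <- NULL
  w0
}
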