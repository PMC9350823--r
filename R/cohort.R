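#' Activity calendar for one patient
#'
#' @param patient_id label.
#' @param active_days integer day indices (or Dates) with at least one
#'   session.
#' @return an `activity_calendar` object.
#' @export
activity_calendar <- function(patient_id, active_days) {
  if (length(active_days) == 0) stop_invalid("active_days must be nonempty")
  days <- sort(unique(as.integer(active_days)))
  structure(list(patient_id = as.character(patient_id), active_days = days),
            class = "activity_calendar")
}

# patient-relative calendar weeks (0-based) of the active days
calendar_weeks <- function(calendar) {
  (calendar$active_days - min(calendar$active_days)) %/% 7L
}

#' Study inclusion rule
#'
#' A patient is eligible when at least 10 of their first 15 patient-relative
#' calendar weeks of use contain at least one active day.
#'
#' @param calendar an [activity_calendar()].
#' @return `TRUE` or `FALSE`.
#' @export
eligible <- function(calendar) {
  wk <- calendar_weeks(calendar)
  length(unique(wk[wk < 15L])) >= 10L
}

#' The 10-week analysis window
#'
#' Returns the first 10 active weeks (weeks with >= 1 active day) among the
#' patient's first 15 calendar weeks; downstream these are re-indexed
#' 0..9 with week 0 the first active week, so a week-0 (baseline) score
#' always exists.
#'
#' @param calendar an [activity_calendar()]; must be [eligible()].
#' @return integer vector of 10 calendar week indices, ascending.
#' @export
analysis_window <- function(calendar) {
  if (!eligible(calendar)) {
    stop_invalid("patient ", calendar$patient_id,
                 " is not eligible: fewer than 10 active weeks in the first 15")
  }
  wk <- sort(unique(calendar_weeks(calendar)))
  utils::head(wk[wk < 15L], 10L)
}

#' Dosage-frequency group from weekly day counts
#'
#' Dosage frequency is the median number of active days per week over the
#' 10 window weeks (weeks in the window with no activity in the unit of
#' interest count 0). Half-integer medians are rounded up; medians of 5 or
#' more are binned into the top `"5+"` group.
#'
#' @param weekly_day_counts integer vector of active-day counts, one per
#'   window week (length 10 in the standard design).
#' @return list with `median_days_per_week` and `group` (factor with
#'   levels `"1","2","3","4","5+"`).
#' @export
dosage_bin <- function(weekly_day_counts) {
  if (length(weekly_day_counts) == 0) stop_invalid("no weekly day counts")
  med <- stats::median(weekly_day_counts)
  g <- round_half_up(med)
  g <- max(1, min(g, 5))
  list(median_days_per_week = med,
       group = factor(ifelse(g >= 5, "5+", as.character(g)),
                      levels = c("1", "2", "3", "4", "5+")))
}

#' Dosage assignment for one patient (or patient x domain)
#'
#' Counts active days in each window week for the given unit and bins the
#' median with [dosage_bin()]. With `domain_id = NULL` activity in any
#' domain counts (per-patient mode); otherwise only sessions in that
#' domain count (per-domain mode, the default unit of the pipeline).
#'
#' @param events session events of one patient.
#' @param window calendar weeks from [analysis_window()].
#' @param domain_id optional domain restriction.
#' @param anchor_day the patient's first-ever active day (week-grid origin).
#' @return list: `median_days_per_week`, `group`.
#' @export
dosage_group <- function(events, window, domain_id = NULL,
                         anchor_day = min(events$day)) {
  ev <- if (is.null(domain_id)) events else
    events[events$domain_id == domain_id, , drop = FALSE]
  wk <- (as.integer(ev$day) - as.integer(anchor_day)) %/% 7L
  counts <- vapply(window, function(w) {
    length(unique(ev$day[wk == w]))
  }, integer(1))
  dosage_bin(counts)
}

#' Total practice hours over the window
#'
#' @param events session events of one patient x domain.
#' @param window calendar weeks from [analysis_window()].
#' @param anchor_day the patient's first-ever active day.
#' @return total hours (sum of minutes / 60) within the window weeks.
#' @export
total_hours <- function(events, window, anchor_day = min(events$day)) {
  if (any(events$minutes < 0)) stop_invalid("negative minutes")
  wk <- (as.integer(events$day) - as.integer(anchor_day)) %/% 7L
  sum(events$minutes[wk %in% window]) / 60
}

#' Assemble the model-ready long table
#'
#' Applies eligibility, derives each eligible patient's analysis window,
#' computes weekly scores within it, attaches the dosage group, total
#' hours, baseline score and demographics, and returns one row per
#' patient x domain x active week. Chronicity is acute at <= 6 months
#' post-stroke, chronic beyond.
#'
#' @param events session events for the whole cohort.
#' @param profiles data.frame with `patient_id`, `age`, `sex`,
#'   `months_post_stroke` (and any extra columns, ignored).
#' @param catalogs named list of task catalogs.
#' @param dosage_unit `"patient-domain"` (default): dosage frequency is
#'   computed from activity in the scored domain; `"patient"`: activity in
#'   any domain counts.
#' @return data.frame with columns `patient_id`, `domain_id`, `week`,
#'   `score`, `group`, `total_hours`, `baseline`, `age`, `sex`,
#'   `chronicity`.
#' @export
assemble_long_table <- function(events, profiles, catalogs,
                                dosage_unit = c("patient-domain", "patient")) {
  dosage_unit <- match.arg(dosage_unit)
  if (!all(events$patient_id %in% profiles$patient_id)) {
    n_bad <- sum(!unique(events$patient_id) %in% profiles$patient_id)
    stop_invalid(n_bad, " patient(s) in events have no profile row")
  }
  ev_by_pat <- split(events, events$patient_id)
  rows <- lapply(names(ev_by_pat), function(pid) {
    ev <- ev_by_pat[[pid]]
    cal <- activity_calendar(pid, ev$day)
    if (!eligible(cal)) return(NULL)
    window <- analysis_window(cal)
    anchor <- min(as.integer(ev$day))
    wk <- weekly_scores(ev, catalogs, window = window)
    if (nrow(wk) == 0) return(NULL)
    base <- baseline_score(wk)
    out <- merge(wk[, c("patient_id", "domain_id", "week", "score")], base,
                 by = c("patient_id", "domain_id"))
    doms <- unique(out$domain_id)
    th <- vapply(doms, function(d)
      total_hours(ev[ev$domain_id == d, ], window, anchor), numeric(1))
    grp <- vapply(doms, function(d) {
      dom <- if (dosage_unit == "patient-domain") d else NULL
      as.character(dosage_group(ev, window, dom, anchor)$group)
    }, character(1))
    out$total_hours <- th[out$domain_id]
    out$group <- grp[out$domain_id]
    out
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) {
    stop_invalid("no eligible patients: every patient fails the ",
                 "10-of-first-15-weeks activity rule")
  }
  prof <- profiles[, c("patient_id", "age", "sex", "months_post_stroke")]
  tab <- merge(tab, prof, by = "patient_id")
  tab$chronicity <- ifelse(tab$months_post_stroke <= 6, "acute", "chronic")
  tab$months_post_stroke <- NULL
  tab$group <- factor(tab$group, levels = c("1", "2", "3", "4", "5+"))
  tab$sex <- factor(tab$sex, levels = c("female", "male", "not_specified"))
  tab$chronicity <- factor(tab$chronicity, levels = c("chronic", "acute"))
  tab <- tab[order(tab$patient_id, tab$domain_id, tab$week),
             c("patient_id", "domain_id", "week", "score", "group",
               "total_hours", "baseline", "age", "sex", "chronicity")]
  rownames(tab) <- NULL
  tab
}
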