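# Small in-code fixtures for scoring and cohort tests.

make_events <- function(patient_id, days, domain_id = "domain01",
                        task_rank = 5L, accuracy = 0.65, minutes = 20) {
  n <- max(length(days), length(task_rank), length(accuracy))
  data.frame(patient_id = patient_id, domain_id = domain_id,
             day = rep_len(as.integer(days), n),
             task_rank = rep_len(task_rank, n),
             accuracy = rep_len(accuracy, n),
             minutes = rep_len(minutes, n),
             stringsAsFactors = FALSE)
}

# a patient active target days per week (days 0..target-1 of each week)
regular_days <- function(n_weeks, days_per_week, start = 0L) {
  as.integer(outer(0:(days_per_week - 1), 7 * (0:(n_weeks - 1)), "+")) + start
}

test_catalogs <- function(n_domains = 1, L = 20) {
  make_task_catalog(n_domains, L, 0.5)
}
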