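test_that("task classification applies the 40/90 thresholds with correct closure", {
  expect_identical(classify_task(0.90), "passed")
  expect_identical(classify_task(0.40), "working")  # fail requires strictly below 40
  expect_identical(classify_task(0.10), "failed")
  expect_identical(classify_task(c(1, 0, 0.8999)),
                   c("passed", "failed", "working"))
  expect_error(classify_task(1.2), class = "dosefreq_error")
  expect_error(classify_task(-0.1), class = "dosefreq_error")
})

test_that("session domain score reproduces the worked endpoint examples", {
  # hi = 9 (working -> 8), lo = 9 (working -> 8): (8+8)/2/20
  expect_equal(session_domain_score(c(8, 9), c(0.92, 0.55), 20), 0.40)
  # hi = 5 passed (unadjusted), lo = 6 failed -> 5: (5+5)/2/20
  expect_equal(session_domain_score(c(5, 6), c(0.93, 0.30), 20), 0.25)
  # floor: single working task at rank 1 adjusts to 0
  expect_equal(session_domain_score(1, 0.50, 20), 0)
  expect_error(session_domain_score(integer(), numeric(), 20),
               class = "dosefreq_error")
  expect_error(session_domain_score(21, 0.5, 20), class = "dosefreq_error")
})

test_that("repeated ranks are pooled by mean accuracy before classification", {
  # two attempts at rank 4: mean(0.95, 0.89) = 0.92 -> passed
  expect_equal(session_domain_score(c(4, 4, 5), c(0.95, 0.89, 0.30), 20),
               session_domain_score(c(4, 5), c(0.92, 0.30), 20))
})

test_that("session scores match the enumeration oracle for 1-3 task sessions", {
  L <- 10
  for (n_tasks in 1:3) {
    en <- enumerate_sessions(L, n_tasks)
    for (ci in seq_len(ncol(en$combs))) {
      ranks <- en$combs[, ci]
      for (pi in seq_len(nrow(en$patterns))) {
        status <- en$patterns[pi, ]
        got <- session_domain_score(ranks, acc_for_status(status), L)
        want <- oracle_session_score(ranks, status, L)
        expect_equal(got, want,
                     info = paste("ranks", paste(ranks, collapse = ","),
                                  "status", paste(status, collapse = ",")))
        expect_true(got >= 0 && got <= 1)
      }
    }
  }
})

test_that("raising the highest passed rank never decreases the score", {
  L <- 10
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(1:3, 1)
    ranks <- sort(sample(1:(L - 1), n))
    status <- sample(c("passed", "working", "failed"), n, replace = TRUE)
    hi <- max(ranks)
    if (status[which.max(ranks)] != "passed") next
    s1 <- session_domain_score(ranks, acc_for_status(status), L)
    ranks2 <- ranks; ranks2[which.max(ranks)] <- hi + 1L
    s2 <- session_domain_score(ranks2, acc_for_status(status), L)
    expect_gte(s2, s1)
  }
})

test_that("adding a passed task below both endpoints leaves the score unchanged", {
  L <- 10
  set.seed(32)
  for (rep in 1:200) {
    n <- sample(1:3, 1)
    ranks <- sort(sample(3:L, n))
    status <- sample(c("passed", "working", "failed"), n, replace = TRUE)
    if (all(status == "failed")) next  # an added pass would become the hi endpoint
    s1 <- session_domain_score(ranks, acc_for_status(status), L)
    low <- min(ranks) - sample(1:2, 1)
    s2 <- session_domain_score(c(low, ranks),
                               c(0.95, acc_for_status(status)), L)
    expect_equal(s2, s1)
  }
})

test_that("weekly scores average sessions within patient-anchored 7-day weeks", {
  cats <- test_catalogs(L = 20)
  # two sessions in week 0 scoring 0.40 and 0.25 -> 0.325
  ev <- rbind(make_events("p1", 0, task_rank = c(8, 9), accuracy = c(0.92, 0.55)),
              make_events("p1", 3, task_rank = c(5, 6), accuracy = c(0.93, 0.30)))
  wk <- weekly_scores(ev, cats)
  expect_equal(nrow(wk), 1)
  expect_equal(wk$score, 0.325)
  expect_equal(wk$n_sessions, 2L)
  expect_equal(wk$hours, 80 / 60)

  # a single-session week keeps that session's score
  wk1 <- weekly_scores(make_events("p1", 0, task_rank = c(8, 9),
                                   accuracy = c(0.92, 0.55)), cats)
  expect_equal(wk1$score, 0.40)

  # activity in weeks 0, 1, 3 -> exactly 3 rows
  ev3 <- make_events("p2", c(0, 8, 22))
  wk3 <- weekly_scores(ev3, cats)
  expect_equal(wk3$week, c(0L, 1L, 3L))
  expect_equal(nrow(wk3), 3)

  expect_error(weekly_scores(make_events("p1", 0, domain_id = "nope"), cats),
               "nope", class = "dosefreq_error")
})

test_that("weekly averaging is invariant to event order", {
  cats <- test_catalogs(L = 20)
  ev <- rbind(make_events("p1", c(0, 2, 4, 9, 11), task_rank = c(3, 5, 7, 4, 8),
                          accuracy = c(0.95, 0.5, 0.3, 0.91, 0.6)),
              make_events("p2", c(1, 3), task_rank = c(2, 6),
                          accuracy = c(0.45, 0.97)))
  set.seed(9)
  perm <- sample(nrow(ev))
  a <- weekly_scores(ev, cats)
  b <- weekly_scores(ev[perm, ], cats)
  expect_equal(a, b)
})

test_that("baseline score is the week-0 score and is required", {
  wk <- data.frame(patient_id = "p1", domain_id = "d", week = c(0L, 1L),
                   score = c(0.30, 0.35), n_sessions = 1L, hours = 1)
  expect_equal(baseline_score(wk)$baseline, 0.30)
  wk_c <- transform(wk, score = 0.5)
  expect_equal(baseline_score(wk_c)$baseline, 0.5)
  expect_error(baseline_score(wk[wk$week > 0, ]), class = "dosefreq_error")
})
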