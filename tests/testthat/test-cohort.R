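test_that("eligibility requires 10 active weeks among the first 15", {
  # one day in each of weeks 0..9
  expect_true(eligible(activity_calendar("a", 7 * (0:9))))
  # exactly 9 distinct active weeks
  expect_false(eligible(activity_calendar("b", 7 * (0:8))))
  # daily use for 15 weeks
  expect_true(eligible(activity_calendar("c", 0:104)))
  # 10 active weeks but only beyond week 15 don't count
  expect_false(eligible(activity_calendar("d", c(0, 7 * (15:24)))))
})

test_that("eligibility is monotone in activity", {
  set.seed(12)
  for (rep in 1:50) {
    days <- sort(sample(0:104, sample(5:30, 1)))
    cal <- activity_calendar("p", days)
    if (!eligible(cal)) next
    extra <- sort(unique(c(days, sample(0:104, 5))))
    expect_true(eligible(activity_calendar("p", extra)))
  }
})

test_that("the analysis window is the first 10 active weeks, re-indexable to 0..9", {
  expect_equal(analysis_window(activity_calendar("a", 7 * (0:9))), 0:9)
  # inactive week 3 is skipped; week 4 maps to index 3
  act <- c(0, 1, 2, 4, 5, 6, 7, 8, 9, 10)
  win <- analysis_window(activity_calendar("b", 7 * act))
  expect_equal(win, act)
  expect_equal(match(4, win) - 1, 3)
  expect_error(analysis_window(activity_calendar("c", 7 * (0:8))),
               class = "dosefreq_error")
})

test_that("dosage binning takes the rounded-half-up median and caps at 5+", {
  b <- dosage_bin(c(1, 1, 1, 2, 1, 1, 1, 1, 2, 1))
  expect_equal(b$median_days_per_week, 1)
  expect_equal(as.character(b$group), "1")

  b <- dosage_bin(c(2, 3, 2, 3, 2, 3, 2, 3, 2, 3))
  expect_equal(b$median_days_per_week, 2.5)
  expect_equal(as.character(b$group), "3")

  b <- dosage_bin(c(5, 6, 7, 5, 5, 6, 5, 7, 6, 5))
  expect_equal(b$median_days_per_week, 5.5)
  expect_equal(as.character(b$group), "5+")
})

test_that("adding an active day to every week never lowers the group", {
  set.seed(13)
  for (rep in 1:100) {
    counts <- sample(0:6, 10, replace = TRUE)
    g1 <- dosage_bin(counts)$group
    g2 <- dosage_bin(counts + 1L)$group
    expect_gte(as.integer(g2), as.integer(g1))
  }
})

test_that("dosage group counts active days within window weeks per unit", {
  # 2 days/week in domain01, 1 day/week in domain02
  ev <- rbind(make_events("p", regular_days(10, 2), domain_id = "domain01"),
              make_events("p", regular_days(10, 1) + 2L, domain_id = "domain02"))
  win <- 0:9
  expect_equal(as.character(dosage_group(ev, win, "domain01", 0)$group), "2")
  expect_equal(as.character(dosage_group(ev, win, "domain02", 0)$group), "1")
  # per-patient mode counts distinct active days in any domain
  expect_equal(as.character(dosage_group(ev, win, NULL, 0)$group), "3")
})

test_that("total hours sum minutes over the window only", {
  ev <- make_events("p", c(0, 1, 2), minutes = c(30, 45, 15))
  expect_equal(total_hours(ev, window = 0:9), 1.5)
  # sessions beyond the window are excluded
  ev2 <- rbind(ev, make_events("p", 120, minutes = 600))
  expect_equal(total_hours(ev2, window = 0:9, anchor_day = 0), 1.5)
  ev$minutes[1] <- -5
  expect_error(total_hours(ev, 0:9), class = "dosefreq_error")
})

test_that("the assembled long table joins scores, dosage and covariates", {
  profs <- data.frame(
    patient_id = c("p1", "p2"), age = c(60, 70),
    sex = c("female", "male"), months_post_stroke = c(6, 7),
    stringsAsFactors = FALSE)
  cats <- test_catalogs(n_domains = 2)
  ev <- rbind(
    make_events("p1", regular_days(10, 2), domain_id = "domain01"),
    make_events("p1", regular_days(10, 2) + 2L, domain_id = "domain02"),
    make_events("p2", regular_days(10, 1), domain_id = "domain01"),
    make_events("p2", regular_days(10, 1), domain_id = "domain02"))
  tab <- assemble_long_table(ev, profs, cats)
  # 2 patients x 2 domains x 10 active weeks
  expect_equal(nrow(tab), 40)
  expect_named(tab, c("patient_id", "domain_id", "week", "score", "group",
                      "total_hours", "baseline", "age", "sex", "chronicity"))
  # 6 months post-stroke is still acute; 7 is chronic
  expect_equal(unique(as.character(tab$chronicity[tab$patient_id == "p1"])),
               "acute")
  expect_equal(unique(as.character(tab$chronicity[tab$patient_id == "p2"])),
               "chronic")
  expect_equal(unique(as.character(tab$group[tab$patient_id == "p1"])), "2")
  # every row of a unit carries its week-0 score as baseline
  w0 <- tab[tab$week == 0, ]
  key <- paste(tab$patient_id, tab$domain_id)
  expect_equal(tab$baseline,
               w0$score[match(key, paste(w0$patient_id, w0$domain_id))])
})

test_that("a patient missing one window week yields 9 rows for that unit", {
  profs <- data.frame(patient_id = "p1", age = 60, sex = "female",
                      months_post_stroke = 2, stringsAsFactors = FALSE)
  cats <- test_catalogs()
  days <- regular_days(11, 1)[-6]  # 11 active weeks, week 5 removed
  tab <- assemble_long_table(make_events("p1", days), profs, cats)
  expect_equal(nrow(tab), 10)  # the 10 active weeks among the first 11
  # eligible through domain01; domain02 skips analysis week 5 -> 9 rows
  cats2 <- test_catalogs(n_domains = 2)
  ev9 <- rbind(make_events("p1", regular_days(10, 1), domain_id = "domain01"),
               make_events("p1", regular_days(10, 1)[-6] + 1L,
                           domain_id = "domain02"))
  tab9 <- assemble_long_table(ev9, profs, cats2)
  expect_equal(sum(tab9$domain_id == "domain02"), 9)
  expect_equal(sum(tab9$domain_id == "domain01"), 10)
})

test_that("ineligible-only cohorts and unknown patients are rejected", {
  profs <- data.frame(patient_id = "p1", age = 60, sex = "female",
                      months_post_stroke = 2, stringsAsFactors = FALSE)
  cats <- test_catalogs()
  expect_error(
    assemble_long_table(make_events("p1", c(0, 7)), profs, cats),
    class = "dosefreq_error")
  expect_error(
    assemble_long_table(make_events("p9", regular_days(10, 1)), profs, cats),
    class = "dosefreq_error")
})
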