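#' Construct a patient profile for the practice simulator
#'
#' Holds the demographics used as model covariates (age, sex, months since
#' stroke) together with the latent quantities that drive simulated
#' practice: a starting ability on the task-difficulty scale, a per-session
#' learning rate, and the number of days per week the patient aims to
#' practice.
#'
#' @param patient_id label.
#' @param age years (> 0).
#' @param sex one of `"male"`, `"female"`, `"not_specified"`.
#' @param months_post_stroke months since the stroke (>= 0). Values <= 6
#'   are later classed acute, > 6 chronic.
#' @param theta0 initial ability on the difficulty scale.
#' @param learning_rate ability gained per completed session (>= 0).
#' @param target_days_per_week intended practice days per week, 1..7.
#' @return a `patient_profile` object (a list).
#' @export
patient_profile <- function(patient_id, age, sex, months_post_stroke,
                            theta0, learning_rate, target_days_per_week) {
  check_scalar_number(age, "age")
  if (age <= 0) stop_invalid("age must be > 0")
  sex <- match.arg(sex, c("male", "female", "not_specified"))
  check_scalar_number(months_post_stroke, "months_post_stroke", lower = 0)
  check_scalar_number(theta0, "theta0")
  check_scalar_number(learning_rate, "learning_rate", lower = 0)
  target_days_per_week <- check_count(target_days_per_week,
                                      "target_days_per_week", lower = 1)
  if (target_days_per_week > 7) {
    stop_invalid("target_days_per_week must be in [1, 7]")
  }
  structure(
    list(patient_id = as.character(patient_id), age = age, sex = sex,
         months_post_stroke = months_post_stroke, theta0 = theta0,
         learning_rate = learning_rate,
         target_days_per_week = target_days_per_week),
    class = "patient_profile")
}

#' Simulator configuration
#'
#' Bundles the knobs of the synthetic cohort: cohort shape, the
#' item-response accuracy model, and the seed. Defaults describe a
#' realistic self-managed therapy cohort: five dosage-frequency groups,
#' three practiced domains, a 10-week analysis period preceded by no
#' run-in, 20 scoreable items per task, and a logistic accuracy slope of 1.
#'
#' @param n_patients_per_group patients allocated to each of the five
#'   target-frequency groups (1,2,3,4,5+ days/week).
#' @param n_domains number of domains each patient practices.
#' @param n_weeks simulated weeks (default 12: ten analysis weeks plus
#'   slack so eligibility is decidable).
#' @param L task levels per domain.
#' @param difficulty_step difficulty increment between ranks.
#' @param kappa logistic slope of the accuracy model.
#' @param n_items items per task attempt; `Inf` gives noise-free accuracy.
#' @param demotion_window consecutive non-improving sessions at a rank that
#'   trigger demotion.
#' @param rng_seed integer root seed; fixes the cohort bit-for-bit.
#' @return a `sim_config` object (a list).
#' @export
sim_config <- function(n_patients_per_group = 10, n_domains = 3,
                       n_weeks = 12, L = 20, difficulty_step = 0.5,
                       kappa = 1, n_items = 20, demotion_window = 3,
                       rng_seed = 1L) {
  n_patients_per_group <- check_count(n_patients_per_group, "n_patients_per_group")
  n_domains <- check_count(n_domains, "n_domains")
  n_weeks <- check_count(n_weeks, "n_weeks")
  L <- check_count(L, "L", lower = 2)
  check_scalar_number(kappa, "kappa")
  if (kappa <= 0) stop_invalid("kappa must be > 0")
  if (!identical(n_items, Inf)) check_count(n_items, "n_items")
  demotion_window <- check_count(demotion_window, "demotion_window")
  structure(
    list(n_patients_per_group = n_patients_per_group, n_domains = n_domains,
         n_weeks = n_weeks, L = L, difficulty_step = difficulty_step,
         kappa = kappa, n_items = n_items,
         demotion_window = demotion_window,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

#' Simulate one patient's practice log in one domain
#'
#' Implements the adaptive-difficulty loop of app-based therapy. Each
#' active day yields one session at the current working rank. Expected
#' accuracy follows a logistic item-response curve,
#' `pi = plogis(kappa * (theta - delta_rank))`; observed accuracy is
#' `Binomial(n_items, pi) / n_items` (or `pi` itself when
#' `n_items = Inf`, the noise-free mode). After every session ability
#' increases by the learning rate. A patient advances one rank after
#' reaching accuracy >= 0.90 on two occasions at the current rank, and is
#' demoted one rank (floor 1) when accuracy falls below 0.40 or after
#' `demotion_window` consecutive sessions with no accuracy increase.
#' Active days are placed uniformly at random within each week.
#'
#' @param profile a [patient_profile()].
#' @param catalog a task catalog from [make_task_catalog()].
#' @param n_weeks number of weeks to simulate.
#' @param rng_seed integer seed; identical seeds give identical logs.
#' @param n_items items per attempt; `Inf` for noise-free accuracy.
#' @param kappa logistic slope.
#' @param demotion_window see [sim_config()].
#' @param start_day day offset of the patient's week grid (default 0).
#' @return a data.frame of session events: `patient_id`, `domain_id`,
#'   `day` (integer day index from the patient's start), `task_rank`,
#'   `accuracy`, `minutes`.
#' @export
simulate_patient <- function(profile, catalog, n_weeks, rng_seed,
                             n_items = 20, kappa = 1, demotion_window = 3,
                             start_day = 0) {
  if (!inherits(profile, "patient_profile")) stop_invalid("profile must be a patient_profile")
  if (!is_task_catalog(catalog)) stop_invalid("catalog must be a task_catalog")
  n_weeks <- check_count(n_weeks, "n_weeks")
  L <- catalog_L(catalog)

  set.seed(as.integer(rng_seed))
  theta <- profile$theta0
  rank <- 1L
  pass_count <- 0L
  stall_count <- 0L
  last_acc <- -Inf

  rows <- vector("list", n_weeks * profile$target_days_per_week)
  i <- 0L
  for (w in seq_len(n_weeks) - 1L) {
    days <- sort(sample.int(7L, profile$target_days_per_week))
    for (d in days) {
      pi_acc <- stats::plogis(kappa * (theta - catalog$difficulty[rank]))
      acc <- if (is.infinite(n_items)) pi_acc else
        stats::rbinom(1L, n_items, pi_acc) / n_items
      minutes <- round(stats::runif(1L, 5, 25), 1)
      i <- i + 1L
      rows[[i]] <- list(patient_id = profile$patient_id,
                        domain_id = catalog$domain_id,
                        day = start_day + w * 7L + (d - 1L),
                        task_rank = rank, accuracy = acc, minutes = minutes)

      # update adaptive state after recording the session
      theta <- theta + profile$learning_rate
      if (acc >= 0.90) pass_count <- pass_count + 1L
      stall_count <- if (acc > last_acc) 0L else stall_count + 1L
      last_acc <- acc

      if (pass_count >= 2L) {
        rank <- min(rank + 1L, L)
        pass_count <- 0L; stall_count <- 0L; last_acc <- -Inf
      } else if (acc < 0.40 || stall_count >= demotion_window) {
        rank <- max(rank - 1L, 1L)
        pass_count <- 0L; stall_count <- 0L; last_acc <- -Inf
      }
    }
  }
  do.call(rbind, lapply(rows[seq_len(i)], as.data.frame))
}

# Demographic sampling used by simulate_cohort: age ~ N(63, 14) truncated
# at 18; sex with the observed cohort mix; months post-stroke lognormal so
# that roughly 59% of patients fall in the acute (<= 6 months) range.
sample_demographics <- function(n) {
  age <- pmax(18, round(stats::rnorm(n, 63, 14)))
  sex <- sample(c("male", "female", "not_specified"), n, replace = TRUE,
                prob = c(0.564, 0.430, 0.006))
  months <- round(stats::rlnorm(n, meanlog = log(5), sdlog = 1.2), 1)
  data.frame(age = age, sex = sex, months_post_stroke = months,
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort across dosage-frequency groups
#'
#' Allocates `n_patients_per_group` patients to each of the five target
#' frequencies (1, 2, 3, 4 and 5+ days/week; the 5+ group draws its target
#' uniformly from 5..7), samples demographics and latent ability, and runs
#' [simulate_patient()] for every patient x domain. Per-patient RNG
#' substreams are derived from `(rng_seed, patient_id)`, so the cohort is
#' reproducible bit-for-bit.
#'
#' @param config a [sim_config()].
#' @param catalogs a non-empty list of task catalogs; patients practice
#'   the first `config$n_domains` of them.
#' @return a list with `sessions` (data.frame of session events) and
#'   `profiles` (data.frame of patient covariates and targets).
#' @export
simulate_cohort <- function(config, catalogs = NULL) {
  if (!inherits(config, "sim_config")) stop_invalid("config must be a sim_config")
  if (is.null(catalogs)) {
    catalogs <- make_task_catalog(config$n_domains, config$L,
                                  config$difficulty_step)
  }
  if (length(catalogs) == 0) stop_invalid("catalogs must be non-empty")
  if (length(catalogs) < config$n_domains) {
    stop_invalid("need at least n_domains catalogs")
  }
  catalogs <- catalogs[seq_len(config$n_domains)]

  n <- config$n_patients_per_group * 5L
  set.seed(config$rng_seed)
  demo <- sample_demographics(n)
  # latent ability centred one third of the way up the ladder, so baseline
  # domain scores land around 0.33 like a typical post-stroke cohort
  delta_max <- config$L * config$difficulty_step
  theta0 <- stats::rnorm(n, 0.33 * delta_max, 0.15 * delta_max)
  learning_rate <- stats::rgamma(n, shape = 2, scale = 0.015)
  group_target <- rep(1:5, each = config$n_patients_per_group)
  target_days <- ifelse(group_target == 5,
                        sample(5:7, n, replace = TRUE), group_target)

  profiles <- data.frame(
    patient_id = sprintf("p%04d", seq_len(n)),
    age = demo$age, sex = demo$sex,
    months_post_stroke = demo$months_post_stroke,
    theta0 = theta0, learning_rate = learning_rate,
    target_days_per_week = target_days,
    stringsAsFactors = FALSE)

  sessions <- vector("list", n * length(catalogs))
  k <- 0L
  for (i in seq_len(n)) {
    prof <- patient_profile(profiles$patient_id[i], profiles$age[i],
                            profiles$sex[i], profiles$months_post_stroke[i],
                            profiles$theta0[i], profiles$learning_rate[i],
                            profiles$target_days_per_week[i])
    for (cat_j in seq_along(catalogs)) {
      k <- k + 1L
      sessions[[k]] <- simulate_patient(
        prof, catalogs[[cat_j]], config$n_weeks,
        rng_seed = derive_seed(config$rng_seed,
                               paste0(prof$patient_id, "/", cat_j)),
        n_items = config$n_items, kappa = config$kappa,
        demotion_window = config$demotion_window)
    }
  }
  list(sessions = do.call(rbind, sessions), profiles = profiles)
}
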