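#' Reference fixed-effect vector of the dose-response model
#'
#' Fixed-effect estimates from a large real-world cohort analysis of
#' self-managed digital therapy (2249 post-stroke patients, 13 skill
#' domains, 10 weeks), used as the simulator's default generating
#' coefficients and as the input for worked contrast/EMM examples. Units:
#' the outcome is a normalized domain score in `[0, 1]`; `week` is 0..9;
#' `total_hours` is cumulative practice hours in the scored domain.
#' Reference levels: dosage group "1" (1 day/week), sex "female",
#' chronicity "chronic".
#'
#' @return named numeric vector of 17 coefficients in design order.
#' @examples
#' reference_fixef()[["week"]]
#' @export
reference_fixef <- function() {
  c("(Intercept)"       =  1.36e-1,
    "week"              =  9.28e-3,
    "group2"            =  1.15e-3,
    "group3"            =  8.00e-3,
    "group4"            =  8.30e-3,
    "group5+"           =  1.13e-2,
    "total_hours"       =  1.13e-4,
    "baseline"          =  6.62e-1,
    "age"               = -1.54e-4,
    "sexmale"           = -1.39e-4,
    "sexnot_specified"  =  2.13e-2,
    "chronicityacute"   =  9.93e-3,
    "week:group2"       =  1.13e-3,
    "week:group3"       =  2.82e-3,
    "week:group4"       =  4.73e-3,
    "week:group5+"      =  5.03e-3,
    "week:total_hours"  =  6.01e-6)
}

#' Reference variance components of the dose-response model
#'
#' Random-effect variances from the same cohort analysis as
#' [reference_fixef()]: correlated random intercepts and week slopes for
#' patient and for domain, plus the residual variance.
#'
#' @return list with `sigma2` (residual variance) and, for `patient` and
#'   `domain`, `var_intercept`, `var_slope` and `corr`.
#' @export
reference_varcomps <- function() {
  list(sigma2 = 1.4e-2,
       patient = list(var_intercept = 2.2e-3, var_slope = 1.5e-5, corr = 0.52),
       domain  = list(var_intercept = 1.3e-3, var_slope = 1.6e-5, corr = 0.03))
}

# zero-variance components, handy for noiseless generation
zero_varcomps <- function() {
  list(sigma2 = 0,
       patient = list(var_intercept = 0, var_slope = 0, corr = 0),
       domain  = list(var_intercept = 0, var_slope = 0, corr = 0))
}

# correlated (intercept, slope) pairs from a bivariate normal
rmvn2 <- function(n, var_int, var_slope, corr) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  int <- sqrt(var_int) * z1
  slp <- sqrt(var_slope) * (corr * z1 + sqrt(max(0, 1 - corr^2)) * z2)
  cbind(int, slp)
}

#' Fixed-effect design matrix of the dose-response model
#'
#' Expands an analysis table into the model's design matrix with columns
#' in the canonical coefficient order of [reference_fixef()].
#'
#' @param table data.frame with `week`, `group`, `total_hours`, `baseline`,
#'   `age`, `sex`, `chronicity` (factors with the standard levels).
#' @return numeric matrix with one column per fixed effect.
#' @export
lmm_design_matrix <- function(table) {
  table$group <- factor(table$group, levels = c("1", "2", "3", "4", "5+"))
  table$sex <- factor(table$sex, levels = c("female", "male", "not_specified"))
  table$chronicity <- factor(table$chronicity, levels = c("chronic", "acute"))
  X <- stats::model.matrix(
    ~ week * (group + total_hours) + baseline + age + sex + chronicity,
    data = table)
  want <- names(reference_fixef())
  if (!all(want %in% colnames(X))) {
    stop_invalid("design is missing column(s): ",
                 paste(setdiff(want, colnames(X)), collapse = ", "))
  }
  X[, want, drop = FALSE]
}

#' Generate a weekly-score dataset directly from the mixed model
#'
#' Draws a balanced long table straight from the linear mixed model the
#' inference layer fits: fixed effects `beta`, correlated random
#' intercept/slope pairs for patient and domain, and Gaussian residuals.
#' With all variance components zero the scores equal the linear predictor
#' exactly, so the generative model is exactly linear-Gaussian; optional
#' clipping to `[0, 1]` is off by default.
#'
#' @param beta named coefficient vector in the order of
#'   [reference_fixef()] (the default).
#' @param varcomps variance components as in [reference_varcomps()] (the
#'   default).
#' @param group_sizes patients per dosage group, length 5.
#' @param n_domains domains per patient.
#' @param n_weeks weeks 0..n_weeks-1.
#' @param rng_seed integer seed.
#' @param clip clip scores into `[0, 1]`? Default `FALSE`.
#' @return data.frame shaped like [assemble_long_table()]'s output plus a
#'   `mu` column holding the true linear predictor (fixed effects only).
#' @export
generate_lmm_dataset <- function(beta = reference_fixef(),
                                 varcomps = reference_varcomps(),
                                 group_sizes = rep(10L, 5L),
                                 n_domains = 3, n_weeks = 10,
                                 rng_seed = 1L, clip = FALSE) {
  if (length(group_sizes) != 5L) stop_invalid("group_sizes must have length 5")
  if (!identical(names(beta), names(reference_fixef()))) {
    stop_invalid("beta must be named exactly as reference_fixef()")
  }
  vc_ok <- function(v) v$var_intercept >= 0 && v$var_slope >= 0 &&
    abs(v$corr) <= 1
  if (varcomps$sigma2 < 0 || !vc_ok(varcomps$patient) || !vc_ok(varcomps$domain)) {
    stop_invalid("variance components must be >= 0 with |corr| <= 1")
  }
  n_domains <- check_count(n_domains, "n_domains")
  n_weeks <- check_count(n_weeks, "n_weeks")

  set.seed(as.integer(rng_seed))
  n_pat <- sum(group_sizes)
  group <- factor(rep(c("1", "2", "3", "4", "5+"), times = group_sizes),
                  levels = c("1", "2", "3", "4", "5+"))
  demo <- sample_demographics(n_pat)
  chronicity <- ifelse(demo$months_post_stroke <= 6, "acute", "chronic")

  # per-group mean total hours mirror the observed dose-exposure gradient
  th_mean <- c(3.7, 5.3, 6.1, 6.9, 10.6)[as.integer(group)]
  pat <- data.frame(
    patient_id = sprintf("p%04d", seq_len(n_pat)), group = group,
    age = demo$age, sex = demo$sex, chronicity = chronicity,
    stringsAsFactors = FALSE)

  units <- expand.grid(patient_id = pat$patient_id,
                       domain_id = sprintf("domain%02d", seq_len(n_domains)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units$baseline <- pmin(1, pmax(0, stats::rnorm(nrow(units), 0.33, 0.20)))
  units$total_hours <- stats::rlnorm(
    nrow(units),
    meanlog = log(th_mean[match(units$patient_id, pat$patient_id)]) - 0.32,
    sdlog = 0.8)

  tab <- merge(units, pat, by = "patient_id")
  tab <- tab[rep(seq_len(nrow(tab)), each = n_weeks), ]
  tab$week <- rep(0:(n_weeks - 1L), times = nrow(units))

  re_pat <- rmvn2(n_pat, varcomps$patient$var_intercept,
                  varcomps$patient$var_slope, varcomps$patient$corr)
  re_dom <- rmvn2(n_domains, varcomps$domain$var_intercept,
                  varcomps$domain$var_slope, varcomps$domain$corr)
  ip <- match(tab$patient_id, pat$patient_id)
  id <- match(tab$domain_id, sprintf("domain%02d", seq_len(n_domains)))

  X <- lmm_design_matrix(tab)
  mu <- drop(X %*% beta)
  score <- mu +
    re_pat[ip, 1] + tab$week * re_pat[ip, 2] +
    re_dom[id, 1] + tab$week * re_dom[id, 2] +
    stats::rnorm(nrow(tab), 0, sqrt(varcomps$sigma2))
  if (clip) score <- pmin(1, pmax(0, score))

  out <- data.frame(
    patient_id = tab$patient_id, domain_id = tab$domain_id,
    week = as.integer(tab$week), score = score,
    group = factor(tab$group, levels = c("1", "2", "3", "4", "5+")),
    total_hours = tab$total_hours, baseline = tab$baseline,
    age = tab$age,
    sex = factor(tab$sex, levels = c("female", "male", "not_specified")),
    chronicity = factor(tab$chronicity, levels = c("chronic", "acute")),
    mu = mu, stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$domain_id, out$week), ]
  rownames(out) <- NULL
  out
}
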