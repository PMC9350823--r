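#' Tukey-adjusted p-value from a t ratio
#'
#' Multiplicity-adjusted p-value for one of the pairwise comparisons in a
#' family of `k` estimates: the upper-tail probability of the studentized
#' range distribution with `k` groups and `df` degrees of freedom
#' evaluated at `|t| * sqrt(2)`. `df = Inf` gives the asymptotic (normal)
#' limit used when mixed-model contrasts are tested with z statistics. At
#' `k = 2` the adjustment vanishes and the value equals the two-sided
#' normal/t p-value.
#'
#' @param t_ratio t (or z) ratio(s) of the contrast; vectorized.
#' @param k family size (number of estimates compared), >= 2.
#' @param df degrees of freedom; `Inf` (default) for asymptotic inference.
#' @return adjusted p-value(s) in `[0, 1]`.
#' @examples
#' tukey_p(-2.37, k = 5)  # ~0.12
#' tukey_p(-0.52, k = 5)  # ~0.99
#' @export
tukey_p <- function(t_ratio, k, df = Inf) {
  k <- check_count(k, "k", lower = 2)
  if (!is.numeric(t_ratio) || anyNA(t_ratio)) {
    stop_invalid("t_ratio must be numeric")
  }
  check_scalar_number(df, "df", lower = 1)
  stats::ptukey(abs(t_ratio) * sqrt(2), nmeans = k, df = df,
                lower.tail = FALSE)
}

# groups present in a fit's coefficients, in dosage order
fit_groups <- function(beta) {
  extra <- sub("^group", "", grep("^group", names(beta), value = TRUE))
  c("1", extra)
}

# weight vector over beta for group g's slope (d score / d week)
slope_weights <- function(beta, g) {
  w <- stats::setNames(numeric(length(beta)), names(beta))
  w["week"] <- 1
  term <- paste0("week:group", g)
  if (term %in% names(beta)) w[term] <- 1
  w
}

contrast_row <- function(beta, vcov, wts, label, k) {
  est <- sum(wts * beta)
  se <- if (is.null(vcov)) NA_real_ else sqrt(drop(t(wts) %*% vcov %*% wts))
  t <- est / se
  data.frame(contrast = label, estimate = est, SE = se, t_ratio = t,
             df = Inf, p_adjusted = if (is.na(t)) NA_real_ else tukey_p(t, k),
             stringsAsFactors = FALSE)
}

#' Pairwise dosage-group slope contrasts
#'
#' For each pair of dosage groups, the difference in weekly improvement
#' rate: group g's slope is `beta_week + beta_week:group_g` (zero
#' interaction for the reference group 1), so the contrast `g vs h` is
#' the difference of the two week-by-group interactions. SEs come from
#' the coefficient covariance; p-values are Tukey-adjusted for the family
#' of all groups with asymptotic df. A contrast is reported as
#' lower-frequency minus higher-frequency group, so an incremental dosage
#' effect shows up as negative estimates.
#'
#' @param fit a `dose_lmm` from [fit_lmm()] or [lmm_fit()].
#' @return data.frame with one row per group pair: `contrast`, `estimate`,
#'   `SE`, `t_ratio`, `df`, `p_adjusted`. Without a covariance in the fit
#'   the SE, t and p columns are `NA`.
#' @export
slope_contrasts <- function(fit) {
  if (!inherits(fit, "dose_lmm")) stop_invalid("fit must be a dose_lmm")
  beta <- fit$beta
  if (!"week" %in% names(beta) || !any(grepl("^week:group", names(beta)))) {
    stop_invalid("fit lacks week:group interaction terms")
  }
  groups <- fit_groups(beta)
  k <- length(groups)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      wts <- slope_weights(beta, groups[i]) - slope_weights(beta, groups[j])
      rows[[length(rows) + 1]] <- contrast_row(
        beta, fit$vcov, wts, paste(groups[i], "vs", groups[j]), k)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# reference-grid weight vector for group g at a given week: categorical
# covariates averaged with equal weight over their observed levels,
# continuous covariates at supplied values (data means when the fit
# carries data, zero otherwise — differences between groups are invariant
# to this choice).
emm_weights <- function(beta, g, week, at) {
  w <- stats::setNames(numeric(length(beta)), names(beta))
  has <- function(term) term %in% names(beta)
  w["(Intercept)"] <- 1
  w["week"] <- week
  if (has(paste0("group", g))) w[paste0("group", g)] <- 1
  if (has(paste0("week:group", g))) w[paste0("week:group", g)] <- week
  if (has("total_hours")) w["total_hours"] <- at$total_hours
  if (has("week:total_hours")) w["week:total_hours"] <- week * at$total_hours
  if (has("baseline")) w["baseline"] <- at$baseline
  if (has("age")) w["age"] <- at$age
  sex_terms <- grep("^sex", names(beta), value = TRUE)
  if (length(sex_terms) > 0) w[sex_terms] <- 1 / (length(sex_terms) + 1)
  chr_terms <- grep("^chronicity", names(beta), value = TRUE)
  if (length(chr_terms) > 0) w[chr_terms] <- 1 / (length(chr_terms) + 1)
  w
}

default_grid <- function(fit, at) {
  base <- list(total_hours = 0, baseline = 0, age = 0)
  if (!is.null(fit$data)) {
    base <- list(total_hours = mean(fit$data$total_hours),
                 baseline = mean(fit$data$baseline),
                 age = mean(fit$data$age))
  }
  utils::modifyList(base, as.list(at))
}

#' Estimated marginal means per dosage group at a given week
#'
#' Model-based group means at a reference grid: categorical covariates
#' (sex, chronicity) averaged with equal weight over their levels,
#' continuous covariates (total hours, baseline score, age) at their
#' sample means (or values supplied via `at`). Week 0 is the start of
#' treatment and week 9 the end of the 10-week analysis period; weeks
#' outside the fitted 0..9 range warn about extrapolation.
#'
#' @param fit a `dose_lmm`.
#' @param week week at which to evaluate (typically 0 or 9).
#' @param at optional named list overriding grid values for
#'   `total_hours`, `baseline`, `age`.
#' @return data.frame `group`, `emm`, `SE`.
#' @export
emm_at_week <- function(fit, week, at = list()) {
  if (!inherits(fit, "dose_lmm")) stop_invalid("fit must be a dose_lmm")
  check_scalar_number(week, "week")
  if (week < 0 || week > 9) {
    warning("week ", week, " lies outside the fitted 0..9 range; ",
            "EMMs are extrapolations")
  }
  grid <- default_grid(fit, at)
  groups <- fit_groups(fit$beta)
  rows <- lapply(groups, function(g) {
    wts <- emm_weights(fit$beta, g, week, grid)
    se <- if (is.null(fit$vcov)) NA_real_ else
      sqrt(drop(t(wts) %*% fit$vcov %*% wts))
    data.frame(group = g, emm = sum(wts * fit$beta), SE = se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise EMM contrasts at a given week
#'
#' Differences of [emm_at_week()] group means (lower-frequency minus
#' higher-frequency group) with Tukey-adjusted asymptotic p-values. At
#' week 0 these differences equal the group main effects; at week `w`
#' they equal main effect plus `w` times the week-by-group interaction.
#'
#' @inheritParams emm_at_week
#' @return data.frame as in [slope_contrasts()].
#' @export
emm_contrasts <- function(fit, week, at = list()) {
  if (!inherits(fit, "dose_lmm")) stop_invalid("fit must be a dose_lmm")
  grid <- default_grid(fit, at)
  groups <- fit_groups(fit$beta)
  k <- length(groups)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      wts <- emm_weights(fit$beta, groups[i], week, grid) -
        emm_weights(fit$beta, groups[j], week, grid)
      rows[[length(rows) + 1]] <- contrast_row(
        fit$beta, fit$vcov, wts, paste(groups[i], "vs", groups[j]), k)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized pre/post treatment effect size per dosage group
#'
#' Cohen's-d-style effect of the 10-week treatment within each dosage
#' group: the change in the group's estimated marginal mean from week 0
#' to week 9, divided by a standardizing SD — the residual SD by default,
#' or the square root of the summed variance components (residual +
#' random intercept and slope variances) in `"total"` mode.
#'
#' @param fit a `dose_lmm` carrying variance components.
#' @param sigma_mode `"residual"` (default) or `"total"`.
#' @return data.frame `group`, `emm_week0`, `emm_week9`, `sigma`, `d`.
#' @export
treatment_effect_size <- function(fit, sigma_mode = c("residual", "total")) {
  sigma_mode <- match.arg(sigma_mode)
  if (!inherits(fit, "dose_lmm")) stop_invalid("fit must be a dose_lmm")
  vc <- fit$varcomps
  if (is.null(vc)) stop_invalid("fit carries no variance components")
  sigma <- if (sigma_mode == "residual") sqrt(vc$sigma2) else {
    tot <- vc$sigma2
    for (term in c("patient", "domain")) {
      if (!is.null(vc[[term]])) {
        tot <- tot + vc[[term]]$var_intercept + vc[[term]]$var_slope
      }
    }
    sqrt(tot)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop_invalid("standardizing SD is zero; effect sizes undefined")
  }
  e0 <- emm_at_week(fit, 0)
  e9 <- emm_at_week(fit, 9)
  data.frame(group = e0$group, emm_week0 = e0$emm, emm_week9 = e9$emm,
             sigma = sigma, d = (e9$emm - e0$emm) / sigma,
             stringsAsFactors = FALSE)
}
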