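#' Construct a mixed-model fit object from coefficients
#'
#' The inference layer (contrasts, EMMs, effect sizes) only needs the
#' fixed-effect vector, optionally its covariance, and variance
#' components. This constructor builds such an object directly — e.g.
#' from published coefficient tables — so the contrast and EMM arithmetic
#' can be exercised without refitting.
#'
#' @param beta named fixed-effect vector (names as in [reference_fixef()]).
#' @param vcov optional covariance matrix of `beta`; when absent, SEs and
#'   p-values of derived quantities are `NA`.
#' @param varcomps optional variance components as in
#'   [reference_varcomps()].
#' @param loglik,n_obs,converged,method optional fit metadata.
#' @param model optional underlying `merMod` object.
#' @param data optional analysis table used for the fit (reference grids).
#' @return an object of class `dose_lmm`.
#' @export
lmm_fit <- function(beta, vcov = NULL, varcomps = NULL, loglik = NA_real_,
                    n_obs = NA_integer_, converged = NA, method = NA_character_,
                    model = NULL, data = NULL) {
  if (is.null(names(beta)) || anyNA(names(beta))) {
    stop_invalid("beta must be a named vector")
  }
  if (!is.null(vcov)) {
    if (!is.matrix(vcov) || nrow(vcov) != length(beta) ||
        ncol(vcov) != length(beta)) {
      stop_invalid("vcov must be a ", length(beta), "x", length(beta), " matrix")
    }
    if (max(abs(vcov - t(vcov))) > 1e-8 * (1 + max(abs(vcov)))) {
      stop_invalid("vcov must be symmetric")
    }
    dimnames(vcov) <- list(names(beta), names(beta))
  }
  structure(
    list(beta = beta, vcov = vcov, varcomps = varcomps, loglik = loglik,
         n_obs = n_obs, converged = converged, method = method,
         model = model, data = data),
    class = "dose_lmm")
}

#' @export
print.dose_lmm <- function(x, ...) {
  cat("Dose-response linear mixed model fit\n")
  cat("  method:", x$method, "  n_obs:", x$n_obs,
      "  logLik:", format(x$loglik, digits = 6),
      "  converged:", x$converged, "\n")
  est <- data.frame(estimate = x$beta)
  if (!is.null(x$vcov)) {
    est$SE <- sqrt(diag(x$vcov))
    est$t <- est$estimate / est$SE
    est$p <- 2 * stats::pnorm(-abs(est$t))
  }
  print(round(est, 6))
  invisible(x)
}

#' Fit the dose-response linear mixed-effects model
#'
#' Fits `score ~ week * (group + total_hours) + baseline + age + sex +
#' chronicity` with correlated random intercepts and week slopes for
#' patient and (in pooled mode) for domain, via `lme4::lmer`. The crossed
#' patient and domain random effects are fitted directly. Reference
#' levels — group "1", sex "female", chronicity "chronic" — are fixed so
#' coefficients align with [reference_fixef()]. REML is the reporting
#' default; ML is used for likelihood-ratio tests on fixed effects.
#'
#' @param table analysis table from [assemble_long_table()] or
#'   [generate_lmm_dataset()].
#' @param per_domain when `TRUE` the domain random term is excluded (the
#'   single-domain analyses).
#' @param method `"REML"` (default) or `"ML"`.
#' @param control optional `lme4::lmerControl`.
#' @return a [lmm_fit()] object wrapping the `merMod` fit, with `beta`,
#'   `vcov`, `varcomps`, `loglik`, `n_obs` and `converged` filled in.
#'   Non-convergence yields a warning and `converged = FALSE`, never a
#'   silent failure.
#' @export
fit_lmm <- function(table, per_domain = FALSE, method = c("REML", "ML"),
                    control = NULL) {
  method <- match.arg(method)
  if (nrow(table) == 0) stop_invalid("analysis table is empty")
  table <- droplevels_keep(table)
  if (nlevels(droplevels(table$group)) < 2) {
    stop_invalid("need >= 2 dosage groups to fit the model")
  }
  X <- stats::model.matrix(
    ~ week * (group + total_hours) + baseline + age + sex + chronicity,
    data = table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("rank-deficient fixed-effect design; collinear column(s): ",
                 paste(bad, collapse = ", "))
  }
  fml <- if (per_domain) {
    score ~ week * (group + total_hours) + baseline + age + sex +
      chronicity + (1 + week | patient_id)
  } else {
    score ~ week * (group + total_hours) + baseline + age + sex +
      chronicity + (1 + week | patient_id) + (1 + week | domain_id)
  }
  if (is.null(control)) {
    control <- lme4::lmerControl(check.conv.singular = "ignore",
                                 check.scaleX = "ignore",
                                 calc.derivs = FALSE)
  }
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = table, REML = (method == "REML"),
               control = control),
    warning = function(w) {
      if (grepl("failed to converge|unable to evaluate", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })

  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  if (!conv) warning("mixed-model fit did not converge cleanly")

  vc <- lme4::VarCorr(fit)
  grab <- function(term) {
    if (!term %in% names(vc)) return(NULL)
    m <- vc[[term]]
    list(var_intercept = m[1, 1], var_slope = m[2, 2],
         corr = attr(m, "correlation")[1, 2])
  }
  varcomps <- list(sigma2 = attr(vc, "sc")^2,
                   patient = grab("patient_id"),
                   domain = grab("domain_id"))

  beta <- lme4::fixef(fit)
  lmm_fit(beta = beta, vcov = as.matrix(stats::vcov(fit)),
          varcomps = varcomps, loglik = as.numeric(stats::logLik(fit)),
          n_obs = nrow(table), converged = conv, method = method,
          model = fit, data = table)
}

# coerce character columns to the canonical factor levels (reference
# levels: group "1", sex "female", chronicity "chronic") and drop unused
# levels so the design keeps full rank
droplevels_keep <- function(table) {
  canon <- list(group = c("1", "2", "3", "4", "5+"),
                sex = c("female", "male", "not_specified"),
                chronicity = c("chronic", "acute"))
  for (col in names(canon)) {
    if (!is.factor(table[[col]])) {
      table[[col]] <- factor(table[[col]], levels = canon[[col]])
    }
    table[[col]] <- droplevels(table[[col]])
  }
  table
}

#' Compare two nested mixed-model fits
#'
#' Likelihood-ratio test of the larger model B against the nested model A,
#' with AIC/BIC deltas. Both fits must be by maximum likelihood when their
#' fixed effects differ (REML likelihoods are not comparable across
#' fixed-effect structures).
#'
#' @param fitA the smaller (nested) model.
#' @param fitB the larger model.
#' @param dfA,dfB parameter counts; taken from the underlying `merMod`
#'   objects when present.
#' @return list: `lrt`, `df`, `p`, `delta_aic`, `delta_bic`.
#' @export
compare_models <- function(fitA, fitB, dfA = NULL, dfB = NULL) {
  for (f in list(fitA, fitB)) {
    if (!inherits(f, "dose_lmm") || is.na(f$loglik)) {
      stop_invalid("compare_models needs fitted dose_lmm objects with log-likelihoods")
    }
  }
  npar <- function(f, df) {
    if (!is.null(df)) return(df)
    if (is.null(f$model)) stop_invalid("parameter count unavailable; supply dfA/dfB")
    attr(stats::logLik(f$model), "df")
  }
  kA <- npar(fitA, dfA); kB <- npar(fitB, dfB)
  if (kB < kA) stop_invalid("fitB must nest fitA (needs >= as many parameters)")
  fixed_differ <- !identical(names(fitA$beta), names(fitB$beta))
  if (fixed_differ && (fitA$method != "ML" || fitB$method != "ML")) {
    stop_invalid("fits with different fixed effects must both use ML")
  }
  lrt <- 2 * (fitB$loglik - fitA$loglik)
  df <- kB - kA
  p <- if (df == 0) 1 else stats::pchisq(lrt, df, lower.tail = FALSE)
  n <- fitB$n_obs
  aic <- function(f, k) -2 * f$loglik + 2 * k
  bic <- function(f, k) -2 * f$loglik + k * log(n)
  list(lrt = lrt, df = df, p = p,
       delta_aic = aic(fitB, kB) - aic(fitA, kA),
       delta_bic = bic(fitB, kB) - bic(fitA, kA))
}
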