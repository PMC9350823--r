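#' Pipeline configuration
#'
#' A fully serializable description of one analysis run: simulator
#' settings, cohort-preparation switches, model settings and the seed.
#' A run is reproducible from the config alone.
#'
#' @param sim a [sim_config()].
#' @param dosage_unit `"patient-domain"` or `"patient"`.
#' @param per_domain fit one model per domain (`TRUE`) or the pooled
#'   model with a domain random term (`FALSE`, default).
#' @param sigma_mode effect-size standardizer, `"residual"` or `"total"`.
#' @param alpha significance cutoff applied to Tukey-adjusted p-values in
#'   the rendered report.
#' @param seed root seed for the run; overrides `sim$rng_seed`.
#' @param verbose print stage progress.
#' @return a `pipeline_config` object (a list).
#' @export
pipeline_config <- function(sim = sim_config(),
                            dosage_unit = c("patient-domain", "patient"),
                            per_domain = FALSE,
                            sigma_mode = c("residual", "total"),
                            alpha = 0.05, seed = 1L, verbose = FALSE) {
  structure(
    list(sim = sim, dosage_unit = match.arg(dosage_unit),
         per_domain = per_domain, sigma_mode = match.arg(sigma_mode),
         alpha = alpha, seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "pipeline_config")
}

config_to_list <- function(config) {
  list(sim = unclass(config$sim), dosage_unit = config$dosage_unit,
       per_domain = config$per_domain, sigma_mode = config$sigma_mode,
       alpha = config$alpha, seed = config$seed)
}

#' Read / write a pipeline config as YAML
#'
#' @param path file path.
#' @param config a [pipeline_config()].
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns the path invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim[setdiff(names(x$sim), character())])
  pipeline_config(sim = sim, dosage_unit = x$dosage_unit,
                  per_domain = isTRUE(x$per_domain),
                  sigma_mode = x$sigma_mode, alpha = x$alpha, seed = x$seed)
}

stage_msg <- function(config, log, ...) {
  line <- paste0(format(length(log) + 1), ". ", ...)
  if (config$verbose) message(line)
  c(log, line)
}

#' Run the full dose-response pipeline
#'
#' Executes simulate -> score -> prepare -> fit -> report and writes every
#' intermediate and final table as CSV into `out_dir`, together with a
#' manifest (config hash, seed, per-stage row counts, convergence flags)
#' and a plain-text log. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if absent.
#' @return invisibly, a list with the in-memory stage results
#'   (`sessions`, `profiles`, `weekly`, `table`, `fit`, `contrasts`,
#'   `emm0`, `emm9`, `effects`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("config must be a pipeline_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  stage <- "simulate"
  res <- tryCatch({
    config$sim$rng_seed <- config$seed
    catalogs <- make_task_catalog(config$sim$n_domains, config$sim$L,
                                  config$sim$difficulty_step)
    cohort <- simulate_cohort(config$sim, catalogs)
    write_table_csv(cohort$sessions, file.path(out_dir, "sessions.csv"))
    write_table_csv(cohort$profiles, file.path(out_dir, "profiles.csv"))
    log <- stage_msg(config, log, "simulate: ", nrow(cohort$sessions),
                     " session events, ", nrow(cohort$profiles), " patients")

    stage <- "score"
    weekly <- weekly_scores(cohort$sessions, catalogs)
    write_table_csv(weekly, file.path(out_dir, "weekly_scores.csv"))
    log <- stage_msg(config, log, "score: ", nrow(weekly), " weekly scores")

    stage <- "prepare"
    table <- assemble_long_table(cohort$sessions, cohort$profiles, catalogs,
                                 dosage_unit = config$dosage_unit)
    write_table_csv(table, file.path(out_dir, "analysis_table.csv"))
    log <- stage_msg(config, log, "prepare: ", nrow(table), " analysis rows, ",
                     nlevels(droplevels(table$group)), " dosage groups")

    stage <- "fit"
    fit <- fit_lmm(table, per_domain = config$per_domain)
    fe <- data.frame(term = names(fit$beta), estimate = fit$beta,
                     SE = sqrt(diag(fit$vcov)))
    fe$t <- fe$estimate / fe$SE
    fe$p <- 2 * stats::pnorm(-abs(fe$t))
    write_table_csv(fe, file.path(out_dir, "fixed_effects.csv"))
    write_table_csv(varcomps_table(fit$varcomps),
                    file.path(out_dir, "varcomps.csv"))
    log <- stage_msg(config, log, "fit: logLik ",
                     format(fit$loglik, digits = 8),
                     ", converged ", fit$converged)

    stage <- "report"
    contrasts <- slope_contrasts(fit)
    emm0 <- emm_contrasts(fit, 0)
    emm9 <- emm_contrasts(fit, 9)
    effects <- treatment_effect_size(fit, sigma_mode = config$sigma_mode)
    write_table_csv(contrasts, file.path(out_dir, "contrasts_slopes.csv"))
    write_table_csv(emm0, file.path(out_dir, "emm_contrasts_week0.csv"))
    write_table_csv(emm9, file.path(out_dir, "emm_contrasts_week9.csv"))
    write_table_csv(effects, file.path(out_dir, "effect_sizes.csv"))
    report <- render_tables(fe, contrasts, list(week0 = emm0, week9 = emm9),
                            effects, alpha = config$alpha)
    writeLines(report, file.path(out_dir, "report.txt"))
    log <- stage_msg(config, log, "report: ", nrow(contrasts),
                     " slope contrasts rendered")

    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
    manifest <- list(
      config_hash = unname(tools::md5sum(cfg_path)),
      seed = config$seed,
      rows = list(sessions = nrow(cohort$sessions),
                  weekly_scores = nrow(weekly),
                  analysis_table = nrow(table)),
      dosage_groups = as.list(table(table$group)),
      converged = fit$converged)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log, file.path(out_dir, "log.txt"))
    list(sessions = cohort$sessions, profiles = cohort$profiles,
         weekly = weekly, table = table, fit = fit, contrasts = contrasts,
         emm0 = emm0, emm9 = emm9, effects = effects, manifest = manifest)
  }, dosefreq_error = function(e) {
    stop_invalid("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e))
  })
  invisible(res)
}

varcomps_table <- function(vc) {
  rows <- list(data.frame(term = "residual", variance = vc$sigma2,
                          sd = sqrt(vc$sigma2), corr = NA_real_))
  for (term in c("patient", "domain")) {
    v <- vc[[term]]
    if (is.null(v)) next
    rows[[length(rows) + 1]] <- data.frame(
      term = paste0(term, c("_intercept", "_slope")),
      variance = c(v$var_intercept, v$var_slope),
      sd = sqrt(c(v$var_intercept, v$var_slope)),
      corr = c(NA_real_, v$corr))
  }
  do.call(rbind, rows)
}

fmt_p <- function(p) ifelse(is.na(p), "   NA",
                            ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))

#' Render publication-style result tables as text
#'
#' Formats the fixed-effect, slope-contrast, EMM-contrast and effect-size
#' tables with significance markers. Markers are applied only to
#' Tukey-adjusted p-values — unadjusted p-values are never presented as
#' adjusted.
#'
#' @param fixed fixed-effects data.frame (`term`, `estimate`, `SE`, `t`, `p`).
#' @param contrasts slope contrasts from [slope_contrasts()].
#' @param emms list with `week0` and `week9` contrast tables.
#' @param effects effect sizes from [treatment_effect_size()].
#' @param alpha significance cutoff for adjusted p-values.
#' @return character vector of report lines.
#' @export
render_tables <- function(fixed, contrasts, emms, effects, alpha = 0.05) {
  if (is.null(contrasts) || nrow(contrasts) == 0) {
    stop_invalid("no contrasts to render")
  }
  missing <- c("fixed", "emms", "effects")[c(is.null(fixed), is.null(emms),
                                             is.null(effects))]
  if (length(missing) > 0) {
    stop_invalid("missing input table(s): ", paste(missing, collapse = ", "))
  }
  lines <- c("Dose-response analysis report", "")
  lines <- c(lines, "Fixed effects (estimate, SE, t, two-sided asymptotic p):")
  lines <- c(lines, sprintf("  %-22s %10.3e %10.3e %7.2f  %s",
                            fixed$term, fixed$estimate, fixed$SE, fixed$t,
                            fmt_p(fixed$p)))
  ctab <- function(tab, title) {
    star <- ifelse(!is.na(tab$p_adjusted) & tab$p_adjusted < alpha, " *", "")
    c("", paste0(title, " (Tukey-adjusted, asymptotic df):"),
      sprintf("  %-9s %10.3e %10.3e %7.2f  %s%s",
              tab$contrast, tab$estimate, tab$SE, tab$t_ratio,
              fmt_p(tab$p_adjusted), star))
  }
  lines <- c(lines, ctab(contrasts, "Pairwise slope contrasts"))
  lines <- c(lines, ctab(emms$week0, "EMM contrasts at week 0"))
  lines <- c(lines, ctab(emms$week9, "EMM contrasts at week 9"))
  lines <- c(lines, "", "Standardized pre/post effect sizes:")
  lines <- c(lines, sprintf("  group %-3s d = %6.3f  (EMM %.3f -> %.3f, sigma %.3f)",
                            effects$group, effects$d, effects$emm_week0,
                            effects$emm_week9, effects$sigma))
  lines
}

#' Which domains show a significant dosage-frequency interaction
#'
#' Runs the per-domain model (domain random term excluded) for every
#' domain in the table and tests the week-by-group interaction with a
#' likelihood-ratio test (ML fits), reporting which domains are
#' significant at `alpha`.
#'
#' @param table analysis table covering several domains.
#' @param alpha significance cutoff.
#' @return data.frame `domain_id`, `lrt`, `df`, `p`, `significant`.
#' @export
per_domain_interactions <- function(table, alpha = 0.05) {
  doms <- unique(table$domain_id)
  rows <- lapply(doms, function(d) {
    sub <- table[table$domain_id == d, , drop = FALSE]
    full <- fit_lmm(sub, per_domain = TRUE, method = "ML")
    sub2 <- droplevels_keep(sub)
    red <- lme4::lmer(
      score ~ week + group + total_hours + week:total_hours + baseline +
        age + sex + chronicity + (1 + week | patient_id),
      data = sub2, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    cmp <- compare_models(
      lmm_fit(lme4::fixef(red), loglik = as.numeric(stats::logLik(red)),
              n_obs = nrow(sub), method = "ML", model = red),
      full)
    data.frame(domain_id = d, lrt = cmp$lrt, df = cmp$df, p = cmp$p,
               significant = cmp$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
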