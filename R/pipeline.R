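#' Analysis configuration
#'
#' Assembles the configuration driving [run_analysis()]. Can be built
#' directly or loaded from a YAML file with [read_analysis_config()].
#'
#' @param effects_path CSV of study effects ([read_study_table()] schema).
#' @param prevalence_path CSV of prevalence records (optional).
#' @param followup_path CSV of follow-up summaries (optional).
#' @param km_curve_path,km_risk_path Digitized KM inputs (optional; both or
#'   neither).
#' @param definitions Definitions to analyse; default: all present.
#' @param compare Character vector of length 2: the pair of definitions to
#'   compare (interaction test, threshold table, Bayes factors), or `NULL`.
#' @param prior A [prior_spec()] (or a list of overrides).
#' @param method Bayesian estimation method, `"quadrature"` or `"mcmc"`.
#' @param seed Integer seed for stochastic stages.
#' @param rounded_z Use 1.96 rather than the exact normal quantile.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(effects_path = NULL, prevalence_path = NULL,
                            followup_path = NULL, km_curve_path = NULL,
                            km_risk_path = NULL, definitions = NULL,
                            compare = NULL, prior = prior_spec(),
                            method = "quadrature", seed = 1L,
                            rounded_z = FALSE) {
  if (is.list(prior) && !inherits(prior, "prior_spec"))
    prior <- do.call(prior_spec, prior)
  if (!is.null(compare) && length(compare) != 2L)
    stop("'compare' must name exactly two definitions")
  if (xor(is.null(km_curve_path), is.null(km_risk_path)))
    stop("supply both km_curve_path and km_risk_path, or neither")
  structure(list(effects_path = effects_path,
                 prevalence_path = prevalence_path,
                 followup_path = followup_path,
                 km_curve_path = km_curve_path, km_risk_path = km_risk_path,
                 definitions = definitions, compare = compare,
                 prior = prior, method = method, seed = as.integer(seed),
                 rounded_z = rounded_z),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()] (`prior` may be a mapping of prior overrides).
#' @return An `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(analysis_config, raw)
}

run_stage <- function(report, name, expr) {
  report$stages[[name]] <- tryCatch({
    value <- force(expr)
    list(status = "ok", value = value)
  }, error = function(e) {
    message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    list(status = "not run", error = conditionMessage(e))
  })
  report
}

pooled_to_list <- function(p) {
  out <- unclass(p)
  out$weights <- NULL
  if (p$scale == "log_hr") {
    hr <- log_to_hr_ci(p$estimate, p$se, p$level)
    out$hr <- hr$hr
    out$hr_ci_low <- hr$ci_low
    out$hr_ci_high <- hr$ci_high
  }
  out
}

posterior_to_list <- function(b) {
  list(mu_mean = b$mu_mean, mu_sd = b$mu_sd,
       cri_low = b$cri_low, cri_high = b$cri_high,
       hr_mean = exp(b$mu_mean), hr_cri_low = exp(b$cri_low),
       hr_cri_high = exp(b$cri_high),
       tau_mean = b$tau_mean, tau2 = b$tau2, method = b$method)
}

#' Run the full evidence-synthesis pipeline
#'
#' Per definition: pooled prevalence (logit random-effects), frequentist
#' pooled hazard ratio (DerSimonian-Laird), Bayesian posterior, and Egger's
#' test (when at least three studies report the definition). For the
#' configured pair: the Altman-Bland interaction test, the symmetric
#' threshold-probability table, and Bayes factors with evidence
#' classification. When digitized KM inputs are configured, reconstructed
#' individual patient data are pooled and a univariable Cox model is fitted.
#' A failing stage is recorded as "not run" instead of aborting the bundle.
#'
#' @param config An [analysis_config()] or a path to a YAML config.
#' @return An object of class `"report_bundle"`: nested list with one entry
#'   per stage plus the config and package version.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (!inherits(config, "analysis_config")) stop("invalid config")
  report <- list(package = "pmimeta",
                 version = as.character(utils::packageVersion("pmimeta")),
                 seed = config$seed,
                 config = lapply(unclass(config), function(x)
                   if (inherits(x, "prior_spec")) unclass(x) else x),
                 stages = list())

  effects <- if (!is.null(config$effects_path))
    read_study_table(config$effects_path, "effects") else NULL
  defs <- config$definitions
  if (is.null(defs) && !is.null(effects)) defs <- unique(effects$definition)

  if (!is.null(config$prevalence_path)) {
    report <- run_stage(report, "prevalence", {
      prev <- read_study_table(config$prevalence_path, "prevalence")
      prev_defs <- if (is.null(config$definitions))
        unique(prev$definition) else config$definitions
      res <- lapply(prev_defs, function(d) {
        sub <- prev[prev$definition == d, ]
        if (nrow(sub) == 0L) return(NULL)
        pooled_to_list(pool_prevalence(sub$events, sub$n))
      })
      Filter(Negate(is.null), setNames(res, prev_defs))
    })
  }

  if (!is.null(effects)) {
    report <- run_stage(report, "frequentist_hr", {
      res <- lapply(defs, function(d) {
        sub <- effects[effects$definition == d, ]
        if (nrow(sub) == 0L) return(NULL)
        pooled_to_list(dersimonian_laird(sub$log_hr, sub$se_log_hr,
                                         rounded_z = config$rounded_z))
      })
      Filter(Negate(is.null), setNames(res, defs))
    })
    report <- run_stage(report, "bayesian_hr", {
      res <- lapply(defs, function(d) {
        sub <- effects[effects$definition == d, ]
        if (nrow(sub) == 0L) return(NULL)
        fit <- fit_bayes_re(sub$log_hr, sub$se_log_hr, config$prior,
                            method = config$method, seed = config$seed)
        out <- posterior_to_list(fit)
        bf <- bayes_factor(sub$log_hr, sub$se_log_hr, config$prior)
        out$bf10 <- bf
        out$evidence <- classify_bf(bf)$evidence
        out
      })
      Filter(Negate(is.null), setNames(res, defs))
    })
    report <- run_stage(report, "egger", {
      res <- lapply(defs, function(d) {
        sub <- effects[effects$definition == d, ]
        if (nrow(sub) < 3L) return(NULL)
        egger_test(sub$log_hr, sub$se_log_hr)
      })
      Filter(Negate(is.null), setNames(res, defs))
    })
  }

  if (!is.null(config$compare) && !is.null(effects)) {
    a <- config$compare[1]; b <- config$compare[2]
    sub_a <- effects[effects$definition == a, ]
    sub_b <- effects[effects$definition == b, ]
    if (nrow(sub_a) && nrow(sub_b)) {
      report <- run_stage(report, "comparison", {
        fa <- dersimonian_laird(sub_a$log_hr, sub_a$se_log_hr)
        fb <- dersimonian_laird(sub_b$log_hr, sub_b$se_log_hr)
        ba <- fit_bayes_re(sub_a$log_hr, sub_a$se_log_hr, config$prior,
                           seed = config$seed)
        bb <- fit_bayes_re(sub_b$log_hr, sub_b$se_log_hr, config$prior,
                           seed = config$seed)
        it <- interaction_test(fa, fb)
        list(interaction = unclass(it),
             thresholds = compare_definitions(ba, bb, names = c(a, b)))
      })
    }
  }

  if (!is.null(config$km_curve_path)) {
    report <- run_stage(report, "km_reconstruction", {
      pairs <- read_km_tables(config$km_curve_path, config$km_risk_path)
      ipd <- do.call(rbind, lapply(pairs, function(p)
        reconstruct_ipd(p$curve, p$risk)))
      cox <- cox_univariable(ipd)
      km <- lapply(split(ipd, ipd$group), km_estimate)
      list(cox = cox, n = nrow(ipd), n_events = sum(ipd$event),
           km = km, ipd = ipd)
    })
  }

  class(report) <- "report_bundle"
  report
}

#' Serialize a report bundle
#'
#' Writes `report.json` (full precision) and `report.md` (rounded the way
#' clinical meta-analyses print: HRs and CIs at 2 decimals, probabilities at
#' 1 decimal in percent, heterogeneity \eqn{\tau^2} at 3 decimals), plus a
#' CSV per pooled table. Every number in the markdown is taken from the JSON
#' content.
#'
#' @param report A `"report_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- report
  if (!is.null(json$stages$km_reconstruction$value$ipd)) {
    ipd <- json$stages$km_reconstruction$value$ipd
    write.csv(ipd, file.path(dir, "reconstructed_ipd.csv"),
              row.names = FALSE)
    json$stages$km_reconstruction$value$ipd <- NULL
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  md <- c("# Evidence-synthesis report",
          sprintf("pmimeta %s, seed %d", report$version, report$seed), "")
  fmt_hr <- function(x)
    sprintf("%.2f [%.2f, %.2f]", x$hr, x$ci_low, x$ci_high)
  st <- report$stages
  if (!is.null(st$prevalence) && st$prevalence$status == "ok") {
    md <- c(md, "## Pooled prevalence", "",
            "| definition | k | prevalence | 95% CI | I2 | tau2 |",
            "|---|---|---|---|---|---|")
    for (d in names(st$prevalence$value)) {
      p <- st$prevalence$value[[d]]
      md <- c(md, sprintf("| %s | %d | %.1f%% | %.1f-%.1f%% | %.1f%% | %.3f |",
                          d, p$k, p$prevalence, p$prev_ci_low,
                          p$prev_ci_high, p$i2, p$tau2))
    }
    md <- c(md, "")
  }
  if (!is.null(st$frequentist_hr) && st$frequentist_hr$status == "ok") {
    md <- c(md, "## Pooled hazard ratios (frequentist, DerSimonian-Laird)",
            "", "| definition | k | HR [95% CI] | I2 | tau2 |",
            "|---|---|---|---|---|")
    for (d in names(st$frequentist_hr$value)) {
      p <- st$frequentist_hr$value[[d]]
      md <- c(md, sprintf("| %s | %d | %.2f [%.2f, %.2f] | %.1f%% | %.3f |",
                          d, p$k, p$hr, p$hr_ci_low, p$hr_ci_high,
                          p$i2, p$tau2))
    }
    md <- c(md, "")
  }
  if (!is.null(st$bayesian_hr) && st$bayesian_hr$status == "ok") {
    md <- c(md, "## Pooled hazard ratios (Bayesian random-effects)", "",
            "| definition | mean HR | 95% CrI | tau2 | BF10 | evidence |",
            "|---|---|---|---|---|---|")
    for (d in names(st$bayesian_hr$value)) {
      p <- st$bayesian_hr$value[[d]]
      md <- c(md, sprintf("| %s | %.2f | %.2f-%.2f | %.3f | %.3g | %s |",
                          d, p$hr_mean, p$hr_cri_low, p$hr_cri_high,
                          p$tau2, p$bf10, gsub("_", " ", p$evidence)))
    }
    md <- c(md, "")
  }
  if (!is.null(st$comparison) && st$comparison$status == "ok") {
    cmp <- st$comparison$value
    md <- c(md, "## Definition comparison", "",
            sprintf("Interaction test: z = %.3f, p = %.3f",
                    cmp$interaction$z, cmp$interaction$p), "",
            "Posterior threshold probabilities (%):", "")
    tt <- cmp$thresholds
    md <- c(md, paste0("| threshold | ", names(tt)[3], " | ",
                       names(tt)[4], " |"), "|---|---|---|")
    for (i in seq_len(nrow(tt)))
      md <- c(md, sprintf("| %s | %.1f | %.1f |",
                          tt$threshold[i], tt[[3]][i], tt[[4]][i]))
    write.csv(tt, file.path(dir, "threshold_table.csv"), row.names = FALSE)
    md <- c(md, "")
  }
  if (!is.null(st$egger) && st$egger$status == "ok") {
    md <- c(md, "## Small-study effects (Egger's regression)", "",
            "| definition | intercept | t | p |", "|---|---|---|---|")
    for (d in names(st$egger$value)) {
      e <- st$egger$value[[d]]
      md <- c(md, sprintf("| %s | %.3f | %.3f | %.3f |",
                          d, e$intercept, e$t, e$p))
    }
    md <- c(md, "")
  }
  if (!is.null(st$km_reconstruction) &&
      st$km_reconstruction$status == "ok") {
    cx <- st$km_reconstruction$value$cox
    md <- c(md, "## Reconstructed individual patient data", "",
            sprintf("Pooled univariable Cox HR (PMI vs no PMI): %s (n = %d, events = %d)",
                    fmt_hr(cx), st$km_reconstruction$value$n,
                    st$km_reconstruction$value$n_events), "")
  }
  md <- c(md,
    "_Pooled follow-up SDs, where shown, use the pooled-variance decomposition combining within- and between-study dispersion._")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
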