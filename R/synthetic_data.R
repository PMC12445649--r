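#' Simulation configuration
#'
#' Defines the generating process used to exercise every stage of the
#' pipeline without external data. Defaults emulate a realistic CABG
#' meta-analysis of the kind the package targets: 8 studies, a true pooled
#' log hazard ratio of 0.86 with heterogeneity SD 0.36 (the scale of the
#' published UDMI-3/4 analysis), per-study standard errors between 0.15 and
#' 0.45, a rare-event prevalence around 3% with substantial between-study
#' spread on the logit scale, study sizes between 150 and 4800 patients, and
#' two-group exponential survival (true HR 2) with administrative censoring
#' at 5 years.
#'
#' @param k Number of studies.
#' @param mu_true True pooled log hazard ratio.
#' @param tau_true True between-study SD of the log hazard ratio (>= 0).
#' @param se_range Range (lo, hi) of per-study standard errors.
#' @param prev_logit_mean,prev_logit_sd Mean and SD of the study-level
#'   prevalence on the logit scale.
#' @param n_range Integer range of study sizes.
#' @param surv_n_per_group Subjects per arm in the survival generator.
#' @param hr_true True hazard ratio of the PMI arm.
#' @param base_hazard Control-arm exponential hazard (events/year).
#' @param censor_time Administrative censoring time (years).
#' @param dropout_rate Fraction censored uniformly before `censor_time`.
#' @param seed Integer seed; each generator derives an independent
#'   substream from it (fixed offsets), so adding a generator never perturbs
#'   existing output.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(k = 8L, mu_true = 0.86, tau_true = 0.36,
                       se_range = c(0.15, 0.45),
                       prev_logit_mean = qlogis(0.032), prev_logit_sd = 1.0,
                       n_range = c(150L, 4800L),
                       surv_n_per_group = 500L, hr_true = 2,
                       base_hazard = 0.08, censor_time = 5,
                       dropout_rate = 0.1, seed = 1L) {
  stopifnot(k >= 1, tau_true >= 0, se_range[1] > 0,
            se_range[1] <= se_range[2], prev_logit_sd >= 0,
            n_range[1] >= 1, n_range[1] <= n_range[2],
            surv_n_per_group >= 2, hr_true > 0, base_hazard > 0,
            censor_time > 0, dropout_rate >= 0, dropout_rate < 1)
  structure(list(k = as.integer(k), mu_true = mu_true, tau_true = tau_true,
                 se_range = se_range, prev_logit_mean = prev_logit_mean,
                 prev_logit_sd = prev_logit_sd,
                 n_range = as.integer(n_range),
                 surv_n_per_group = as.integer(surv_n_per_group),
                 hr_true = hr_true, base_hazard = base_hazard,
                 censor_time = censor_time, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# substream offsets keep the generators independent under one global seed
SIM_STREAM <- c(effects = 101L, prevalence = 202L, survival = 303L)

#' Simulate study-level hazard-ratio effects
#'
#' Draws study effects from the hierarchical normal model the analysis
#' assumes: \eqn{\theta_i \sim N(\mu, \tau^2)},
#' \eqn{se_i \sim U(\mathrm{se\_range})},
#' \eqn{y_i \sim N(\theta_i, se_i^2)}, then expresses each study as the
#' published form (HR with a 95% CI).
#'
#' @param cfg A [sim_config()].
#' @param definition Definition label attached to the records.
#' @return A `data.frame` in the effects schema of [read_study_table()]
#'   (plus `log_hr`, `se_log_hr`), with the true `theta` as an attribute.
#' @export
simulate_effects <- function(cfg, definition = "UDMI34") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + SIM_STREAM[["effects"]])
  theta <- rnorm(cfg$k, cfg$mu_true, cfg$tau_true)
  se <- runif(cfg$k, cfg$se_range[1], cfg$se_range[2])
  y <- rnorm(cfg$k, theta, se)
  n <- sample(seq(cfg$n_range[1], cfg$n_range[2]), cfg$k, replace = TRUE)
  z <- ci_z(0.95)
  out <- data.frame(study_id = sprintf("sim%02d", seq_len(cfg$k)),
                    definition = definition,
                    hr = exp(y), ci_low = exp(y - z * se),
                    ci_high = exp(y + z * se),
                    adjusted = FALSE, n = n,
                    log_hr = y, se_log_hr = se,
                    stringsAsFactors = FALSE)
  attr(out, "theta") <- theta
  class(out) <- c("pmi_effects", class(out))
  out
}

#' Simulate study-level prevalence records
#'
#' Logit-normal prevalence model: study-level logit prevalences
#' \eqn{l_i \sim N(\mathrm{prev\_logit\_mean}, \mathrm{prev\_logit\_sd}^2)},
#' sizes uniform over `n_range`, events binomial.
#'
#' @param cfg A [sim_config()].
#' @param definition Definition label attached to the records.
#' @return A `data.frame` in the prevalence schema of [read_study_table()].
#' @export
simulate_prevalence <- function(cfg, definition = "UDMI34") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + SIM_STREAM[["prevalence"]])
  l <- rnorm(cfg$k, cfg$prev_logit_mean, cfg$prev_logit_sd)
  n <- sample(seq(cfg$n_range[1], cfg$n_range[2]), cfg$k, replace = TRUE)
  events <- rbinom(cfg$k, n, plogis(l))
  out <- data.frame(study_id = sprintf("sim%02d", seq_len(cfg$k)),
                    definition = definition, events = events, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("pmi_prevalence", class(out))
  out
}

#' Simulate two-group survival data with a digitizable KM curve
#'
#' Generates exponential event times for a control (`no_PMI`) arm with
#' hazard `base_hazard` and a `PMI` arm with hazard
#' `base_hazard * hr_true`, censored administratively at `censor_time` with
#' additional uniform dropout. Returns the exact individual patient data
#' together with, per arm, the exact KM step curve sampled at `n_points`
#' times (emulating digitization) and a numbers-at-risk table every
#' `risk_interval` years -- the inputs the reconstruction stage consumes.
#'
#' @param cfg A [sim_config()].
#' @param n_points Number of digitized curve points per arm.
#' @param risk_interval Spacing of the risk table (years).
#' @param study_id Study label.
#' @return A list with components `ipd` (data frame `time`, `event`,
#'   `group`, `study_id`), `curves` (list of [clean_curve()] objects per
#'   arm) and `risk` (list of [risk_table()] objects per arm).
#' @export
simulate_survival <- function(cfg, n_points = 200L, risk_interval = 1,
                              study_id = "sim_surv") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + SIM_STREAM[["survival"]])
  n <- cfg$surv_n_per_group
  gen_arm <- function(hazard, group) {
    ev <- rexp(n, hazard)
    cens <- rep(cfg$censor_time, n)
    drop <- runif(n) < cfg$dropout_rate
    cens[drop] <- runif(sum(drop), 0, cfg$censor_time)
    data.frame(time = pmin(ev, cens), event = ev <= cens,
               group = group, study_id = study_id,
               stringsAsFactors = FALSE)
  }
  ipd <- rbind(gen_arm(cfg$base_hazard, "no_PMI"),
               gen_arm(cfg$base_hazard * cfg$hr_true, "PMI"))
  digitize_arm <- function(group) {
    arm <- ipd[ipd$group == group, ]
    km <- km_estimate(arm)
    tmax <- max(arm$time)
    tt <- seq(0, tmax, length.out = n_points)
    clean_curve(tt, step_survival(km, tt), group, study_id)
  }
  risk_arm <- function(group) {
    arm <- ipd[ipd$group == group, ]
    tt <- seq(0, cfg$censor_time, by = risk_interval)
    at_risk <- vapply(tt, function(x) sum(arm$time >= x), integer(1))
    risk_table(tt, at_risk, total_events = sum(arm$event))
  }
  groups <- c("no_PMI", "PMI")
  list(ipd = ipd,
       curves = setNames(lapply(groups, digitize_arm), groups),
       risk = setNames(lapply(groups, risk_arm), groups))
}

#' Write a full synthetic fixture to disk
#'
#' Writes the three CSV schemas (effects, prevalence, KM curve + risk table)
#' plus a JSON manifest of the true generating parameters.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  eff <- simulate_effects(cfg)
  prev <- simulate_prevalence(cfg)
  surv <- simulate_survival(cfg)
  write_study_table(eff, file.path(dir, "studies_effects.csv"))
  write_study_table(prev, file.path(dir, "studies_prevalence.csv"))
  curves <- do.call(rbind, lapply(surv$curves, function(cv)
    data.frame(study_id = cv$study_id, group = cv$group,
               time = cv$time, survival = cv$survival)))
  risks <- do.call(rbind, lapply(surv$risk, function(rk)
    data.frame(study_id = "sim_surv", group = NA, time = rk$time,
               at_risk = rk$at_risk)))
  risks$group <- rep(names(surv$risk), vapply(surv$risk,
                                              function(r) length(r$time),
                                              integer(1)))
  write.csv(curves, file.path(dir, "km_curve.csv"), row.names = FALSE)
  write.csv(risks, file.path(dir, "km_risk.csv"), row.names = FALSE)
  manifest <- unclass(cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
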