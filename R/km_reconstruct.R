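#' Clean a digitized Kaplan-Meier curve
#'
#' Digitized curve coordinates carry click jitter: points may be slightly out
#' of order, survival may exceed [0, 1] or rise by a pixel. Cleaning sorts by
#' time, averages duplicate times, clamps survival to [0, 1], enforces
#' monotone non-increase by running-minimum clipping, and prepends the
#' anchor point (0, 1) when absent.
#'
#' @param time,survival Numeric vectors of digitized coordinates (years,
#'   survival fraction).
#' @param group Group label, `"PMI"` or `"no_PMI"`.
#' @param study_id Study identifier.
#' @return An object of class `"digitized_curve"`: list with `time`,
#'   `survival`, `group`, `study_id`.
#' @export
clean_curve <- function(time, survival, group = c("PMI", "no_PMI"),
                        study_id = "study") {
  group <- match.arg(group)
  if (length(time) != length(survival)) stop("coordinate lengths differ")
  keep <- is.finite(time) & is.finite(survival)
  time <- time[keep]; survival <- survival[keep]
  if (length(time) < 2L && !(length(time) == 1L && time[1] > 0))
    stop("need at least two curve points")
  o <- order(time)
  time <- time[o]; survival <- survival[o]
  # average duplicate times
  if (anyDuplicated(time)) {
    survival <- tapply(survival, time, mean)
    time <- as.numeric(names(survival))
    survival <- as.numeric(survival)
  }
  survival <- pmin(1, pmax(0, survival))
  survival <- cummin(survival)
  if (time[1] > 0) {
    time <- c(0, time)
    survival <- c(1, survival)
  } else {
    survival[1] <- 1
    survival <- cummin(survival)
  }
  if (length(time) < 2L) stop("degenerate curve: only the anchor point")
  structure(list(time = time, survival = survival, group = group,
                 study_id = study_id),
            class = "digitized_curve")
}

#' Risk table accompanying a digitized curve
#'
#' @param time Times (years) at which numbers at risk are printed; the first
#'   entry must be 0 and carries the group's sample size.
#' @param at_risk Non-increasing integer counts.
#' @param total_events Optional reported total number of events.
#' @return An object of class `"risk_table"`.
#' @export
risk_table <- function(time, at_risk, total_events = NULL) {
  if (length(time) != length(at_risk)) stop("lengths differ")
  if (length(time) < 2L) stop("risk table needs at least 2 entries")
  o <- order(time)
  time <- time[o]; at_risk <- at_risk[o]
  if (time[1] != 0) stop("first risk-table entry must be at time 0")
  if (any(diff(at_risk) > 0))
    stop(sprintf("at-risk counts increase at time %g",
                 time[which(diff(at_risk) > 0)[1] + 1L]))
  if (any(at_risk < 0)) stop("negative at-risk count")
  structure(list(time = time, at_risk = as.integer(round(at_risk)),
                 total_events = total_events),
            class = "risk_table")
}

#' Reconstruct individual patient data from a KM curve and risk table
#'
#' Interval solver in the Guyot family: within each risk-table interval, an
#' initial censoring count is guessed from the mismatch between the curve's
#' survival drop and the decline in numbers at risk, censoring times are
#' spread uniformly over the interval, event counts at each digitized step
#' are recovered from the survival ratios, and the censoring count is
#' adjusted iteratively until the reconstructed number at risk matches the
#' printed value at the next risk time. After the last risk time, remaining
#' subjects are administratively censored at the final curve time; when the
#' reported total event count is supplied, a final pass searches the
#' last-interval censoring count that matches it.
#'
#' @param curve A [clean_curve()] result.
#' @param risk A [risk_table()].
#' @return An object of class `"reconstructed_ipd"`: a `data.frame` with
#'   columns `time`, `event` (logical), `group`, `study_id`; one row per
#'   subject initially at risk.
#' @export
reconstruct_ipd <- function(curve, risk) {
  if (!inherits(curve, "digitized_curve")) stop("'curve' must be cleaned")
  if (!inherits(risk, "risk_table")) stop("'risk' must be a risk_table")
  t <- curve$time; S <- curve$survival
  K <- length(t)
  trisk <- risk$time; nrisk <- risk$at_risk
  nint <- length(trisk)
  if (max(trisk) > max(t) + 1e-9)
    stop("risk table extends beyond the digitized curve")
  # lower[i]: first curve index at or after trisk[i]
  lower <- vapply(trisk, function(tt) which(t >= tt - 1e-9)[1], integer(1))
  if (anyNA(lower)) stop("risk times not covered by the curve")

  solve_interval <- function(i, n_enter, km_enter, ncen_guess) {
    # returns event/censor placements for clicks lower[i] .. (lower[i+1]-1)
    k_lo <- lower[i]
    k_hi <- if (i < nint) lower[i + 1L] - 1L else K
    t_end <- if (i < nint) trisk[i + 1L] else max(t) + 1e-9
    ncen <- max(0L, ncen_guess)
    best <- NULL
    for (iter in 1:40) {
      cen_t <- if (ncen > 0)
        trisk[i] + seq_len(ncen) * (t_end - trisk[i]) / (ncen + 1)
      else numeric(0)
      nhat <- n_enter
      km <- km_enter
      d <- integer(k_hi - k_lo + 1L)
      cen <- integer(k_hi - k_lo + 1L)
      for (k in k_lo:k_hi) {
        j <- k - k_lo + 1L
        if (km > 0 && nhat > 0) {
          d[j] <- min(nhat, max(0L, round(nhat * (1 - S[k] / km))))
          if (d[j] > 0) km <- km * (1 - d[j] / nhat)
        }
        t_next <- if (k < K) t[k + 1L] else Inf
        cen[j] <- sum(cen_t >= t[k] - 1e-12 & cen_t < min(t_next, t_end))
        nhat <- nhat - d[j] - cen[j]
      }
      res <- list(d = d, cen = cen, cen_t = cen_t, n_exit = nhat,
                  km_exit = km, ncen = ncen)
      if (i == nint) return(res)
      gap <- nhat - nrisk[i + 1L]
      if (gap == 0L) return(res)
      best <- res
      ncen_new <- min(n_enter, max(0L, ncen + gap))
      if (ncen_new == ncen) return(best)
      ncen <- ncen_new
    }
    best
  }

  run_all <- function(last_ncen_guess = 0L) {
    rec_time <- numeric(0); rec_event <- logical(0)
    n_enter <- nrisk[1]; km_enter <- 1
    total_d <- 0L
    for (i in seq_len(nint)) {
      k_lo <- lower[i]
      guess <- if (i < nint) {
        # censorings implied by at-risk decline not explained by the curve
        s_ratio <- S[lower[i + 1L]] / max(km_enter, 1e-12)
        round(n_enter * s_ratio) - nrisk[i + 1L]
      } else last_ncen_guess
      sol <- solve_interval(i, n_enter, km_enter, guess)
      k_hi <- if (i < nint) lower[i + 1L] - 1L else K
      ev_times <- rep(t[k_lo:k_hi], sol$d)
      if (i < nint && sol$n_exit < nrisk[i + 1L]) {
        # integer rounding overshot the events an interval can hold:
        # return the excess subjects to the risk set
        deficit <- nrisk[i + 1L] - sol$n_exit
        if (deficit > length(ev_times))
          stop(sprintf("infeasible risk table in interval [%g, %g): implies negative counts",
                       trisk[i], trisk[i + 1L]))
        ev_times <- ev_times[seq_len(length(ev_times) - deficit)]
        sol$n_exit <- sol$n_exit + deficit
      }
      rec_time <- c(rec_time, ev_times, sol$cen_t)
      rec_event <- c(rec_event, rep(TRUE, length(ev_times)),
                     rep(FALSE, length(sol$cen_t)))
      total_d <- total_d + sum(ev_times > 0)
      if (i < nint && sol$n_exit != nrisk[i + 1L]) {
        # force consistency: residual subjects censored at the boundary
        resid <- sol$n_exit - nrisk[i + 1L]
        if (resid < 0)
          stop(sprintf("infeasible risk table in interval [%g, %g): implies negative counts",
                       trisk[i], trisk[i + 1L]))
        rec_time <- c(rec_time, rep(trisk[i + 1L] * (1 - 1e-9), resid))
        rec_event <- c(rec_event, rep(FALSE, resid))
        sol$n_exit <- nrisk[i + 1L]
      }
      n_enter <- sol$n_exit
      km_enter <- sol$km_exit
    }
    # administrative censoring of survivors at the end of the curve
    if (n_enter > 0) {
      rec_time <- c(rec_time, rep(max(t), n_enter))
      rec_event <- c(rec_event, rep(FALSE, n_enter))
    }
    list(time = rec_time, event = rec_event, total_d = total_d)
  }

  out <- run_all(0L)
  if (!is.null(risk$total_events) && out$total_d != risk$total_events) {
    # rescaling pass: search last-interval censoring matching total events
    best <- out
    for (g in seq_len(nrisk[nint])) {
      cand <- run_all(g)
      if (abs(cand$total_d - risk$total_events) <
          abs(best$total_d - risk$total_events)) best <- cand
      if (cand$total_d <= risk$total_events) break
    }
    out <- best
  }
  ipd <- data.frame(time = out$time, event = out$event,
                    group = curve$group, study_id = curve$study_id,
                    stringsAsFactors = FALSE)
  ipd <- ipd[order(ipd$time, -as.integer(ipd$event)), , drop = FALSE]
  rownames(ipd) <- NULL
  ipd$time <- pmax(ipd$time, .Machine$double.eps)
  class(ipd) <- c("reconstructed_ipd", class(ipd))
  ipd
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' data frame, for plotting or sup-norm comparison against a digitized curve.
#'
#' @param ipd A data frame with columns `time` and `event` (logical/0-1).
#' @return A data frame with columns `time` and `survival`, starting at
#'   `(0, 1)`.
#' @export
km_estimate <- function(ipd) {
  if (NROW(ipd) == 0L) stop("empty data")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ipd))
  data.frame(time = c(0, fit$time), survival = c(1, fit$surv))
}

# evaluate a right-continuous step curve at arbitrary times
step_survival <- function(km, times) {
  idx <- findInterval(times, km$time)
  idx[idx < 1L] <- 1L
  km$survival[idx]
}

#' Univariable Cox regression on (pooled) reconstructed IPD
#'
#' Fits the single-covariate Cox proportional hazards model (PMI vs no PMI)
#' by partial likelihood via [survival::coxph()], with the Efron tie
#' correction by default (reconstruction groups events at digitized step
#' times, so ties are common). A Wald confidence interval is reported on the
#' log scale.
#'
#' @param ipd Data frame with columns `time`, `event`, `group` (and
#'   optionally `study_id`), e.g. pooled [reconstruct_ipd()] output.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param stratify_by_study Stratify the baseline hazard by `study_id`.
#' @param level Confidence level.
#' @return A list with `hr`, `ci_low`, `ci_high`, `log_hr`, `se`, `n`,
#'   `n_events`.
#' @export
cox_univariable <- function(ipd, ties = c("efron", "breslow"),
                            stratify_by_study = FALSE, level = 0.95) {
  ties <- match.arg(ties)
  ipd <- as.data.frame(ipd)
  if (!all(c("time", "event", "group") %in% names(ipd)))
    stop("'ipd' must have columns time, event, group")
  ipd$group <- factor(ipd$group, levels = c("no_PMI", "PMI"))
  if (any(table(ipd$group) == 0L))
    stop("both groups must be present")
  if (sum(ipd$event) < 1L) stop("no events observed")
  fml <- if (stratify_by_study)
    survival::Surv(time, event) ~ group + survival::strata(study_id)
  else survival::Surv(time, event) ~ group
  fit <- survival::coxph(fml, data = ipd, ties = ties)
  b <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  z <- ci_z(level)
  list(hr = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
       log_hr = b, se = se, n = nrow(ipd), n_events = sum(ipd$event))
}

#' Read digitized curve and risk-table CSVs
#'
#' `km_curve.csv` schema: `study_id, group, time, survival`;
#' `km_risk.csv` schema: `study_id, group, time, at_risk`.
#'
#' @param curve_path,risk_path CSV paths.
#' @return A list of `list(curve, risk)` pairs, one per
#'   (study, group) combination present in both files.
#' @export
read_km_tables <- function(curve_path, risk_path) {
  cv <- read.csv(curve_path, stringsAsFactors = FALSE)
  rk <- read.csv(risk_path, stringsAsFactors = FALSE)
  need_cv <- c("study_id", "group", "time", "survival")
  need_rk <- c("study_id", "group", "time", "at_risk")
  if (!all(need_cv %in% names(cv))) stop("curve file: wrong schema")
  if (!all(need_rk %in% names(rk))) stop("risk file: wrong schema")
  keys <- unique(cv[c("study_id", "group")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sid <- keys$study_id[i]; grp <- keys$group[i]
    ci <- cv[cv$study_id == sid & cv$group == grp, ]
    ri <- rk[rk$study_id == sid & rk$group == grp, ]
    if (nrow(ri) < 2L)
      stop(sprintf("no risk table for study %s group %s", sid, grp))
    list(curve = clean_curve(ci$time, ci$survival, grp, sid),
         risk = risk_table(ri$time, ri$at_risk))
  })
  names(out) <- paste(keys$study_id, keys$group, sep = ".")
  out
}
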