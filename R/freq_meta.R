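#' DerSimonian-Laird random-effects pooling
#'
#' Pools study-level effects with inverse-variance weights and the
#' moment-based DerSimonian-Laird estimate of the between-study variance
#' \eqn{\tau^2}. With fixed-effect weights \eqn{w_i = 1/se_i^2},
#' \deqn{Q = \sum w_i (y_i - \bar y_{FE})^2, \quad
#'   C = \sum w_i - \sum w_i^2 / \sum w_i, \quad
#'   \tau^2 = \max\{0, (Q - (k-1))/C\},}
#' after which random-effects weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)} give
#' the pooled estimate, its standard error \eqn{1/\sqrt{\sum w_i^*}}, and a
#' Wald confidence interval. \eqn{I^2 = \max\{0, (Q - df)/Q\} \cdot 100}.
#'
#' @param y Numeric vector of study effects (e.g. log hazard ratios).
#' @param se Positive standard errors, same length as `y`.
#' @param scale Label for the analysis scale, `"log_hr"` or `"logit"`.
#' @param level Confidence level for the Wald interval.
#' @param rounded_z Use 1.96 instead of the exact normal quantile.
#' @return An object of class `"pooled_result"`: a list with `k`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `Q`, `df`, `tau2`, `i2` (percent), `scale`,
#'   `level`, and the per-study random-effects `weights` (normalized to
#'   percentages).
#' @examples
#' dersimonian_laird(c(0.1, 0.5, 0.9), c(0.2, 0.2, 0.2))
#' @export
dersimonian_laird <- function(y, se, scale = c("log_hr", "logit"),
                              level = 0.95, rounded_z = FALSE) {
  scale <- match.arg(scale)
  if (length(y) == 0L) stop("no study effects supplied")
  if (length(y) != length(se)) stop("'y' and 'se' must have equal length")
  if (any(!is.finite(y)) || any(!is.finite(se))) stop("non-finite inputs")
  if (any(se <= 0)) stop("all standard errors must be positive")
  k <- length(y)
  w <- 1 / se^2
  yfe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yfe)^2)
  df <- k - 1L
  if (k > 1L) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    i2 <- max(0, (Q - df) / Q) * 100
  } else {
    tau2 <- 0
    i2 <- 0
  }
  wstar <- 1 / (se^2 + tau2)
  est <- sum(wstar * y) / sum(wstar)
  se_pooled <- 1 / sqrt(sum(wstar))
  z <- ci_z(level, rounded_z)
  structure(list(k = k, estimate = est, se = se_pooled,
                 ci_low = est - z * se_pooled, ci_high = est + z * se_pooled,
                 Q = Q, df = df, tau2 = tau2, i2 = i2,
                 scale = scale, level = level,
                 weights = 100 * wstar / sum(wstar)),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects pooling (DerSimonian-Laird), k = %d studies\n",
              x$k))
  cat(sprintf("  estimate (%s): %.*f  [%.*f, %.*f]  (%.0f%% CI)\n",
              x$scale, digits, x$estimate, digits, x$ci_low,
              digits, x$ci_high, 100 * x$level))
  if (x$scale == "log_hr") {
    hr <- log_to_hr_ci(x$estimate, x$se, x$level)
    cat(sprintf("  HR: %.2f [%.2f, %.2f]\n", hr$hr, hr$ci_low, hr$ci_high))
  }
  if (!is.null(x$prevalence))
    cat(sprintf("  prevalence: %.1f%% [%.1f%%, %.1f%%]\n",
                x$prevalence, x$prev_ci_low, x$prev_ci_high))
  cat(sprintf("  Q = %.*f (df = %d), tau^2 = %.*f, I^2 = %.1f%%\n",
              digits, x$Q, x$df, digits, x$tau2, x$i2))
  invisible(x)
}

#' Pool prevalences on the logit scale
#'
#' Each study's proportion is transformed to a logit,
#' \eqn{y_i = \log(e_i/(n_i - e_i))} with standard error
#' \eqn{\sqrt{1/e_i + 1/(n_i - e_i)}}, pooled with
#' [dersimonian_laird()], and back-transformed to a prevalence (percent) with
#' its confidence interval. \eqn{\tau^2} and \eqn{I^2} are reported on the
#' logit scale. A continuity correction (0.5 added to both cells) for
#' boundary counts (`events` of 0 or `n`) is available but off by default;
#' with it off, boundary counts are an error.
#'
#' @param events Integer vector of event counts.
#' @param n Integer vector of study sizes.
#' @param correction Apply the 0.5 continuity correction to boundary counts.
#' @param level Confidence level.
#' @return A `"pooled_result"` (scale `"logit"`) with additional components
#'   `prevalence`, `prev_ci_low`, `prev_ci_high` (percent).
#' @export
pool_prevalence <- function(events, n, correction = FALSE, level = 0.95) {
  if (length(events) == 0L) stop("no prevalence records supplied")
  if (length(events) != length(n)) stop("'events' and 'n' lengths differ")
  if (any(events < 0 | events > n)) stop("require 0 <= events <= n")
  boundary <- events == 0 | events == n
  if (any(boundary)) {
    if (!correction)
      stop("boundary event counts (0 or n) need correction = TRUE")
    e <- events + ifelse(boundary, 0.5, 0)
    nn <- n + ifelse(boundary, 1, 0)
  } else {
    e <- events
    nn <- n
  }
  y <- log(e / (nn - e))
  se <- sqrt(1 / e + 1 / (nn - e))
  res <- dersimonian_laird(y, se, scale = "logit", level = level)
  res$prevalence <- 100 * plogis(res$estimate)
  res$prev_ci_low <- 100 * plogis(res$ci_low)
  res$prev_ci_high <- 100 * plogis(res$ci_high)
  res
}

#' Egger's regression test for small-study effects
#'
#' Classical form: ordinary least squares of the standardized effect
#' \eqn{y_i/se_i} on the precision \eqn{1/se_i}. The intercept estimates
#' funnel-plot asymmetry; its two-sided p-value uses a t distribution with
#' \eqn{k - 2} degrees of freedom.
#'
#' @param y Study effects.
#' @param se Positive standard errors.
#' @param alpha Significance threshold for the `significant` flag.
#' @return A list with `intercept`, `se_intercept`, `t`, `df`, `p`, `k`,
#'   `significant`.
#' @export
egger_test <- function(y, se, alpha = 0.05) {
  if (length(y) != length(se)) stop("'y' and 'se' must have equal length")
  if (any(se <= 0)) stop("all standard errors must be positive")
  k <- length(y)
  if (k < 3L) stop("Egger's test needs at least 3 studies")
  fit <- lm(I(y / se) ~ I(1 / se))
  sm <- suppressWarnings(summary(fit))
  est <- coef(sm)
  intercept <- est["(Intercept)", "Estimate"]
  se_int <- est["(Intercept)", "Std. Error"]
  scale <- mean(abs(y / se)) + .Machine$double.eps
  if (sm$sigma < 1e-10 * scale) {
    # numerically exact fit: the intercept is determined without error
    intercept <- if (abs(intercept) < 1e-10 * scale) 0 else intercept
    se_int <- 0
    tval <- if (intercept == 0) 0 else sign(intercept) * Inf
  } else {
    tval <- intercept / se_int
  }
  p <- 2 * pt(-abs(tval), df = k - 2)
  list(intercept = intercept, se_intercept = se_int, t = tval,
       df = k - 2L, p = p, k = k, significant = p < alpha)
}

#' Altman-Bland interaction test between two pooled effects
#'
#' Compares two independent pooled log hazard ratios:
#' \eqn{z = (\hat\theta_a - \hat\theta_b)/\sqrt{se_a^2 + se_b^2}} with a
#' two-sided normal p-value.
#'
#' @param a,b `"pooled_result"` objects on the log-HR scale, or lists with
#'   components `estimate` and `se`.
#' @return An object of class `"interaction_result"`: `z`, `p`,
#'   `diff_log_hr`, `se_diff`.
#' @export
interaction_test <- function(a, b) {
  for (x in list(a, b)) {
    if (!is.list(x) || is.null(x$estimate) || is.null(x$se))
      stop("inputs must be pooled results with 'estimate' and 'se'")
  }
  scale_a <- if (!is.null(a$scale)) a$scale else "log_hr"
  scale_b <- if (!is.null(b$scale)) b$scale else "log_hr"
  if (scale_a != scale_b || scale_a != "log_hr")
    stop("interaction test requires both results on the log_hr scale")
  diff <- a$estimate - b$estimate
  se_diff <- sqrt(a$se^2 + b$se^2)
  z <- diff / se_diff
  structure(list(z = z, p = 2 * pnorm(-abs(z)),
                 diff_log_hr = diff, se_diff = se_diff),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Interaction test: z = %.3f, p = %.3f (diff log HR %.3f, se %.3f)\n",
              x$z, x$p, x$diff_log_hr, x$se_diff))
  invisible(x)
}
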