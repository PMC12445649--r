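#' @importFrom stats qnorm pnorm dnorm lm coef vcov optim rnorm runif rbinom
#'   rexp plogis qlogis approx setNames pt complete.cases
#' @importFrom utils read.csv write.csv
NULL

# Definitions of periprocedural myocardial infarction handled by the package.
PMI_DEFINITIONS <- c("UDMI1", "UDMI3", "UDMI4", "UDMI34", "SCAI", "ARC2")

#' Normal quantile used for two-sided confidence limits
#'
#' Returns the standard-normal quantile for a two-sided `level` interval.
#' Published meta-analyses differ in whether they carry the exact quantile
#' (1.959964 for 95%) or the hand-rounded 1.96; the choice is exposed so that
#' numbers printed in reports built with either convention can be reproduced.
#'
#' @param level Two-sided confidence level in (0, 1). Default 0.95.
#' @param rounded If `TRUE`, return the conventional hand-rounded value
#'   (1.96 at the 95% level); otherwise the exact quantile.
#' @return A single numeric quantile.
#' @export
ci_z <- function(level = 0.95, rounded = FALSE) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be a single number in (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  if (rounded) round(z, 2) else z
}

#' Convert a hazard ratio and confidence interval to the log scale
#'
#' Recovers the log hazard ratio and its standard error from a point estimate
#' with symmetric (on the log scale) two-sided confidence limits, the usual
#' form in which study-level hazard ratios are published.
#'
#' @param hr Hazard ratio (> 0).
#' @param ci_low,ci_high Lower and upper confidence limits (> 0), with
#'   `ci_low <= hr <= ci_high`.
#' @param level Confidence level of the interval. Default 0.95.
#' @param rounded_z Use 1.96 instead of the exact normal quantile.
#' @return A list with components `log_hr` and `se_log_hr`.
#' @examples
#' hr_ci_to_log(2.54, 1.62, 4.00)
#' @export
hr_ci_to_log <- function(hr, ci_low, ci_high, level = 0.95, rounded_z = FALSE) {
  if (any(c(hr, ci_low, ci_high) <= 0))
    stop("hazard ratio and confidence limits must be positive")
  if (ci_low > hr || hr > ci_high)
    stop("require ci_low <= hr <= ci_high")
  if (ci_high == ci_low)
    stop("zero-width confidence interval: standard error undefined")
  z <- ci_z(level, rounded_z)
  list(log_hr = log(hr),
       se_log_hr = (log(ci_high) - log(ci_low)) / (2 * z))
}

#' Back-transform a log hazard ratio to a hazard ratio with CI
#'
#' @param log_hr Log hazard ratio.
#' @param se_log_hr Standard error of the log hazard ratio (> 0).
#' @param level Confidence level. Default 0.95.
#' @param rounded_z Use 1.96 instead of the exact normal quantile.
#' @return A list with components `hr`, `ci_low`, `ci_high`.
#' @export
log_to_hr_ci <- function(log_hr, se_log_hr, level = 0.95, rounded_z = FALSE) {
  if (se_log_hr <= 0) stop("'se_log_hr' must be positive")
  z <- ci_z(level, rounded_z)
  list(hr = exp(log_hr),
       ci_low = exp(log_hr - z * se_log_hr),
       ci_high = exp(log_hr + z * se_log_hr))
}

validate_definition <- function(definition, rows = NULL) {
  bad <- !(definition %in% PMI_DEFINITIONS)
  if (any(bad)) {
    where <- if (is.null(rows)) which(bad) else rows[bad]
    stop(sprintf("row %s: unknown definition '%s' (expected one of %s)",
                 where[1L], definition[bad][1L],
                 paste(PMI_DEFINITIONS, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a study-level table of effects or prevalences
#'
#' Reads a comma-separated table (UTF-8, dot decimal, header required) in one
#' of two schemas:
#' \describe{
#'   \item{`"effects"`}{columns `study_id, definition, hr, ci_low, ci_high,
#'     adjusted, n` -- one published (possibly adjusted) hazard ratio per
#'     study and PMI definition. Log-scale columns `log_hr` and `se_log_hr`
#'     are derived on read.}
#'   \item{`"prevalence"`}{columns `study_id, definition, events, n` -- PMI
#'     event counts per study and definition.}
#' }
#' Rows violating the schema invariants (non-positive limits, `events > n`,
#' `n < 1`, unknown definition) are rejected with a row-numbered message.
#'
#' @param path Path to a CSV file.
#' @param schema `"effects"` or `"prevalence"`.
#' @param level Confidence level assumed for published intervals.
#' @return A `data.frame` of validated records, with class
#'   `"pmi_effects"` or `"pmi_prevalence"` prepended. An empty file yields an
#'   empty data frame with a warning.
#' @export
read_study_table <- function(path, schema = c("effects", "prevalence"),
                             level = 0.95) {
  schema <- match.arg(schema)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  required <- if (schema == "effects")
    c("study_id", "definition", "hr", "ci_low", "ci_high", "adjusted", "n")
  else
    c("study_id", "definition", "events", "n")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(dat) == 0L) {
    warning(sprintf("'%s' contains a header but no rows", path))
    class(dat) <- c(paste0("pmi_", schema), class(dat))
    return(dat)
  }
  rows <- seq_len(nrow(dat)) + 1L   # header is line 1
  num_cols <- setdiff(required, c("study_id", "definition", "adjusted"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(dat[[col]]))
    bad <- is.na(v) & !is.na(dat[[col]])
    if (any(bad))
      stop(sprintf("row %d: non-numeric value '%s' in column '%s'",
                   rows[bad][1L], dat[[col]][bad][1L], col))
    if (any(is.na(v)))
      stop(sprintf("row %d: missing value in column '%s'",
                   rows[is.na(v)][1L], col))
    dat[[col]] <- v
  }
  validate_definition(dat$definition, rows)
  if (any(dat$n < 1))
    stop(sprintf("row %d: n must be a positive integer", rows[dat$n < 1][1L]))
  if (schema == "effects") {
    dat$adjusted <- as.logical(dat$adjusted)
    if (anyNA(dat$adjusted))
      stop("column 'adjusted' must be TRUE/FALSE")
    conv <- Map(hr_ci_to_log, dat$hr, dat$ci_low, dat$ci_high,
                MoreArgs = list(level = level))
    dat$log_hr <- vapply(conv, `[[`, numeric(1), "log_hr")
    dat$se_log_hr <- vapply(conv, `[[`, numeric(1), "se_log_hr")
  } else {
    bad <- dat$events < 0 | dat$events > dat$n
    if (any(bad))
      stop(sprintf("row %d: events (%g) must lie in [0, n = %g]",
                   rows[bad][1L], dat$events[bad][1L], dat$n[bad][1L]))
  }
  class(dat) <- c(paste0("pmi_", schema), class(dat))
  dat
}

#' Write a study-level table
#'
#' Inverse of [read_study_table()]: writes the schema columns (derived
#' log-scale columns are dropped) so that tables round-trip losslessly.
#'
#' @param x A data frame as returned by [read_study_table()] or the
#'   synthetic-data generators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  keep <- intersect(c("study_id", "definition", "hr", "ci_low", "ci_high",
                      "adjusted", "n", "events"), names(x))
  write.csv(x[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Follow-up summary in one of the published reporting forms
#'
#' @param form One of `"mean_sd"`, `"median_iqr"`, `"median_range"`,
#'   `"fixed"`.
#' @param values Numeric vector of reported values (years):
#'   `mean_sd = c(mean, sd)`; `median_iqr = c(q1, median, q3)`;
#'   `median_range = c(min, median, max)`; `fixed = value`.
#' @param n Number of patients the summary describes.
#' @return An object of class `"followup_summary"`.
#' @export
followup_summary <- function(form = c("mean_sd", "median_iqr",
                                      "median_range", "fixed"),
                             values, n) {
  form <- match.arg(form)
  values <- as.numeric(values)
  expected <- c(mean_sd = 2L, median_iqr = 3L, median_range = 3L, fixed = 1L)
  if (length(values) != expected[[form]])
    stop(sprintf("'%s' expects %d value(s), got %d",
                 form, expected[[form]], length(values)))
  if (length(n) != 1L || n < 1) stop("'n' must be a positive integer")
  if (form == "median_iqr" &&
      !(values[1] <= values[2] && values[2] <= values[3]))
    stop("median_iqr requires q1 <= median <= q3")
  if (form == "median_range" &&
      !(values[1] <= values[2] && values[2] <= values[3]))
    stop("median_range requires min <= median <= max")
  if (form == "mean_sd" && values[2] < 0) stop("sd must be non-negative")
  structure(list(form = form, values = values, n = as.integer(n)),
            class = "followup_summary")
}

#' Convert a follow-up summary to mean and SD (Wan's method)
#'
#' Medians with quartiles or ranges are converted to an approximate mean and
#' standard deviation with the sample-size-dependent normal-quantile
#' denominators of Wan's method:
#' \deqn{median/IQR:\; \bar x = (q_1 + m + q_3)/3,\quad
#'   s = (q_3 - q_1) / \left(2\,\Phi^{-1}\!\big((0.75n - 0.125)/(n + 0.25)\big)\right)}
#' \deqn{median/range:\; \bar x = (a + 2m + b)/4,\quad
#'   s = (b - a) / \left(2\,\Phi^{-1}\!\big((n - 0.375)/(n + 0.25)\big)\right)}
#' Mean/SD summaries pass through unchanged; a fixed follow-up has SD 0.
#'
#' @param summary A [followup_summary()].
#' @return A list with components `mean`, `sd` and `n`.
#' @export
wan_convert <- function(summary) {
  if (!inherits(summary, "followup_summary"))
    stop("'summary' must be a followup_summary object")
  v <- summary$values
  n <- summary$n
  out <- switch(summary$form,
    mean_sd = list(mean = v[1], sd = v[2]),
    fixed = list(mean = v[1], sd = 0),
    median_iqr = {
      if (n < 2) stop("Wan conversion requires n >= 2")
      denom <- 2 * qnorm((0.75 * n - 0.125) / (n + 0.25))
      list(mean = (v[1] + v[2] + v[3]) / 3, sd = (v[3] - v[1]) / denom)
    },
    median_range = {
      if (n < 2) stop("Wan conversion requires n >= 2")
      denom <- 2 * qnorm((n - 0.375) / (n + 0.25))
      list(mean = (v[1] + 2 * v[2] + v[3]) / 4, sd = (v[3] - v[1]) / denom)
    })
  out$n <- n
  out
}

#' Pool per-study follow-up summaries
#'
#' Converts each summary via [wan_convert()] and pools with sample-size
#' weights. The pooled mean is the n-weighted mean; the pooled SD uses the
#' standard pooled-variance decomposition combining within-study variances
#' and between-study dispersion about the pooled mean:
#' \deqn{s^2 = \frac{\sum_i (n_i - 1) s_i^2 + \sum_i n_i (\bar x_i - \bar x)^2}
#'   {\sum_i n_i - 1}}
#'
#' @param summaries A list of [followup_summary()] objects.
#' @return A list with `mean`, `sd` and `total_n`.
#' @export
pooled_followup <- function(summaries) {
  if (length(summaries) == 0L) stop("no follow-up summaries supplied")
  conv <- lapply(summaries, wan_convert)
  m <- vapply(conv, `[[`, numeric(1), "mean")
  s <- vapply(conv, `[[`, numeric(1), "sd")
  n <- vapply(conv, `[[`, numeric(1), "n")
  total_n <- sum(n)
  pooled_mean <- sum(n * m) / total_n
  pooled_var <- sum((n - 1) * s^2 + n * (m - pooled_mean)^2) / (total_n - 1)
  list(mean = pooled_mean, sd = sqrt(max(0, pooled_var)), total_n = total_n)
}

#' Read a follow-up table
#'
#' CSV schema `study_id, form, v1, v2, v3, n`. The `v` slots hold the
#' reported values in the order documented in [followup_summary()]; unused
#' slots are left empty.
#'
#' @param path Path to a CSV file.
#' @return A list of [followup_summary()] objects named by study id.
#' @export
read_followup_table <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "form", "v1", "n")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  out <- lapply(seq_len(nrow(dat)), function(i) {
    row <- dat[i, ]
    vals <- suppressWarnings(as.numeric(c(row$v1, row$v2, row$v3)))
    vals <- vals[!is.na(vals)]
    followup_summary(row$form, vals, row$n)
  })
  names(out) <- dat$study_id
  out
}
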