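# Shared fixtures and independent oracles used across test files.

# Published study characteristics table used for follow-up pooling:
# CABG sample size, mean follow-up (years) and, where reported, its SD
# (a missing SD means the study reported a fixed follow-up horizon).
table2_followup <- function() {
  studies <- list(
    list(id = "BelleyCote2019", n = 4752, form = "fixed", v = 1),
    list(id = "Cho2017",        n = 3183, form = "mean_sd", v = c(4.8, 4.2)),
    list(id = "Gregson2020",    n = 923,  form = "fixed", v = 5),
    list(id = "Hara2020",       n = 795,  form = "mean_sd", v = c(10.7, 2.5)),
    list(id = "Hinton2022",     n = 138,  form = "fixed", v = 1),
    list(id = "Jang2016",       n = 367,  form = "mean_sd", v = c(3.7, 2.8)),
    list(id = "Litwinowicz2022", n = 4642, form = "mean_sd", v = c(5.1, 2.1)),
    list(id = "Polzl2022",      n = 2829, form = "fixed", v = 5),
    list(id = "Wang2013",       n = 560,  form = "mean_sd", v = c(1.8, 0.6)),
    list(id = "Yau2008",        n = 3014, form = "fixed", v = 2))
  lapply(studies, function(s) followup_summary(s$form, s$v, s$n))
}

# Brute-force Cox partial log-likelihood for untied data (Breslow = Efron
# when there are no ties); independent of survival::coxph.
brute_cox_loglik <- function(beta, time, event, x) {
  o <- order(time)
  time <- time[o]; event <- event[o]; x <- x[o]
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# Write a small CSV fixture and return its path.
write_fixture_csv <- function(lines, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
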