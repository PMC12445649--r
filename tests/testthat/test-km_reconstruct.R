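test_that("curve cleaning repairs digitization artefacts idempotently", {
  # jitter: a one-pixel rise is flattened to the running minimum
  cv <- clean_curve(c(0, 1, 2, 3), c(1, 0.832, 0.833, 0.7), "PMI")
  expect_equal(cv$survival, c(1, 0.832, 0.832, 0.7))

  # already clean: unchanged
  cv2 <- clean_curve(cv$time, cv$survival, "PMI")
  expect_equal(cv2$survival, cv$survival)
  expect_equal(cv2$time, cv$time)

  # anchor prepended, values clamped, times sorted
  cv3 <- clean_curve(c(2, 1), c(0.6, 1.2), "no_PMI")
  expect_equal(cv3$time, c(0, 1, 2))
  expect_equal(cv3$survival, c(1, 1, 0.6))

  expect_error(clean_curve(0, 1, "PMI"), "at least two|degenerate")
})

test_that("risk tables validate monotone structure", {
  rk <- risk_table(c(0, 1, 2), c(100, 80, 60))
  expect_equal(rk$at_risk, c(100L, 80L, 60L))
  expect_error(risk_table(c(0, 1), c(50, 60)), "increase")
  expect_error(risk_table(c(1, 2), c(50, 40)), "time 0")
  expect_error(risk_table(0, 100), "2 entries")
})

test_that("reconstruction is lossless without censoring", {
  # 20 subjects, 4 events at each of t = 1..5, no censoring
  ipd0 <- data.frame(time = rep(1:5, each = 4), event = TRUE,
                     group = "PMI", study_id = "s")
  km0 <- km_estimate(ipd0)
  cv <- clean_curve(km0$time, km0$survival, "PMI", "s")
  rk <- risk_table(0:5, c(20, 20, 16, 12, 8, 4))
  rec <- reconstruct_ipd(cv, rk)
  expect_equal(nrow(rec), 20)
  expect_equal(sum(rec$event), 20)
  expect_equal(sort(rec$time[rec$event]), sort(ipd0$time))
})

test_that("a flat curve yields only censorings matching the risk decrements", {
  cv <- clean_curve(c(0, 1, 2, 3), c(1, 1, 1, 1), "PMI", "s")
  rk <- risk_table(c(0, 1, 2, 3), c(10, 8, 5, 3))
  rec <- reconstruct_ipd(cv, rk)
  expect_equal(sum(rec$event), 0)
  expect_equal(nrow(rec), 10)   # conservation: all subjects accounted for
})

test_that("infeasible risk tables are reported", {
  cv <- clean_curve(c(0, 1, 2), c(1, 0.5, 0.4), "PMI", "s")
  # at-risk increase is caught at construction
  expect_error(risk_table(c(0, 1, 2), c(10, 12, 5)), "increase")
  # curve not covering the risk table is caught at reconstruction
  rk <- risk_table(c(0, 1, 2, 5), c(10, 8, 6, 2))
  expect_error(reconstruct_ipd(cv, rk), "beyond")
})

test_that("simulated survival round-trips through reconstruction", {
  cfg <- sim_config(surv_n_per_group = 500, hr_true = 2, seed = 7,
                    dropout_rate = 0.15)
  s <- simulate_survival(cfg, n_points = 200, risk_interval = 1)
  rec <- rbind(reconstruct_ipd(s$curves$no_PMI, s$risk$no_PMI),
               reconstruct_ipd(s$curves$PMI, s$risk$PMI))
  # conservation: every subject initially at risk is reconstructed
  expect_equal(nrow(rec), nrow(s$ipd))
  # recovered event count within 2% of truth
  expect_lt(abs(sum(rec$event) - sum(s$ipd$event)) / sum(s$ipd$event), 0.02)
  # recomputed KM within 0.01 sup-norm of the digitized input, per arm
  for (g in c("no_PMI", "PMI")) {
    km_r <- km_estimate(rec[rec$group == g, ])
    cv <- s$curves[[g]]
    idx <- findInterval(cv$time, km_r$time)
    expect_lt(max(abs(km_r$survival[pmax(idx, 1)] - cv$survival)), 0.01)
  }
})

test_that("finer digitization tightens the reconstruction", {
  cfg <- sim_config(surv_n_per_group = 300, seed = 21)
  s <- simulate_survival(cfg, n_points = 1000, risk_interval = 1)
  rec <- reconstruct_ipd(s$curves$PMI, s$risk$PMI)
  km_r <- km_estimate(rec)
  cv <- s$curves$PMI
  idx <- pmax(findInterval(cv$time, km_r$time), 1)
  expect_lt(max(abs(km_r$survival[idx] - cv$survival)), 0.005)
})

test_that("product-limit estimate matches the hand oracle", {
  # events at 1 and 2, censored at 3 and 4: S = 1, .75, .50, .50
  ipd <- data.frame(time = 1:4, event = c(TRUE, TRUE, FALSE, FALSE))
  km <- km_estimate(ipd)
  expect_equal(km$survival[km$time %in% c(1, 2)], c(0.75, 0.50))
  expect_equal(km$survival[length(km$survival)], 0.50)

  # no events: survival stays at 1
  flat <- km_estimate(data.frame(time = 1:5, event = FALSE))
  expect_true(all(flat$survival == 1))

  # mass extinction at one time
  drop <- km_estimate(data.frame(time = rep(2, 4), event = TRUE))
  expect_equal(min(drop$survival), 0)
  expect_error(km_estimate(data.frame()), "empty")
})

test_that("Cox fit matches brute-force partial likelihood and symmetry", {
  # identical event patterns in both groups: HR = 1
  base <- data.frame(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, FALSE, TRUE))
  sym <- rbind(transform(base, group = "PMI", study_id = "s"),
               transform(base, group = "no_PMI", study_id = "s"))
  expect_equal(cox_univariable(sym)$hr, 1, tolerance = 1e-8)

  # 6-subject untied instance vs brute-force maximization
  toy <- data.frame(time = c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9),
                    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                    group = c("PMI", "no_PMI", "PMI", "no_PMI", "PMI",
                              "no_PMI"),
                    study_id = "s")
  fit <- cox_univariable(toy)
  x <- as.integer(toy$group == "PMI")
  opt <- optimize(function(b) -brute_cox_loglik(b, toy$time, toy$event, x),
                  c(-5, 5), tol = 1e-10)
  expect_equal(fit$log_hr, opt$minimum, tolerance = 1e-6)

  # Efron and Breslow agree on tie-free data
  expect_equal(fit$log_hr, cox_univariable(toy, ties = "breslow")$log_hr,
               tolerance = 1e-8)

  expect_error(cox_univariable(toy[toy$group == "PMI", ]), "both groups")
})

test_that("Cox CIs achieve near-nominal coverage on exponential data", {
  hits <- vapply(1:300, function(i) {
    set.seed(30000 + i)
    n <- 150
    t0 <- rexp(n, 0.1); t1 <- rexp(n, 0.2)
    ipd <- data.frame(
      time = pmin(c(t0, t1), 8),
      event = c(t0, t1) <= 8,
      group = rep(c("no_PMI", "PMI"), each = n), study_id = "s")
    fit <- cox_univariable(ipd)
    fit$ci_low <= 2 && 2 <= fit$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("KM tables read from CSV and reconstruct per study-group", {
  cfg <- sim_config(surv_n_per_group = 120, seed = 9)
  s <- simulate_survival(cfg, n_points = 120)
  dir <- withr::local_tempdir()
  curves <- do.call(rbind, lapply(s$curves, function(cv)
    data.frame(study_id = cv$study_id, group = cv$group, time = cv$time,
               survival = cv$survival)))
  risks <- do.call(rbind, lapply(names(s$risk), function(g)
    data.frame(study_id = "sim_surv", group = g, time = s$risk[[g]]$time,
               at_risk = s$risk[[g]]$at_risk)))
  write.csv(curves, file.path(dir, "km_curve.csv"), row.names = FALSE)
  write.csv(risks, file.path(dir, "km_risk.csv"), row.names = FALSE)
  pairs <- read_km_tables(file.path(dir, "km_curve.csv"),
                          file.path(dir, "km_risk.csv"))
  expect_length(pairs, 2)
  rec <- reconstruct_ipd(pairs[[1]]$curve, pairs[[1]]$risk)
  expect_equal(nrow(rec), 120)
})
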