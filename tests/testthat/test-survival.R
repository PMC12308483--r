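# Gamma GLM, standardisation, Cox models, concordance, delta-C, diagnostics.

test_that("standardize divides by the analysis-sample SD and round-trips", {
  set.seed(1)
  d <- data.frame(x = rnorm(500, 10, 2), y = runif(500))
  st <- standardize(d, c("x", "y"))
  expect_equal(sd(st$data$x), 1, tolerance = 1e-12)
  expect_equal(st$sd_map[["x"]], sd(d$x), tolerance = 1e-12)
  expect_equal(st$data$x * st$sd_map[["x"]], d$x, tolerance = 1e-14)
  expect_error(standardize(data.frame(z = rep(1, 10)), "z"), "zero")
})

test_that("per-SD and per-unit Cox coefficients interconvert exactly", {
  set.seed(2)
  sim <- generate_cohort(cohort_sim_config(n = 4000, seed = 2,
                                           segment_level = FALSE))
  f_sd <- fit_cox(sim$cohort, "MadWT", per = "sd", endpoint = "MACE")
  f_un <- fit_cox(sim$cohort, "MadWT", per = "unit", endpoint = "MACE")
  s <- f_sd$sd_map[["MadWT"]]
  expect_equal(f_sd$coefficients$log_hr, f_un$coefficients$log_hr * s,
               tolerance = 1e-8)
  expect_equal(f_sd$coefficients$hr, f_un$coefficients$hr^s,
               tolerance = 1e-8)
})

test_that("identity-link Gamma GLM recovers simulated coefficients", {
  sim <- generate_cohort(cohort_sim_config(n = 20000, seed = 14))
  g <- fit_gamma_glm(sim$cohort, "MadWT",
                     c("age", "male", "bmi", "hypertension"))
  tab <- g$coefficients
  # truth: 0.05 mm per (configured) SD of age; sample SD ~ configured SD
  est_age <- tab$estimate[tab$term == "age"]
  se_age <- tab$se[tab$term == "age"]
  expect_lt(abs(est_age - 0.05), 3 * se_age)
  est_htn <- tab$estimate[tab$term == "hypertension"]
  expect_lt(abs(est_htn - 0.10), 3 * tab$se[tab$term == "hypertension"])
  expect_true(all(g$fit$fitted.values > 0))
})

test_that("Gamma GLM: intercept-only fit returns the mean; errors guarded", {
  d <- data.frame(y = rep(2.5, 50))
  g <- fit_gamma_glm(d, "y", character(0))
  expect_equal(g$coefficients$estimate[1], 2.5, tolerance = 1e-9)
  d2 <- data.frame(y = c(rep(1, 20), -0.5), x = rnorm(21))
  expect_error(fit_gamma_glm(d2, "y", "x"), "strictly positive")
})

test_that("Gamma GLM null-coefficient CIs achieve nominal coverage", {
  set.seed(99)
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    d <- data.frame(y = rgamma(300, shape = 10, rate = 10 / 0.95),
                    x = rnorm(300))
    tab <- fit_gamma_glm(d, "y", "x")$coefficients
    row <- tab[tab$term == "x", ]
    hits <- hits + (row$ci_lower <= 0 && 0 <= row$ci_upper)
  }
  expect_gt(hits / n_rep, 0.91)
  expect_lt(hits / n_rep, 0.99)
})

test_that("Cox HR matches the closed-form rate ratio for exponential data", {
  set.seed(8)
  n <- 4000
  x <- rep(0:1, each = n / 2)
  t <- rexp(n, rate = ifelse(x == 1, 2, 1))    # true HR = 2, no censoring
  d <- data.frame(x = x, time_E = t, event_E = 1)
  f <- fit_cox(d, "x", per = "unit", endpoint = "E")
  expect_lt(abs(f$coefficients$log_hr - log(2)),
            3 * sqrt(diag(f$fit$var)))
  expect_equal(f$n_events, n)
})

test_that("Cox estimates are invariant to time rescaling and centering", {
  sim <- generate_cohort(cohort_sim_config(n = 3000, seed = 16,
                                           segment_level = FALSE))
  co <- sim$cohort
  f0 <- fit_cox(co, c("MadWT", "age"), per = "unit", endpoint = "MACE")
  co2 <- co
  co2$time_MACE <- co2$time_MACE * 365.25
  f1 <- fit_cox(co2, c("MadWT", "age"), per = "unit", endpoint = "MACE")
  expect_equal(f0$coefficients$log_hr, f1$coefficients$log_hr,
               tolerance = 1e-8)
  co3 <- co
  co3$age <- co3$age - 64.6
  f2 <- fit_cox(co3, c("MadWT", "age"), per = "unit", endpoint = "MACE")
  expect_equal(f0$coefficients$log_hr, f2$coefficients$log_hr,
               tolerance = 1e-6)
})

test_that("Cox fit errors on no events and degenerate designs", {
  d <- data.frame(x = rnorm(50), time_E = rexp(50), event_E = 0)
  expect_error(fit_cox(d, "x", endpoint = "E"), "no events")
  expect_error(fit_cox(d, "x", per = "unit"), "endpoint")
})

test_that("model levels 1-4 are strictly nested with the documented sets", {
  specs <- lapply(1:4, function(l) cox_model_spec("MACE", l))
  expect_identical(specs[[1]]$predictors, "MadWT")
  expect_true(all(c("age", "male", "white", "bmi", "smoker",
                    "hyperlipidaemia", "hypertension", "diabetes")
                  %in% specs[[2]]$predictors))
  expect_true(all(c("LVEDVi", "LVEF") %in% specs[[3]]$predictors))
  expect_true("LVMi" %in% specs[[4]]$predictors)
  for (l in 2:4) {
    expect_true(all(specs[[l - 1]]$predictors %in% specs[[l]]$predictors))
  }
  expect_error(cox_model_spec("MACE", 5), "level")
})

test_that("concordance matches the brute-force pair oracle", {
  # spec fixtures
  expect_identical(concordance_index(c(3, 2, 1), 1:3, rep(1, 3)), 1)
  expect_identical(concordance_index(rep(1, 5), 1:5, rep(1, 5)), 0.5)
  r4 <- c(4, 3, 2, 1)
  expect_identical(concordance_index(r4, 1:4, c(1, 1, 0, 1)),
                   cindex_brute(r4, 1:4, c(1, 1, 0, 1)))
  # random fixtures with risk ties and censoring, n up to 200
  set.seed(21)
  for (k in 1:8) {
    n <- sample(20:200, 1)
    risk <- round(rnorm(n), 1)
    time <- rexp(n)
    event <- rbinom(n, 1, 0.6)
    expect_equal(concordance_index(risk, time, event),
                 cindex_brute(risk, time, event), tolerance = 1e-12)
  }
  expect_error(concordance_index(1:3, 1:3, c(0, 0, 0)), "usable")
})

test_that("delta-C is exactly zero for identical models and null for noise", {
  sim <- generate_cohort(cohort_sim_config(n = 2000, seed = 33,
                                           segment_level = FALSE))
  co <- sim$cohort
  lp <- sim$truth$hazard$MACE$lp
  same <- delta_cindex(lp, lp, co$time_MACE, co$event_MACE)
  expect_identical(same$delta_c, 0)
  expect_identical(same$p, 1)
  set.seed(34)
  noisy <- delta_cindex(lp, lp + rnorm(2000, 0, 1e-4), co$time_MACE,
                        co$event_MACE, n_boot = 200, seed = 35)
  expect_lt(abs(noisy$delta_c), 0.02)
  expect_gt(noisy$p, 0.05)
  expect_error(delta_cindex(lp[-1], lp, co$time_MACE, co$event_MACE),
               "identical rows")
})

test_that("diagnostics: orthogonal VIF 1, collinear errors, PH violation found", {
  set.seed(44)
  n <- 3000
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  t <- rexp(n, exp(0.3 * x1))
  d <- data.frame(x1 = x1, x2 = x2, time_E = t, event_E = 1)
  f <- fit_cox(d, c("x1", "x2"), per = "unit", endpoint = "E")
  diag <- cox_diagnostics(f)
  expect_true(all(diag$vif < 1.1))
  expect_gt(min(diag$vif), 1 - 1e-9)
  # duplicated predictor -> singular
  d$x3 <- d$x1
  expect_error(fit_cox(d, c("x1", "x3"), per = "unit", endpoint = "E"),
               "singular")
  # designed PH violation: effect reverses over time
  detect <- vapply(1:25, function(r) {
    set.seed(1000 + r)
    m <- 5000
    x <- rnorm(m)
    u <- runif(m)
    tau <- 1
    # hazard e^{0.8x} before tau, e^{-0.8x} after
    t1 <- -log(u) / exp(0.8 * x)
    late <- t1 > tau
    t_all <- ifelse(late, tau + rexp(m, exp(-0.8 * x)), t1)
    dd <- data.frame(x = x, time_E = t_all, event_E = 1)
    ff <- fit_cox(dd, "x", per = "unit", endpoint = "E")
    cox_diagnostics(ff)$schoenfeld_p[1] < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.8)
})

test_that("the model ladder fits nested models on identical rows", {
  sim <- generate_cohort(cohort_sim_config(n = 8000, seed = 50,
                                           segment_level = FALSE))
  lad <- fit_cox_ladder(sim$cohort, "MACE", n_boot = 0)
  expect_identical(unique(lad$summary$n), lad$fits[[1]]$n)
  expect_identical(vapply(lad$fits, function(f) f$n_events, integer(1)),
                   rep(lad$fits[[1]]$n_events, 4L))
  expect_equal(nrow(lad$summary), 4)
  expect_true(all(is.finite(lad$summary$c_index)))
})
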