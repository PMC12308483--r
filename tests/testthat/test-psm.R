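# Propensity estimation, greedy matching, activity strata, comparisons.

test_that("propensity model recovers a known logistic truth", {
  sim <- generate_cohort(cohort_sim_config(n = 20000, seed = 61,
                                           segment_level = FALSE))
  prop <- estimate_propensity(sim$cohort, confounders = c("age", "bmi"))
  truth <- sim$truth$hypertension_model
  se <- sqrt(diag(vcov(prop$fit)))
  expect_lt(abs(prop$coefficients[["age"]] - truth[["beta_age"]]),
            3 * se[["age"]])
  expect_lt(abs(prop$coefficients[["bmi"]] - truth[["beta_bmi"]]),
            3 * se[["bmi"]])
  expect_true(all(prop$scores > 0 & prop$scores < 1))
})

test_that("confounder-free treatment gives scores near the prevalence", {
  set.seed(62)
  d <- data.frame(id = 1:5000, hypertension = rbinom(5000, 1, 0.3),
                  age = rnorm(5000), male = rbinom(5000, 1, 0.5),
                  white = 1, height = rnorm(5000, 170, 9),
                  bmi = rnorm(5000, 26, 4), smoker = rbinom(5000, 1, 0.05),
                  hyperlipidaemia = rbinom(5000, 1, 0.3),
                  diabetes = rbinom(5000, 1, 0.06))
  d$white <- rbinom(5000, 1, 0.97)
  prop <- estimate_propensity(d)
  expect_lt(sd(prop$scores), 0.05)
  expect_equal(mean(prop$scores), mean(d$hypertension), tolerance = 1e-6)
})

test_that("deterministic treatment raises a separation error", {
  d <- data.frame(age = c(rnorm(50, 40, 1), rnorm(50, 80, 1)),
                  hypertension = rep(0:1, each = 50))
  expect_error(estimate_propensity(d, confounders = "age"), "separation")
})

test_that("matching picks the nearest control without replacement", {
  m <- match_pairs(c(0.5, 0.4, 0.9), treated = c(TRUE, FALSE, FALSE))
  expect_identical(m$pairs$control_id, 2L)
  expect_equal(m$pairs$abs_diff, 0.1, tolerance = 1e-12)

  # identical score multisets match perfectly
  sc <- c(runif(20), runif(20))
  sc[21:40] <- sc[1:20]
  m2 <- match_pairs(sc, treated = rep(c(TRUE, FALSE), each = 20))
  expect_identical(m2$n_matched, 20L)
  expect_true(all(m2$pairs$abs_diff == 0))
})

test_that("greedy matcher reproduces the hand-traced adversarial oracle", {
  # treated 0.80 grabs 0.79 first (descending order), forcing treated 0.70
  # onto the distant 0.20: greedy, NOT optimal
  scores <- c(0.80, 0.70, 0.79, 0.20)
  treated <- c(TRUE, TRUE, FALSE, FALSE)
  m <- match_pairs(scores, treated)
  expect_identical(m$pairs$treated_id, c(1L, 2L))
  expect_identical(m$pairs$control_id, c(3L, 4L))
  expect_identical(greedy_match_brute(scores, treated),
                   cbind(c(1L, 2L), c(3L, 4L)))
})

test_that("matching agrees with the literal greedy oracle on random inputs", {
  set.seed(63)
  for (k in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), 2)           # coarse scores force ties
    treated <- rep(FALSE, n)
    treated[sample(n, sample(3:(n %/% 2), 1))] <- TRUE
    m <- match_pairs(scores, treated)
    oracle <- greedy_match_brute(scores, treated)
    expect_identical(cbind(m$pairs$treated_id, m$pairs$control_id),
                     oracle)
  }
})

test_that("fewer controls than treated yields a warning and partial matching", {
  expect_warning(
    m <- match_pairs(c(0.2, 0.5, 0.8, 0.4), c(TRUE, TRUE, TRUE, FALSE)),
    "unmatched")
  expect_identical(m$n_matched, 1L)
  expect_identical(m$n_treated, 3L)
  expect_error(match_pairs(c(0.1, 0.2), c(TRUE, TRUE)), "non-empty")
})

test_that("top-active strata respect quantile threshold and tie rule", {
  d <- data.frame(id = 1:1000, TPA = c(rep(5, 990), 100 + 1:10),
                  vigorous_MET = runif(1000),
                  accel_mean = NA_real_, accel_valid = FALSE)
  top <- select_top_active(d, "TPA", 0.01)
  expect_identical(nrow(top), 10L)
  expect_true(all(top$TPA >= max(d$TPA[!d$id %in% top$id])))
  expect_identical(nrow(select_top_active(d, "TPA", 1)), 1000L)
  # ties at the threshold are all included
  d2 <- data.frame(TPA = c(rep(1, 90), rep(2, 10)))
  expect_identical(nrow(select_top_active(d2, "TPA", 0.05)), 10L)
  # accel metric needs valid wear
  expect_error(select_top_active(d, "accel_mean", 0.1), "empty")
})

test_that("post-match SMD shrinks below 0.1 on a confounded simulation", {
  sim <- generate_cohort(cohort_sim_config(n = 20000, seed = 64,
                                           segment_level = FALSE))
  co <- sim$cohort
  confs <- c("age", "male", "white", "height", "bmi", "smoker",
             "hyperlipidaemia", "diabetes")
  prop <- estimate_propensity(co, confs)
  m <- match_pairs(prop$scores, co$hypertension[prop$rows] == 1,
                   ids = co$id[prop$rows])
  bal <- match_balance(co, confs, "hypertension", m)
  expect_gt(max(abs(bal$smd_pre)), 0.25)   # confounding is real pre-match
  expect_true(all(abs(bal$smd_post) < 0.1))
  expect_false(any(duplicated(m$pairs$control_id)))
  expect_false(any(duplicated(m$pairs$treated_id)))
})

test_that("Mann-Whitney comparison handles the exact fixture and edge cases", {
  d <- data.frame(id = 1:6, MadWT = c(1, 2, 3, 4, 5, 6))
  m <- structure(list(pairs = data.frame(treated_id = 1:3, control_id = 4:6,
                                         score_treated = 0.5,
                                         score_control = 0.5,
                                         abs_diff = 0),
                      n_treated = 3L, n_matched = 3L),
                 class = "match_result")
  cmp <- compare_biomarkers(d, m, biomarkers = "MadWT", n_boot = 50,
                            alpha_family = 1, seed = 1)
  expect_identical(unname(cmp$U), 0)
  expect_equal(cmp$p, 0.10, tolerance = 1e-9)

  # identical groups: relative difference 0, p = 1
  d2 <- data.frame(id = 1:6, MadWT = rep(c(1, 2, 3), 2))
  cmp2 <- compare_biomarkers(d2, m, biomarkers = "MadWT", n_boot = 50,
                             alpha_family = 1, seed = 1)
  expect_identical(cmp2$relative_difference, 0)
  expect_equal(cmp2$p, 1, tolerance = 1e-9)

  # all-NaN biomarker is skipped with a message
  d3 <- d
  d3$flat <- NaN
  expect_message(
    cmp3 <- compare_biomarkers(d3, m, biomarkers = c("MadWT", "flat"),
                               n_boot = 50, seed = 1),
    "skipped")
  expect_identical(nrow(cmp3), 1L)
})

test_that("exact and approximate Mann-Whitney p agree to 2 decimals", {
  set.seed(65)
  for (k in 1:10) {
    x <- rnorm(sample(15:20, 1))
    y <- rnorm(sample(15:20, 1), 0.3)
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.011)
  }
})

test_that("bootstrap median CIs reach nominal coverage on log-normal data", {
  set.seed(66)
  true_med <- exp(0)
  m <- structure(list(pairs = data.frame(treated_id = 1:60,
                                         control_id = 61:120,
                                         score_treated = 0.5,
                                         score_control = 0.5, abs_diff = 0),
                      n_treated = 60L, n_matched = 60L),
                 class = "match_result")
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    d <- data.frame(id = 1:120, X = rlnorm(120))
    cmp <- compare_biomarkers(d, m, biomarkers = "X", n_boot = 400,
                              alpha_family = 1, seed = 660 + r)
    hits <- hits + (cmp$ci_treated_lower <= true_med &&
                      true_med <= cmp$ci_treated_upper)
  }
  expect_gt(hits / n_rep, 0.89)
  expect_lte(hits / n_rep, 0.98)
})

test_that("end-to-end matched comparison runs within a top-activity stratum", {
  sim <- generate_cohort(cohort_sim_config(n = 15000, seed = 67,
                                           segment_level = FALSE))
  pc <- suppressWarnings(psm_compare(sim$cohort, metric = "vigorous_MET",
                                     fraction = 0.10, n_boot = 100,
                                     seed = 68))
  expect_gt(pc$match$n_matched, 100)
  expect_identical(nrow(pc$comparison), 9L)
  expect_true(all(pc$comparison$ci_treated_lower <=
                    pc$comparison$median_treated))
  expect_true(all(pc$comparison$median_treated <=
                    pc$comparison$ci_treated_upper))
  expect_true(all(abs(pc$balance$smd_post) <= 1))
})
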