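# Propensity-score matching of hypertensive vs non-hypertensive participants
# within high-activity strata, and Bonferroni-corrected nonparametric
# biomarker comparisons.

#' Estimate the propensity of hypertension
#'
#' Logistic regression of the hypertension indicator on recognised
#' confounders (default: age, sex, ethnicity, height, BMI, smoking,
#' hyperlipidaemia, diabetes); the fitted probability is the propensity
#' score used for matching.
#'
#' @param data cohort data.frame (complete cases on the model columns used).
#' @param confounders character vector of confounder columns.
#' @param treatment treated-indicator column (default `"hypertension"`).
#' @return object of class `propensity_model`: `scores` (named by row id),
#'   `coefficients`, `rows` (row indices used), and the `glm` fit.
#' @export
estimate_propensity <- function(data,
                                confounders = c("age", "male", "white",
                                                "height", "bmi", "smoker",
                                                "hyperlipidaemia",
                                                "diabetes"),
                                treatment = "hypertension") {
  if (is.null(data[[treatment]])) {
    stop(sprintf("treatment column `%s` not found", treatment), call. = FALSE)
  }
  keep <- stats::complete.cases(data[c(treatment, confounders)])
  data <- data[keep, , drop = FALSE]
  form <- stats::reformulate(confounders, response = treatment)
  fit <- suppressWarnings(stats::glm(form, data = data,
                                     family = stats::binomial()))
  scores <- stats::fitted(fit)
  # full separation: the model reproduces the indicator exactly (infinite
  # MLE) — scores carry no overlap and matching is meaningless
  if (!fit$converged || all(abs(scores - data[[treatment]]) < 1e-6)) {
    stop("separation in the propensity model: treatment is perfectly predicted",
         call. = FALSE)
  }
  # quasi-separation on individual rare covariates leaves usable scores but
  # deserves a warning (their coefficients are unstable)
  big <- names(which(abs(stats::coef(fit)[-1]) > 10))
  if (length(big) > 0) {
    warning("quasi-separation on: ", paste(big, collapse = ", "),
            "; propensity scores retained", call. = FALSE)
  }
  structure(list(scores = scores,
                 coefficients = stats::coef(fit),
                 rows = which(keep),
                 treatment = treatment,
                 fit = fit),
            class = "propensity_model")
}

#' Greedy 1:1 nearest-neighbour matching without replacement
#'
#' Treated subjects are processed in descending propensity-score order (ties
#' broken by id order); each is paired with the unused control nearest in
#' propensity score (|score difference|, ties to the lower id). No caliper is
#' applied. If controls run out a warning is raised and the remaining treated
#' stay unmatched.
#'
#' @param scores propensity scores.
#' @param treated logical/0-1 treated indicator, same length.
#' @param ids subject identifiers (default positional).
#' @return object of class `match_result`: data.frame `pairs` with columns
#'   `treated_id`, `control_id`, `score_treated`, `score_control`,
#'   `abs_diff`, plus counts `n_treated`, `n_matched`.
#' @export
match_pairs <- function(scores, treated, ids = seq_along(scores)) {
  stopifnot(length(scores) == length(treated),
            length(ids) == length(scores))
  treated <- as.logical(treated)
  if (!any(treated) || all(treated)) {
    stop("both treated and control groups must be non-empty", call. = FALSE)
  }
  t_idx <- which(treated)
  c_idx <- which(!treated)
  if (length(c_idx) < length(t_idx)) {
    warning(sprintf(
      "fewer controls (%d) than treated (%d); %d treated will stay unmatched",
      length(c_idx), length(t_idx), length(t_idx) - length(c_idx)))
  }
  # treated in descending score order, id as tie-break
  t_ord <- t_idx[order(-scores[t_idx], ids[t_idx])]
  # controls sorted ascending by score (then id) for nearest-neighbour scans
  c_ord <- c_idx[order(scores[c_idx], ids[c_idx])]
  c_scores <- scores[c_ord]
  used <- logical(length(c_ord))
  n_avail <- length(c_ord)

  pairs <- vector("list", length(t_ord))
  nc <- length(c_ord)
  for (k in seq_along(t_ord)) {
    if (n_avail == 0L) break
    s <- scores[t_ord[k]]
    pos <- findInterval(s, c_scores)
    lo <- pos
    hi <- pos + 1L
    while (lo >= 1L && used[lo]) lo <- lo - 1L
    while (hi <= nc && used[hi]) hi <- hi + 1L
    d_lo <- if (lo >= 1L) abs(s - c_scores[lo]) else Inf
    d_hi <- if (hi <= nc) abs(s - c_scores[hi]) else Inf
    best <- if (d_lo <= d_hi) lo else hi   # tie -> lower-score side
    # among equal-score unused controls take the lowest id (controls are
    # sorted by score then id; the rightward scan already does this)
    while (best > 1L && !used[best - 1L] &&
           c_scores[best - 1L] == c_scores[best]) {
      best <- best - 1L
    }
    used[best] <- TRUE
    n_avail <- n_avail - 1L
    pairs[[k]] <- c(t_ord[k], c_ord[best])
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) stop("no pairs could be formed", call. = FALSE)
  out <- data.frame(
    treated_id = ids[pairs[, 1]],
    control_id = ids[pairs[, 2]],
    score_treated = scores[pairs[, 1]],
    score_control = scores[pairs[, 2]])
  out$abs_diff <- abs(out$score_treated - out$score_control)
  structure(list(pairs = out,
                 n_treated = length(t_idx),
                 n_matched = nrow(out)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d/%d treated matched; median |dscore| = %.4g\n",
              x$n_matched, x$n_treated, stats::median(x$pairs$abs_diff)))
  invisible(x)
}

#' Standardised mean differences before and after matching
#'
#' SMD = (mean_treated - mean_control) / sqrt((var_treated + var_control)/2),
#' computed on the full sample (pre) and on the matched pairs (post).
#'
#' @param data cohort data.frame with an `id` column.
#' @param confounders columns to balance-check.
#' @param treatment treated-indicator column.
#' @param matching a [match_pairs()] result (ids refer to `data$id`).
#' @return data.frame with columns `confounder`, `smd_pre`, `smd_post`.
#' @export
match_balance <- function(data, confounders, treatment, matching) {
  stopifnot(inherits(matching, "match_result"))
  smd <- function(x_t, x_c) {
    s <- sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
    if (s == 0) return(0)
    (mean(x_t) - mean(x_c)) / s
  }
  tr <- data[[treatment]] == 1
  rows_t <- match(matching$pairs$treated_id, data$id)
  rows_c <- match(matching$pairs$control_id, data$id)
  out <- do.call(rbind, lapply(confounders, function(v) {
    data.frame(confounder = v,
               smd_pre = smd(data[[v]][tr], data[[v]][!tr]),
               smd_post = smd(data[[v]][rows_t], data[[v]][rows_c]))
  }))
  rownames(out) <- NULL
  out
}

#' Select the most physically active stratum
#'
#' Keeps the rows at or above the `(1 - fraction)` quantile of the chosen
#' activity metric (type-7 quantile). Rows tied with the threshold are all
#' included. The accelerometer metric is first restricted to participants
#' with valid (>= 72 h calibrated) wear data.
#'
#' @param data cohort data.frame.
#' @param metric `"TPA"`, `"vigorous_MET"` or `"accel_mean"`.
#' @param fraction stratum size as a fraction (1 keeps everyone, 0.01 the
#'   top 1%).
#' @return the subset data.frame.
#' @export
select_top_active <- function(data,
                              metric = c("TPA", "vigorous_MET",
                                         "accel_mean"),
                              fraction) {
  metric <- match.arg(metric)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  if (metric == "accel_mean") {
    data <- data[!is.na(data$accel_valid) & data$accel_valid, , drop = FALSE]
  }
  x <- data[[metric]]
  data <- data[!is.na(x), , drop = FALSE]
  x <- data[[metric]]
  if (nrow(data) == 0L) {
    stop("activity stratum is empty", call. = FALSE)
  }
  if (fraction == 1) return(data)
  thr <- stats::quantile(x, 1 - fraction, type = 7, names = FALSE)
  data[x >= thr, , drop = FALSE]
}

#' Compare biomarkers between matched groups
#'
#' For each biomarker: group medians with percentile-bootstrap 95% CIs,
#' a two-sided Mann-Whitney U test (exact when both groups have <= 20
#' observations and no ties, normal approximation with tie correction
#' otherwise), a Bonferroni significance flag at `0.05 / alpha_family`, and
#' the relative difference `(median_treated - median_control) /
#' median_control`.
#'
#' @param data cohort data.frame with an `id` column.
#' @param matching a [match_pairs()] result; treated/control groups are the
#'   matched rows.
#' @param biomarkers columns to compare (all-`NA` biomarkers are skipped
#'   with a message).
#' @param n_boot bootstrap resamples for the median CIs (default 2000).
#' @param alpha_family Bonferroni family size (default: number of
#'   biomarkers compared).
#' @param seed optional seed for the bootstrap.
#' @return data.frame of class `biomarker_comparison`: per biomarker the
#'   group medians, CIs, U statistic, p, `significant` flag and
#'   `relative_difference`.
#' @export
compare_biomarkers <- function(data, matching,
                               biomarkers = c("MadWT", "MaxWT", "MeanWT",
                                              "LVMi", "LVEDVi", "LVMVR",
                                              "LVEF", "GLS", "nativeT1"),
                               n_boot = 2000,
                               alpha_family = length(biomarkers),
                               seed = NULL) {
  stopifnot(inherits(matching, "match_result"))
  if (!is.null(seed)) set.seed(seed)
  rows_t <- match(matching$pairs$treated_id, data$id)
  rows_c <- match(matching$pairs$control_id, data$id)
  alpha <- 0.05 / alpha_family

  boot_ci <- function(x) {
    meds <- vapply(seq_len(n_boot), function(b) {
      stats::median(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    stats::quantile(meds, c(0.025, 0.975), names = FALSE)
  }

  res <- lapply(biomarkers, function(bm) {
    x_t <- data[[bm]][rows_t]
    x_c <- data[[bm]][rows_c]
    x_t <- x_t[is.finite(x_t)]
    x_c <- x_c[is.finite(x_c)]
    if (length(x_t) == 0L || length(x_c) == 0L) {
      message("biomarker ", bm, " has no finite values in a group; skipped")
      return(NULL)
    }
    exact <- length(x_t) <= 20 && length(x_c) <= 20 &&
      !any(duplicated(c(x_t, x_c)))
    wt <- stats::wilcox.test(x_t, x_c, exact = exact, correct = !exact)
    ci_t <- boot_ci(x_t)
    ci_c <- boot_ci(x_c)
    med_c <- stats::median(x_c)
    data.frame(biomarker = bm,
               median_treated = stats::median(x_t),
               ci_treated_lower = ci_t[1], ci_treated_upper = ci_t[2],
               median_control = med_c,
               ci_control_lower = ci_c[1], ci_control_upper = ci_c[2],
               U = unname(wt$statistic),
               p = wt$p.value,
               significant = wt$p.value < alpha,
               relative_difference = (stats::median(x_t) - med_c) / med_c)
  })
  out <- do.call(rbind, res)
  attr(out, "alpha") <- alpha
  attr(out, "n_boot") <- n_boot
  class(out) <- c("biomarker_comparison", "data.frame")
  out
}

#' End-to-end matched comparison within an activity stratum
#'
#' Convenience wrapper: select the top-active stratum, estimate propensity
#' scores within it, match 1:1, and compare the biomarkers between matched
#' hypertensive and non-hypertensive groups.
#'
#' @inheritParams select_top_active
#' @inheritParams estimate_propensity
#' @inheritParams compare_biomarkers
#' @return list of class `psm_comparison` with `stratum_n`, `propensity`,
#'   `match`, `balance`, `comparison`.
#' @export
psm_compare <- function(data, metric = "TPA", fraction = 0.01,
                        confounders = c("age", "male", "white", "height",
                                        "bmi", "smoker", "hyperlipidaemia",
                                        "diabetes"),
                        treatment = "hypertension",
                        biomarkers = c("MadWT", "MaxWT", "MeanWT", "LVMi",
                                       "LVEDVi", "LVMVR", "LVEF", "GLS",
                                       "nativeT1"),
                        n_boot = 2000, alpha_family = length(biomarkers),
                        seed = NULL) {
  stratum <- select_top_active(data, metric, fraction)
  prop <- estimate_propensity(stratum, confounders, treatment)
  sub <- stratum[prop$rows, , drop = FALSE]
  mres <- match_pairs(prop$scores, sub[[treatment]] == 1, ids = sub$id)
  bal <- match_balance(sub, confounders, treatment, mres)
  cmp <- compare_biomarkers(sub, mres, biomarkers, n_boot = n_boot,
                            alpha_family = alpha_family, seed = seed)
  structure(list(stratum_n = nrow(stratum), propensity = prop,
                 match = mres, balance = bal, comparison = cmp),
            class = "psm_comparison")
}

#' @export
print.psm_comparison <- function(x, ...) {
  cat(sprintf("PSM comparison: stratum n = %d, %d matched pairs\n",
              x$stratum_n, x$match$n_matched))
  cmp <- x$comparison
  cmp$median_treated <- round(cmp$median_treated, 3)
  cmp$median_control <- round(cmp$median_control, 3)
  cmp$p <- signif(cmp$p, 3)
  print(as.data.frame(cmp)[c("biomarker", "median_treated", "median_control",
                             "p", "significant", "relative_difference")])
  invisible(x)
}
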