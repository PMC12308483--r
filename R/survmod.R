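# Risk-factor modelling (Gamma GLM) and stepwise Cox prognosis models.

#' Standardise variables to SD units
#'
#' Divides each variable by its analysis-sample SD (computed on the supplied
#' rows, i.e. after exclusions and before modelling) and keeps the SD map so
#' per-unit and per-SD hazard ratios interconvert exactly:
#' `HR_SD = HR_unit ^ SD`.
#'
#' @param data data.frame.
#' @param vars character vector of numeric columns to standardise.
#' @return list with `data` (standardised copy) and `sd_map` (named numeric).
#' @export
standardize <- function(data, vars) {
  sd_map <- vapply(vars, function(v) {
    x <- data[[v]]
    if (is.null(x) || !is.numeric(x)) {
      stop(sprintf("`%s` is not a numeric column", v), call. = FALSE)
    }
    stats::sd(x, na.rm = TRUE)
  }, numeric(1))
  if (any(!is.finite(sd_map)) || any(sd_map == 0)) {
    stop("zero or undefined SD for: ",
         paste(vars[!is.finite(sd_map) | sd_map == 0], collapse = ", "),
         call. = FALSE)
  }
  for (v in vars) data[[v]] <- data[[v]] / sd_map[[v]]
  list(data = data, sd_map = sd_map)
}

#' Gamma GLM risk-factor model with identity link
#'
#' Fits `outcome ~ predictors` by maximum likelihood with a Gamma response
#' and identity link, the natural model for a strictly positive biomarker
#' whose covariate effects are additive on the mm scale. Continuous
#' predictors are standardised to SD units first (so coefficients read "mm
#' per SD"); binary predictors enter per unit. Fitted means are checked to
#' stay positive.
#'
#' @param data cohort data.frame.
#' @param outcome outcome column name (strictly positive), default `"MadWT"`.
#' @param predictors character vector of predictor columns.
#' @param standardize_continuous standardise continuous predictors to SD
#'   units (default `TRUE`; columns with more than 2 distinct values count
#'   as continuous).
#' @return object of class `gamma_glm_result`: coefficient table
#'   (`estimate`, `se`, `ci_lower`, `ci_upper`, `p`), `sd_map`, `n`, and the
#'   underlying `glm` fit.
#' @export
fit_gamma_glm <- function(data, outcome = "MadWT", predictors,
                          standardize_continuous = TRUE) {
  keep <- stats::complete.cases(data[c(outcome, predictors)])
  data <- data[keep, , drop = FALSE]
  y <- data[[outcome]]
  if (any(y <= 0)) {
    stop(sprintf("`%s` must be strictly positive for a Gamma model (%d violations)",
                 outcome, sum(y <= 0)), call. = FALSE)
  }
  sd_map <- NULL
  if (standardize_continuous && length(predictors) > 0) {
    cont <- predictors[vapply(predictors, function(v) {
      length(unique(data[[v]])) > 2L
    }, logical(1))]
    if (length(cont) > 0) {
      st <- standardize(data, cont)
      data <- st$data
      sd_map <- st$sd_map
    }
  }
  form <- stats::reformulate(if (length(predictors)) predictors else "1",
                             response = outcome)
  # degenerate inputs (e.g. a constant outcome) make the Gamma AIC warn
  # about NaNs; convergence and mean positivity are checked explicitly below
  fit <- suppressWarnings(
    stats::glm(form, data = data,
               family = stats::Gamma(link = "identity"),
               start = c(mean(y), rep(0, length(predictors))),
               control = stats::glm.control(maxit = 100)))
  if (!fit$converged) {
    stop(sprintf("Gamma GLM did not converge in %d iterations", fit$iter),
         call. = FALSE)
  }
  if (any(fit$fitted.values <= 0)) {
    stop("Gamma GLM produced non-positive fitted means", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm),
                    estimate = sm[, 1], se = sm[, 2],
                    ci_lower = sm[, 1] - stats::qnorm(0.975) * sm[, 2],
                    ci_upper = sm[, 1] + stats::qnorm(0.975) * sm[, 2],
                    p = sm[, 4], row.names = NULL)
  structure(list(coefficients = tab, sd_map = sd_map, n = nrow(data),
                 fit = fit),
            class = "gamma_glm_result")
}

#' @export
print.gamma_glm_result <- function(x, ...) {
  cat(sprintf("Gamma GLM (identity link), n = %d\n", x$n))
  print(transform(x$coefficients,
                  estimate = round(estimate, 4), se = round(se, 4),
                  ci_lower = round(ci_lower, 4), ci_upper = round(ci_upper, 4),
                  p = signif(p, 3)))
  invisible(x)
}

#' Stepwise Cox model specifications
#'
#' The four nested prognosis models for a wall-thickness biomarker:
#' Model 1 is the biomarker alone; Model 2 adds cardiovascular risk factors
#' (age, sex, ethnicity, BMI, smoking, hyperlipidaemia, hypertension,
#' diabetes); Model 3 adds the standard CMR biomarkers LVEDVi and LVEF;
#' exploratory Model 4 additionally adjusts for LVMi.
#'
#' @param endpoint endpoint name; time/event columns are
#'   `time_<endpoint>` / `event_<endpoint>`.
#' @param level model level, 1-4.
#' @param biomarker biomarker of interest (default `"MadWT"`).
#' @return object of class `cox_model_spec` with the predictor list.
#' @export
cox_model_spec <- function(endpoint, level, biomarker = "MadWT") {
  if (!level %in% 1:4) stop("`level` must be 1, 2, 3 or 4", call. = FALSE)
  cvrf <- c("age", "male", "white", "bmi", "smoker", "hyperlipidaemia",
            "hypertension", "diabetes")
  preds <- biomarker
  if (level >= 2) preds <- c(preds, cvrf)
  if (level >= 3) preds <- c(preds, "LVEDVi", "LVEF")
  if (level >= 4) preds <- c(preds, "LVMi")
  structure(list(endpoint = endpoint, level = as.integer(level),
                 biomarker = biomarker, predictors = preds),
            class = "cox_model_spec")
}

# assert that specs form a strictly nested sequence (used when several
# levels are fitted together)
#' @keywords internal
#' @noRd
assert_nested <- function(specs) {
  for (i in seq_along(specs)[-1]) {
    if (!all(specs[[i - 1]]$predictors %in% specs[[i]]$predictors) ||
        length(specs[[i]]$predictors) <= length(specs[[i - 1]]$predictors)) {
      stop("model specifications are not strictly nested", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fit a Cox proportional-hazards prognosis model
#'
#' Partial-likelihood fit with Efron tie handling and right censoring at end
#' of follow-up. With `per = "sd"` continuous predictors are divided by their
#' analysis-sample SD so hazard ratios read "per SD"; binary predictors are
#' never rescaled. Harrell's C for the model's linear predictor is attached.
#'
#' @param data cohort data.frame, prevalent-disease subjects already
#'   excluded; complete cases on the model columns are used (count reported
#'   in the result).
#' @param spec a [cox_model_spec()] (or character vector of predictors plus
#'   `endpoint`).
#' @param per `"sd"` (default) or `"unit"` scaling for continuous predictors.
#' @param endpoint used only when `spec` is a bare predictor vector.
#' @return object of class `cox_result`: coefficient table (`log_hr`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `scaling`), `c_index`, `n`, `n_events`,
#'   `sd_map`, `endpoint`, and the `coxph` fit.
#' @export
fit_cox <- function(data, spec, per = c("sd", "unit"), endpoint = NULL) {
  per <- match.arg(per)
  if (inherits(spec, "cox_model_spec")) {
    predictors <- spec$predictors
    endpoint <- spec$endpoint
  } else {
    predictors <- spec
    if (is.null(endpoint)) stop("`endpoint` required", call. = FALSE)
  }
  tcol <- paste0("time_", endpoint)
  ecol <- paste0("event_", endpoint)
  if (is.null(data[[tcol]]) || is.null(data[[ecol]])) {
    stop(sprintf("columns `%s`/`%s` not found", tcol, ecol), call. = FALSE)
  }
  keep <- stats::complete.cases(data[c(tcol, ecol, predictors)])
  data <- data[keep, , drop = FALSE]
  if (any(data[[tcol]] <= 0)) {
    stop("event/censoring times must be positive", call. = FALSE)
  }
  if (sum(data[[ecol]]) == 0) {
    stop("no events for endpoint ", endpoint, call. = FALSE)
  }
  sd_map <- NULL
  if (per == "sd") {
    cont <- predictors[vapply(predictors, function(v) {
      length(unique(data[[v]])) > 2L
    }, logical(1))]
    if (length(cont) > 0) {
      st <- standardize(data, cont)
      data <- st$data
      sd_map <- st$sd_map
    }
  }
  form <- stats::as.formula(paste0(
    "survival::Surv(", tcol, ", ", ecol, ") ~ ",
    paste(predictors, collapse = " + ")))
  fit <- survival::coxph(form, data = data, ties = "efron", x = TRUE)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: some coefficients are not estimable",
         call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  if (any(se > 50)) {
    stop("separation / monotone likelihood detected (unbounded coefficient)",
         call. = FALSE)
  }
  beta <- stats::coef(fit)
  z <- beta / se
  scaling <- ifelse(names(beta) %in% names(sd_map), "per_sd", "per_unit")
  tab <- data.frame(term = names(beta),
                    log_hr = unname(beta), hr = exp(unname(beta)),
                    ci_lower = exp(unname(beta - stats::qnorm(0.975) * se)),
                    ci_upper = exp(unname(beta + stats::qnorm(0.975) * se)),
                    p = 2 * stats::pnorm(-abs(z)),
                    scaling = scaling, row.names = NULL)
  ci <- concordance_index(fit$linear.predictors, data[[tcol]], data[[ecol]])
  structure(list(coefficients = tab, c_index = ci, n = nrow(data),
                 n_events = sum(data[[ecol]]), sd_map = sd_map,
                 endpoint = endpoint, fit = fit,
                 data_rows = which(keep)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox model, endpoint %s: n = %d, events = %d, C-index = %.3f\n",
              x$endpoint, x$n, x$n_events, x$c_index))
  tab <- x$coefficients
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_lower, tab$ci_upper)
  print(tab[c("term", "hr", "p", "scaling")])
  invisible(x)
}

#' Harrell's concordance index
#'
#' Probability that, over usable pairs (both events with distinct times, or
#' an event paired with a subject censored later), the model ranks the
#' earlier event as higher risk; ties in risk count 0.5.
#'
#' @param risk numeric risk scores (higher = higher risk).
#' @param time follow-up times.
#' @param event event indicators (0/1).
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  counts <- cc$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (!is.finite(usable) || usable == 0) {
    stop("no usable pairs for concordance", call. = FALSE)
  }
  unname(cc$concordance)
}

#' Incremental discrimination: delta C-index with bootstrap inference
#'
#' `delta_C = C_aug - C_ref` for two risk scores evaluated on identical
#' subjects, with a two-sided p-value from a paired bootstrap over subjects:
#' subjects are resampled with replacement, both C-indices recomputed on each
#' resample, and the p-value is `2 * min(P(delta* <= 0), P(delta* >= 0))`.
#'
#' @param risk_ref,risk_aug risk scores of the reference and augmented model
#'   on the same rows.
#' @param time,event shared outcome data.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed optional integer seed for the resampling.
#' @return list with `delta_c`, `p`, `c_ref`, `c_aug`, `n_boot`.
#' @export
delta_cindex <- function(risk_ref, risk_aug, time, event, n_boot = 1000,
                         seed = NULL) {
  n <- length(time)
  if (length(risk_ref) != n || length(risk_aug) != n || length(event) != n) {
    stop("risk scores and outcomes must cover identical rows", call. = FALSE)
  }
  c_ref <- concordance_index(risk_ref, time, event)
  c_aug <- concordance_index(risk_aug, time, event)
  delta <- c_aug - c_ref
  if (identical(risk_ref, risk_aug)) {
    return(list(delta_c = 0, p = 1, c_ref = c_ref, c_aug = c_aug,
                n_boot = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  deltas <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(event[idx]) == 0) return(NA_real_)
    concordance_index(risk_aug[idx], time[idx], event[idx]) -
      concordance_index(risk_ref[idx], time[idx], event[idx])
  }, numeric(1))
  deltas <- deltas[is.finite(deltas)]
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(delta_c = delta, p = min(p, 1), c_ref = c_ref, c_aug = c_aug,
       n_boot = length(deltas))
}

#' Cox model diagnostics: multicollinearity and proportional hazards
#'
#' Variance inflation factors are computed from auxiliary linear regressions
#' of each design-matrix column on the others (`VIF = 1 / (1 - R^2)`); the
#' proportional-hazards assumption is checked by regressing each predictor's
#' Schoenfeld residuals on event time and testing the slope.
#'
#' @param cox_result a [fit_cox()] result.
#' @return data.frame of class `cox_diagnostics` with columns `term`, `vif`,
#'   `schoenfeld_slope`, `schoenfeld_p`.
#' @export
cox_diagnostics <- function(cox_result) {
  stopifnot(inherits(cox_result, "cox_result"))
  fit <- cox_result$fit
  X <- fit$x
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("singular design matrix: VIF undefined (perfectly collinear predictors)",
         call. = FALSE)
  }
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    res <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])$residuals
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(res^2) / tss
    1 / (1 - r2)
  }, numeric(1))
  vif <- pmax(vif, 1)

  sr <- stats::residuals(fit, type = "schoenfeld")
  if (is.null(dim(sr))) sr <- matrix(sr, ncol = 1L,
                                     dimnames = list(names(sr), NULL))
  etimes <- as.numeric(rownames(sr))
  slope <- p <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    lmfit <- stats::lm(sr[, j] ~ etimes)
    cf <- summary(lmfit)$coefficients
    slope[j] <- cf[2, 1]
    p[j] <- cf[2, 4]
  }
  structure(data.frame(term = colnames(X), vif = vif,
                       schoenfeld_slope = slope, schoenfeld_p = p,
                       row.names = NULL),
            class = c("cox_diagnostics", "data.frame"))
}

#' Fit the full stepwise model ladder for one biomarker and endpoint
#'
#' Fits Models 1-4 on the identical complete-case row set (so levels are
#' comparable), asserting strict nesting, and reports each level's hazard
#' ratio for the biomarker, C-index, and delta-C against the previous level.
#'
#' @param data cohort data.frame.
#' @param endpoint endpoint name.
#' @param biomarker biomarker of interest.
#' @param per `"sd"` or `"unit"`.
#' @param n_boot bootstrap resamples for each delta-C p-value (0 skips the
#'   bootstrap).
#' @param seed seed for the delta-C bootstrap.
#' @return list of class `cox_ladder`: per-level `cox_result`s, a summary
#'   data.frame, and delta-C entries.
#' @export
fit_cox_ladder <- function(data, endpoint, biomarker = "MadWT",
                           per = "sd", n_boot = 0, seed = NULL) {
  specs <- lapply(1:4, function(l) cox_model_spec(endpoint, l, biomarker))
  assert_nested(specs)
  all_cols <- unique(c(paste0("time_", endpoint), paste0("event_", endpoint),
                       specs[[4]]$predictors))
  rows <- stats::complete.cases(data[all_cols])
  data <- data[rows, , drop = FALSE]
  fits <- lapply(specs, function(sp) fit_cox(data, sp, per = per))
  delta <- vector("list", 3L)
  tcol <- paste0("time_", endpoint)
  ecol <- paste0("event_", endpoint)
  for (l in 2:4) {
    delta[[l - 1]] <- delta_cindex(fits[[l - 1]]$fit$linear.predictors,
                                   fits[[l]]$fit$linear.predictors,
                                   data[[tcol]], data[[ecol]],
                                   n_boot = n_boot,
                                   seed = if (is.null(seed)) NULL
                                   else seed + l)
  }
  summary <- do.call(rbind, lapply(seq_along(fits), function(l) {
    tab <- fits[[l]]$coefficients
    bm <- tab[tab$term == biomarker, ]
    data.frame(model = l, hr = bm$hr, ci_lower = bm$ci_lower,
               ci_upper = bm$ci_upper, p = bm$p,
               c_index = fits[[l]]$c_index,
               n = fits[[l]]$n, n_events = fits[[l]]$n_events)
  }))
  structure(list(fits = fits, summary = summary, delta_c = delta,
                 endpoint = endpoint, biomarker = biomarker),
            class = "cox_ladder")
}

#' @export
print.cox_ladder <- function(x, ...) {
  cat(sprintf("Stepwise Cox models for %s on %s (n = %d, events = %d)\n",
              x$biomarker, x$endpoint, x$fits[[1]]$n, x$fits[[1]]$n_events))
  print(transform(x$summary, hr = round(hr, 3), ci_lower = round(ci_lower, 3),
                  ci_upper = round(ci_upper, 3), p = signif(p, 3),
                  c_index = round(c_index, 4)))
  invisible(x)
}
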