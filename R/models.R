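# Outcome models: negative binomial rates, Cox time-to-event, logistic,
# ordinal logistic and linear models, all reported as covariate-adjusted
# effect estimates with Wald 95% CIs, plus the negative binomial
# sample-size calculation.

new_estimate <- function(measure, estimate, ci_low, ci_high, p_value,
                         arm_summaries = NULL, covariates = character(0),
                         model = NULL, notes = character(0)) {
  structure(list(measure = measure, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, p_value = p_value,
                 arm_summaries = arm_summaries, covariates = covariates,
                 model = model, notes = notes),
            class = "copd_estimate")
}

#' @export
print.copd_estimate <- function(x, digits = 3, ...) {
  lab <- c(rate_ratio = "Rate ratio", odds_ratio = "Odds ratio",
           hazard_ratio = "Hazard ratio",
           mean_difference = "Mean difference")[x$measure]
  cat(sprintf("%s (BFC vs FSC): %.*f  [95%% CI %.*f, %.*f]  p = %.4g\n",
              lab, digits, x$estimate, digits, x$ci_low, digits, x$ci_high,
              x$p_value))
  if (!is.null(x$arm_summaries)) {
    cat(sprintf("  adjusted BFC: %.*f   adjusted FSC: %.*f\n", digits,
                x$arm_summaries[["BFC"]], digits, x$arm_summaries[["FSC"]]))
  }
  if (length(x$covariates)) {
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

# Covariate frame preparation shared by the model fits: coerce
# character/logical to factor, drop zero-variance columns.
prep_covariates <- function(covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(list(df = NULL, used = character(0), dropped = character(0)))
  }
  cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
  dropped <- character(0)
  for (col in names(cv)) {
    if (is.character(cv[[col]]) || is.logical(cv[[col]])) {
      cv[[col]] <- factor(cv[[col]])
    }
    v <- cv[[col]]
    if ((is.factor(v) && nlevels(droplevels(v)) < 2L) ||
        (is.numeric(v) && stats::var(v) == 0)) {
      dropped <- c(dropped, col)
    }
  }
  if (length(dropped)) cv <- cv[, setdiff(names(cv), dropped), drop = FALSE]
  if (NCOL(cv) == 0) cv <- NULL
  list(df = cv, used = if (is.null(cv)) character(0) else names(cv),
       dropped = dropped)
}

arm_factor <- function(arm, ref = "FSC") {
  lev <- c(ref, setdiff(c("BFC", "FSC"), ref))
  f <- factor(as.character(arm), levels = lev)
  if (anyNA(f)) stop("arm must be BFC/FSC", call. = FALSE)
  f
}

wald <- function(est_log, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(exp(est_log - z * se), exp(est_log + z * se))
}

#' Negative binomial exacerbation-rate model
#'
#' Fits a negative binomial GLM with log link of event counts on
#' treatment arm and covariates, with a `log(person_time)` offset. The
#' rate ratio is the exponentiated arm coefficient (BFC vs FSC); the
#' adjusted per-arm rates are obtained by marginal standardization
#' (mean predicted rate per person-year with every patient's arm set to
#' each level).
#'
#' @param counts Non-negative integer event counts.
#' @param arm Treatment arm (`"BFC"`/`"FSC"`).
#' @param covariates Optional data.frame of adjustment covariates.
#' @param person_time Person-time in years (default 1 per patient).
#' @param dispersion `NULL` to estimate the dispersion by maximum
#'   likelihood (the default); a positive value `k` to fix it (variance
#'   `mu + k mu^2`); `0` for Poisson.
#' @param ref Reference arm (default `"FSC"`).
#' @return A `copd_estimate` with `measure = "rate_ratio"`.
#' @export
fit_rate_model <- function(counts, arm, covariates = NULL, person_time = NULL,
                           dispersion = NULL, ref = "FSC") {
  stopifnot(all(counts >= 0))
  if (is.null(person_time)) person_time <- rep(1, length(counts))
  stopifnot(all(person_time > 0))
  f <- arm_factor(arm, ref)
  notes <- character(0)
  by_arm_tot <- tapply(counts, f, sum)
  if (any(by_arm_tot == 0)) {
    notes <- c(notes, "all-zero counts in one arm; ratio undefined")
    return(new_estimate("rate_ratio", NA_real_, NA_real_, NA_real_, NA_real_,
                        notes = notes))
  }
  prep <- prep_covariates(covariates)
  d <- data.frame(.y = counts, .arm = f, .lpt = log(person_time))
  if (!is.null(prep$df)) d <- cbind(d, prep$df)
  fml <- stats::reformulate(c("offset(.lpt)", ".arm", prep$used),
                            response = ".y")
  fit <- withCallingHandlers(
    {
      if (is.null(dispersion)) {
        # the dispersion MLE is unbounded on under-dispersed data; the
        # NB likelihood then degenerates to its Poisson limit
        tryCatch(MASS::glm.nb(fml, data = d), error = function(e) {
          notes <<- c(notes,
                      "dispersion estimate unbounded; Poisson limit used")
          stats::glm(fml, data = d, family = stats::poisson())
        })
      } else if (dispersion > 0) {
        stats::glm(fml, data = d,
                   family = MASS::negative.binomial(theta = 1 / dispersion))
      } else {
        stats::glm(fml, data = d, family = stats::poisson())
      }
    },
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  arm_term <- paste0(".arm", setdiff(levels(f), ref))
  b <- co[arm_term, 1]; se <- co[arm_term, 2]
  ci <- wald(b, se)
  # marginal standardization, rate per person-year
  pred_rate <- function(level) {
    nd <- d
    nd$.arm <- factor(level, levels = levels(f))
    nd$.lpt <- 0
    mean(stats::predict(fit, newdata = nd, type = "response"))
  }
  adj <- c(BFC = pred_rate("BFC"), FSC = pred_rate("FSC"))
  new_estimate("rate_ratio", exp(b), ci[1], ci[2], co[arm_term, 4],
               arm_summaries = adj, covariates = prep$used, model = fit,
               notes = unique(notes))
}

#' Cox model for time to first event, with Kaplan-Meier curves
#'
#' @param times Days from index to the first event or censoring.
#' @param event_flags Logical, event observed.
#' @param arm,covariates,ref As in [fit_rate_model()].
#' @return A `copd_estimate` with `measure = "hazard_ratio"`; the per-arm
#'   Kaplan-Meier fit is stored in `$km` for plotting.
#' @export
fit_time_to_event <- function(times, event_flags, arm, covariates = NULL,
                              ref = "FSC") {
  stopifnot(all(times > 0))
  f <- arm_factor(arm, ref)
  if (sum(event_flags) == 0) stop("no events in either arm", call. = FALSE)
  prep <- prep_covariates(covariates)
  d <- data.frame(.time = times, .event = as.integer(event_flags), .arm = f)
  if (!is.null(prep$df)) d <- cbind(d, prep$df)
  fml <- stats::reformulate(c(".arm", prep$used),
                            response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(fml, data = d, ties = "efron")
  co <- summary(fit)$coefficients
  arm_term <- paste0(".arm", setdiff(levels(f), ref))
  b <- co[arm_term, "coef"]; se <- co[arm_term, "se(coef)"]
  ci <- wald(b, se)
  km <- survival::survfit(survival::Surv(.time, .event) ~ .arm, data = d)
  est <- new_estimate("hazard_ratio", exp(b), ci[1], ci[2],
                      co[arm_term, "Pr(>|z|)"], covariates = prep$used,
                      model = fit)
  est$km <- km
  est
}

#' Logistic model for any-event outcomes
#'
#' @param flags Logical outcome (>= 1 event vs none).
#' @param arm,covariates,ref As in [fit_rate_model()].
#' @return A `copd_estimate` with `measure = "odds_ratio"` and
#'   per-arm observed proportions in `arm_summaries`.
#' @export
fit_binary_model <- function(flags, arm, covariates = NULL, ref = "FSC") {
  f <- arm_factor(arm, ref)
  y <- as.integer(flags)
  notes <- character(0)
  prep <- prep_covariates(covariates)
  d <- data.frame(.y = y, .arm = f)
  if (!is.null(prep$df)) d <- cbind(d, prep$df)
  fml <- stats::reformulate(c(".arm", prep$used), response = ".y")
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::binomial()),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  arm_term <- paste0(".arm", setdiff(levels(f), ref))
  b <- co[arm_term, 1]; se <- co[arm_term, 2]
  ci <- wald(b, se)
  prop <- tapply(y, f, mean)
  new_estimate("odds_ratio", exp(b), ci[1], ci[2], co[arm_term, 4],
               arm_summaries = c(BFC = unname(prop["BFC"]),
                                 FSC = unname(prop["FSC"])),
               covariates = prep$used, model = fit, notes = unique(notes))
}

#' Ordinal (proportional odds) logistic model
#'
#' Used for the distribution of index-medication fills (1, 2, 3, 4+).
#' The proportional-odds assumption is not tested; a note records this.
#'
#' @param category Ordered category labels (character or factor).
#' @param levels Category order (default `c("1","2","3","4+")`).
#' @param arm,covariates,ref As in [fit_rate_model()].
#' @return A `copd_estimate` with `measure = "odds_ratio"` (proportional
#'   odds of being in a higher category, BFC vs FSC).
#' @export
fit_ordinal_model <- function(category, arm, covariates = NULL,
                              levels = c("1", "2", "3", "4+"), ref = "FSC") {
  f <- arm_factor(arm, ref)
  y <- factor(as.character(category), levels = levels, ordered = TRUE)
  if (anyNA(y)) stop("category outside the declared levels", call. = FALSE)
  notes <- "proportional-odds assumption not tested"
  if (length(unique(as.character(y))) < 2L) {
    return(new_estimate("odds_ratio", NA_real_, NA_real_, NA_real_, NA_real_,
                        notes = c(notes, "degenerate outcome: single category")))
  }
  prep <- prep_covariates(covariates)
  d <- data.frame(.y = y, .arm = f)
  if (!is.null(prep$df)) d <- cbind(d, prep$df)
  fml <- stats::reformulate(c(".arm", prep$used), response = ".y")
  fit <- withCallingHandlers(
    MASS::polr(fml, data = d, Hess = TRUE),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  arm_term <- paste0(".arm", setdiff(levels(f), ref))
  b <- stats::coef(fit)[arm_term]
  se <- sqrt(diag(stats::vcov(fit)))[arm_term]
  ci <- wald(b, se)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_estimate("odds_ratio", exp(unname(b)), ci[1], ci[2], unname(p),
               covariates = prep$used, model = fit, notes = unique(notes))
}

#' Linear model for continuous outcomes
#'
#' Used for the proportion of days covered; reports the adjusted mean
#' difference (BFC minus FSC).
#'
#' @param values Numeric outcome.
#' @param arm,covariates,ref As in [fit_rate_model()].
#' @return A `copd_estimate` with `measure = "mean_difference"`.
#' @export
fit_linear_model <- function(values, arm, covariates = NULL, ref = "FSC") {
  f <- arm_factor(arm, ref)
  prep <- prep_covariates(covariates)
  d <- data.frame(.y = values, .arm = f)
  if (!is.null(prep$df)) d <- cbind(d, prep$df)
  fml <- stats::reformulate(c(".arm", prep$used), response = ".y")
  fit <- stats::lm(fml, data = d)
  co <- summary(fit)$coefficients
  arm_term <- paste0(".arm", setdiff(levels(f), ref))
  b <- co[arm_term, 1]; se <- co[arm_term, 2]
  z <- stats::qnorm(0.975)
  means <- tapply(values, f, mean)
  new_estimate("mean_difference", b, b - z * se, b + z * se, co[arm_term, 4],
               arm_summaries = c(BFC = unname(means["BFC"]),
                                 FSC = unname(means["FSC"])),
               covariates = prep$used, model = fit)
}

#' Sample size for comparing two negative binomial rates
#'
#' Minimum per-group sample size to detect a proportional rate reduction
#' between two overdispersed count outcomes, using the Wald variance of
#' the log rate ratio with per-arm contribution `1/(mu t) + k`:
#'
#' `n = ceil( (z_{1-a/2} + z_{1-b})^2 * ((1/(mu0 t) + k) + (1/(mu1 t) + k))
#'            / ln(mu1/mu0)^2 )`,  `mu1 = mu0 (1 - reduction)`.
#'
#' With `dispersion = 0` this reduces to the classical two-rate Poisson
#' formula.
#'
#' @param base_rate Control-arm rate `mu0` (events per person-year).
#' @param rate_reduction Proportional reduction in the treated arm,
#'   in (0, 1).
#' @param alpha Two-sided type I error (default 0.05).
#' @param power Target power (default 0.90).
#' @param dispersion Negative binomial dispersion `k` (variance
#'   `mu + k mu^2`).
#' @param follow_up Follow-up per patient, years (default 1).
#' @return Integer: patients required per group.
#' @export
#' @examples
#' sample_size_nb(0.5, 0.20, dispersion = 1.2)  # 1457
sample_size_nb <- function(base_rate, rate_reduction, alpha = 0.05,
                           power = 0.90, dispersion = 1.2, follow_up = 1) {
  stopifnot(base_rate > 0, alpha > 0, alpha < 1, power > 0.5, power < 1,
            dispersion >= 0, follow_up > 0)
  if (rate_reduction <= 0 || rate_reduction >= 1) {
    stop("rate_reduction must be in (0, 1)", call. = FALSE)
  }
  mu0 <- base_rate
  mu1 <- base_rate * (1 - rate_reduction)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  v <- (1 / (mu0 * follow_up) + dispersion) +
    (1 / (mu1 * follow_up) + dispersion)
  as.integer(ceiling(z^2 * v / log(mu1 / mu0)^2))
}
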