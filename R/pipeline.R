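# End-to-end study runner: simulate -> cohort -> adjudicate -> match ->
# model, as one seeded, reproducible bundle.

#' Study configuration
#'
#' @param sim A [sim_config()] describing the synthetic population.
#' @param variants Follow-up variants to analyze (see [followup_spec()]).
#' @param matching_covariates Covariates the propensity model must
#'   balance; must contain every pre-specified variable
#'   ([prespecified_covariates()]).
#' @param optional_cov Additional balance variables.
#' @param extra_balance_vars Variables evaluated for balance but not
#'   pre-specified (the residual-imbalance candidates forwarded to all
#'   outcome models when unbalanced).
#' @param n_trees Number of trees in the propensity forest.
#' @param caliper_sd_logit Matching caliper (logit-SD multiples).
#' @param seed Seed for propensity estimation and match ordering.
#' @return A validated list of class `"study_config"`.
#' @export
study_config <- function(sim = sim_config(),
                         variants = c("fixed_12mo", "censor_at_switch",
                                      "all_available", "severe_only"),
                         matching_covariates = c(prespecified_covariates(),
                                                 optional_covariates()),
                         optional_cov = optional_covariates(),
                         extra_balance_vars = c("long_stay", "ltra_cat",
                                                "region", "pvd", "specialty"),
                         n_trees = 1000, caliper_sd_logit = 0.2, seed = 1) {
  stopifnot(inherits(sim, "sim_config"))
  variants <- match.arg(variants, several.ok = TRUE)
  missing_prespec <- setdiff(prespecified_covariates(), matching_covariates)
  if (length(missing_prespec)) {
    stop("matching_covariates must include every pre-specified variable; ",
         "missing: ", paste(missing_prespec, collapse = ", "), call. = FALSE)
  }
  dictionary <- c(prespecified_covariates(), optional_covariates(),
                  "long_stay", "ltra_cat", "region", "pvd", "specialty",
                  "index_month", "female", "age_at_index")
  unknown <- setdiff(c(matching_covariates, extra_balance_vars), dictionary)
  if (length(unknown)) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(sim = sim, variants = variants,
                 matching_covariates = matching_covariates,
                 optional_cov = optional_cov,
                 extra_balance_vars = extra_balance_vars,
                 n_trees = n_trees, caliper_sd_logit = caliper_sd_logit,
                 seed = seed),
            class = "study_config")
}

# Analogous pre-index adjustment variable per outcome.
analogous_covariate <- function(outcome) {
  switch(outcome,
         exacerbation = "pre_exac",
         pneumonia = "prior_pneumonia",
         NULL)
}

model_covariate_frame <- function(matched, vars) {
  if (!length(vars)) return(NULL)
  as.data.frame(matched)[, vars, drop = FALSE]
}

#' Run a complete simulated comparative-effectiveness study
#'
#' Generates a synthetic claims database, builds the new-user cohort,
#' adjudicates exacerbation and pneumonia outcomes under the configured
#' follow-up variants, estimates random-forest propensity scores,
#' matches 1:1, evaluates balance, and fits all outcome models on the
#' matched sample. Variables unbalanced after matching (p <= 0.05) are
#' included as covariates in every outcome model, together with the
#' analogous pre-index variable.
#'
#' @param config A [study_config()].
#' @return A list of class `"copd_study"`: `truth`, `cohort`,
#'   `attrition`, `propensity`, `match`, `balance`, `outcomes` (one
#'   data.frame per variant), `estimates` (named `copd_estimate` list),
#'   and `manifest`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  sim <- simulate_claims(config$sim)
  db <- sim$db

  cohort <- build_cohort(db, config$sim$intake_window,
                         epoch_year = config$sim$epoch_year)
  if (!nrow(cohort)) stop("cohort stage: no eligible patients", call. = FALSE)

  prop <- estimate_propensity(cohort, config$matching_covariates,
                              n_trees = config$n_trees, seed = config$seed)
  match <- match_1to1(cohort, prop, config$caliper_sd_logit,
                      seed = config$seed)
  if (!nrow(match$pairs)) stop("matching stage: no pairs formed", call. = FALSE)
  bal_vars <- unique(c(config$matching_covariates, config$extra_balance_vars))
  balance <- balance_table(cohort, match, bal_vars)
  matched <- matched_sample(cohort, match)
  residual <- attr(balance, "residual_covariates")

  outcomes <- list()
  estimates <- list()
  for (v in config$variants) {
    spec <- followup_spec(v)
    out <- build_outcomes(db, matched, spec)
    outcomes[[v]] <- out
    covs <- model_covariate_frame(matched,
                                  unique(c(residual,
                                           analogous_covariate("exacerbation"))))
    estimates[[paste0("exacerbation_rate_", v)]] <-
      fit_rate_model(out$count, out$arm, covariates = covs,
                     person_time = out$person_time)
  }

  main <- outcomes[[config$variants[1]]]
  covs_ex <- model_covariate_frame(matched,
                                   unique(c(residual,
                                            analogous_covariate("exacerbation"))))
  estimates$time_to_first <- fit_time_to_event(
    pmax(main$time_to_first, 0.5), main$event_flag, main$arm,
    covariates = covs_ex)
  covs_pn <- model_covariate_frame(matched,
                                   unique(c(residual,
                                            analogous_covariate("pneumonia"))))
  estimates$pneumonia_any <- fit_binary_model(main$pneumonia, main$arm,
                                              covariates = covs_pn)
  estimates$index_fills <- fit_ordinal_model(main$fill_category, main$arm,
                                             covariates =
                                               model_covariate_frame(matched,
                                                                     residual))
  estimates$pdc <- fit_linear_model(main$pdc, main$arm,
                                    covariates =
                                      model_covariate_frame(matched, residual))

  manifest <- list(seed = config$seed, sim_seed = config$sim$seed,
                   n_patients = config$sim$n_patients,
                   n_cohort = nrow(cohort), n_matched = nrow(match$pairs),
                   package_version = as.character(utils::packageVersion("copdce")),
                   config_string = paste(deparse(config), collapse = "\n"))

  structure(list(truth = sim$truth, cohort = cohort,
                 attrition = attr(cohort, "attrition"),
                 propensity = prop, match = match, balance = balance,
                 outcomes = outcomes, estimates = estimates,
                 manifest = manifest),
            class = "copd_study")
}

#' @export
print.copd_study <- function(x, ...) {
  cat("<copd_study>\n")
  cat(sprintf("  cohort %d -> matched %d pairs\n", nrow(x$cohort),
              nrow(x$match$pairs)))
  cat(sprintf("  balanced %d/%d variables (post-match p > 0.05)\n",
              sum(x$balance$balanced), nrow(x$balance)))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-32s", nm))
    e <- x$estimates[[nm]]
    cat(sprintf("%6.3f [%.3f, %.3f] p=%.3g\n", e$estimate, e$ci_low,
                e$ci_high, e$p_value))
  }
  invisible(x)
}

#' Kaplan-Meier plot of time to first exacerbation
#'
#' @param x A `copd_study`.
#' @param ... Passed to `plot.survfit`.
#' @export
plot.copd_study <- function(x, ...) {
  km <- x$estimates$time_to_first$km
  plot(km, col = c("grey40", "firebrick"), xlab = "Days since index",
       ylab = "Event-free probability", ...)
  graphics::legend("bottomleft", legend = c("FSC", "BFC"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
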