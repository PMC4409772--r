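#' Simulation configuration
#'
#' Parameters of the synthetic claims generator. Defaults emulate the
#' marginal structure of a US managed-care COPD population initiating
#' fixed-dose ICS/LABA therapy: age 64 (SD 11.5), 53% female, 35% with
#' prior asthma, pre-index exacerbation mean 1.06 events/year,
#' post-index exacerbation rate 0.86/person-year (FSC arm) with
#' gamma-frailty dispersion 1.2, event types split
#' inpatient/ED/outpatient-Rx = 0.07/0.15/0.78, 18% annual pneumonia
#' probability, a fill process with 33% single-fill patients and mean 3.9
#' index fills of 30 days supply each, and a 37% BFC market share.
#'
#' Treatment assignment is confounded by default: `assignment_coefs` are
#' log-odds effects of observed covariates on receiving BFC, and
#' `outcome_coefs` are log-rate effects of (a subset of) the same
#' covariates on the exacerbation rate, so the crude unmatched rate ratio
#' is biased away from `true_rr`. The default coefficients are sized so
#' the pre-match arm differences mirror those reported for this
#' population (BFC initiators slightly younger, ~4 points more prior
#' asthma, ~0.14 more prior exacerbations/year, slightly fewer women),
#' using the small-coefficient approximation that a standardized log-odds
#' coefficient `b` induces an arm difference of about `b` SDs.
#'
#' @param n_patients Number of eligible patients to generate.
#' @param seed Integer seed; the same config and seed give an identical
#'   database.
#' @param bfc_share Marginal probability of initiating BFC (vs FSC).
#' @param age_mean,age_sd,age_min,age_max Age-at-index model (years,
#'   truncated normal).
#' @param p_female,p_asthma,p_prior_pneumonia Covariate prevalences.
#' @param prior_exac_mean Marginal mean pre-index exacerbation count
#'   (gamma-Poisson with the patient's shared frailty).
#' @param fsc_rate Annual post-index exacerbation rate in the FSC arm.
#' @param true_rr True BFC:FSC rate ratio (1 = null).
#' @param dispersion Negative binomial dispersion k: count variance is
#'   `mu + k mu^2` (gamma frailty with mean 1, variance k). `0` gives
#'   Poisson counts.
#' @param event_type_split Probabilities of inpatient / ED / outpatient-Rx
#'   event types (must sum to 1).
#' @param pneumonia_prob Probability of >=1 pneumonia diagnosis in the
#'   post-index year.
#' @param single_fill_prob Probability a patient never refills the index
#'   drug.
#' @param mean_index_fills Target mean number of index-drug fills
#'   (including the index fill); the refill geometric parameter is
#'   calibrated so the truncated fill distribution hits this mean.
#' @param days_supply Days supply per index-drug fill.
#' @param switch_prob Probability of filling a different ICS/LABA
#'   combination during follow-up.
#' @param assignment_coefs Named log-odds coefficients (on
#'   `age_z`, `female`, `asthma`, `prior_exac`) for treatment assignment.
#' @param outcome_coefs Named log-rate coefficients (on `age_z`,
#'   `asthma`) for the exacerbation rate.
#' @param comorbidity_prev Named prevalences of the comorbidity flags.
#' @param prior_med_means,post_med_means Named Poisson means of random
#'   pre-/post-index fill counts by drug class (pre-index OCS capped at 4
#'   fills so chronic-OCS exclusion is never triggered by chance).
#' @param intake_window Integer day-index interval `[start, end]` in which
#'   index fills occur.
#' @param epoch_year Calendar year of day 0, used to derive `birth_year`
#'   from age.
#' @param extra_followup_mean Mean extra enrollment (days) beyond
#'   `index + 365` (geometric).
#' @param decoy_share Ineligible decoy patients to add, as a fraction of
#'   `n_patients`; decoys each violate exactly one selection criterion.
#' @param noise Add decoy claims (same-day ED + admission pairs, OCS
#'   fills near hospitalizations, duplicate fills per visit) that the
#'   adjudication attribution rules must absorb without changing event
#'   counts.
#' @param dx_slots Number of diagnosis columns on medical claims.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 2000,
                       seed = 1,
                       bfc_share = 0.37,
                       age_mean = 64, age_sd = 11.5, age_min = 40, age_max = 95,
                       p_female = 0.53,
                       p_asthma = 0.35,
                       p_prior_pneumonia = 0.23,
                       prior_exac_mean = 1.06,
                       fsc_rate = 0.86,
                       true_rr = 1.0,
                       dispersion = 1.2,
                       event_type_split = c(inpatient = 0.07, ed = 0.15,
                                            outpatient_rx = 0.78),
                       pneumonia_prob = 0.18,
                       single_fill_prob = 0.33,
                       mean_index_fills = 3.9,
                       days_supply = 30,
                       switch_prob = 0.10,
                       assignment_coefs = c(age_z = -0.11, female = -0.10,
                                            asthma = 0.17, prior_exac = 0.10),
                       outcome_coefs = c(age_z = 0.10, asthma = 0.25),
                       comorbidity_prev = c(hypertension = 0.68, diabetes = 0.30,
                                            pvd = 0.10, cad = 0.25,
                                            depression = 0.15,
                                            heart_failure = 0.12),
                       prior_med_means = c(OCS = 0.8, ANTIBIOTIC = 2.3,
                                           SABA = 2.4, SABA_SAMA = 0.5,
                                           LABA = 0.2, LAMA = 1.1, ICS = 0.3,
                                           LTRA = 0.3),
                       post_med_means = c(OCS = 0.8, ANTIBIOTIC = 1.8,
                                          SABA = 1.5, SABA_SAMA = 0.4,
                                          LABA = 0.1, LAMA = 0.8, ICS = 0.2,
                                          LTRA = 0.3),
                       intake_window = c(400L, 1400L),
                       epoch_year = 2008L,
                       extra_followup_mean = 365,
                       decoy_share = 0,
                       noise = FALSE,
                       dx_slots = 5L) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 1,
            bfc_share > 0, bfc_share < 1,
            p_female >= 0, p_female <= 1,
            p_asthma >= 0, p_asthma <= 1,
            prior_exac_mean > 0, fsc_rate > 0, true_rr > 0,
            dispersion >= 0,
            abs(sum(event_type_split) - 1) < 1e-8,
            all(event_type_split >= 0),
            pneumonia_prob >= 0, pneumonia_prob <= 1,
            single_fill_prob >= 0, single_fill_prob < 1,
            mean_index_fills >= 1, days_supply >= 1,
            switch_prob >= 0, switch_prob <= 1,
            intake_window[1] >= 366, intake_window[2] >= intake_window[1],
            decoy_share >= 0, dx_slots >= 2)
  if (!all(c("inpatient", "ed", "outpatient_rx") %in% names(event_type_split))) {
    stop("event_type_split must be named inpatient/ed/outpatient_rx", call. = FALSE)
  }
  cfg$fill_geom_p <- calibrate_fill_p(mean_index_fills, single_fill_prob)
  structure(cfg, class = "sim_config")
}

# Solve for the geometric refill parameter so that the truncated fill-count
# distribution (1 with prob p1; otherwise 2 + Geom(p), truncated at
# max_fills) has the configured mean.
calibrate_fill_p <- function(target_mean, single_prob, max_fills = 12L) {
  f <- function(p) {
    k <- 0:(max_fills - 3L)
    e <- sum((2 + k) * p * (1 - p)^k) + max_fills * (1 - p)^(max_fills - 2L)
    single_prob + (1 - single_prob) * e - target_mean
  }
  if (f(1 - 1e-9) > 0) return(1 - 1e-9)  # target at/below the minimum mean
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# Expected number of index fills implied by a config (exact, truncated
# distribution) -- used as the calibration reference.
expected_index_fills <- function(config, max_fills = 12L) {
  p <- config$fill_geom_p
  k <- 0:(max_fills - 3L)
  e <- sum((2 + k) * p * (1 - p)^k) + max_fills * (1 - p)^(max_fills - 2L)
  config$single_fill_prob + (1 - config$single_fill_prob) * e
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_patients %d (decoy share %.2f), seed %d\n",
              x$n_patients, x$decoy_share, x$seed))
  cat(sprintf("  BFC share %.2f; FSC rate %.2f/py; true RR %.2f; dispersion %.1f\n",
              x$bfc_share, x$fsc_rate, x$true_rr, x$dispersion))
  cat(sprintf("  noise %s\n", if (isTRUE(x$noise)) "ON" else "off"))
  invisible(x)
}
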