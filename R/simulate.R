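# Synthetic claims generator.
#
# Layout guarantees (noise off) that running cohort selection + event
# adjudication on the output reproduces the intended ground truth exactly:
#
#   * intended event onsets are spaced >= 26 days apart, so an
#     outpatient-Rx fill (0-10 days after its visit) can never fall within
#     the 14-day absorption window of a neighbouring severe event, and no
#     two intended events merge under the 14-day rule;
#   * the pre-index year is partitioned into non-interacting zones:
#       zone A [index-365, index-221]  exacerbation bundles
#       zone B [index-195, index-100]  diagnosis-pathway claims
#       zone C [index-85,  index-15]   random medication fills and
#                                      comorbidity diagnosis visits
#     with buffers wide enough that no zone-C fill can pair with a zone-B
#     COPD visit (gap > 10 days) or be absorbed by a zone-A/B severe event
#     (gap > 14 days);
#   * post-index random fills are adjudication-neutral: a stray OCS or
#     antibiotic fill either pairs with an intended event visit (deduped
#     to the same single candidate) or with no COPD visit at all, and
#     non-event post-index medical claims never carry COPD codes.

COPD_CODES      <- c("491.21", "491.22", "492.8", "496")
PNEUMONIA_CODES <- c("486", "481", "482.41", "480.9")
FILLER_DX       <- "786.09"   # dyspnea; used when COPD sits in slot 2

COMORBIDITY_DX <- c(hypertension = "401.9", diabetes = "250.00", pvd = "443.9",
                    cad = "414.01", depression = "311", heart_failure = "428.0")

SPECIALTIES <- c("pulmonology", "internal_medicine", "family_medicine",
                 "cardiology", "other")
REGIONS <- c("northeast", "midwest", "south", "west")

ZONE_A <- c(-365L, -221L)
ZONE_B <- c(-195L, -100L)
ZONE_C <- c(-85L, -15L)
POST_EVENT_SPAN <- c(0L, 350L)
EVENT_GAP <- 26L
PATHWAY_PROBS <- c(inpatient = 0.12, ed = 0.13, office2 = 0.75)

# Sorted integer onsets in [lo, hi], pairwise >= gap apart.
space_events <- function(m, lo, hi, gap = EVENT_GAP) {
  if (m == 0L) return(integer(0))
  span <- (hi - lo) - gap * (m - 1L)
  u <- sort(runif(m, 0, span + 1))
  lo + pmin(floor(u), span) + gap * (seq_len(m) - 1L)
}

max_events_in <- function(lo, hi, gap = EVENT_GAP) {
  as.integer((hi - lo) %/% gap + 1L)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

rbind_blocks <- function(blocks, schema) {
  blocks <- Filter(function(b) !is.null(b) && nrow(b) > 0, blocks)
  if (!length(blocks)) {
    return(as.data.frame(lapply(schema, function(cl) vector(cl, 0)),
                         stringsAsFactors = FALSE))
  }
  do.call(rbind, blocks)
}

MED_SCHEMA <- c(patient_id = "character", service_date = "integer",
                place_of_service = "character", icu_flag = "logical",
                admission_date = "integer", discharge_date = "integer",
                dx1 = "character", dx2 = "character")
RX_SCHEMA <- c(patient_id = "character", fill_date = "integer",
               drug_class = "character", days_supply = "integer")

med_block <- function(patient_id, service_date, place, dx1, dx2 = NA_character_,
                      icu = FALSE, admission = NA_integer_,
                      discharge = NA_integer_) {
  k <- max(length(patient_id), length(service_date))
  if (k == 0L || length(patient_id) == 0L) return(NULL)
  data.frame(patient_id = rep_len(patient_id, k),
             service_date = rep_len(as.integer(service_date), k),
             place_of_service = rep_len(place, k),
             icu_flag = rep_len(icu, k),
             admission_date = as.integer(rep_len(admission, k)),
             discharge_date = as.integer(rep_len(discharge, k)),
             dx1 = rep_len(as.character(dx1), k),
             dx2 = rep_len(as.character(dx2), k),
             stringsAsFactors = FALSE)
}

rx_block <- function(patient_id, fill_date, drug_class, days_supply) {
  k <- max(length(patient_id), length(fill_date))
  if (k == 0L || length(patient_id) == 0L) return(NULL)
  data.frame(patient_id = rep_len(patient_id, k),
             fill_date = rep_len(as.integer(fill_date), k),
             drug_class = rep_len(drug_class, k),
             days_supply = as.integer(rep_len(days_supply, k)),
             stringsAsFactors = FALSE)
}

# Claim bundles for a table of intended exacerbation events
# (patient_id, onset, type). Returns list(med = ..., rx = ...).
realize_exacerbations <- function(ev) {
  med <- list(); rx <- list()
  inp <- ev[ev$type == "inpatient", , drop = FALSE]
  if (nrow(inp)) {
    stay <- sample(0:13, nrow(inp), replace = TRUE)
    med$inp <- med_block(inp$patient_id, inp$onset, "inpatient",
                         dx1 = sample(COPD_CODES, nrow(inp), replace = TRUE),
                         icu = stats::runif(nrow(inp)) < 0.08,
                         admission = inp$onset, discharge = inp$onset + stay)
  }
  ed <- ev[ev$type == "ed", , drop = FALSE]
  if (nrow(ed)) {
    copd <- sample(COPD_CODES, nrow(ed), replace = TRUE)
    primary <- stats::runif(nrow(ed)) < 0.5
    med$ed <- med_block(ed$patient_id, ed$onset, "ed",
                        dx1 = ifelse(primary, copd, FILLER_DX),
                        dx2 = ifelse(primary, NA_character_, copd))
  }
  out <- ev[ev$type == "outpatient_rx", , drop = FALSE]
  if (nrow(out)) {
    copd <- sample(COPD_CODES, nrow(out), replace = TRUE)
    primary <- stats::runif(nrow(out)) < 0.7
    med$visit <- med_block(out$patient_id, out$onset, "office",
                           dx1 = ifelse(primary, copd, FILLER_DX),
                           dx2 = ifelse(primary, NA_character_, copd))
    rx$burst <- rx_block(out$patient_id,
                         out$onset + sample(0:10, nrow(out), replace = TRUE),
                         sample(c("OCS", "ANTIBIOTIC"), nrow(out), replace = TRUE),
                         days_supply = 5L)
  }
  list(med = med, rx = rx)
}

#' Generate a synthetic claims database with known ground truth
#'
#' Draws a population of COPD patients initiating BFC or FSC, realises
#' every intended exacerbation and pneumonia event as the minimal claim
#' bundle of its type, populates pre-index history (inclusion-pathway
#' diagnoses, prior exacerbations, medication fills, comorbidity codes)
#' and post-index medication use, and returns both the claims database
#' and the generator's intent (the ground truth) for recovery testing.
#'
#' With `config$noise = TRUE`, decoy claims are added that the
#' adjudication attribution rules must absorb (same-day ED + admission
#' pairs, OCS fills near hospitalizations, duplicate fills per visit);
#' the intended event set is unchanged. With `config$decoy_share > 0`,
#' ineligible decoy patients are appended, each violating exactly one
#' selection criterion recorded in the ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `"copd_sim"` with elements `db` (a
#'   [claims_db()]), `truth` (list of `patients`, `events`, `pre_events`
#'   data frames) and `config`.
#' @export
simulate_claims <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_elig <- cfg$n_patients
  n_decoy <- round(cfg$decoy_share * n_elig)
  decoy_types <- c("age_lt_40", "enrollment_gap", "cancer", "chronic_ocs",
                   "dual_initiation", "prior_ics_laba", "insufficient_dx")
  n <- n_elig + n_decoy
  decoy <- c(rep("", n_elig), rep_len(decoy_types, n_decoy))

  pid <- sprintf("PT%06d", seq_len(n))
  index_date <- sample(cfg$intake_window[1]:cfg$intake_window[2], n, replace = TRUE)

  age <- round(rtrunc_norm(n, cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max))
  young <- decoy == "age_lt_40"
  if (any(young)) age[young] <- sample(25:39, sum(young), replace = TRUE)
  birth_year <- as.integer(cfg$epoch_year + floor(index_date / 365.25) - age)

  female <- stats::runif(n) < cfg$p_female
  asthma <- stats::runif(n) < cfg$p_asthma
  prior_pneu <- stats::runif(n) < cfg$p_prior_pneumonia
  comorb <- vapply(cfg$comorbidity_prev, function(p) stats::runif(n) < p,
                   logical(n))
  if (is.null(dim(comorb))) comorb <- matrix(comorb, nrow = n,
                                             dimnames = list(NULL, names(cfg$comorbidity_prev)))
  region <- sample(REGIONS, n, replace = TRUE, prob = c(0.20, 0.25, 0.35, 0.20))
  specialty <- sample(SPECIALTIES, n, replace = TRUE,
                      prob = c(0.25, 0.30, 0.30, 0.05, 0.10))

  frailty <- if (cfg$dispersion > 0) {
    stats::rgamma(n, shape = 1 / cfg$dispersion, scale = cfg$dispersion)
  } else rep(1, n)

  # --- pre-index exacerbations and the inclusion diagnosis pathway -------
  pathway <- sample(names(PATHWAY_PROBS), n, replace = TRUE, prob = PATHWAY_PROBS)
  pathway[decoy == "insufficient_dx"] <- "single_office"
  base_pre <- max(cfg$prior_exac_mean - sum(PATHWAY_PROBS[c("inpatient", "ed")]),
                  0.05)
  cap_pre <- max_events_in(ZONE_A[1], ZONE_A[2])
  m_pre <- pmin(stats::rpois(n, base_pre * frailty), cap_pre)
  m_pre[decoy == "insufficient_dx"] <- 0L
  path_severe <- pathway %in% c("inpatient", "ed")
  pre_exac_count <- m_pre + as.integer(path_severe)

  # --- confounded treatment assignment ----------------------------------
  ac <- cfg$assignment_coefs
  age_z <- (age - cfg$age_mean) / cfg$age_sd
  lp <- ac[["age_z"]] * age_z + ac[["female"]] * female +
    ac[["asthma"]] * asthma + ac[["prior_exac"]] * pre_exac_count
  p_bfc <- stats::plogis(stats::qlogis(cfg$bfc_share) + (lp - mean(lp)))
  arm <- ifelse(stats::runif(n) < p_bfc, "BFC", "FSC")

  # --- post-index exacerbation process ----------------------------------
  oc <- cfg$outcome_coefs
  mult <- exp(oc[["age_z"]] * age_z + oc[["asthma"]] * asthma)
  mult <- mult / mean(mult)
  rate <- cfg$fsc_rate * ifelse(arm == "BFC", cfg$true_rr, 1) * mult
  cap_post <- min(max_events_in(POST_EVENT_SPAN[1], POST_EVENT_SPAN[2]), 13L)
  m_post <- pmin(stats::rpois(n, rate * frailty), cap_post)

  type_levels <- c("inpatient", "ed", "outpatient_rx")
  draw_events <- function(counts, lo, hi, offset) {
    idx <- which(counts > 0L)
    if (!length(idx)) {
      return(data.frame(patient_id = character(0), onset = integer(0),
                        type = character(0), stringsAsFactors = FALSE))
    }
    onsets <- unlist(lapply(idx, function(i) {
      offset[i] + space_events(counts[i], lo, hi)
    }), use.names = FALSE)
    data.frame(
      patient_id = rep(pid[idx], counts[idx]),
      onset = as.integer(onsets),
      type = sample(type_levels, sum(counts[idx]), replace = TRUE,
                    prob = cfg$event_type_split[type_levels]),
      stringsAsFactors = FALSE)
  }

  post_events <- draw_events(m_post, POST_EVENT_SPAN[1], POST_EVENT_SPAN[2],
                             index_date)
  pre_events <- draw_events(m_pre, ZONE_A[1], ZONE_A[2], index_date)

  sev_idx <- which(path_severe)
  if (length(sev_idx)) {
    path_events <- data.frame(
      patient_id = pid[sev_idx],
      onset = as.integer(index_date[sev_idx] +
                           sample(ZONE_B[1]:ZONE_B[2], length(sev_idx),
                                  replace = TRUE)),
      type = pathway[sev_idx],
      stringsAsFactors = FALSE)
    pre_events <- rbind(pre_events, path_events)
  }
  pre_events <- pre_events[order(pre_events$patient_id, pre_events$onset), ,
                           drop = FALSE]
  rownames(pre_events) <- NULL

  med <- list(); rx <- list()
  post_bundle <- realize_exacerbations(post_events)
  pre_bundle <- realize_exacerbations(pre_events)
  med <- c(med, post_bundle$med, pre_bundle$med)
  rx <- c(rx, post_bundle$rx, pre_bundle$rx)

  # pathway office visits (zone B): two distinct-day COPD visits, no fills
  off2 <- which(pathway == "office2")
  if (length(off2)) {
    d1 <- sample(ZONE_B[1]:(ZONE_B[2] - 1L), length(off2), replace = TRUE)
    d2 <- d1 + sample(1:20, length(off2), replace = TRUE)
    d2 <- pmin(d2, ZONE_B[2])
    med$path1 <- med_block(pid[off2], index_date[off2] + d1, "office",
                           dx1 = sample(COPD_CODES, length(off2), replace = TRUE))
    med$path2 <- med_block(pid[off2], index_date[off2] + d2, "office",
                           dx1 = sample(COPD_CODES, length(off2), replace = TRUE))
  }
  one_off <- which(pathway == "single_office")
  if (length(one_off)) {
    med$path_single <- med_block(
      pid[one_off],
      index_date[one_off] + sample(ZONE_B[1]:ZONE_B[2], length(one_off),
                                   replace = TRUE),
      "office", dx1 = sample(COPD_CODES, length(one_off), replace = TRUE))
  }

  # comorbidity / history diagnosis visits (zone C, never COPD-coded)
  zone_c_day <- function(k) sample(ZONE_C[1]:ZONE_C[2], k, replace = TRUE)
  for (cond in colnames(comorb)) {
    has <- which(comorb[, cond])
    if (length(has)) {
      med[[paste0("cm_", cond)]] <- med_block(
        pid[has], index_date[has] + zone_c_day(length(has)), "office",
        dx1 = COMORBIDITY_DX[[cond]])
    }
  }
  has <- which(asthma)
  if (length(has)) {
    med$cm_asthma <- med_block(pid[has], index_date[has] + zone_c_day(length(has)),
                               "office", dx1 = "493.20")
  }
  has <- which(prior_pneu)
  if (length(has)) {
    med$cm_pneu <- med_block(pid[has], index_date[has] + zone_c_day(length(has)),
                             "office",
                             dx1 = sample(PNEUMONIA_CODES, length(has),
                                          replace = TRUE))
  }

  # --- post-index pneumonia ---------------------------------------------
  pneu <- stats::runif(n) < cfg$pneumonia_prob
  pneu_day <- ifelse(pneu, index_date + sample(0:365, n, replace = TRUE),
                     NA_integer_)
  pneu_place <- ifelse(pneu,
                       sample(c("inpatient", "ed", "outpatient"), n,
                              replace = TRUE, prob = c(0.45, 0.05, 0.50)),
                       NA_character_)
  for (pl in c("inpatient", "ed", "outpatient")) {
    sel <- which(pneu & pneu_place == pl)
    if (!length(sel)) next
    code <- sample(PNEUMONIA_CODES, length(sel), replace = TRUE)
    if (pl == "inpatient") {
      med[[paste0("pn_", pl)]] <- med_block(
        pid[sel], pneu_day[sel], "inpatient", dx1 = code,
        icu = stats::runif(length(sel)) < 0.15,
        admission = pneu_day[sel],
        discharge = pneu_day[sel] + sample(0:9, length(sel), replace = TRUE))
    } else {
      med[[paste0("pn_", pl)]] <- med_block(
        pid[sel], pneu_day[sel], if (pl == "ed") "ed" else "office", dx1 = code)
    }
  }

  # --- index-drug fill process ------------------------------------------
  singles <- stats::runif(n) < cfg$single_fill_prob
  n_fills <- ifelse(singles, 1L,
                    pmin(2L + stats::rgeom(n, cfg$fill_geom_p), 12L))
  rx$index <- rx_block(rep(pid, n_fills),
                       unlist(lapply(seq_len(n), function(i) {
                         index_date[i] + 28L * (seq_len(n_fills[i]) - 1L)
                       }), use.names = FALSE),
                       rep(arm, n_fills), cfg$days_supply)

  # --- ICS/LABA switching ------------------------------------------------
  switched <- stats::runif(n) < cfg$switch_prob
  switch_day <- ifelse(switched, index_date + sample(30:330, n, replace = TRUE),
                       NA_integer_)
  switch_class <- ifelse(stats::runif(n) < 0.5, "OTHER_ICS_LABA",
                         ifelse(arm == "BFC", "FSC", "BFC"))
  sel <- which(switched)
  if (length(sel)) {
    rx$switch <- rx_block(pid[sel], switch_day[sel], switch_class[sel], 30L)
  }

  # --- random medication fills (pre: zone C; post: anywhere in follow-up)
  draw_fills <- function(means, when, ocs_cap = NULL) {
    out <- list()
    for (cls in names(means)) {
      cnt <- stats::rpois(n, means[[cls]])
      if (!is.null(ocs_cap) && cls == "OCS") cnt <- pmin(cnt, ocs_cap)
      idx <- which(cnt > 0L)
      if (!length(idx)) next
      total <- sum(cnt[idx])
      days <- if (identical(when, "pre")) {
        sample(ZONE_C[1]:ZONE_C[2], total, replace = TRUE)
      } else {
        sample(0:364, total, replace = TRUE)
      }
      ds <- if (cls %in% c("OCS", "ANTIBIOTIC")) 10L else 30L
      out[[cls]] <- rx_block(rep(pid[idx], cnt[idx]),
                             rep(index_date[idx], cnt[idx]) + days, cls, ds)
    }
    out
  }
  pre_f <- draw_fills(cfg$prior_med_means, "pre", ocs_cap = 4L)
  names(pre_f) <- paste0("pre_", names(pre_f))
  post_f <- draw_fills(cfg$post_med_means, "post")
  names(post_f) <- paste0("post_", names(post_f))
  rx <- c(rx, pre_f, post_f)

  # --- decoy patients: break exactly one criterion -----------------------
  sel <- which(decoy == "cancer")
  if (length(sel)) {
    med$decoy_cancer <- med_block(pid[sel],
                                  index_date[sel] + zone_c_day(length(sel)),
                                  "office", dx1 = "153.9")
  }
  sel <- which(decoy == "chronic_ocs")
  if (length(sel)) {
    rx$decoy_ocs <- rx_block(rep(pid[sel], 2L),
                             c(index_date[sel] + zone_c_day(length(sel)),
                               index_date[sel] + zone_c_day(length(sel))),
                             "OCS", 90L)
  }
  sel <- which(decoy == "dual_initiation")
  if (length(sel)) {
    rx$decoy_dual <- rx_block(pid[sel], index_date[sel],
                              ifelse(arm[sel] == "BFC", "FSC", "BFC"), 30L)
  }
  sel <- which(decoy == "prior_ics_laba")
  if (length(sel)) {
    rx$decoy_naive <- rx_block(pid[sel],
                               index_date[sel] + zone_c_day(length(sel)),
                               "OTHER_ICS_LABA", 30L)
  }

  # --- optional noise exercising the attribution rules -------------------
  if (isTRUE(cfg$noise)) {
    inp <- post_events[post_events$type == "inpatient", , drop = FALSE]
    if (nrow(inp)) {
      copd <- sample(COPD_CODES, nrow(inp), replace = TRUE)
      # ED visit during the hospital stay: collapsed by rule (i)
      med$noise_ed <- med_block(inp$patient_id, inp$onset, "ed",
                                dx1 = FILLER_DX, dx2 = copd)
      # office visit + fill hugging the admission: absorbed by rule (ii)
      ok <- inp$onset - 5L >= index_date[match(inp$patient_id, pid)]
      if (any(ok)) {
        med$noise_visit <- med_block(inp$patient_id[ok], inp$onset[ok] - 5L,
                                     "office",
                                     dx1 = sample(COPD_CODES, sum(ok),
                                                  replace = TRUE))
        rx$noise_fill <- rx_block(inp$patient_id[ok], inp$onset[ok] - 2L,
                                  "OCS", 5L)
      }
    }
    out <- post_events[post_events$type == "outpatient_rx", , drop = FALSE]
    if (nrow(out)) {
      # second qualifying fill for the same visit: deduped by rule (iii)
      rx$noise_dup <- rx_block(out$patient_id,
                               out$onset + sample(0:10, nrow(out), replace = TRUE),
                               "ANTIBIOTIC", 10L)
    }
  }

  # --- enrollment --------------------------------------------------------
  extra <- stats::rgeom(n, 1 / (cfg$extra_followup_mean + 1))
  enroll_start <- index_date - 365L - sample(0:60, n, replace = TRUE)
  enroll_end <- index_date + 365L + extra
  enroll_end[decoy == "enrollment_gap"] <-
    index_date[decoy == "enrollment_gap"] + 200L

  # --- assemble tables ---------------------------------------------------
  medical <- rbind_blocks(med, MED_SCHEMA)
  pharmacy <- rbind_blocks(rx, RX_SCHEMA)
  medical <- medical[order(medical$patient_id, medical$service_date,
                           medical$place_of_service), , drop = FALSE]
  pharmacy <- pharmacy[order(pharmacy$patient_id, pharmacy$fill_date,
                             pharmacy$drug_class), , drop = FALSE]
  medical$provider_specialty <- specialty[match(medical$patient_id, pid)]
  for (k in seq_len(cfg$dx_slots)[-(1:2)]) {
    medical[[paste0("dx", k)]] <- NA_character_
  }
  medical <- cbind(claim_id = sprintf("M%08d", seq_len(nrow(medical))), medical,
                   stringsAsFactors = FALSE)
  dxn <- paste0("dx", seq_len(cfg$dx_slots))
  medical <- medical[, c("claim_id", "patient_id", "service_date",
                         "place_of_service", "icu_flag", "admission_date",
                         "discharge_date", dxn, "provider_specialty")]
  pharmacy <- cbind(claim_id = sprintf("P%08d", seq_len(nrow(pharmacy))),
                    pharmacy, stringsAsFactors = FALSE)
  rownames(medical) <- rownames(pharmacy) <- NULL

  patients <- data.frame(patient_id = pid, birth_year = birth_year,
                         sex = ifelse(female, "female", "male"),
                         region = region, stringsAsFactors = FALSE)
  enrollment <- data.frame(patient_id = pid, start_date = enroll_start,
                           end_date = as.integer(enroll_end),
                           medical_eligible = TRUE, pharmacy_eligible = TRUE,
                           stringsAsFactors = FALSE)
  db <- claims_db(patients, enrollment, medical, pharmacy)

  truth_patients <- data.frame(
    patient_id = pid, eligible = decoy == "",
    ineligible_reason = ifelse(decoy == "", NA_character_, decoy),
    arm = arm, index_date = index_date, age = age,
    female = female, asthma = asthma, prior_pneumonia = prior_pneu,
    pre_exac_count = pre_exac_count, post_exac_count = m_post,
    n_index_fills = n_fills,
    pdc = pmin(1, n_fills * cfg$days_supply / 365),
    switch_day = as.integer(switch_day),
    pneumonia_day = as.integer(pneu_day), pneumonia_place = pneu_place,
    frailty = frailty, enroll_start = enroll_start,
    enroll_end = as.integer(enroll_end),
    region = region, specialty = specialty,
    stringsAsFactors = FALSE)
  truth_patients <- cbind(truth_patients, as.data.frame(comorb))

  structure(list(db = db,
                 truth = list(patients = truth_patients,
                              events = post_events,
                              pre_events = pre_events),
                 config = cfg),
            class = "copd_sim")
}

#' @export
print.copd_sim <- function(x, ...) {
  cat("<copd_sim>\n")
  cat(sprintf("  %d patients (%d eligible), seed %d\n",
              nrow(x$truth$patients), sum(x$truth$patients$eligible),
              x$config$seed))
  cat(sprintf("  intended post-index events: %d; true RR %.2f\n",
              nrow(x$truth$events), x$config$true_rr))
  print(x$db)
  invisible(x)
}
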