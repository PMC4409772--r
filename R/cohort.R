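# New-user cohort construction: index-date identification, sequential
# inclusion/exclusion with a per-criterion attrition table, and pre-index
# covariate extraction.

#' Identify index dates
#'
#' The index date is each patient's earliest BFC or FSC fill inside the
#' intake window. Patients whose earliest BFC and FSC fills share that
#' date are flagged as dual initiators (excluded later). Patients without
#' a qualifying fill are absent from the result.
#'
#' @param db A [claims_db()].
#' @param intake_window Integer `[start, end]` day-index interval.
#' @return data.frame: `patient_id`, `index_date`, `index_drug`
#'   (`NA` for dual initiators), `dual`.
#' @export
find_index <- function(db, intake_window) {
  ph <- db$pharmacy
  sel <- ph$drug_class %in% c("BFC", "FSC") &
    ph$fill_date >= intake_window[1] & ph$fill_date <= intake_window[2]
  ph <- ph[sel, , drop = FALSE]
  if (!nrow(ph)) {
    return(data.frame(patient_id = character(0), index_date = integer(0),
                      index_drug = character(0), dual = logical(0),
                      stringsAsFactors = FALSE))
  }
  ph <- ph[order(ph$patient_id, ph$fill_date), , drop = FALSE]
  first <- ph[!duplicated(ph$patient_id), c("patient_id", "fill_date")]
  at_index <- merge(ph, stats::setNames(first, c("patient_id", "index_date")),
                    by = "patient_id")
  at_index <- at_index[at_index$fill_date == at_index$index_date, ,
                       drop = FALSE]
  ncls <- tapply(at_index$drug_class, at_index$patient_id,
                 function(x) length(unique(x)))
  drug <- tapply(at_index$drug_class, at_index$patient_id, function(x) x[1])
  out <- data.frame(patient_id = names(ncls),
                    index_date = first$fill_date[match(names(ncls),
                                                       first$patient_id)],
                    index_drug = ifelse(ncls > 1L, NA_character_,
                                        as.character(drug)),
                    dual = as.vector(ncls > 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

# Day-level continuous-coverage check of [lo, hi] per patient, merging
# abutting spans, allowing gaps up to `gap` days.
covers_window <- function(enrollment, patient_id, lo, hi, gap = 0L) {
  enr <- enrollment[enrollment$medical_eligible & enrollment$pharmacy_eligible, ,
                    drop = FALSE]
  enr <- enr[order(enr$patient_id, enr$start_date), , drop = FALSE]
  spans <- split(seq_len(nrow(enr)), enr$patient_id)
  ok <- logical(length(patient_id))
  for (k in seq_along(patient_id)) {
    rows <- spans[[patient_id[k]]]
    if (is.null(rows)) next
    s <- enr$start_date[rows]; e <- enr$end_date[rows]
    cov_end <- -Inf
    covered <- TRUE
    pos <- lo[k]
    for (j in seq_along(s)) {
      if (e[j] < pos) next
      if (s[j] > pos + gap) { covered <- FALSE; break }
      pos <- max(pos, e[j] + 1L)
      if (pos > hi[k]) break
    }
    ok[k] <- covered && pos > hi[k]
  }
  ok
}

#' Apply the inclusion/exclusion criteria
#'
#' Sequentially filters index-date candidates through the study's
#' selection waterfall, recording attrition per criterion:
#' (1) naive to ICS/LABA combinations in the pre-index year;
#' (2) age >= 40 at index; (3) continuous medical + pharmacy enrollment
#' over `[index - 365, index + 365]`; (4) the COPD diagnosis criterion
#' (>= 1 inpatient claim with primary COPD, or >= 1 ED claim with COPD in
#' any position, or >= 2 other medical claims with COPD in any position
#' on distinct dates, all pre-index); (5) no cancer diagnosis pre-index;
#' (6) < 180 days of OCS supply pre-index; (7) not a dual initiator.
#' Eligibility is conjunctive; the sequential order only shapes the
#' attrition table.
#'
#' @param db A [claims_db()].
#' @param candidates Output of [find_index()].
#' @param codeset A code set from [default_codesets()].
#' @param epoch_year Calendar year of day 0 (for age from `birth_year`).
#' @param min_age Minimum age at index (years).
#' @param ocs_days_cutoff Chronic-OCS exclusion threshold (total
#'   pre-index days supply; `>=` excludes).
#' @param enrollment_gap Allowable enrollment gap in days (default 0,
#'   i.e. strictly continuous).
#' @param distinct_dates Require the two "other" COPD claims to fall on
#'   distinct service dates.
#' @return A list with `cohort` (eligible records: `patient_id`,
#'   `index_date`, `index_drug`, `age_at_index`) and `attrition`
#'   (data.frame of per-criterion removals, in order). The per-candidate
#'   criterion matrix is attached as attribute `"criteria"` of `cohort`.
#' @export
apply_criteria <- function(db, candidates, codeset = default_codesets(),
                           epoch_year = 2008L, min_age = 40L,
                           ocs_days_cutoff = 180L, enrollment_gap = 0L,
                           distinct_dates = TRUE) {
  cand <- candidates
  n <- nrow(cand)
  idx <- cand$index_date
  lo <- idx - 365L
  hi <- idx - 1L

  ph <- db$pharmacy
  pi <- match(ph$patient_id, cand$patient_id)
  ph_keep <- !is.na(pi)
  ph <- ph[ph_keep, , drop = FALSE]; pi <- pi[ph_keep]
  ph_pre <- ph$fill_date >= lo[pi] & ph$fill_date <= hi[pi]

  med <- db$medical
  mi <- match(med$patient_id, cand$patient_id)
  med_keep <- !is.na(mi)
  med <- med[med_keep, , drop = FALSE]; mi <- mi[med_keep]
  med_pre <- med$service_date >= lo[mi] & med$service_date <= hi[mi]

  flag_by_cand <- function(sel, claim_idx) {
    out <- logical(n)
    out[unique(claim_idx[sel])] <- TRUE
    out
  }

  # (1) naive to ICS/LABA combination therapy
  naive <- !flag_by_cand(ph_pre & ph$drug_class %in% ICS_LABA_CLASSES, pi)

  # (2) age
  birth <- db$patients$birth_year[match(cand$patient_id,
                                        db$patients$patient_id)]
  age <- epoch_year + floor(idx / 365.25) - birth
  age_ok <- age >= min_age

  # (3) continuous enrollment
  enrolled <- covers_window(db$enrollment, cand$patient_id,
                            idx - 365L, idx + 365L, gap = enrollment_gap)

  # (4) diagnosis criterion
  copd_any <- claims_condition_flag(med, "copd", "any", codeset)
  copd_primary <- match_code(med$dx1, "copd", codeset)
  dx_inp <- flag_by_cand(med_pre & med$place_of_service == "inpatient" &
                           copd_primary, mi)
  dx_ed <- flag_by_cand(med_pre & med$place_of_service == "ed" & copd_any, mi)
  other_sel <- med_pre & !med$place_of_service %in% c("inpatient", "ed") &
    copd_any
  n_other <- integer(n)
  if (any(other_sel)) {
    key <- if (distinct_dates) {
      paste(mi[other_sel], med$service_date[other_sel])
    } else {
      paste(mi[other_sel], seq_len(sum(other_sel)))
    }
    cnt <- table(as.integer(sub(" .*", "", unique(key))))
    n_other[as.integer(names(cnt))] <- as.integer(cnt)
  }
  dx_ok <- dx_inp | dx_ed | (n_other >= 2L)

  # (5) cancer
  cancer <- flag_by_cand(med_pre & claims_condition_flag(med, "cancer", "any",
                                                         codeset), mi)

  # (6) chronic OCS
  ocs_sel <- ph_pre & ph$drug_class == "OCS"
  ocs_days <- numeric(n)
  if (any(ocs_sel)) {
    s <- tapply(ph$days_supply[ocs_sel], pi[ocs_sel], sum)
    ocs_days[as.integer(names(s))] <- as.numeric(s)
  }
  ocs_ok <- ocs_days < ocs_days_cutoff

  # (7) dual initiation
  not_dual <- !cand$dual

  crit <- cbind(naive_ics_laba = naive, age_40 = age_ok,
                continuous_enrollment = enrolled, copd_diagnosis = dx_ok,
                no_cancer = !cancer, no_chronic_ocs = ocs_ok,
                not_dual_initiator = not_dual)

  remaining <- rep(TRUE, n)
  removed <- integer(ncol(crit))
  for (k in seq_len(ncol(crit))) {
    fail <- remaining & !crit[, k]
    removed[k] <- sum(fail)
    remaining <- remaining & crit[, k]
  }
  attrition <- data.frame(criterion = c("candidates", colnames(crit)),
                          removed = c(0L, removed),
                          remaining = c(n, n - cumsum(removed)),
                          stringsAsFactors = FALSE)

  cohort <- cand[remaining, c("patient_id", "index_date", "index_drug"),
                 drop = FALSE]
  cohort$age_at_index <- as.integer(age[remaining])
  rownames(cohort) <- NULL
  attr(cohort, "criteria") <- crit
  list(cohort = cohort, attrition = attrition)
}

#' Extract pre-index covariates
#'
#' Computes the matching/adjustment covariates over the pre-index year
#' `[index - 365, index - 1]`: demographics, pre-index utilization and
#' medication-fill counts, adjudicated pre-index exacerbations (the same
#' candidate/attribution/merge machinery applied to the pre-index
#' window), comorbidity flags, the LTRA fill category (0/1/2+), the
#' long-stay flag (any inpatient stay of more than 5 days), region,
#' modal pre-index provider specialty, and index month.
#'
#' @param db A [claims_db()].
#' @param records Cohort records from [apply_criteria()].
#' @param codeset A code set from [default_codesets()].
#' @return `records` with covariate columns appended.
#' @export
extract_covariates <- function(db, records, codeset = default_codesets()) {
  n <- nrow(records)
  idx <- records$index_date
  lo <- idx - 365L
  hi <- idx - 1L
  out <- records

  pat <- db$patients[match(records$patient_id, db$patients$patient_id), ]
  out$female <- pat$sex == "female"
  out$region <- pat$region

  med <- db$medical
  mi <- match(med$patient_id, records$patient_id)
  keep <- !is.na(mi)
  med <- med[keep, , drop = FALSE]; mi <- mi[keep]
  pre <- med$service_date >= lo[mi] & med$service_date <= hi[mi]

  count_by <- function(sel, claim_idx) {
    cnt <- integer(n)
    if (any(sel)) {
      t <- table(claim_idx[sel])
      cnt[as.integer(names(t))] <- as.integer(t)
    }
    cnt
  }
  flag_by <- function(sel, claim_idx) {
    f <- logical(n)
    f[unique(claim_idx[sel])] <- TRUE
    f
  }

  copd_any <- claims_condition_flag(med, "copd", "any", codeset)
  copd_primary <- match_code(med$dx1, "copd", codeset)
  inp <- med$place_of_service == "inpatient"
  out$pre_copd_inpatient <- count_by(pre & inp & copd_primary, mi)
  out$pre_copd_ed <- count_by(pre & med$place_of_service == "ed" & copd_any, mi)

  for (cond in c("asthma", "hypertension", "diabetes", "pvd", "cad",
                 "depression", "heart_failure", "pneumonia")) {
    f <- claims_condition_flag(med, cond, "any", codeset)
    col <- if (cond == "pneumonia") "prior_pneumonia" else cond
    out[[col]] <- flag_by(pre & f, mi)
  }

  long <- pre & inp & (med$discharge_date - med$admission_date) > 5L
  out$long_stay <- flag_by(long, mi)

  # modal pre-index provider specialty (fallback: any claim, then "other")
  out$specialty <- "other"
  if (any(pre)) {
    sp <- tapply(med$provider_specialty[pre], mi[pre], function(x) {
      names(sort(table(x), decreasing = TRUE))[1]
    })
    out$specialty[as.integer(names(sp))] <- as.character(sp)
  }

  ph <- db$pharmacy
  pi <- match(ph$patient_id, records$patient_id)
  keep <- !is.na(pi)
  ph <- ph[keep, , drop = FALSE]; pi <- pi[keep]
  pre_rx <- ph$fill_date >= lo[pi] & ph$fill_date <= hi[pi]
  out$pre_ocs_fills <- count_by(pre_rx & ph$drug_class == "OCS", pi)
  out$pre_abx_fills <- count_by(pre_rx & ph$drug_class == "ANTIBIOTIC", pi)
  out$pre_saba_fills <- count_by(pre_rx & ph$drug_class %in%
                                   c("SABA", "SABA_SAMA"), pi)
  out$pre_laba_fills <- count_by(pre_rx & ph$drug_class == "LABA", pi)
  out$pre_lama_fills <- count_by(pre_rx & ph$drug_class == "LAMA", pi)
  ltra <- count_by(pre_rx & ph$drug_class == "LTRA", pi)
  out$ltra_cat <- ifelse(ltra >= 2L, "2+", as.character(ltra))

  # adjudicated pre-index exacerbations
  windows <- data.frame(patient_id = records$patient_id, start = lo, end = hi,
                        stringsAsFactors = FALSE)
  ev <- merge_events(apply_attribution(candidates_in_window(db, windows,
                                                            codeset)))
  out$pre_exac <- count_by(rep(TRUE, nrow(ev)),
                           match(ev$patient_id, records$patient_id))
  for (ty in c("inpatient", "ed", "outpatient_rx")) {
    sel <- ev$type == ty
    out[[paste0("pre_exac_", ty)]] <-
      flag_by(sel, match(ev$patient_id, records$patient_id))
  }

  out$index_month <- as.integer((idx %/% 30L) %% 12L + 1L)
  out
}

#' Build the analyzable cohort
#'
#' Runs [find_index()], [apply_criteria()] and [extract_covariates()].
#'
#' @param db A [claims_db()].
#' @param intake_window Integer `[start, end]` day-index interval.
#' @param codeset A code set from [default_codesets()].
#' @param ... Passed to [apply_criteria()].
#' @return A data.frame of class `"copd_cohort"` with the attrition
#'   table attached as attribute `"attrition"`.
#' @export
build_cohort <- function(db, intake_window, codeset = default_codesets(), ...) {
  candidates <- find_index(db, intake_window)
  res <- apply_criteria(db, candidates, codeset, ...)
  cohort <- extract_covariates(db, res$cohort, codeset)
  attr(cohort, "attrition") <- res$attrition
  attr(cohort, "criteria") <- attr(res$cohort, "criteria")
  class(cohort) <- c("copd_cohort", "data.frame")
  cohort
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf("<copd_cohort> %d patients (BFC %d / FSC %d)\n", nrow(x),
              sum(x$index_drug == "BFC"), sum(x$index_drug == "FSC")))
  att <- attr(x, "attrition")
  if (!is.null(att)) {
    cat("attrition:\n")
    print(att, row.names = FALSE)
  }
  invisible(x)
}
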