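# Claims-based COPD exacerbation adjudication.
#
# Candidate events:
#   inpatient      inpatient claim with a PRIMARY COPD diagnosis
#                  (onset = admission date)
#   ed             ED claim with a COPD diagnosis in ANY position
#                  (onset = service date)
#   outpatient_rx  (office/outpatient visit with COPD diagnosis in any
#                  position, OCS or antibiotic fill 0-10 days after the
#                  visit); one candidate row per (visit, fill) pair,
#                  onset = visit date
#
# Attribution rules, applied in order:
#   (i)   an ED candidate whose service date falls inside [admission,
#         discharge] of an inpatient candidate of the same patient is
#         counted as the hospitalization only;
#   (ii)  an outpatient_rx pair whose FILL date is within 14 days
#         (|gap| <= 14) of any severe (ED/inpatient) candidate's onset is
#         absorbed by that event;
#   (iii) the surviving pairs of one visit collapse to a single candidate.
#
# Merging: candidates within 14 days of each other form one event. The
# cluster is anchored at its FIRST onset (non-chained by default): a
# candidate joins the cluster iff onset <= anchor + 14. The retained
# event keeps the anchor onset and the most severe member type
# (inpatient > ed > outpatient_rx).

SEVERITY <- c(outpatient_rx = 1L, ed = 2L, inpatient = 3L)

#' Follow-up specification
#'
#' @param variant One of `"fixed_12mo"` (12-month post-index window,
#'   person-time 1.0), `"censor_at_switch"` (follow-up ends at the first
#'   fill of an ICS/LABA combination different from the index drug),
#'   `"all_available"` (until end of enrollment or `study_end`), or
#'   `"severe_only"` (12-month window, severe events only).
#' @param study_end Day index ending the study period (used by
#'   `all_available`); default unbounded.
#' @param merge_rule `"anchored"` (default): the 14-day merge cluster is
#'   anchored at its first event. `"chained"`: a candidate joins if it is
#'   within 14 days of the cluster's most recent member.
#' @return An object of class `"followup_spec"`.
#' @export
followup_spec <- function(variant = c("fixed_12mo", "censor_at_switch",
                                      "all_available", "severe_only"),
                          study_end = Inf,
                          merge_rule = c("anchored", "chained")) {
  structure(list(variant = match.arg(variant), study_end = study_end,
                 merge_rule = match.arg(merge_rule)),
            class = "followup_spec")
}

# First post-index fill of an ICS/LABA combination different from the
# index drug; same-class refills never censor. NA when no switch.
find_switch <- function(db, records) {
  ph <- db$pharmacy[db$pharmacy$drug_class %in% ICS_LABA_CLASSES, , drop = FALSE]
  i <- match(ph$patient_id, records$patient_id)
  keep <- !is.na(i) &
    ph$fill_date > records$index_date[i] &
    ph$drug_class != records$index_drug[i]
  ph <- ph[keep, , drop = FALSE]
  out <- rep(NA_integer_, nrow(records))
  if (nrow(ph)) {
    first <- tapply(ph$fill_date, ph$patient_id, min)
    j <- match(names(first), records$patient_id)
    out[j] <- as.integer(first)
  }
  out
}

# Per-patient event windows implied by a follow-up spec.
resolve_followup <- function(db, records, spec) {
  idx <- records$index_date
  start <- idx
  end <- idx + 365L
  pt <- rep(1, nrow(records))
  if (spec$variant == "censor_at_switch") {
    sw <- find_switch(db, records)
    has <- !is.na(sw)
    end[has] <- pmin(idx[has] + 365L, sw[has] - 1L)
    pt[has] <- (pmin(sw[has], idx[has] + 365L) - idx[has]) / 365
  } else if (spec$variant == "all_available") {
    enr <- db$enrollment[db$enrollment$medical_eligible &
                           db$enrollment$pharmacy_eligible, , drop = FALSE]
    last <- tapply(enr$end_date, enr$patient_id, max)
    e <- as.integer(last[match(records$patient_id, names(last))])
    end <- pmin(ifelse(is.na(e), idx + 365L, e), spec$study_end)
    pt <- (end - idx) / 365
  }
  if (any(end < start)) stop("follow-up end before start", call. = FALSE)
  data.frame(patient_id = records$patient_id, start = start,
             end = as.integer(end), person_time = pt,
             stringsAsFactors = FALSE)
}

# Candidate extraction over arbitrary per-patient windows.
# windows: data.frame(patient_id, start, end).
candidates_in_window <- function(db, windows, codeset = default_codesets()) {
  med <- db$medical
  i <- match(med$patient_id, windows$patient_id)
  keep <- !is.na(i)
  med <- med[keep, , drop = FALSE]
  i <- i[keep]
  w_start <- windows$start[i]
  w_end <- windows$end[i]

  copd_any <- claims_condition_flag(med, "copd", "any", codeset)
  copd_primary <- match_code(med$dx1, "copd", codeset)

  is_inp <- med$place_of_service == "inpatient" & copd_primary &
    med$admission_date >= w_start & med$admission_date <= w_end
  inp <- if (any(is_inp)) {
    data.frame(patient_id = med$patient_id[is_inp],
               onset = med$admission_date[is_inp],
               type = "inpatient",
               fill_date = NA_integer_,
               admission_date = med$admission_date[is_inp],
               discharge_date = med$discharge_date[is_inp],
               stringsAsFactors = FALSE)
  } else NULL

  is_ed <- med$place_of_service == "ed" & copd_any &
    med$service_date >= w_start & med$service_date <= w_end
  ed <- if (any(is_ed)) {
    data.frame(patient_id = med$patient_id[is_ed],
               onset = med$service_date[is_ed],
               type = "ed",
               fill_date = NA_integer_,
               admission_date = NA_integer_,
               discharge_date = NA_integer_,
               stringsAsFactors = FALSE)
  } else NULL

  is_visit <- med$place_of_service %in% c("office", "outpatient") & copd_any &
    med$service_date >= w_start & med$service_date <= w_end
  outp <- NULL
  if (any(is_visit)) {
    visits <- data.frame(patient_id = med$patient_id[is_visit],
                         onset = med$service_date[is_visit],
                         stringsAsFactors = FALSE)
    rx <- db$pharmacy[db$pharmacy$drug_class %in% c("OCS", "ANTIBIOTIC"), ,
                      drop = FALSE]
    rx <- rx[rx$patient_id %in% visits$patient_id,
             c("patient_id", "fill_date"), drop = FALSE]
    if (nrow(rx)) {
      pairs <- merge(visits, rx, by = "patient_id")
      gap <- pairs$fill_date - pairs$onset
      pairs <- pairs[gap >= 0L & gap <= 10L, , drop = FALSE]
      if (nrow(pairs)) {
        outp <- data.frame(patient_id = pairs$patient_id,
                           onset = pairs$onset,
                           type = "outpatient_rx",
                           fill_date = pairs$fill_date,
                           admission_date = NA_integer_,
                           discharge_date = NA_integer_,
                           stringsAsFactors = FALSE)
        outp <- outp[!duplicated(outp[, c("patient_id", "onset", "fill_date")]), ,
                     drop = FALSE]
      }
    }
  }

  cand <- rbind_blocks(list(inp, ed, outp),
                       c(patient_id = "character", onset = "integer",
                         type = "character", fill_date = "integer",
                         admission_date = "integer",
                         discharge_date = "integer"))
  cand <- cand[order(cand$patient_id, cand$onset, -SEVERITY[cand$type],
                     cand$fill_date, na.last = TRUE), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Extract candidate exacerbation events
#'
#' Identifies inpatient, ED and outpatient-Rx candidates within each
#' patient's follow-up window. Outpatient-Rx candidates are one row per
#' (visit, qualifying fill) pair; [apply_attribution()] collapses them.
#'
#' @param db A [claims_db()].
#' @param records Cohort records (data.frame with `patient_id`,
#'   `index_date`, `index_drug`).
#' @param spec A [followup_spec()].
#' @param codeset A code set from [default_codesets()].
#' @return data.frame of candidates: `patient_id`, `onset`, `type`,
#'   `fill_date`, `admission_date`, `discharge_date`.
#' @export
extract_candidates <- function(db, records, spec = followup_spec(),
                               codeset = default_codesets()) {
  windows <- resolve_followup(db, records, spec)
  candidates_in_window(db, windows, codeset)
}

#' Apply the attribution rules to candidate events
#'
#' Rule (i): ED visits during a hospital stay count as the
#' hospitalization only. Rule (ii): an outpatient-Rx pair whose fill is
#' within 14 days of a severe candidate's onset is absorbed. Rule (iii):
#' the surviving fills of one visit give exactly one candidate.
#'
#' @param candidates Output of [extract_candidates()].
#' @return data.frame of attributed candidates (same columns).
#' @export
apply_attribution <- function(candidates) {
  cand <- candidates
  inp <- cand[cand$type == "inpatient", , drop = FALSE]
  ed <- cand[cand$type == "ed", , drop = FALSE]
  outp <- cand[cand$type == "outpatient_rx", , drop = FALSE]

  # (i) ED during an inpatient stay
  if (nrow(ed) && nrow(inp)) {
    ed$.row <- seq_len(nrow(ed))
    m <- merge(ed[, c("patient_id", "onset", ".row")],
               inp[, c("patient_id", "admission_date", "discharge_date")],
               by = "patient_id")
    drop <- unique(m$.row[m$onset >= m$admission_date &
                            m$onset <= m$discharge_date])
    if (length(drop)) ed <- ed[-drop, , drop = FALSE]
    ed$.row <- NULL
  }

  # (ii) fills hugging a severe event (severe set taken before rule i:
  # an ED collapsed into its stay still anchors absorption)
  severe <- rbind(inp[, c("patient_id", "onset")],
                  candidates[candidates$type == "ed", c("patient_id", "onset")])
  if (nrow(outp) && nrow(severe)) {
    outp$.row <- seq_len(nrow(outp))
    m <- merge(outp[, c("patient_id", "fill_date", ".row")],
               severe, by = "patient_id")
    drop <- unique(m$.row[abs(m$fill_date - m$onset) <= 14L])
    if (length(drop)) outp <- outp[-drop, , drop = FALSE]
    outp$.row <- NULL
  }

  # (iii) one candidate per visit
  if (nrow(outp)) {
    outp <- outp[order(outp$patient_id, outp$onset, outp$fill_date), ,
                 drop = FALSE]
    outp <- outp[!duplicated(outp[, c("patient_id", "onset")]), , drop = FALSE]
  }

  out <- rbind(inp, ed, outp)
  out <- out[order(out$patient_id, out$onset, -SEVERITY[out$type]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge candidates within 14 days into single events
#'
#' @param candidates Attributed candidates from [apply_attribution()],
#'   sorted by onset within patient.
#' @param rule `"anchored"` (default) or `"chained"`; see
#'   [followup_spec()].
#' @return data.frame of adjudicated events: `patient_id`, `onset`,
#'   `type`, `severe`, `merged_from` (number of absorbed candidates).
#' @export
merge_events <- function(candidates, rule = c("anchored", "chained")) {
  rule <- match.arg(rule)
  cand <- candidates[order(candidates$patient_id, candidates$onset,
                           -SEVERITY[candidates$type]), , drop = FALSE]
  n <- nrow(cand)
  if (n == 0L) {
    return(data.frame(patient_id = character(0), onset = integer(0),
                      type = character(0), severe = logical(0),
                      merged_from = integer(0), stringsAsFactors = FALSE))
  }
  cluster <- integer(n)
  cid <- 0L
  anchor <- -Inf
  last <- -Inf
  prev_pid <- ""
  for (r in seq_len(n)) {
    ref <- if (rule == "anchored") anchor else last
    if (cand$patient_id[r] != prev_pid || cand$onset[r] > ref + 14L) {
      cid <- cid + 1L
      anchor <- cand$onset[r]
      prev_pid <- cand$patient_id[r]
    }
    last <- cand$onset[r]
    cluster[r] <- cid
  }
  first <- !duplicated(cluster)
  sev <- vapply(split(SEVERITY[cand$type], cluster)[as.character(seq_len(cid))],
                max, integer(1))
  size <- tabulate(cluster)
  out <- data.frame(patient_id = cand$patient_id[first],
                    onset = cand$onset[first],
                    type = names(SEVERITY)[as.integer(sev)],
                    merged_from = size - 1L,
                    stringsAsFactors = FALSE)
  out$severe <- out$type %in% c("inpatient", "ed")
  rownames(out) <- NULL
  out[, c("patient_id", "onset", "type", "severe", "merged_from")]
}

#' Adjudicate COPD exacerbation events for a cohort
#'
#' Runs candidate extraction, attribution and 14-day merging under a
#' follow-up specification.
#'
#' @inheritParams extract_candidates
#' @return data.frame of events as in [merge_events()].
#' @export
adjudicate_events <- function(db, records, spec = followup_spec(),
                              codeset = default_codesets()) {
  cand <- extract_candidates(db, records, spec, codeset)
  merge_events(apply_attribution(cand), rule = spec$merge_rule)
}

#' Count exacerbations and person-time per patient
#'
#' @param events Adjudicated events from [adjudicate_events()] under the
#'   same `spec`.
#' @param db,records,spec,codeset As in [extract_candidates()].
#' @return data.frame: `patient_id`, `count`, `person_time` (years),
#'   `time_to_first` (days from index; censoring time when no event),
#'   `event_flag`.
#' @export
count_exacerbations <- function(events, db, records, spec = followup_spec(),
                                codeset = default_codesets()) {
  windows <- resolve_followup(db, records, spec)
  ev <- events
  if (spec$variant == "severe_only") ev <- ev[ev$severe, , drop = FALSE]
  cnt <- integer(nrow(records))
  if (nrow(ev)) {
    t <- table(factor(ev$patient_id, levels = records$patient_id))
    cnt <- as.integer(t)
  }
  first <- rep(NA_integer_, nrow(records))
  if (nrow(ev)) {
    f <- tapply(ev$onset, ev$patient_id, min)
    j <- match(names(f), records$patient_id)
    first[j] <- as.integer(f)
  }
  ttf <- ifelse(is.na(first), windows$end - records$index_date,
                first - records$index_date)
  data.frame(patient_id = records$patient_id,
             count = cnt,
             person_time = windows$person_time,
             time_to_first = as.numeric(ttf),
             event_flag = !is.na(first),
             stringsAsFactors = FALSE)
}

#' Detect pneumonia during the post-index year
#'
#' A pneumonia event is any claim with an ICD-9-CM 480-486 diagnosis in
#' any position during `[index, index + 365]`. Place-specific flags use
#' the claim's place of service (office/outpatient/SNF count as
#' outpatient).
#'
#' @inheritParams extract_candidates
#' @return data.frame: `patient_id`, `any`, `first_date`, `inpatient`,
#'   `ed`, `outpatient`.
#' @export
detect_pneumonia <- function(db, records, codeset = default_codesets()) {
  med <- db$medical
  i <- match(med$patient_id, records$patient_id)
  keep <- !is.na(i)
  med <- med[keep, , drop = FALSE]; i <- i[keep]
  idx <- records$index_date[i]
  inwin <- med$service_date >= idx & med$service_date <= idx + 365L
  pneu <- inwin & claims_condition_flag(med, "pneumonia", "any", codeset)
  med <- med[pneu, , drop = FALSE]
  out <- data.frame(patient_id = records$patient_id, any = FALSE,
                    first_date = NA_integer_, inpatient = FALSE, ed = FALSE,
                    outpatient = FALSE, stringsAsFactors = FALSE)
  if (nrow(med)) {
    place <- ifelse(med$place_of_service == "inpatient", "inpatient",
                    ifelse(med$place_of_service == "ed", "ed", "outpatient"))
    j <- match(med$patient_id, records$patient_id)
    out$any[unique(j)] <- TRUE
    f <- tapply(med$service_date, med$patient_id, min)
    out$first_date[match(names(f), records$patient_id)] <- as.integer(f)
    for (pl in c("inpatient", "ed", "outpatient")) {
      out[[pl]][unique(j[place == pl])] <- TRUE
    }
  }
  out
}

#' Tally healthcare utilization per patient
#'
#' Counts visits by place of service over the post-index year, with
#' total inpatient length of stay (same-day admission and discharge
#' counts as one day). `copd_related` requires a primary COPD diagnosis
#' for inpatient stays and a COPD diagnosis in any position elsewhere;
#' `all_cause` counts every claim.
#'
#' @inheritParams extract_candidates
#' @param scope `"copd_related"` or `"all_cause"`.
#' @return data.frame per patient: counts `inpatient_n`, `icu_n`, `ed_n`,
#'   `outpatient_n`, `snf_n` and lengths of stay `inpatient_los`,
#'   `icu_los`.
#' @export
tally_utilization <- function(db, records, scope = c("copd_related", "all_cause"),
                              codeset = default_codesets()) {
  scope <- match.arg(scope)
  med <- db$medical
  i <- match(med$patient_id, records$patient_id)
  keep <- !is.na(i)
  med <- med[keep, , drop = FALSE]; i <- i[keep]
  idx <- records$index_date[i]
  med <- med[med$service_date >= idx & med$service_date <= idx + 365L, ,
             drop = FALSE]
  if (scope == "copd_related" && nrow(med)) {
    primary <- match_code(med$dx1, "copd", codeset)
    any_pos <- claims_condition_flag(med, "copd", "any", codeset)
    keep <- ifelse(med$place_of_service == "inpatient", primary, any_pos)
    med <- med[keep, , drop = FALSE]
  }
  out <- data.frame(patient_id = records$patient_id,
                    inpatient_n = 0L, inpatient_los = 0L,
                    icu_n = 0L, icu_los = 0L, ed_n = 0L,
                    outpatient_n = 0L, snf_n = 0L, stringsAsFactors = FALSE)
  if (!nrow(med)) return(out)
  j <- match(med$patient_id, records$patient_id)
  add_count <- function(col, sel) {
    if (any(sel)) {
      t <- table(factor(records$patient_id[j[sel]],
                        levels = records$patient_id))
      out[[col]] <<- out[[col]] + as.integer(t)
    }
  }
  inp <- med$place_of_service == "inpatient"
  add_count("inpatient_n", inp)
  add_count("icu_n", inp & med$icu_flag)
  add_count("ed_n", med$place_of_service == "ed")
  add_count("outpatient_n", med$place_of_service %in% c("office", "outpatient"))
  add_count("snf_n", med$place_of_service == "snf")
  if (any(inp)) {
    los <- pmax(1L, med$discharge_date[inp] - med$admission_date[inp])
    s <- tapply(los, factor(records$patient_id[j[inp]],
                            levels = records$patient_id), sum)
    out$inpatient_los <- as.integer(ifelse(is.na(s), 0L, s))
    icu <- inp & med$icu_flag
    if (any(icu)) {
      los <- pmax(1L, med$discharge_date[icu] - med$admission_date[icu])
      s <- tapply(los, factor(records$patient_id[j[icu]],
                              levels = records$patient_id), sum)
      out$icu_los <- as.integer(ifelse(is.na(s), 0L, s))
    }
  }
  out
}

#' Post-index medication-use flags
#'
#' One logical column per drug class: at least one fill during
#' `[index, index + 365]`.
#'
#' @inheritParams extract_candidates
#' @return data.frame, `patient_id` plus one column per drug class.
#' @export
medication_flags <- function(db, records) {
  ph <- db$pharmacy
  i <- match(ph$patient_id, records$patient_id)
  keep <- !is.na(i)
  ph <- ph[keep, , drop = FALSE]; i <- i[keep]
  idx <- records$index_date[i]
  ph <- ph[ph$fill_date >= idx & ph$fill_date <= idx + 365L, , drop = FALSE]
  out <- data.frame(patient_id = records$patient_id, stringsAsFactors = FALSE)
  for (cls in DRUG_CLASSES) {
    flag <- rep(FALSE, nrow(records))
    sel <- ph$drug_class == cls
    if (any(sel)) {
      flag[match(unique(ph$patient_id[sel]), records$patient_id)] <- TRUE
    }
    out[[tolower(cls)]] <- flag
  }
  out
}

#' Index-medication adherence
#'
#' Number of index-drug fills (including the index fill) during
#' `[index, index + 365]`, the fill category (1/2/3/4+) and the
#' proportion of days covered, `pdc = min(1, sum(days_supply) / 365)`.
#' Overlapping fills are not shifted forward.
#'
#' @inheritParams extract_candidates
#' @return data.frame: `patient_id`, `n_index_fills`, `fill_category`,
#'   `pdc`.
#' @export
compute_adherence <- function(db, records) {
  ph <- db$pharmacy
  i <- match(ph$patient_id, records$patient_id)
  keep <- !is.na(i)
  ph <- ph[keep, , drop = FALSE]; i <- i[keep]
  idx <- records$index_date[i]
  sel <- ph$drug_class == records$index_drug[i] &
    ph$fill_date >= idx & ph$fill_date <= idx + 365L
  ph <- ph[sel, , drop = FALSE]
  n <- as.integer(table(factor(ph$patient_id, levels = records$patient_id)))
  supply <- tapply(ph$days_supply, factor(ph$patient_id,
                                          levels = records$patient_id), sum)
  supply <- as.numeric(ifelse(is.na(supply), 0, supply))
  data.frame(patient_id = records$patient_id,
             n_index_fills = n,
             fill_category = ifelse(n >= 4L, "4+", as.character(n)),
             pdc = pmin(1, supply / 365),
             stringsAsFactors = FALSE)
}

#' Build the per-patient outcome table
#'
#' Convenience wrapper combining adjudicated exacerbation counts,
#' time-to-first, pneumonia flags, adherence and medication-use flags
#' into one analysis-ready data frame.
#'
#' @inheritParams extract_candidates
#' @return data.frame keyed by `patient_id` with `arm`
#'   (`records$index_drug`), counts, person-time, flags and adherence.
#' @export
build_outcomes <- function(db, records, spec = followup_spec(),
                           codeset = default_codesets()) {
  ev <- adjudicate_events(db, records, spec, codeset)
  cx <- count_exacerbations(ev, db, records, spec, codeset)
  pn <- detect_pneumonia(db, records, codeset)
  ad <- compute_adherence(db, records)
  out <- data.frame(patient_id = records$patient_id,
                    arm = records$index_drug,
                    stringsAsFactors = FALSE)
  out$count <- cx$count
  out$person_time <- cx$person_time
  out$time_to_first <- cx$time_to_first
  out$event_flag <- cx$event_flag
  out$pneumonia <- pn$any
  out$pneumonia_inpatient <- pn$inpatient
  out$pneumonia_ed <- pn$ed
  out$pneumonia_outpatient <- pn$outpatient
  out$pneumonia_time <- ifelse(pn$any, pn$first_date - records$index_date,
                               365)
  out$n_index_fills <- ad$n_index_fills
  out$fill_category <- ad$fill_category
  out$pdc <- ad$pdc
  out
}
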