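make_cohort_db <- function(medical = NULL, pharmacy = NULL, birth_year = 1950L,
                           enroll = c(-400L, 1500L), dx_slots = 5L) {
  pid <- "CH0001"
  patients <- data.frame(patient_id = pid, birth_year = birth_year,
                         sex = "female", region = "midwest",
                         stringsAsFactors = FALSE)
  enrollment <- data.frame(patient_id = pid, start_date = enroll[1],
                           end_date = enroll[2], medical_eligible = TRUE,
                           pharmacy_eligible = TRUE, stringsAsFactors = FALSE)
  med <- copdce:::rbind_blocks(medical, copdce:::MED_SCHEMA)
  med$provider_specialty <- rep("pulmonology", nrow(med))
  for (k in seq_len(dx_slots)[-(1:2)]) {
    med[[paste0("dx", k)]] <- rep(NA_character_, nrow(med))
  }
  med <- cbind(claim_id = sprintf("M%03d", seq_len(nrow(med))), med,
               stringsAsFactors = FALSE)
  rx <- copdce:::rbind_blocks(pharmacy, copdce:::RX_SCHEMA)
  rx <- cbind(claim_id = sprintf("P%03d", seq_len(nrow(rx))), rx,
              stringsAsFactors = FALSE)
  claims_db(patients, enrollment, med, rx)
}

mb <- copdce:::med_block
rb <- copdce:::rx_block

test_that("find_index takes the earliest study-drug fill in the window", {
  db <- make_cohort_db(pharmacy = list(rb("CH0001", c(100L, 200L),
                                          c("FSC", "BFC"), 30L)))
  cand <- find_index(db, c(0L, 1000L))
  expect_equal(cand$index_date, 100L)
  expect_equal(cand$index_drug, "FSC")
  expect_false(cand$dual)

  # same-day dual initiation flagged
  db2 <- make_cohort_db(pharmacy = list(rb("CH0001", c(50L, 50L),
                                           c("BFC", "FSC"), 30L)))
  cand2 <- find_index(db2, c(0L, 1000L))
  expect_true(cand2$dual)
  expect_true(is.na(cand2$index_drug))

  # fills outside the window yield no candidate
  db3 <- make_cohort_db(pharmacy = list(rb("CH0001", 1100L, "BFC", 30L)))
  expect_equal(nrow(find_index(db3, c(0L, 1000L))), 0L)
})

eligible_parts <- function(index = 600L) {
  list(medical = list(mb("CH0001", index - c(150L, 120L), "office",
                         dx1 = "491.21")),
       pharmacy = list(rb("CH0001", index, "BFC", 30L)))
}

test_that("apply_criteria enforces each selection rule at its boundary", {
  index <- 600L
  base <- eligible_parts(index)
  run <- function(med_extra = NULL, rx_extra = NULL, ...) {
    db <- make_cohort_db(c(base$medical, med_extra),
                         c(base$pharmacy, rx_extra), ...)
    cand <- find_index(db, c(0L, 1000L))
    apply_criteria(db, cand)
  }
  # fully eligible baseline
  expect_equal(nrow(run()$cohort), 1L)

  # single office COPD claim is not enough (needs two)
  db <- make_cohort_db(list(mb("CH0001", index - 150L, "office",
                               dx1 = "491.21")), base$pharmacy)
  res <- apply_criteria(db, find_index(db, c(0L, 1000L)))
  expect_equal(nrow(res$cohort), 0L)
  expect_equal(res$attrition$removed[res$attrition$criterion ==
                                       "copd_diagnosis"], 1L)
  # ...but a single ED COPD visit or a primary-COPD hospitalization is
  db <- make_cohort_db(list(mb("CH0001", index - 150L, "ed", dx1 = "786.09",
                               dx2 = "496")), base$pharmacy)
  expect_equal(nrow(apply_criteria(db, find_index(db, c(0L, 1000L)))$cohort), 1L)
  # two office claims on the SAME date do not satisfy the two-claim route
  db <- make_cohort_db(list(mb("CH0001", c(index - 150L, index - 150L),
                               "office", dx1 = "491.21")), base$pharmacy)
  expect_equal(nrow(apply_criteria(db, find_index(db, c(0L, 1000L)))$cohort), 0L)

  # chronic OCS: 90 + 90 days reaches the >= 180 cutoff
  expect_equal(nrow(run(rx_extra = list(rb("CH0001", index - c(200L, 100L),
                                           "OCS", 90L)))$cohort), 0L)
  expect_equal(nrow(run(rx_extra = list(rb("CH0001", index - c(200L, 100L),
                                           "OCS", c(90L, 89L))))$cohort), 1L)

  # prior combination fill violates the new-user rule; monotherapy doesn't
  expect_equal(nrow(run(rx_extra = list(rb("CH0001", index - 100L,
                                           "OTHER_ICS_LABA", 30L)))$cohort), 0L)
  expect_equal(nrow(run(rx_extra = list(rb("CH0001", index - 100L,
                                           "ICS", 30L)))$cohort), 1L)

  # cancer diagnosis pre-index excludes
  expect_equal(nrow(run(med_extra = list(mb("CH0001", index - 90L, "office",
                                            dx1 = "162.9")))$cohort), 0L)

  # age < 40 at index excludes (born 1990 -> age ~19 at day 600)
  db <- make_cohort_db(base$medical, base$pharmacy, birth_year = 1990L)
  expect_equal(nrow(apply_criteria(db, find_index(db, c(0L, 1000L)))$cohort), 0L)

  # enrollment must cover [index - 365, index + 365]
  db <- make_cohort_db(base$medical, base$pharmacy,
                       enroll = c(-400L, index + 200L))
  expect_equal(nrow(apply_criteria(db, find_index(db, c(0L, 1000L)))$cohort), 0L)
})

test_that("attrition counts always sum to the cohort size", {
  s <- simulate_claims(sim_config(n_patients = 200, seed = 21,
                                  decoy_share = 0.3))
  ch <- build_cohort(s$db, s$config$intake_window)
  att <- attr(ch, "attrition")
  expect_equal(att$remaining[1] - sum(att$removed), nrow(ch))
  expect_equal(att$remaining[nrow(att)], nrow(ch))
})

test_that("planted ineligibility reasons are recovered exactly", {
  s <- simulate_claims(sim_config(n_patients = 140, seed = 13,
                                  decoy_share = 0.5))
  tt <- s$truth$patients
  cand <- find_index(s$db, s$config$intake_window)
  res <- apply_criteria(s$db, cand)
  expect_setequal(res$cohort$patient_id, tt$patient_id[tt$eligible])
  crit <- attr(res$cohort, "criteria")
  reason_map <- c(age_lt_40 = "age_40", enrollment_gap = "continuous_enrollment",
                  cancer = "no_cancer", chronic_ocs = "no_chronic_ocs",
                  dual_initiation = "not_dual_initiator",
                  prior_ics_laba = "naive_ics_laba",
                  insufficient_dx = "copd_diagnosis")
  decoys <- tt[!tt$eligible, ]
  for (r in seq_len(nrow(decoys))) {
    k <- match(decoys$patient_id[r], cand$patient_id)
    failed <- colnames(crit)[!crit[k, ]]
    expect_equal(failed, unname(reason_map[decoys$ineligible_reason[r]]),
                 label = decoys$ineligible_reason[r])
  }
})

test_that("covariates use only the pre-index window", {
  index <- 600L
  base <- eligible_parts(index)
  db <- make_cohort_db(
    c(base$medical,
      list(mb("CH0001", index - 200L, "inpatient", dx1 = "491.21",
              admission = index - 200L, discharge = index - 194L))),
    c(base$pharmacy,
      list(rb("CH0001", index - c(300L, 200L, 100L), "OCS", 10L),
           rb("CH0001", index, "OCS", 10L),       # index-day fill: excluded
           rb("CH0001", index + 50L, "LAMA", 30L))))  # post-index: excluded
  ch <- build_cohort(db, c(0L, 1000L))
  expect_equal(ch$pre_ocs_fills, 3L)
  expect_equal(ch$pre_lama_fills, 0L)
  expect_true(ch$long_stay)       # stay of 6 days (> 5)
  expect_equal(ch$pre_copd_inpatient, 1L)
  expect_equal(ch$pre_exac, 1L)   # the hospitalization adjudicates as one

  # no pre-index claims at all -> all-zero counts
  db0 <- make_cohort_db(
    list(mb("CH0001", index - c(150L, 120L), "office", dx1 = "491.21")),
    base$pharmacy)
  ch0 <- build_cohort(db0, c(0L, 1000L))
  expect_equal(ch0$pre_ocs_fills, 0L)
  expect_false(ch0$long_stay)

  # shifting every post-index claim leaves covariates unchanged
  s <- simulate_claims(sim_config(n_patients = 120, seed = 31))
  ch1 <- build_cohort(s$db, s$config$intake_window)
  db2 <- s$db
  idx <- ch1$index_date[match(db2$medical$patient_id, ch1$patient_id)]
  post <- !is.na(idx) & db2$medical$service_date >= idx
  for (col in c("service_date", "admission_date", "discharge_date")) {
    db2$medical[[col]][post] <- db2$medical[[col]][post] + 37L
  }
  idxr <- ch1$index_date[match(db2$pharmacy$patient_id, ch1$patient_id)]
  postr <- !is.na(idxr) & db2$pharmacy$fill_date > idxr
  db2$pharmacy$fill_date[postr] <- db2$pharmacy$fill_date[postr] + 37L
  ch2 <- build_cohort(db2, s$config$intake_window)
  cov_cols <- setdiff(names(ch1), c("patient_id"))
  expect_equal(as.data.frame(ch2)[cov_cols], as.data.frame(ch1)[cov_cols])
})
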