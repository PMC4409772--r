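# Hand-auditable micro-databases, one per adjudication rule.

fixture_patient_db <- function(medical = NULL, pharmacy = NULL,
                               index_date = 0L, index_drug = "BFC",
                               dx_slots = 5L) {
  pid <- "TOY001"
  patients <- data.frame(patient_id = pid, birth_year = 1948L, sex = "female",
                         region = "south", stringsAsFactors = FALSE)
  enrollment <- data.frame(patient_id = pid, start_date = index_date - 400L,
                           end_date = index_date + 400L,
                           medical_eligible = TRUE, pharmacy_eligible = TRUE,
                           stringsAsFactors = FALSE)
  mk_med <- function(rows) {
    df <- rbind_blocks(rows, MED_SCHEMA)
    df$provider_specialty <- rep("pulmonology", nrow(df))
    for (k in seq_len(dx_slots)[-(1:2)]) {
      df[[paste0("dx", k)]] <- rep(NA_character_, nrow(df))
    }
    df <- cbind(claim_id = sprintf("M%04d", seq_len(nrow(df))), df,
                stringsAsFactors = FALSE)
    df[, c("claim_id", "patient_id", "service_date", "place_of_service",
           "icu_flag", "admission_date", "discharge_date",
           paste0("dx", seq_len(dx_slots)), "provider_specialty")]
  }
  mk_rx <- function(rows) {
    df <- rbind_blocks(rows, RX_SCHEMA)
    cbind(claim_id = sprintf("P%04d", seq_len(nrow(df))), df,
          stringsAsFactors = FALSE)
  }
  index_fill <- rx_block(pid, index_date, index_drug, 30L)
  db <- claims_db(patients, enrollment, mk_med(medical),
                  mk_rx(c(list(index_fill), pharmacy)))
  list(db = db,
       record = data.frame(patient_id = pid, index_date = index_date,
                           index_drug = index_drug, stringsAsFactors = FALSE))
}

#' Hand-auditable adjudication fixtures
#'
#' Returns a named list of single-patient claims databases, one per
#' adjudication rule, each with the expected adjudicated event set
#' attached. Every fixture's patient has index date 0 and index drug BFC.
#'
#' Fixtures: `empty` (no claims, 0 events), `ed_collapse` (ED visit
#' during a hospital stay collapses into one inpatient event),
#' `fill_absorb` (an outpatient visit + fill hugging an admission is
#' absorbed), `multi_fill` (two fills after one visit give one event),
#' `merge_14d` (candidates at days 0/10/20 merge to events at 0 and 20),
#' `switch_censor` (switch fill at day 90 censors the second event),
#' `severe_only` (inpatient + outpatient events; the severe subset has
#' one).
#'
#' @return Named list; each element has `db`, `record` (patient_id,
#'   index_date, index_drug), `expected` (data.frame of onset/type) and,
#'   where relevant, variant-specific expectations.
#' @export
generate_toy_fixtures <- function() {
  pid <- "TOY001"
  fx <- list()

  fx$empty <- fixture_patient_db()
  fx$empty$expected <- data.frame(onset = integer(0), type = character(0))

  fx$ed_collapse <- fixture_patient_db(
    medical = list(
      med_block(pid, 7L, "ed", dx1 = FILLER_DX, dx2 = "491.21"),
      med_block(pid, 7L, "inpatient", dx1 = "491.21",
                admission = 7L, discharge = 12L)))
  fx$ed_collapse$expected <- data.frame(onset = 7L, type = "inpatient")

  fx$fill_absorb <- fixture_patient_db(
    medical = list(
      med_block(pid, 5L, "office", dx1 = "496"),
      med_block(pid, 3L, "inpatient", dx1 = "491.22",
                admission = 3L, discharge = 4L)),
    pharmacy = list(rx_block(pid, 12L, "OCS", 5L)))
  fx$fill_absorb$expected <- data.frame(onset = 3L, type = "inpatient")

  fx$multi_fill <- fixture_patient_db(
    medical = list(med_block(pid, 5L, "office", dx1 = "491.21")),
    pharmacy = list(rx_block(pid, 6L, "OCS", 5L),
                    rx_block(pid, 9L, "ANTIBIOTIC", 10L)))
  fx$multi_fill$expected <- data.frame(onset = 5L, type = "outpatient_rx")

  fx$merge_14d <- fixture_patient_db(
    medical = list(med_block(pid, c(0L, 10L, 20L), "office", dx1 = "496")),
    pharmacy = list(rx_block(pid, c(0L, 10L, 20L), "OCS", 5L)))
  fx$merge_14d$expected <- data.frame(onset = c(0L, 20L),
                                      type = c("outpatient_rx", "outpatient_rx"))

  fx$switch_censor <- fixture_patient_db(
    medical = list(med_block(pid, c(30L, 100L), "office", dx1 = "491.21")),
    pharmacy = list(rx_block(pid, c(31L, 101L), "OCS", 5L),
                    rx_block(pid, 90L, "OTHER_ICS_LABA", 30L)))
  fx$switch_censor$expected <- data.frame(onset = c(30L, 100L),
                                          type = c("outpatient_rx",
                                                   "outpatient_rx"))
  fx$switch_censor$expected_censored <- list(count = 1L,
                                             person_time = 90 / 365)

  fx$severe_only <- fixture_patient_db(
    medical = list(
      med_block(pid, 50L, "inpatient", dx1 = "491.21",
                admission = 50L, discharge = 53L),
      med_block(pid, 200L, "office", dx1 = "496")),
    pharmacy = list(rx_block(pid, 205L, "ANTIBIOTIC", 10L)))
  fx$severe_only$expected <- data.frame(onset = c(50L, 200L),
                                        type = c("inpatient", "outpatient_rx"))
  fx$severe_only$expected_severe <- 1L

  fx
}
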