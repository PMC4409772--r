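adj_db <- function(medical = NULL, pharmacy = NULL) {
  f <- copdce:::fixture_patient_db(medical, pharmacy)
  f
}

mb <- copdce:::med_block
rb <- copdce:::rx_block
PID <- "TOY001"

test_that("candidate extraction honours the 10-day fill window and dx position", {
  spec <- followup_spec()
  # gap 10 qualifies, gap 11 does not
  x <- adj_db(list(mb(PID, 20L, "office", dx1 = "491.21")),
              list(rb(PID, 30L, "OCS", 5L)))
  cand <- extract_candidates(x$db, x$record, spec)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$onset, 20L)
  expect_equal(cand$type, "outpatient_rx")

  x <- adj_db(list(mb(PID, 20L, "office", dx1 = "491.21")),
              list(rb(PID, 31L, "ANTIBIOTIC", 10L)))
  expect_equal(nrow(extract_candidates(x$db, x$record, spec)), 0L)

  # fill BEFORE the visit never qualifies
  x <- adj_db(list(mb(PID, 20L, "office", dx1 = "491.21")),
              list(rb(PID, 19L, "OCS", 5L)))
  expect_equal(nrow(extract_candidates(x$db, x$record, spec)), 0L)

  # inpatient claim with COPD only in position 2 is not a candidate
  x <- adj_db(list(mb(PID, 30L, "inpatient", dx1 = "428.0", dx2 = "491.21",
                      admission = 30L, discharge = 35L)))
  expect_equal(nrow(extract_candidates(x$db, x$record, spec)), 0L)
  # ...but an ED claim with COPD in position 2 is
  x <- adj_db(list(mb(PID, 30L, "ed", dx1 = "428.0", dx2 = "491.21")))
  expect_equal(extract_candidates(x$db, x$record, spec)$type, "ed")
})

test_that("attribution rules drop the right candidates", {
  spec <- followup_spec()
  # (i) ED during a hospital stay
  x <- adj_db(list(mb(PID, 7L, "ed", dx1 = "491.21"),
                   mb(PID, 7L, "inpatient", dx1 = "491.21",
                      admission = 7L, discharge = 12L)))
  att <- apply_attribution(extract_candidates(x$db, x$record, spec))
  expect_equal(att$type, "inpatient")

  # (ii) outpatient fill within 14 days of an admission
  x <- adj_db(list(mb(PID, 5L, "office", dx1 = "496"),
                   mb(PID, 3L, "inpatient", dx1 = "491.21",
                      admission = 3L, discharge = 4L)),
              list(rb(PID, 12L, "OCS", 5L)))
  att <- apply_attribution(extract_candidates(x$db, x$record, spec))
  expect_equal(att$type, "inpatient")
  # gap 15 survives
  x <- adj_db(list(mb(PID, 17L, "office", dx1 = "496"),
                   mb(PID, 3L, "inpatient", dx1 = "491.21",
                      admission = 3L, discharge = 4L)),
              list(rb(PID, 18L, "OCS", 5L)))
  att <- apply_attribution(extract_candidates(x$db, x$record, spec))
  expect_setequal(att$type, c("inpatient", "outpatient_rx"))

  # (iii) multiple fills of one visit collapse to one candidate
  x <- adj_db(list(mb(PID, 5L, "office", dx1 = "491.21")),
              list(rb(PID, 6L, "OCS", 5L), rb(PID, 9L, "ANTIBIOTIC", 10L)))
  cand <- extract_candidates(x$db, x$record, spec)
  expect_equal(nrow(cand), 2L)  # one row per (visit, fill) pair
  att <- apply_attribution(cand)
  expect_equal(nrow(att), 1L)
  expect_equal(att$onset, 5L)
})

test_that("14-day merging is anchored at the first event", {
  cand <- data.frame(patient_id = PID, onset = c(0L, 10L, 20L),
                     type = "outpatient_rx", fill_date = c(0L, 10L, 20L),
                     admission_date = NA_integer_,
                     discharge_date = NA_integer_, stringsAsFactors = FALSE)
  ev <- merge_events(cand)
  expect_equal(ev$onset, c(0L, 20L))
  # boundary: 14 days apart merge into one
  cand2 <- cand[1:2, ]; cand2$onset <- c(0L, 14L)
  expect_equal(nrow(merge_events(cand2)), 1L)
  cand2$onset <- c(0L, 15L)
  expect_equal(nrow(merge_events(cand2)), 2L)
  # single candidate is the identity
  ev1 <- merge_events(cand[1, ])
  expect_equal(ev1$onset, 0L)
  expect_equal(ev1$merged_from, 0L)
  # chained rule absorbs the whole run
  expect_equal(nrow(merge_events(cand, rule = "chained")), 1L)
  # merged type is the most severe member
  cand3 <- cand
  cand3$type <- c("outpatient_rx", "ed", "outpatient_rx")
  ev3 <- merge_events(cand3)
  expect_equal(ev3$type[1], "ed")
  expect_true(ev3$severe[1])
})

test_that("count variants, censoring and person-time behave per design", {
  # 3 events at 30/100/300
  x <- adj_db(list(mb(PID, c(30L, 100L, 300L), "office", dx1 = "491.21")),
              list(rb(PID, c(31L, 101L, 301L), "OCS", 5L)))
  spec <- followup_spec("fixed_12mo")
  ev <- adjudicate_events(x$db, x$record, spec)
  cx <- count_exacerbations(ev, x$db, x$record, spec)
  expect_equal(cx$count, 3L)
  expect_equal(cx$person_time, 1)
  expect_equal(cx$time_to_first, 30)
  expect_true(cx$event_flag)

  # switch fill at day 90 censors later events
  x2 <- adj_db(list(mb(PID, c(30L, 100L, 300L), "office", dx1 = "491.21")),
               list(rb(PID, c(31L, 101L, 301L), "OCS", 5L),
                    rb(PID, 90L, "FSC", 30L)))
  spec2 <- followup_spec("censor_at_switch")
  ev2 <- adjudicate_events(x2$db, x2$record, spec2)
  cx2 <- count_exacerbations(ev2, x2$db, x2$record, spec2)
  expect_equal(cx2$count, 1L)
  expect_equal(cx2$person_time, 90 / 365)
  # a same-class refill never censors
  x3 <- adj_db(list(mb(PID, c(30L, 100L), "office", dx1 = "491.21")),
               list(rb(PID, c(31L, 101L), "OCS", 5L),
                    rb(PID, 90L, "BFC", 30L)))
  cx3 <- count_exacerbations(adjudicate_events(x3$db, x3$record, spec2),
                             x3$db, x3$record, spec2)
  expect_equal(cx3$count, 2L)
  expect_equal(cx3$person_time, 1)

  # severe-only counts severe events
  x4 <- adj_db(list(mb(PID, 50L, "inpatient", dx1 = "491.21",
                       admission = 50L, discharge = 52L),
                    mb(PID, 200L, "office", dx1 = "496")),
               list(rb(PID, 205L, "ANTIBIOTIC", 10L)))
  spec4 <- followup_spec("severe_only")
  cx4 <- count_exacerbations(adjudicate_events(x4$db, x4$record, spec4),
                             x4$db, x4$record, spec4)
  expect_equal(cx4$count, 1L)

  # all-available follow-up extends person-time to enrollment end
  spec5 <- followup_spec("all_available")
  cx5 <- count_exacerbations(adjudicate_events(x$db, x$record, spec5),
                             x$db, x$record, spec5)
  expect_equal(cx5$person_time, 400 / 365)  # enrollment ends at day 400
})

test_that("pneumonia detection uses the post-index window and places", {
  x <- adj_db(list(mb(PID, 100L, "ed", dx1 = "786.09", dx2 = "482.1"),
                   mb(PID, -50L, "office", dx1 = "486")))
  pn <- detect_pneumonia(x$db, x$record)
  expect_true(pn$any)
  expect_true(pn$ed)
  expect_false(pn$inpatient)
  expect_false(pn$outpatient)
  expect_equal(pn$first_date, 100L)

  # only pre-index pneumonia -> all false
  x2 <- adj_db(list(mb(PID, -50L, "office", dx1 = "486")))
  pn2 <- detect_pneumonia(x2$db, x2$record)
  expect_false(pn2$any)
  expect_true(is.na(pn2$first_date))
})

test_that("utilization tallies split by scope and count same-day stays as one", {
  x <- adj_db(list(
    mb(PID, 10L, "inpatient", dx1 = "491.21", admission = 10L,
       discharge = 10L),
    mb(PID, 60L, "inpatient", dx1 = "428.0", dx2 = "491.21",
       admission = 60L, discharge = 67L),
    mb(PID, 120L, "ed", dx1 = "428.0"),
    mb(PID, 150L, "office", dx1 = "491.21")))
  copd <- tally_utilization(x$db, x$record, "copd_related")
  expect_equal(copd$inpatient_n, 1L)   # COPD-primary stay only
  expect_equal(copd$inpatient_los, 1L) # same-day stay counts as one
  expect_equal(copd$ed_n, 0L)          # no COPD code on the ED claim
  expect_equal(copd$outpatient_n, 1L)
  all_c <- tally_utilization(x$db, x$record, "all_cause")
  expect_equal(all_c$inpatient_n, 2L)
  expect_equal(all_c$inpatient_los, 1L + 7L)
  expect_equal(all_c$ed_n, 1L)
})

test_that("adherence follows the PDC formula with the cap", {
  x <- adj_db()  # index fill only, 30 days supply
  ad <- compute_adherence(x$db, x$record)
  expect_equal(ad$n_index_fills, 1L)
  expect_equal(ad$fill_category, "1")
  expect_equal(ad$pdc, 30 / 365)

  x2 <- adj_db(pharmacy = list(rb(PID, 28L * (1:11), "BFC", 30L),
                               rb(PID, 320L, "BFC", 60L)))
  ad2 <- compute_adherence(x2$db, x2$record)
  expect_equal(ad2$n_index_fills, 13L)
  expect_equal(ad2$fill_category, "4+")
  expect_equal(ad2$pdc, 1)  # 420 supplied days capped at 365

  x3 <- adj_db(pharmacy = list(rb(PID, 28L * (1:3), "BFC", 30L)))
  ad3 <- compute_adherence(x3$db, x3$record)
  expect_equal(ad3$n_index_fills, 4L)
  expect_equal(ad3$fill_category, "4+")
  expect_equal(ad3$pdc, 120 / 365)

  fl <- medication_flags(x3$db, x3$record)
  expect_true(fl$bfc)
  expect_false(fl$ocs)
})

test_that("adjudication matches the brute-force oracle on random micro-streams", {
  set.seed(404)
  for (i in seq_len(250)) {
    st <- random_micro_stream()
    ora <- oracle_adjudicate(st$med, st$rx, 0, 60)
    got <- package_adjudicate_stream(st)
    expect_equal(got$onset, ora$onset, label = paste("stream", i))
    expect_equal(got$type, ora$type, label = paste("stream", i))
    if (nrow(got) > 1) {
      gaps <- unlist(tapply(got$onset, rep(1, nrow(got)), function(x)
        diff(sort(x))))
      expect_true(all(gaps > 14), label = paste("spacing stream", i))
    }
  }
})

test_that("monotonicity: severity and censoring only reduce counts", {
  s <- simulate_claims(sim_config(n_patients = 150, seed = 77, noise = TRUE,
                                  switch_prob = 0.4))
  ch <- build_cohort(s$db, s$config$intake_window)
  fixed <- count_exacerbations(
    adjudicate_events(s$db, ch, followup_spec()), s$db, ch, followup_spec())
  sev <- count_exacerbations(
    adjudicate_events(s$db, ch, followup_spec("severe_only")), s$db, ch,
    followup_spec("severe_only"))
  cens_spec <- followup_spec("censor_at_switch")
  cens <- count_exacerbations(adjudicate_events(s$db, ch, cens_spec),
                              s$db, ch, cens_spec)
  expect_true(all(sev$count <= fixed$count))
  expect_true(all(cens$count <= fixed$count))
  expect_true(all(cens$person_time <= fixed$person_time))

  # adding a claim never decreases the candidate count
  x <- adj_db(list(mb(PID, 20L, "office", dx1 = "491.21")),
              list(rb(PID, 25L, "OCS", 5L)))
  n0 <- nrow(extract_candidates(x$db, x$record, followup_spec()))
  x2 <- adj_db(list(mb(PID, 20L, "office", dx1 = "491.21"),
                    mb(PID, 120L, "ed", dx1 = "491.21")),
               list(rb(PID, 25L, "OCS", 5L)))
  n1 <- nrow(extract_candidates(x2$db, x2$record, followup_spec()))
  expect_gte(n1, n0)
})

test_that("retained events are always pairwise more than 14 days apart", {
  s <- simulate_claims(sim_config(n_patients = 200, seed = 55, noise = TRUE))
  ch <- build_cohort(s$db, s$config$intake_window)
  ev <- adjudicate_events(s$db, ch, followup_spec())
  gaps <- unlist(tapply(ev$onset, ev$patient_id, function(x) diff(sort(x))))
  expect_true(all(gaps > 14))
})
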