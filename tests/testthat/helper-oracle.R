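# Independent brute-force reference for the exacerbation adjudication
# rules, written as literal rule-by-rule loops over a single patient's
# claims. Shares no code with the package implementation.

oracle_is_copd <- function(code) {
  !is.na(code) & grepl("^(491|492|496)", gsub(".", "", code, fixed = TRUE))
}

# med: data.frame(service_date, place, admission, discharge, dx1, dx2)
# rx:  data.frame(fill_date, drug_class)
# Returns data.frame(onset, type) of adjudicated events in [start, end].
oracle_adjudicate <- function(med, rx, start, end) {
  cand <- list()
  # candidates
  for (r in seq_len(nrow(med))) {
    m <- med[r, ]
    if (m$place == "inpatient" && oracle_is_copd(m$dx1) &&
        m$admission >= start && m$admission <= end) {
      cand[[length(cand) + 1]] <- list(onset = m$admission, type = "inpatient",
                                       fill = NA, disch = m$discharge)
    }
    if (m$place == "ed" && (oracle_is_copd(m$dx1) || oracle_is_copd(m$dx2)) &&
        m$service_date >= start && m$service_date <= end) {
      cand[[length(cand) + 1]] <- list(onset = m$service_date, type = "ed",
                                       fill = NA, disch = NA)
    }
    if (m$place %in% c("office", "outpatient") &&
        (oracle_is_copd(m$dx1) || oracle_is_copd(m$dx2)) &&
        m$service_date >= start && m$service_date <= end) {
      for (q in seq_len(nrow(rx))) {
        f <- rx[q, ]
        if (f$drug_class %in% c("OCS", "ANTIBIOTIC") &&
            f$fill_date >= m$service_date &&
            f$fill_date <= m$service_date + 10) {
          cand[[length(cand) + 1]] <- list(onset = m$service_date,
                                           type = "outpatient_rx",
                                           fill = f$fill_date, disch = NA)
        }
      }
    }
  }
  if (!length(cand)) return(data.frame(onset = integer(0), type = character(0)))

  # rule (i): ED inside an inpatient stay
  keep <- rep(TRUE, length(cand))
  for (k in seq_along(cand)) {
    if (cand[[k]]$type != "ed") next
    for (j in seq_along(cand)) {
      if (cand[[j]]$type == "inpatient" &&
          cand[[k]]$onset >= cand[[j]]$onset &&
          cand[[k]]$onset <= cand[[j]]$disch) keep[k] <- FALSE
    }
  }
  # rule (ii): fill within 14 days of a severe onset (severe set taken
  # before rule i)
  for (k in seq_along(cand)) {
    if (cand[[k]]$type != "outpatient_rx") next
    for (j in seq_along(cand)) {
      if (cand[[j]]$type %in% c("inpatient", "ed") &&
          abs(cand[[k]]$fill - cand[[j]]$onset) <= 14) keep[k] <- FALSE
    }
  }
  cand <- cand[keep]
  if (!length(cand)) return(data.frame(onset = integer(0), type = character(0)))

  # rule (iii): one candidate per visit
  df <- data.frame(onset = vapply(cand, function(c) as.integer(c$onset),
                                  integer(1)),
                   type = vapply(cand, function(c) c$type, character(1)),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  # but distinct severe candidates at the same onset all survive; only
  # outpatient pairs collapse -- unique() over (onset, type) does both,
  # because severe duplicates at one onset merge anyway.

  # merge: anchored 14-day clusters
  sev_rank <- c(outpatient_rx = 1, ed = 2, inpatient = 3)
  df <- df[order(df$onset, -sev_rank[df$type]), , drop = FALSE]
  events <- list()
  i <- 1
  while (i <= nrow(df)) {
    anchor <- df$onset[i]
    members <- i
    j <- i + 1
    while (j <= nrow(df) && df$onset[j] <= anchor + 14) {
      members <- c(members, j)
      j <- j + 1
    }
    types <- df$type[members]
    events[[length(events) + 1]] <-
      data.frame(onset = anchor,
                 type = names(sev_rank)[max(sev_rank[types])],
                 stringsAsFactors = FALSE)
    i <- j
  }
  do.call(rbind, events)
}

# Random micro-stream of claims for one synthetic patient, dense enough
# in time to exercise every attribution and merge rule.
random_micro_stream <- function() {
  n_med <- sample(0:8, 1)
  n_rx <- sample(0:4, 1)
  med <- NULL
  if (n_med > 0) {
    place <- sample(c("inpatient", "ed", "office", "outpatient", "snf"),
                    n_med, replace = TRUE)
    day <- sample(0:60, n_med, replace = TRUE)
    copd_dx <- sample(c("491.21", "492.8", "496"), n_med, replace = TRUE)
    has_copd <- runif(n_med) < 0.6
    in_pos2 <- runif(n_med) < 0.3
    dx1 <- ifelse(has_copd & !in_pos2, copd_dx, "786.09")
    dx2 <- ifelse(has_copd & in_pos2, copd_dx, NA_character_)
    stay <- sample(0:6, n_med, replace = TRUE)
    med <- data.frame(service_date = day, place = place,
                      admission = ifelse(place == "inpatient", day, NA),
                      discharge = ifelse(place == "inpatient", day + stay, NA),
                      dx1 = dx1, dx2 = dx2, stringsAsFactors = FALSE)
  } else {
    med <- data.frame(service_date = integer(0), place = character(0),
                      admission = integer(0), discharge = integer(0),
                      dx1 = character(0), dx2 = character(0),
                      stringsAsFactors = FALSE)
  }
  rx <- if (n_rx > 0) {
    data.frame(fill_date = sample(0:70, n_rx, replace = TRUE),
               drug_class = sample(c("OCS", "ANTIBIOTIC", "SABA", "BFC"),
                                   n_rx, replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(fill_date = integer(0), drug_class = character(0),
               stringsAsFactors = FALSE)
  }
  list(med = med, rx = rx)
}

# Wrap a micro-stream into a one-patient claims_db + cohort record so the
# package pipeline can adjudicate it; window [0, 60] mapped onto a fixed
# index date.
stream_to_db <- function(stream, index_date = 1000L) {
  med <- stream$med
  rx <- stream$rx
  pid <- "MS0001"
  patients <- data.frame(patient_id = pid, birth_year = 1945L, sex = "male",
                         region = "west", stringsAsFactors = FALSE)
  enrollment <- data.frame(patient_id = pid, start_date = index_date - 400L,
                           end_date = index_date + 400L,
                           medical_eligible = TRUE, pharmacy_eligible = TRUE,
                           stringsAsFactors = FALSE)
  medical <- data.frame(
    claim_id = sprintf("M%03d", seq_len(nrow(med))),
    patient_id = rep(pid, nrow(med)),
    service_date = index_date + med$service_date,
    place_of_service = med$place,
    icu_flag = rep(FALSE, nrow(med)),
    admission_date = index_date + med$admission,
    discharge_date = index_date + med$discharge,
    dx1 = med$dx1, dx2 = med$dx2,
    dx3 = rep(NA_character_, nrow(med)), dx4 = rep(NA_character_, nrow(med)),
    dx5 = rep(NA_character_, nrow(med)),
    provider_specialty = rep("other", nrow(med)),
    stringsAsFactors = FALSE)
  # inpatient service date must equal admission
  inp <- medical$place_of_service == "inpatient"
  medical$service_date[inp] <- medical$admission_date[inp]
  pharmacy <- data.frame(
    claim_id = sprintf("P%03d", seq_len(nrow(rx) + 1L)),
    patient_id = rep(pid, nrow(rx) + 1L),
    fill_date = c(index_date, index_date + rx$fill_date),
    drug_class = c("BFC", rx$drug_class),
    days_supply = rep(10L, nrow(rx) + 1L),
    stringsAsFactors = FALSE)
  db <- claims_db(patients, enrollment, medical, pharmacy)
  record <- data.frame(patient_id = pid, index_date = index_date,
                       index_drug = "BFC", stringsAsFactors = FALSE)
  list(db = db, record = record)
}

# Package-side adjudication of a micro-stream over window [0, 60]
# (relative), returned on the relative day scale.
package_adjudicate_stream <- function(stream, index_date = 1000L) {
  x <- stream_to_db(stream, index_date)
  windows <- data.frame(patient_id = x$record$patient_id,
                        start = index_date, end = index_date + 60L,
                        stringsAsFactors = FALSE)
  cand <- copdce:::candidates_in_window(x$db, windows)
  # the stream index fill (a BFC fill) never qualifies; window arithmetic
  # keeps candidates inside [0, 60]
  ev <- merge_events(apply_attribution(cand))
  data.frame(onset = ev$onset - index_date, type = ev$type,
             stringsAsFactors = FALSE)
}
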