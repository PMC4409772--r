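POS_LEVELS <- c("inpatient", "ed", "office", "outpatient", "snf")

DRUG_CLASSES <- c(
  "BFC", "FSC", "OTHER_ICS_LABA", "ICS", "LABA", "LAMA", "SABA", "SAMA",
  "SABA_SAMA", "OCS", "ANTIBIOTIC", "LTRA", "ROFLUMILAST", "THEOPHYLLINE",
  "OMALIZUMAB", "CARDIOVASCULAR", "OTHER"
)

ICS_LABA_CLASSES <- c("BFC", "FSC", "OTHER_ICS_LABA")

#' Construct a claims database
#'
#' Bundles the four linked tables of an administrative-claims extract:
#' `patients`, `enrollment` spans, `medical` claims (with ordered diagnosis
#' slots `dx1..dxK`) and `pharmacy` claims. All dates are integer day
#' indices relative to an arbitrary epoch (day 0).
#'
#' @param patients data.frame with `patient_id`, `birth_year`, `sex`
#'   (`"female"`/`"male"`), `region`.
#' @param enrollment data.frame with `patient_id`, `start_date`, `end_date`
#'   (inclusive), `medical_eligible`, `pharmacy_eligible`.
#' @param medical data.frame with `claim_id`, `patient_id`, `service_date`,
#'   `place_of_service`, `icu_flag`, `admission_date`, `discharge_date`
#'   (inpatient only, otherwise `NA`), diagnosis columns `dx1..dxK`
#'   (slot 1 is the primary diagnosis), `provider_specialty`.
#' @param pharmacy data.frame with `claim_id`, `patient_id`, `fill_date`,
#'   `drug_class`, `days_supply`.
#' @param validate Run [validate_claims_db()] on the result (default `TRUE`).
#' @return An object of class `"claims_db"`.
#' @export
claims_db <- function(patients, enrollment, medical, pharmacy, validate = TRUE) {
  db <- structure(
    list(patients = as.data.frame(patients),
         enrollment = as.data.frame(enrollment),
         medical = as.data.frame(medical),
         pharmacy = as.data.frame(pharmacy)),
    class = "claims_db")
  if (validate) validate_claims_db(db)
  db
}

#' @export
print.claims_db <- function(x, ...) {
  cat("<claims_db>\n")
  cat(sprintf("  patients:        %6d\n", nrow(x$patients)))
  cat(sprintf("  enrollment spans:%6d\n", nrow(x$enrollment)))
  cat(sprintf("  medical claims:  %6d\n", nrow(x$medical)))
  cat(sprintf("  pharmacy claims: %6d\n", nrow(x$pharmacy)))
  invisible(x)
}

#' Validate a claims database
#'
#' Checks referential integrity (every claim's `patient_id` exists in
#' `patients`), required columns, enumerated vocabularies, non-overlapping
#' enrollment spans, inpatient date consistency
#' (`admission_date <= discharge_date`, `service_date == admission_date`)
#' and positive `days_supply`. Errors name the offending table and row.
#'
#' @param db A [claims_db()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_claims_db <- function(db) {
  req <- function(tab, cols, name) {
    miss <- setdiff(cols, names(tab))
    if (length(miss)) {
      stop("table '", name, "' is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  req(db$patients, c("patient_id", "birth_year", "sex", "region"), "patients")
  req(db$enrollment, c("patient_id", "start_date", "end_date",
                       "medical_eligible", "pharmacy_eligible"), "enrollment")
  req(db$medical, c("claim_id", "patient_id", "service_date",
                    "place_of_service", "icu_flag", "admission_date",
                    "discharge_date", "dx1", "provider_specialty"), "medical_claims")
  req(db$pharmacy, c("claim_id", "patient_id", "fill_date", "drug_class",
                     "days_supply"), "pharmacy_claims")

  if (anyDuplicated(db$patients$patient_id)) {
    stop("duplicate patient_id in patients: row ",
         anyDuplicated(db$patients$patient_id), call. = FALSE)
  }
  for (tab in c("enrollment", "medical", "pharmacy")) {
    bad <- which(!db[[tab]]$patient_id %in% db$patients$patient_id)
    if (length(bad)) {
      stop("referential-integrity violation in '", tab, "': unknown patient_id at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(!db$medical$place_of_service %in% POS_LEVELS)
  if (length(bad)) {
    stop("invalid place_of_service in medical_claims at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!db$pharmacy$drug_class %in% DRUG_CLASSES)
  if (length(bad)) {
    stop("invalid drug_class in pharmacy_claims at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(db$pharmacy$days_supply < 1)
  if (length(bad)) {
    stop("days_supply < 1 in pharmacy_claims at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(db$enrollment$start_date > db$enrollment$end_date)
  if (length(bad)) {
    stop("enrollment start_date > end_date at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  # non-overlapping spans per patient
  if (nrow(db$enrollment) > 1) {
    enr <- db$enrollment[order(db$enrollment$patient_id, db$enrollment$start_date), ]
    same <- enr$patient_id[-1] == enr$patient_id[-nrow(enr)]
    overlap <- same & enr$start_date[-1] <= enr$end_date[-nrow(enr)]
    if (any(overlap)) {
      stop("overlapping enrollment spans for patient ",
           enr$patient_id[which(overlap)[1] + 1], call. = FALSE)
    }
  }
  inp <- db$medical$place_of_service == "inpatient"
  if (any(inp)) {
    m <- db$medical[inp, ]
    bad <- which(is.na(m$admission_date) | is.na(m$discharge_date) |
                   m$admission_date > m$discharge_date |
                   m$service_date != m$admission_date)
    if (length(bad)) {
      stop("inconsistent inpatient dates in medical_claims (claim_id ",
           paste(utils::head(m$claim_id[bad], 5), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  bad <- which(is.na(db$medical$dx1) | !nzchar(db$medical$dx1))
  if (length(bad)) {
    stop("empty primary diagnosis in medical_claims at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

claims_files <- c(patients = "patients.csv", enrollment = "enrollment.csv",
                  medical = "medical_claims.csv", pharmacy = "pharmacy_claims.csv")

#' Write a claims database to a directory of CSV tables
#'
#' @param db A [claims_db()].
#' @param dir_path Output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_claims <- function(db, dir_path) {
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  for (tab in names(claims_files)) {
    utils::write.csv(db[[tab]], file.path(dir_path, claims_files[[tab]]),
                     row.names = FALSE)
  }
  invisible(dir_path)
}

#' Read a claims database from a directory of CSV tables
#'
#' Expects `patients.csv`, `enrollment.csv`, `medical_claims.csv` and
#' `pharmacy_claims.csv` as written by [write_claims()]. The read is a
#' round-trip identity for databases produced by this package.
#'
#' @param dir_path Directory containing the four CSV files.
#' @param validate Run [validate_claims_db()] after reading (default `TRUE`).
#' @return A [claims_db()].
#' @export
read_claims <- function(dir_path, validate = TRUE) {
  paths <- file.path(dir_path, claims_files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing claims file(s): ", paste(claims_files[missing], collapse = ", "),
         call. = FALSE)
  }
  int_cols <- list(
    patients = "birth_year",
    enrollment = c("start_date", "end_date"),
    medical = c("service_date", "admission_date", "discharge_date"),
    pharmacy = c("fill_date", "days_supply"))
  lgl_cols <- list(
    enrollment = c("medical_eligible", "pharmacy_eligible"),
    medical = "icu_flag")
  tabs <- list()
  for (tab in names(claims_files)) {
    # read everything as character so diagnosis codes like "493.20" keep
    # their trailing zeros, then restore the typed columns
    df <- utils::read.csv(file.path(dir_path, claims_files[[tab]]),
                          stringsAsFactors = FALSE, colClasses = "character")
    for (col in intersect(int_cols[[tab]], names(df))) {
      df[[col]] <- as.integer(df[[col]])
    }
    for (col in intersect(lgl_cols[[tab]], names(df))) {
      df[[col]] <- as.logical(df[[col]])
    }
    tabs[[tab]] <- df
  }
  claims_db(tabs$patients, tabs$enrollment, tabs$medical, tabs$pharmacy,
            validate = validate)
}
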