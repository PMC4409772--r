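#' Default diagnosis code sets
#'
#' Returns the named list of ICD-9-CM prefix sets used throughout the
#' pipeline. Matching is prefix-based on the code stem with any period
#' removed, so `"491.21"`, `"49121"` and `"4912"` all match the COPD stem
#' `"491"`.
#'
#' The defaults are: COPD (491, 492, 496), pneumonia (480-486), cancer
#' (140-208), and a small set of comorbidity conditions used as matching
#' covariates (asthma 493, hypertension 401-405, diabetes 250, peripheral
#' vascular disease 443-444, coronary artery disease 414, depression 311,
#' heart failure 428).
#'
#' @param cancer_prefixes Character vector of ICD-9-CM stems treated as a
#'   cancer diagnosis (exclusion criterion). Default 140-208.
#' @return A named list of character vectors of code prefixes, class
#'   `"codeset"`.
#' @export
#' @examples
#' cs <- default_codesets()
#' match_code("491.21", "copd", cs)
default_codesets <- function(cancer_prefixes = as.character(140:208)) {
  structure(list(
    copd       = c("491", "492", "496"),
    pneumonia  = as.character(480:486),
    cancer     = as.character(cancer_prefixes),
    asthma     = "493",
    hypertension = as.character(401:405),
    diabetes   = "250",
    pvd        = c("443", "444"),
    cad        = "414",
    depression = "311",
    heart_failure = "428"
  ), class = "codeset")
}

#' Match an ICD-9-CM code against a condition's prefix set
#'
#' Period-insensitive prefix matching: the code is stripped of any `"."`
#' and tested for starting with one of the condition's stems.
#'
#' @param code Character vector of ICD-9-CM codes (may contain periods).
#' @param condition Single condition name present in `codeset`.
#' @param codeset A code set from [default_codesets()].
#' @return Logical vector, `TRUE` where the code matches. `NA` and empty
#'   codes never match.
#' @export
match_code <- function(code, condition, codeset = default_codesets()) {
  if (!condition %in% names(codeset)) {
    stop("unknown condition '", condition, "' in code set", call. = FALSE)
  }
  stems <- codeset[[condition]]
  bare <- gsub(".", "", as.character(code), fixed = TRUE)
  out <- rep(FALSE, length(bare))
  ok <- !is.na(bare) & nzchar(bare)
  if (any(ok)) {
    hit <- rep(FALSE, sum(ok))
    for (s in stems) hit <- hit | startsWith(bare[ok], s)
    out[ok] <- hit
  }
  out
}

#' Test whether a medical claim carries a condition diagnosis
#'
#' @param claim One row of the `medical` table of a [claims_db()].
#' @param condition Condition name in `codeset`.
#' @param position `"primary"` tests diagnosis slot 1 only; `"any"` tests
#'   every slot.
#' @param codeset A code set from [default_codesets()].
#' @return `TRUE`/`FALSE`.
#' @export
claim_has_condition <- function(claim, condition, position = c("any", "primary"),
                                codeset = default_codesets()) {
  position <- match.arg(position)
  dx_cols <- grep("^dx[0-9]+$", names(claim), value = TRUE)
  if (position == "primary") dx_cols <- "dx1"
  codes <- unlist(claim[1, dx_cols], use.names = FALSE)
  any(match_code(codes, condition, codeset))
}

# Vectorised condition indicator over a whole medical-claims table.
# Returns a logical vector, one element per claim row.
claims_condition_flag <- function(medical, condition, position = "any",
                                  codeset = default_codesets()) {
  dx_cols <- grep("^dx[0-9]+$", names(medical), value = TRUE)
  if (position == "primary") dx_cols <- "dx1"
  flag <- rep(FALSE, nrow(medical))
  for (col in dx_cols) {
    flag <- flag | match_code(medical[[col]], condition, codeset)
  }
  flag
}
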