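# Random-forest propensity scores, 1:1 greedy matching on the logit
# scale, and covariate balance diagnostics.

#' Pre-specified matching covariates
#'
#' The variables the study design requires to be balanced: age, gender,
#' prior asthma diagnosis, and pre-index counts of COPD hospitalizations,
#' COPD ED visits, OCS fills, antibiotic fills, SABA/SABA-SAMA fills,
#' LABA fills and LAMA fills.
#'
#' @return Character vector of covariate column names.
#' @export
prespecified_covariates <- function() {
  c("age_at_index", "female", "asthma", "pre_copd_inpatient", "pre_copd_ed",
    "pre_ocs_fills", "pre_abx_fills", "pre_saba_fills", "pre_laba_fills",
    "pre_lama_fills")
}

#' Optional matching covariates
#'
#' Additional balance variables: pre-index exacerbations and their type
#' flags, prior pneumonia, comorbidity flags.
#'
#' @return Character vector of covariate column names.
#' @export
optional_covariates <- function() {
  c("pre_exac", "pre_exac_inpatient", "pre_exac_ed", "pre_exac_outpatient_rx",
    "prior_pneumonia", "hypertension", "diabetes", "pvd", "cad", "depression",
    "heart_failure")
}

#' Estimate propensity scores with a random forest
#'
#' Fits a probability forest of treatment (BFC = 1, FSC = 0) on baseline
#' covariates: a random forest grown in regression mode on the 0/1
#' treatment indicator with large terminal nodes, whose leaves estimate
#' treatment probabilities rather than class votes. Each patient's score
#' is the out-of-bag prediction (avoiding in-bag overfitting), clipped
#' to `[1/(2N), 1 - 1/(2N)]` so downstream logits are finite.
#'
#' @param cohort A [build_cohort()] result (or any data.frame with an
#'   `index_drug` column and the covariates).
#' @param covariates Character vector of covariate columns; default the
#'   pre-specified plus optional sets.
#' @param n_trees Number of trees (default 1000).
#' @param nodesize Minimum terminal-node size; default 10% of the cohort
#'   (at least 25). Large nodes smooth the leaf probability estimates.
#' @param mtry Covariates tried per split; default the regression-forest
#'   convention `max(floor(p / 3), 1)`.
#' @param seed Integer seed for reproducibility.
#' @return List of class `"propensity_result"`: `score` (named by
#'   patient_id), `covariates`, `n_trees`, `seed`, `model`.
#' @export
estimate_propensity <- function(cohort,
                                covariates = c(prespecified_covariates(),
                                               optional_covariates()),
                                n_trees = 1000, nodesize = NULL, mtry = NULL,
                                seed = 1) {
  arm <- factor(cohort$index_drug, levels = c("FSC", "BFC"))
  if (nlevels(droplevels(arm)) < 2L || min(table(arm)) < 2L) {
    stop("propensity estimation needs at least 2 patients per arm",
         call. = FALSE)
  }
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop("covariate(s) not in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(cohort)[, covariates, drop = FALSE]
  for (col in names(x)) {
    if (is.character(x[[col]]) || is.logical(x[[col]])) {
      x[[col]] <- factor(x[[col]])
    }
  }
  n <- nrow(x)
  if (is.null(nodesize)) nodesize <- max(25L, ceiling(0.1 * n))
  if (is.null(mtry)) mtry <- max(floor(ncol(x) / 3), 1L)
  set.seed(seed)
  rf <- suppressWarnings(
    randomForest::randomForest(x = x, y = as.numeric(arm == "BFC"),
                               ntree = n_trees, nodesize = nodesize,
                               mtry = mtry))
  score <- rf$predicted  # out-of-bag predictions
  score <- pmin(pmax(score, 1 / (2 * n)), 1 - 1 / (2 * n))
  names(score) <- cohort$patient_id
  structure(list(score = score, covariates = covariates, n_trees = n_trees,
                 nodesize = nodesize, mtry = mtry, seed = seed, model = rf),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("<propensity_result> %d patients, %d trees, %d covariates\n",
              length(x$score), x$n_trees, length(x$covariates)))
  print(summary(x$score))
  invisible(x)
}

#' 1:1 greedy propensity-score matching
#'
#' Greedy nearest-neighbour matching without replacement on the logit of
#' the propensity score. BFC patients are processed in random (seeded)
#' order; each takes the closest unused FSC patient within the caliper,
#' ties broken by lower patient id.
#'
#' @param cohort Cohort data.frame (`patient_id`, `index_drug`).
#' @param scores Named score vector from [estimate_propensity()] (or the
#'   `propensity_result` itself).
#' @param caliper_sd_logit Caliper as a multiple of the SD of the logit
#'   scores (default 0.2); `Inf` disables the caliper.
#' @param seed Seed for the processing order.
#' @return List of class `"copd_match"`: `pairs` (data.frame
#'   `bfc_patient_id`, `fsc_patient_id`), `unmatched` (ids), `caliper`
#'   (logit units), `scores`.
#' @export
match_1to1 <- function(cohort, scores, caliper_sd_logit = 0.2, seed = 1) {
  if (inherits(scores, "propensity_result")) scores <- scores$score
  s <- scores[cohort$patient_id]
  if (anyNA(s)) stop("scores missing for some cohort patients", call. = FALSE)
  lg <- stats::qlogis(s)
  caliper <- caliper_sd_logit * stats::sd(lg)
  bfc <- which(cohort$index_drug == "BFC")
  fsc <- which(cohort$index_drug == "FSC")

  set.seed(seed)
  bfc <- bfc[order(stats::runif(length(bfc)))]
  # candidate pool sorted by logit, then id, for binary-search matching
  ord <- fsc[order(lg[fsc], cohort$patient_id[fsc])]
  pool_lg <- lg[ord]
  pool_id <- cohort$patient_id[ord]
  used <- rep(FALSE, length(ord))
  m_bfc <- character(0); m_fsc <- character(0)
  for (b in bfc) {
    target <- lg[b]
    # nearest unused pool member
    pos <- findInterval(target, pool_lg)
    lo <- pos; hi <- pos + 1L
    while (lo >= 1L && used[lo]) lo <- lo - 1L
    while (hi <= length(ord) && used[hi]) hi <- hi + 1L
    d_lo <- if (lo >= 1L) abs(target - pool_lg[lo]) else Inf
    d_hi <- if (hi <= length(ord)) abs(pool_lg[hi] - target) else Inf
    if (is.infinite(d_lo) && is.infinite(d_hi)) next
    tol <- 1e-9 * max(1, abs(target))
    pick <- if (d_lo < d_hi - tol) {
      lo
    } else if (d_hi < d_lo - tol) {
      hi
    } else if (pool_id[lo] <= pool_id[hi]) lo else hi
    if (abs(pool_lg[pick] - target) > caliper) next
    used[pick] <- TRUE
    m_bfc <- c(m_bfc, cohort$patient_id[b])
    m_fsc <- c(m_fsc, pool_id[pick])
  }
  pairs <- data.frame(bfc_patient_id = m_bfc, fsc_patient_id = m_fsc,
                      stringsAsFactors = FALSE)
  matched <- c(pairs$bfc_patient_id, pairs$fsc_patient_id)
  structure(list(pairs = pairs,
                 unmatched = setdiff(cohort$patient_id, matched),
                 caliper = caliper, scores = s),
            class = "copd_match")
}

#' @export
print.copd_match <- function(x, ...) {
  cat(sprintf("<copd_match> %d pairs, %d unmatched (caliper %.3f logits)\n",
              nrow(x$pairs), length(x$unmatched), x$caliper))
  invisible(x)
}

#' Extract the matched sample
#'
#' @param cohort Cohort data.frame.
#' @param match A [match_1to1()] result.
#' @return Subset of `cohort` restricted to matched patients.
#' @export
matched_sample <- function(cohort, match) {
  ids <- c(match$pairs$bfc_patient_id, match$pairs$fsc_patient_id)
  out <- cohort[cohort$patient_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

smd <- function(x1, x2) {
  m <- mean(x1) - mean(x2)
  s <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  if (!is.finite(s) || s == 0) return(if (m == 0) 0 else Inf)
  m / s
}

balance_one <- function(x, arm) {
  x1 <- x[arm == "BFC"]; x2 <- x[arm == "FSC"]
  if (is.logical(x) || (is.numeric(x) && length(unique(x)) <= 2L)) {
    x1 <- as.numeric(x1); x2 <- as.numeric(x2)
    tab <- table(arm, x)
    p <- if (stats::var(as.numeric(x)) == 0) {
      1
    } else {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    list(p = p, smd = smd(x1, x2), mean_bfc = mean(x1), mean_fsc = mean(x2))
  } else if (is.character(x) || is.factor(x)) {
    tab <- table(arm, x)
    p <- if (length(unique(x)) < 2L) {
      1
    } else {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    # SMD for multi-category variables: largest per-level proportion SMD
    lv <- unique(x)
    smds <- vapply(lv, function(l) smd(as.numeric(x1 == l),
                                       as.numeric(x2 == l)), numeric(1))
    list(p = p, smd = smds[which.max(abs(smds))],
         mean_bfc = NA_real_, mean_fsc = NA_real_)
  } else {
    p <- if (stats::var(x1) == 0 && stats::var(x2) == 0) {
      if (mean(x1) == mean(x2)) 1 else 0
    } else {
      stats::t.test(x1, x2, var.equal = TRUE)$p.value
    }
    list(p = p, smd = smd(x1, x2), mean_bfc = mean(x1), mean_fsc = mean(x2))
  }
}

#' Covariate balance table
#'
#' Pre- and post-match balance for each variable: arm means, pooled
#' two-sample t-test (continuous) or chi-square test (categorical)
#' p-values, and standardized mean differences. A variable is flagged
#' balanced when its post-match p-value exceeds 0.05; zero-variance
#' variables are balanced with p = 1.
#'
#' @param cohort Full (pre-match) cohort data.frame.
#' @param match A [match_1to1()] result.
#' @param variables Covariate columns to evaluate.
#' @return data.frame of class `"balance_table"`: one row per variable
#'   with `p_pre`, `p_post`, `smd_pre`, `smd_post`, `balanced`. The
#'   post-match unbalanced variable names are attached as attribute
#'   `"residual_covariates"`.
#' @export
balance_table <- function(cohort, match,
                          variables = c(prespecified_covariates(),
                                        optional_covariates())) {
  if (nrow(match$pairs) == 0L) stop("no matched pairs", call. = FALSE)
  post <- matched_sample(cohort, match)
  rows <- lapply(variables, function(v) {
    pre_b <- balance_one(cohort[[v]], cohort$index_drug)
    post_b <- balance_one(post[[v]], post$index_drug)
    data.frame(variable = v,
               mean_bfc_pre = pre_b$mean_bfc, mean_fsc_pre = pre_b$mean_fsc,
               p_pre = pre_b$p, smd_pre = pre_b$smd,
               mean_bfc_post = post_b$mean_bfc,
               mean_fsc_post = post_b$mean_fsc,
               p_post = post_b$p, smd_post = post_b$smd,
               balanced = post_b$p > 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "residual_covariates") <- out$variable[!out$balanced]
  class(out) <- c("balance_table", "data.frame")
  out
}
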