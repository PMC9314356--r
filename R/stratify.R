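#' Age filter on AAO/AAE
#'
#' Retains cases with age at onset and controls with age at last examination
#' at or above `min_age` (default 60 years, the conventional lower bound for
#' late-onset disease).
#'
#' @param study A [genotype_study()].
#' @param min_age Minimum age in years.
#' @return The filtered [genotype_study()]; removing every sample is fatal.
#' @export
filter_age <- function(study, min_age = 60) {
  keep <- study$samples$age >= min_age
  if (!any(keep)) stopf("age filter >= %g removed every sample in study %s",
                        min_age, study$study_id)
  if (!all(keep))
    pr_log("filter_age: removed %d of %d samples below %g years in %s",
           sum(!keep), length(keep), min_age, study$study_id)
  study$samples <- study$samples[keep, , drop = FALSE]
  study$dosages <- study$dosages[keep, , drop = FALSE]
  rownames(study$samples) <- NULL
  study
}

new_stratified_cohort <- function(study_id, design, resilient_ids,
                                  risk_matched_case_ids, cutoff, max_ctrl,
                                  n_controls_total, n_cases_total,
                                  dropped = FALSE, reason = NA_character_) {
  structure(list(study_id = study_id, design = design,
                 resilient_ids = resilient_ids,
                 risk_matched_case_ids = risk_matched_case_ids,
                 control_cutoff_score = cutoff,
                 control_max_score = max_ctrl,
                 n_controls_total = n_controls_total,
                 n_cases_total = n_cases_total,
                 dropped = dropped, reason = reason),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  if (x$dropped) {
    cat(sprintf("<stratified_cohort %s design %d: DROPPED (%s)>\n",
                x$study_id, x$design, x$reason))
  } else {
    cat(sprintf("<stratified_cohort %s design %d: %d resilient of %d controls, %d risk-matched of %d cases>\n",
                x$study_id, x$design, length(x$resilient_ids),
                x$n_controls_total, length(x$risk_matched_case_ids),
                x$n_cases_total))
  }
  invisible(x)
}

strat_core <- function(study, prs, control_percentile, design,
                       subset_ids = NULL, min_group = 2L) {
  s <- study$samples
  if (!is.null(subset_ids)) s <- s[s$sample_id %in% subset_ids, , drop = FALSE]
  ctrl <- s$sample_id[s$status == "control"]
  case <- s$sample_id[s$status == "case"]
  fail <- function(reason) {
    pr_log("study %s dropped from design %d: %s", study$study_id, design, reason)
    new_stratified_cohort(study$study_id, design, character(0), character(0),
                          NA_real_, NA_real_, length(ctrl), length(case),
                          dropped = TRUE, reason = reason)
  }
  if (length(ctrl) < 2 || length(case) < 1) return(fail("too few controls or cases"))
  ranked <- rank_within_study(prs, ctrl)
  sc <- setNames(ranked$raw_score, ranked$sample_id)
  pct <- setNames(ranked$percentile, ranked$sample_id)
  resilient <- ctrl[pct[ctrl] >= control_percentile]
  if (length(resilient) < 2) return(fail("<2 resilient controls"))
  cutoff <- min(sc[resilient])
  max_ctrl <- max(sc[ctrl])
  matched <- case[sc[case] >= cutoff & sc[case] <= max_ctrl]
  if (length(matched) < 2) return(fail("<2 risk-matched cases"))
  new_stratified_cohort(study$study_id, design, resilient, matched,
                        cutoff, max_ctrl, length(ctrl), length(case))
}

#' Design-1 selection of resilient controls and risk-matched cases
#'
#' Within one study, controls whose PRS percentile (computed among controls,
#' strict-below rule, ties inclusive at the cutoff) is at or above
#' `control_percentile` are labelled resilient; cases whose PRS lies within
#' `[min resilient PRS, max control PRS]` are retained as risk-matched.
#' Studies yielding fewer than two members in either group are dropped with a
#' logged reason rather than erroring, so multi-study runs degrade gracefully.
#'
#' @param study A [genotype_study()] (already age-filtered).
#' @param prs A `prs_result` from the full-genome risk weights (p < 0.5, no
#'   region excision).
#' @param control_percentile Selection percentile (default 90, i.e. the top
#'   10% of controls).
#' @return A `stratified_cohort`.
#' @export
select_design1 <- function(study, prs, control_percentile = 90) {
  strat_core(study, prs, control_percentile, design = 1L)
}

#' Design-2 selection among APOE-e4-like carriers
#'
#' Restricts to carriers of the major-effect allele, computes PRS percentiles
#' within carrier controls using an *APOE*-excised PRS, and applies the
#' design-1 rule at a more lenient percentile (default 80).
#'
#' @param study A [genotype_study()] (already age-filtered).
#' @param prs_no_apoe `prs_result` computed with the *APOE* region excised.
#' @param carrier Logical vector named by sample ID (or character vector of
#'   carrier sample IDs): carries at least one e4-like allele. See
#'   [carrier_flags()].
#' @param control_percentile Selection percentile (default 80).
#' @return A `stratified_cohort`.
#' @export
select_design2 <- function(study, prs_no_apoe, carrier,
                           control_percentile = 80) {
  if (is.logical(carrier)) {
    if (is.null(names(carrier))) stopf("logical carrier vector must be named")
    carrier <- names(carrier)[carrier]
  }
  strat_core(study, prs_no_apoe, control_percentile, design = 2L,
             subset_ids = carrier)
}

#' Carrier flags from a major-effect locus
#'
#' @param study A [genotype_study()].
#' @param snp_id The e4-like locus ID.
#' @param min_dosage Dosage at or above which a sample counts as a carrier.
#' @return Named logical vector over the study's samples.
#' @export
carrier_flags <- function(study, snp_id, min_dosage = 1) {
  j <- match(snp_id, study$variants$snp_id)
  if (is.na(j)) stopf("major locus %s not in study %s", snp_id, study$study_id)
  setNames(study$dosages[, j] >= min_dosage, study$samples$sample_id)
}

#' Per-study and total accounting of retained samples
#'
#' Reproduces the bookkeeping of the workflow's sample-accounting table:
#' counts of high-risk ("resilient") controls, all controls, risk-matched
#' cases and all cases, with percentages retained to one decimal, per study
#' plus a grand-total row.
#'
#' @param cohorts List of `stratified_cohort` objects from one design.
#' @return A data frame; empty input gives an empty table. See also
#'   [accounting_from_counts()].
#' @export
accounting_table <- function(cohorts) {
  if (!length(cohorts)) {
    return(accounting_from_counts(data.frame(
      study = character(0), n_highrisk = integer(0), n_controls = integer(0),
      n_riskmatched = integer(0), n_cases = integer(0))))
  }
  counts <- do.call(rbind, lapply(cohorts, function(ch) data.frame(
    study = ch$study_id,
    n_highrisk = length(ch$resilient_ids),
    n_controls = ch$n_controls_total,
    n_riskmatched = length(ch$risk_matched_case_ids),
    n_cases = ch$n_cases_total, stringsAsFactors = FALSE)))
  accounting_from_counts(counts)
}

#' Accounting table from raw per-study counts
#'
#' @param counts Data frame with columns `study`, `n_highrisk`, `n_controls`,
#'   `n_riskmatched`, `n_cases` (extra columns are carried through).
#' @return The counts with `pct_controls_retained` / `pct_cases_retained`
#'   (one decimal) and a `Total` row appended.
#' @export
accounting_from_counts <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("study", "n_highrisk", "n_controls", "n_riskmatched", "n_cases")
  if (!all(need %in% names(counts))) stopf("counts lack columns: %s",
    paste(setdiff(need, names(counts)), collapse = ", "))
  if (nrow(counts)) {
    tot <- data.frame(study = "Total",
                      n_highrisk = sum(counts$n_highrisk),
                      n_controls = sum(counts$n_controls),
                      n_riskmatched = sum(counts$n_riskmatched),
                      n_cases = sum(counts$n_cases), stringsAsFactors = FALSE)
    out <- rbind(counts[need], tot)
  } else {
    out <- counts[need]
  }
  pct <- function(a, b) ifelse(b > 0, round(100 * a / b, 1), NA_real_)
  out$pct_controls_retained <- pct(out$n_highrisk, out$n_controls)
  out$pct_cases_retained <- pct(out$n_riskmatched, out$n_cases)
  rownames(out) <- NULL
  out
}
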