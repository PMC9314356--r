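#' Build polygenic risk-score weights from risk-GWAS summary statistics
#'
#' Retains variants with association `p < p_threshold` that fall outside the
#' optional excluded region, weighting each retained variant by its beta
#' toward the effect allele. The default threshold of 0.5 is the deliberately
#' permissive cut at which LOAD PRS performance is maximized; the *APOE*
#' flanking region chr19:44,400,000-46,500,000 is the conventional excision
#' used for *APOE*-free scores.
#'
#' @param stats A validated [summary_stats()] table.
#' @param p_threshold Strict upper P bound for inclusion.
#' @param excluded_region Optional region (`"chr19:44400000-46500000"` or a
#'   `list(chr=, start=, end=)`); positions inside the closed interval are
#'   removed.
#' @return A [score_weights()] set; an empty result is fatal.
#' @export
build_risk_weights <- function(stats, p_threshold = 0.5,
                               excluded_region = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  region <- parse_region(excluded_region)
  keep <- stats$p < p_threshold & !in_region(stats$chr, stats$pos, region)
  if (!any(keep)) stopf("no variants pass p < %g outside the excluded region",
                        p_threshold)
  pr_log("build_risk_weights: %d of %d variants retained (p < %g%s)",
         sum(keep), nrow(stats), p_threshold,
         if (is.null(region)) "" else sprintf(", excising %s:%d-%d",
                                              region$chr, region$start, region$end))
  score_weights(data.frame(snp_id = stats$snp_id[keep],
                           effect_allele = stats$effect_allele[keep],
                           weight = stats$beta[keep],
                           stringsAsFactors = FALSE),
                p_threshold = p_threshold, excluded_region = region,
                provenance = "risk")
}

#' Compute polygenic scores for a study
#'
#' `raw_score(sample) = sum_i weight_i * dosage_i(sample)` over the variants
#' present in both the weight set and the study. Alleles are assumed
#' harmonized (see [harmonize_alleles()]); weights for variants absent from
#' the study are skipped with a logged count.
#'
#' @param study A [genotype_study()].
#' @param weights A [score_weights()] set.
#' @return A `prs_result` data frame (`sample_id`, `raw_score`, `percentile`
#'   initially `NA`) with metadata attributes `p_threshold`,
#'   `excluded_region` and `n_variants_used`.
#' @export
compute_prs <- function(study, weights) {
  stopifnot(inherits(study, "genotype_study"), inherits(weights, "score_weights"))
  idx <- match(weights$snp_id, study$variants$snp_id)
  used <- which(!is.na(idx))
  if (!length(used)) stopf("no overlap between weights and study %s variants",
                           study$study_id)
  if (length(used) < nrow(weights))
    pr_log("compute_prs: %d weight variants absent from study %s; skipped",
           nrow(weights) - length(used), study$study_id)
  mism <- weights$effect_allele[used] !=
    study$variants$effect_allele[idx[used]]
  if (any(mism)) stopf("%d weight variants have unharmonized effect alleles",
                       sum(mism))
  score <- drop(study$dosages[, idx[used], drop = FALSE] %*% weights$weight[used])
  structure(data.frame(sample_id = study$samples$sample_id,
                       raw_score = score, percentile = NA_real_,
                       stringsAsFactors = FALSE),
            p_threshold = attr(weights, "p_threshold"),
            excluded_region = attr(weights, "excluded_region"),
            n_variants_used = length(used),
            class = c("prs_result", "data.frame"))
}

#' Rank scores against a stated population
#'
#' The percentile of sample *s* is `100 * (# population members with score
#' strictly below s) / (population size)`; tied scores share a percentile.
#' Every sample in `prs` receives a percentile relative to the population
#' (typically the study's controls), so cases can be compared against
#' control-derived cutoffs.
#'
#' @param prs A `prs_result` from [compute_prs()].
#' @param population Character vector of sample IDs defining the ranking
#'   population; must be non-empty and present in `prs`.
#' @return The `prs_result` with `percentile` filled in and attribute
#'   `ranking_population` set.
#' @export
rank_within_study <- function(prs, population) {
  stopifnot(inherits(prs, "prs_result"))
  if (!length(population)) stopf("ranking population is empty")
  pop <- prs$raw_score[match(population, prs$sample_id)]
  if (anyNA(pop)) stopf("ranking population contains unknown sample IDs")
  sp <- sort(pop)
  # findInterval with left.open counts population scores strictly below x
  below <- findInterval(prs$raw_score, sp, left.open = TRUE)
  prs$percentile <- 100 * below / length(sp)
  attr(prs, "ranking_population") <- population
  prs
}
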