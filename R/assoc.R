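default_covariates <- function(samples) c("age", "sex", pc_columns(samples))

# Covariate design matrix for an analysis subset; drops constant columns
# (singular otherwise) with a log line.
covariate_design <- function(samples, covariates) {
  covariates <- intersect(covariates, names(samples))
  X <- cbind(`(Intercept)` = 1, as.matrix(samples[covariates]))
  storage.mode(X) <- "double"
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) sd(v) > 0))
  if (!all(keep)) {
    pr_log("dropping constant covariates: %s",
           paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Per-variant resilience GWAS within one study
#'
#' Logistic regression of group membership (resilient control = 1,
#' risk-matched case = 0) on effect-allele dosage plus covariates, fitted per
#' variant by iteratively reweighted least squares (max 100 iterations,
#' coefficient tolerance 1e-8). Monomorphic variants are skipped;
#' non-convergence and quasi-separation (any coefficient diverging past
#' |beta| > 20) skip the variant with a logged reason instead of erroring.
#'
#' @param study A [genotype_study()].
#' @param cohort A `stratified_cohort` for the study.
#' @param covariates Character vector of sample-table columns; defaults to
#'   age, sex and all principal components.
#' @return A [summary_stats()] table (beta = log OR per effect allele) with a
#'   `skipped` attribute tabulating skip reasons.
#' @export
run_resilience_gwas <- function(study, cohort,
                                covariates = default_covariates(study$samples)) {
  stopifnot(inherits(study, "genotype_study"),
            inherits(cohort, "stratified_cohort"))
  if (cohort$dropped) stopf("cohort for study %s was dropped (%s)",
                            cohort$study_id, cohort$reason)
  ids <- c(cohort$resilient_ids, cohort$risk_matched_case_ids)
  rows <- match(ids, study$samples$sample_id)
  if (anyNA(rows)) stopf("cohort sample IDs missing from study %s", study$study_id)
  if (length(cohort$resilient_ids) < 2 || length(cohort$risk_matched_case_ids) < 2)
    stopf("need at least 2 samples per group")
  y <- as.numeric(ids %in% cohort$resilient_ids)
  C <- covariate_design(study$samples[rows, , drop = FALSE], covariates)
  G <- study$dosages[rows, , drop = FALSE]
  fit <- irls_gwas(C, G, y)
  status <- fit$status
  ok <- status == 0
  skipped <- table(factor(c("monomorphic", "not_converged", "separation",
                            "singular")[status[!ok]], levels =
                          c("monomorphic", "not_converged", "separation",
                            "singular")))
  if (any(!ok))
    pr_log("resilience GWAS %s: skipped %d variants (%s)", study$study_id,
           sum(!ok), paste(names(skipped)[skipped > 0], skipped[skipped > 0],
                           sep = "=", collapse = ", "))
  v <- study$variants[ok, , drop = FALSE]
  z <- fit$beta[ok] / fit$se[ok]
  out <- summary_stats(data.frame(
    snp_id = v$snp_id, chr = v$chr, pos = v$pos,
    effect_allele = v$effect_allele, other_allele = v$other_allele,
    beta = fit$beta[ok], se = fit$se[ok], p = p_from_z(z),
    n_studies = 1L, stringsAsFactors = FALSE))
  attr(out, "skipped") <- skipped
  attr(out, "n") <- length(y)
  out
}

#' Evaluate a resilience score against group membership
#'
#' Logistic regression of resilient-group inclusion on the within-subset
#' standardized score plus covariates. The reported effect is the log odds
#' ratio per score SD; OR > 1 means higher scores favour membership in the
#' resilient (high-risk unaffected) group. The covariate-only model is also
#' fitted, serving as the null for [nagelkerke_r2()] so the pseudo-R2
#' isolates the score's increment.
#'
#' @param study A [genotype_study()].
#' @param cohort A `stratified_cohort`.
#' @param scores Per-sample scores: a `prs_result` or a numeric vector named
#'   by sample ID.
#' @param covariates Sample-table columns, as in [run_resilience_gwas()].
#' @return A `logistic_fit` list: `lnor`, `se`, `z`, `p`, `ll_full`,
#'   `ll_null`, `n`, `n_resilient`, `coefficients`.
#' @export
evaluate_score <- function(study, cohort, scores,
                           covariates = default_covariates(study$samples)) {
  if (inherits(scores, "prs_result"))
    scores <- setNames(scores$raw_score, scores$sample_id)
  ids <- c(cohort$resilient_ids, cohort$risk_matched_case_ids)
  sc <- scores[ids]
  if (anyNA(sc)) stopf("scores missing for %d cohort samples", sum(is.na(sc)))
  if (sd(sc) == 0) stopf("zero score variance in study %s", cohort$study_id)
  sc <- (sc - mean(sc)) / sd(sc)
  rows <- match(ids, study$samples$sample_id)
  y <- as.numeric(ids %in% cohort$resilient_ids)
  C <- covariate_design(study$samples[rows, , drop = FALSE], covariates)
  df <- data.frame(y = y, score = as.numeric(sc),
                   C[, -1, drop = FALSE], check.names = TRUE)
  full <- glm(y ~ ., data = df, family = binomial())
  null <- glm(y ~ . - score, data = df, family = binomial())
  cf <- summary(full)$coefficients
  structure(list(
    lnor = unname(cf["score", "Estimate"]),
    se = unname(cf["score", "Std. Error"]),
    z = unname(cf["score", "z value"]),
    p = unname(cf["score", "Pr(>|z|)"]),
    ll_full = as.numeric(logLik(full)),
    ll_null = as.numeric(logLik(null)),
    n = length(y), n_resilient = sum(y),
    coefficients = cf
  ), class = "logistic_fit")
}

#' Nagelkerke pseudo-R2 of the score increment
#'
#' `R2 = [1 - exp(2 (LL0 - LL1) / n)] / [1 - exp(2 LL0 / n)]`, where the
#' null model LL0 is the covariate-only fit (not intercept-only), so the
#' statistic measures variance attributable to the score.
#'
#' @param fit A `logistic_fit` from [evaluate_score()], or a list with
#'   `ll_full`, `ll_null` and `n`.
#' @return The pseudo-R2 in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit) {
  if (is.null(fit$n) || fit$n == 0) stopf("nagelkerke_r2 undefined for n = 0")
  cox_snell <- 1 - exp(2 * (fit$ll_null - fit$ll_full) / fit$n)
  max_r2 <- 1 - exp(2 * fit$ll_null / fit$n)
  r2 <- cox_snell / max_r2
  min(max(r2, 0), 1)
}

#' Convert observed-scale R2 to the liability scale
#'
#' Threshold-model conversion: with *K* the population prevalence of the
#' trait, *P* the sample case proportion, *t* the liability threshold
#' `qnorm(1 - K)` and *z* the normal density at *t*,
#' `R2_liab = R2_obs * K(1-K)/z^2 * K(1-K)/(P(1-P))` when correcting for
#' case-control ascertainment (the default), and
#' `R2_liab = R2_obs * K(1-K)/z^2` without the correction.
#'
#' @param obs_r2 Observed-scale (e.g. Nagelkerke) R2.
#' @param K Population prevalence, in (0,1).
#' @param P Sample case proportion, in (0,1).
#' @param ascertained Apply the ascertainment correction term.
#' @return Liability-scale R2, clamped to \[0, 1\].
#' @export
liability_scale_r2 <- function(obs_r2, K, P = K, ascertained = TRUE) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) stopf("K and P must be in (0,1)")
  t <- qnorm(1 - K)
  z <- dnorm(t)
  C <- K * (1 - K) / z^2
  if (ascertained) C <- C * K * (1 - K) / (P * (1 - P))
  min(max(obs_r2 * C, 0), 1)
}
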