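#' Default P-value threshold series for resilience scoring
#'
#' Ten increasing thresholds (5e-8 to 0.5); successive weight sets are
#' nested, so per-threshold results are correlated rather than independent.
#'
#' @return Numeric vector of 10 thresholds.
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5)
}

#' Build resilience-score weight sets across P-value thresholds
#'
#' For each threshold *t*, the weight set holds every marginal variant with
#' meta-analysis `P < t`, weighted by its pooled lnOR toward the effect
#' allele. Empty sets are allowed (and logged); an entirely empty series is
#' fatal.
#'
#' @param marginal [summary_stats()] of the pruned and clumped resilience
#'   meta-GWAS (must already satisfy the risk-orthogonality certificate).
#' @param thresholds Strictly increasing thresholds; see
#'   [default_thresholds()].
#' @return A `threshold_series`: list with `thresholds`, per-threshold
#'   `weights` ([score_weights()]), and `results` (`NULL` until filled by
#'   [score_and_evaluate()]).
#' @export
build_resilience_weights <- function(marginal, thresholds = default_thresholds()) {
  stopifnot(inherits(marginal, "summary_stats"))
  if (any(diff(thresholds) <= 0)) stopf("thresholds must be strictly increasing")
  weights <- lapply(thresholds, function(t) {
    keep <- marginal$p < t
    score_weights(data.frame(snp_id = marginal$snp_id[keep],
                             effect_allele = marginal$effect_allele[keep],
                             weight = marginal$beta[keep],
                             stringsAsFactors = FALSE),
                  p_threshold = t, provenance = "resilience")
  })
  n_per <- vapply(weights, nrow, integer(1))
  if (all(n_per == 0)) stopf("every threshold yields an empty weight set")
  if (any(n_per == 0))
    pr_log("build_resilience_weights: empty sets at thresholds %s",
           paste(thresholds[n_per == 0], collapse = ", "))
  structure(list(thresholds = thresholds, weights = weights, results = NULL),
            class = "threshold_series")
}

#' Score replication cohorts and evaluate each threshold
#'
#' Per threshold: computes resilience scores in every replication study,
#' standardizes within study, regresses resilient-group inclusion on the
#' score plus covariates ([evaluate_score()]), meta-analyzes the per-study
#' lnORs with DerSimonian-Laird random effects, converts each study's
#' Nagelkerke pseudo-R2 to the liability scale, and pools R2 with the
#' random-effects meta weights. Studies with zero overlapping variants or
#' zero score variance at a threshold are excluded from that threshold's
#' meta-analysis with a log line.
#'
#' @param studies List of replication [genotype_study()] objects (disjoint
#'   from discovery).
#' @param cohorts List of `stratified_cohort` objects aligned with `studies`
#'   (same design as the weights' derivation).
#' @param series A `threshold_series` from [build_resilience_weights()].
#' @param covariates Covariate columns, as in [evaluate_score()].
#' @param K Assumed population prevalence of resilience for the liability
#'   conversion; defaults to the pooled proportion of resilient individuals
#'   among all high-risk samples in `cohorts`.
#' @return The series with `results`: a data frame of per-threshold n_snps,
#'   OR, 95% CI, P, tau2 and pooled observed/liability R2.
#' @export
score_and_evaluate <- function(studies, cohorts, series, covariates = NULL,
                               K = NULL) {
  stopifnot(inherits(series, "threshold_series"),
            length(studies) == length(cohorts))
  live <- !vapply(cohorts, `[[`, logical(1), "dropped")
  studies <- studies[live]
  cohorts <- cohorts[live]
  if (!length(studies)) stopf("no usable replication cohorts")
  n_res <- sum(vapply(cohorts, function(ch) length(ch$resilient_ids), integer(1)))
  n_tot <- n_res + sum(vapply(cohorts, function(ch)
    length(ch$risk_matched_case_ids), integer(1)))
  if (is.null(K)) K <- n_res / n_tot
  rows <- vector("list", length(series$thresholds))
  for (ti in seq_along(series$thresholds)) {
    t <- series$thresholds[ti]
    w <- series$weights[[ti]]
    lnor <- se <- r2o <- r2l <- numeric(0)
    for (si in seq_along(studies)) {
      study <- studies[[si]]
      ch <- cohorts[[si]]
      if (nrow(w) == 0 ||
          !any(w$snp_id %in% study$variants$snp_id)) {
        pr_log("threshold %g: study %s has no overlapping variants; excluded",
               t, study$study_id)
        next
      }
      prs <- compute_prs(study, w)
      fit <- tryCatch(
        evaluate_score(study, ch, prs,
                       covariates = covariates %||%
                         default_covariates(study$samples)),
        error = function(e) {
          pr_log("threshold %g: study %s excluded (%s)", t, study$study_id,
                 conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      lnor <- c(lnor, fit$lnor)
      se <- c(se, fit$se)
      obs <- nagelkerke_r2(fit)
      r2o <- c(r2o, obs)
      r2l <- c(r2l, liability_scale_r2(obs, K, P = fit$n_resilient / fit$n))
    }
    if (!length(lnor)) {
      rows[[ti]] <- data.frame(threshold = t, n_snps = nrow(w), n_studies = 0L,
                               lnor = NA, se = NA, or = NA, ci_lower = NA,
                               ci_upper = NA, p = NA, tau2 = NA,
                               r2_obs_pooled = NA, r2_liab_pooled = NA)
      next
    }
    mr <- meta_random(lnor, se)
    rows[[ti]] <- data.frame(
      threshold = t, n_snps = nrow(w), n_studies = length(lnor),
      lnor = mr$effect, se = mr$se, or = exp(mr$effect),
      ci_lower = exp(mr$ci_lower), ci_upper = exp(mr$ci_upper), p = mr$p,
      tau2 = mr$tau2,
      r2_obs_pooled = pool_r2(r2o, mr$per_study$weight),
      r2_liab_pooled = pool_r2(r2l, mr$per_study$weight))
  }
  series$results <- do.call(rbind, rows)
  series$K <- K
  series
}

#' Correlation of risk and resilience scores in controls vs cases
#'
#' Pearson correlation between the PRS and the standardized resilience score
#' within controls and within cases (Fisher-z confidence intervals,
#' two-sided P), plus a one-tailed comparison of the two independent
#' correlations: `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` testing whether
#' the control-group correlation exceeds the case-group one. With
#' `trim = TRUE`, ultra-high-risk cases (PRS above the maximum control PRS)
#' and ultra-low-risk controls (PRS below the minimum case PRS) are excluded
#' first.
#'
#' @param samples Data frame with `sample_id`, `status` (`case`/`control`),
#'   `prs` and `res_score`, pooled across the stated studies.
#' @param trim Apply the ultra-outlier exclusion.
#' @return A `correlation_contrast` list: per-group `r`, `ci`, `p`, `n`;
#'   `z` and `p_one_tailed` for the contrast; exclusion counts.
#' @export
correlate_risk_resilience <- function(samples, trim = TRUE) {
  need <- c("sample_id", "status", "prs", "res_score")
  if (!all(need %in% names(samples))) stopf("samples lack columns: %s",
    paste(setdiff(need, names(samples)), collapse = ", "))
  n_excluded <- c(cases = 0L, controls = 0L)
  if (trim) {
    ctrl_max <- max(samples$prs[samples$status == "control"])
    case_min <- min(samples$prs[samples$status == "case"])
    drop_case <- samples$status == "case" & samples$prs > ctrl_max
    drop_ctrl <- samples$status == "control" & samples$prs < case_min
    n_excluded <- c(cases = sum(drop_case), controls = sum(drop_ctrl))
    pr_log("correlate_risk_resilience: excluded %d ultra-high-risk cases, %d ultra-low-risk controls",
           n_excluded[1], n_excluded[2])
    samples <- samples[!drop_case & !drop_ctrl, , drop = FALSE]
  }
  grp <- function(st) {
    s <- samples[samples$status == st, , drop = FALSE]
    if (nrow(s) < 4) stopf("fewer than 4 %ss after trimming", st)
    ct <- cor.test(s$prs, s$res_score)
    list(r = unname(ct$estimate), ci = unname(ct$conf.int), p = ct$p.value,
         n = nrow(s))
  }
  ctrl <- grp("control")
  case <- grp("case")
  z <- (atanh(ctrl$r) - atanh(case$r)) /
    sqrt(1 / (ctrl$n - 3) + 1 / (case$n - 3))
  structure(list(controls = ctrl, cases = case, z = z,
                 p_one_tailed = pnorm(z, lower.tail = FALSE),
                 n_excluded = n_excluded, trimmed = trim),
            class = "correlation_contrast")
}

#' @export
print.correlation_contrast <- function(x, ...) {
  cat(sprintf("<correlation contrast: controls r=%.3f [%.3f, %.3f] (n=%d, p=%.3g); cases r=%.3f [%.3f, %.3f] (n=%d, p=%.3g); one-tailed p=%.3g>\n",
              x$controls$r, x$controls$ci[1], x$controls$ci[2], x$controls$n,
              x$controls$p, x$cases$r, x$cases$ci[1], x$cases$ci[2],
              x$cases$n, x$cases$p, x$p_one_tailed))
  invisible(x)
}

#' APOE flanking region excised from design-2 scores
#'
#' @return Region list for chr19:44,400,000-46,500,000.
#' @export
apoe_region <- function() parse_region("chr19:44400000-46500000")

#' Run the whole resilience-score workflow on simulated cohorts
#'
#' End-to-end driver: simulate multi-study cohorts -> emulate the prior risk
#' GWAS -> risk PRS -> age filter and per-study stratification (design 1 or
#' 2) -> per-study resilience GWAS on the discovery studies -> random-effects
#' meta-analysis with genomic control -> risk-variant exclusion -> LD
#' clumping -> threshold weight sets -> scoring/evaluation on the held-out
#' replication studies -> PRS-vs-resilience-score correlation contrast. The
#' risk-orthogonality certificate is asserted on every run. With a fixed
#' seed the full report is deterministic.
#'
#' @param config A [sim_config()].
#' @param design 1 or 2.
#' @param n_replication Number of trailing studies held out for replication
#'   (must leave at least one discovery study).
#' @param thresholds Resilience-score thresholds.
#' @param control_percentile Selection percentile; defaults to 90 (design 1)
#'   or 80 (design 2).
#' @param risk_p_threshold,r2_max,window_bp Risk-exclusion / clumping
#'   parameters.
#' @param n_effective Effective sample size of the emulated prior risk GWAS.
#' @param corr_threshold Threshold whose score feeds the correlation
#'   contrast (default 0.1).
#' @param min_age Age filter in years.
#' @param covariates Covariate columns for both GWAS and evaluation.
#' @return A `resilience_report` list: `accounting` (all studies),
#'   `series$results` (per-threshold OR/R2 table), `correlation`,
#'   `gwas_lambda`, marginal-variant counts, the truth set and the cohort
#'   objects.
#' @export
run_pipeline <- function(config, design = 1, n_replication = 2,
                         thresholds = default_thresholds(),
                         control_percentile = if (design == 1) 90 else 80,
                         risk_p_threshold = 0.5, r2_max = 0.2,
                         window_bp = 1e6, n_effective = 50000,
                         corr_threshold = 0.1, min_age = 60,
                         covariates = NULL) {
  stopifnot(inherits(config, "sim_config"), design %in% c(1, 2))
  if (n_replication >= config$n_studies || n_replication < 1)
    stopf("need 1 <= n_replication < n_studies")

  sim <- simulate_cohorts(config)
  studies <- lapply(sim$studies, filter_age, min_age = min_age)
  disc_idx <- seq_len(config$n_studies - n_replication)
  repl_idx <- setdiff(seq_len(config$n_studies), disc_idx)

  panel_ref <- simulate_reference_panel(config)
  set.seed(derive_seed(config$seed, 4L))
  risk_gwas <- make_prior_risk_gwas(panel_ref, sim$truth, n_effective)

  region <- if (design == 2) apoe_region() else NULL
  risk_w <- build_risk_weights(risk_gwas, p_threshold = 0.5,
                               excluded_region = region)
  major_id <- sim$truth$major_locus_id

  cohorts <- lapply(studies, function(st) {
    prs <- compute_prs(st, risk_w)
    if (design == 1) {
      select_design1(st, prs, control_percentile)
    } else {
      select_design2(st, prs, carrier_flags(st, major_id), control_percentile)
    }
  })
  live <- !vapply(cohorts, `[[`, logical(1), "dropped")
  if (!any(live[disc_idx])) stopf("every discovery study was dropped")
  if (!any(live[repl_idx])) stopf("every replication study was dropped")

  per_study_gwas <- lapply(which(live)[which(live) %in% disc_idx], function(i)
    run_resilience_gwas(studies[[i]], cohorts[[i]],
                        covariates = covariates %||%
                          default_covariates(studies[[i]]$samples)))
  res_meta <- meta_gwas(per_study_gwas, gc = TRUE)

  panel <- ld_panel(bind_studies(studies[intersect(disc_idx, which(live))]),
                    window_bp = window_bp)
  marginal <- exclude_risk_variants(res_meta, risk_gwas, panel,
                                    risk_p = risk_p_threshold,
                                    r2_max = r2_max, window_bp = window_bp)
  marginal <- clump(marginal, panel, r2_max = r2_max, window_bp = window_bp)
  check_risk_orthogonality(marginal, risk_gwas, panel,
                           risk_p = risk_p_threshold, r2_max = r2_max,
                           window_bp = window_bp)

  series <- build_resilience_weights(marginal, thresholds)
  series <- score_and_evaluate(studies[repl_idx], cohorts[repl_idx], series,
                               covariates = covariates)

  # correlation contrast on the pooled replication samples
  ct <- which.min(abs(thresholds - corr_threshold))
  corr <- NULL
  wct <- series$weights[[ct]]
  if (nrow(wct) > 0) {
    pooled <- do.call(rbind, lapply(repl_idx, function(i) {
      st <- studies[[i]]
      rs <- compute_prs(st, wct)$raw_score
      data.frame(sample_id = st$samples$sample_id, status = st$samples$status,
                 prs = compute_prs(st, risk_w)$raw_score, res_score = rs,
                 stringsAsFactors = FALSE)
    }))
    pooled$res_score <- (pooled$res_score - mean(pooled$res_score)) /
      sd(pooled$res_score)
    corr <- tryCatch(correlate_risk_resilience(pooled, trim = TRUE),
                     error = function(e) {
                       pr_log("correlation contrast unavailable: %s",
                              conditionMessage(e))
                       NULL
                     })
  }

  structure(list(
    config = config, design = design,
    discovery_studies = vapply(sim$studies[disc_idx], `[[`, "", "study_id"),
    replication_studies = vapply(sim$studies[repl_idx], `[[`, "", "study_id"),
    accounting = accounting_table(cohorts[live]),
    gwas_lambda = attr(res_meta, "lambda"),
    n_meta_variants = nrow(res_meta),
    n_marginal = nrow(marginal),
    marginal = marginal, risk_gwas = risk_gwas,
    series = series, correlation = corr,
    cohorts = cohorts, truth = sim$truth
  ), class = "resilience_report")
}

#' @export
print.resilience_report <- function(x, ...) {
  cat(sprintf("<resilience_report design %d: %d discovery + %d replication studies>\n",
              x$design, length(x$discovery_studies), length(x$replication_studies)))
  cat("\nSample accounting:\n")
  print(x$accounting)
  cat(sprintf("\n%d meta-analyzed variants -> %d marginal after risk exclusion + clumping\n",
              x$n_meta_variants, x$n_marginal))
  cat("\nPer-threshold evaluation (replication meta-analysis):\n")
  print(x$series$results, digits = 3)
  if (!is.null(x$correlation)) { cat("\n"); print(x$correlation) }
  invisible(x)
}
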