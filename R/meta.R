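CHI2_MEDIAN <- 0.4549364  # median of a 1-df chi-square

#' Genomic-control correction
#'
#' `lambda = median(z^2) / 0.4549`; when `lambda > 1`, standard errors are
#' inflated by `sqrt(lambda)` and P-values recomputed from the adjusted Wald
#' statistic; `lambda <= 1` leaves the statistics unchanged.
#'
#' @param stats A [summary_stats()] table.
#' @return The corrected table with attribute `lambda`.
#' @export
genomic_control <- function(stats) {
  stopifnot(inherits(stats, "summary_stats"), nrow(stats) >= 1)
  z2 <- (stats$beta / stats$se)^2
  lambda <- median(z2) / CHI2_MEDIAN
  if (lambda > 1) {
    stats$se <- stats$se * sqrt(lambda)
    z <- stats$beta / stats$se
    stats$p <- p_from_z(z)
  }
  attr(stats, "lambda") <- lambda
  stats
}

new_meta_result <- function(method, effect, se, tau2, Q, k, effects, ses,
                            weights) {
  df <- k - 1L
  i2 <- if (k > 1 && Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(
    method = method, effect = effect, se = se,
    ci_lower = effect - 1.96 * se, ci_upper = effect + 1.96 * se,
    p = p_from_z(effect / se),
    tau2 = tau2, Q = Q, df = df, i2 = i2, k = k,
    per_study = data.frame(effect = effects, se = ses, weight = weights)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<%s-effects meta: k=%d, effect=%.4f [%.4f, %.4f], p=%.3g, tau2=%.4g, I2=%.1f%%>\n",
              x$method, x$k, x$effect, x$ci_lower, x$ci_upper, x$p, x$tau2, x$i2))
  invisible(x)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights `1/se^2`; pooled effect `sum(w e)/sum(w)`, `SE = 1/sqrt(sum w)`,
#' heterogeneity `Q = sum w (e - pooled)^2`.
#'
#' @param effects,ses Numeric vectors of per-study effects (log scale) and
#'   positive standard errors.
#' @return A `meta_result`.
#' @export
meta_fixed <- function(effects, ses) {
  if (!length(effects)) stopf("empty meta-analysis input")
  if (length(effects) != length(ses) || any(ses <= 0))
    stopf("effects/ses must have equal length and positive ses")
  w <- 1 / ses^2
  pooled <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - pooled)^2)
  new_meta_result("fixed", pooled, 1 / sqrt(sum(w)), 0, Q,
                  length(effects), effects, ses, w)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))` from the
#' fixed-effect Q, then inverse-variance pooling with weights
#' `1/(se^2 + tau2)`. With one study the input is returned unchanged
#' (tau2 = 0, logged). Homogeneous inputs (`Q <= k-1`) reduce exactly to
#' [meta_fixed()].
#'
#' @inheritParams meta_fixed
#' @return A `meta_result`.
#' @export
meta_random <- function(effects, ses) {
  fx <- meta_fixed(effects, ses)
  k <- fx$k
  if (k == 1) {
    pr_log("meta_random: single study; returning it unchanged (tau2 = 0)")
    out <- new_meta_result("random", effects[1], ses[1], 0, 0, 1L,
                           effects, ses, 1 / ses^2)
    return(out)
  }
  w <- 1 / ses^2
  tau2 <- max(0, (fx$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  pooled <- sum(ws * effects) / sum(ws)
  new_meta_result("random", pooled, 1 / sqrt(sum(ws)), tau2, fx$Q, k,
                  effects, ses, ws)
}

#' Per-variant meta-analysis across studies
#'
#' Applies genomic control per input study (optional), harmonizes every
#' variant to the allele orientation of the first study carrying it (flipping
#' beta when effect/other alleles are swapped; irreconcilable allele pairs
#' are dropped with a logged count), then combines each variant across
#' studies with DerSimonian-Laird random effects. Variants present in a
#' single study pass through with their (GC-adjusted) statistics. A union
#' policy is used: variants are analyzed if present in at least `min_studies`
#' studies.
#'
#' @param per_study_stats List of [summary_stats()] tables.
#' @param gc Apply [genomic_control()] per study first.
#' @param min_studies Minimum number of studies carrying a variant.
#' @return A [summary_stats()] table with `n_studies` and `direction` (one
#'   `+`/`-`/`?` per input study) columns; per-study lambdas in attribute
#'   `lambda`.
#' @export
meta_gwas <- function(per_study_stats, gc = TRUE, min_studies = 1L) {
  stopifnot(length(per_study_stats) >= 1)
  lambdas <- rep(NA_real_, length(per_study_stats))
  if (gc) {
    per_study_stats <- lapply(per_study_stats, genomic_control)
    lambdas <- vapply(per_study_stats, attr, numeric(1), "lambda")
    pr_log("meta_gwas: per-study lambda = %s",
           paste(sprintf("%.3f", lambdas), collapse = ", "))
  }
  k <- length(per_study_stats)
  all_ids <- unique(unlist(lapply(per_study_stats, `[[`, "snp_id")))
  ref <- NULL  # first-seen orientation per variant
  for (st in per_study_stats) {
    new <- if (is.null(ref)) st else st[!(st$snp_id %in% ref$snp_id), , drop = FALSE]
    ref <- rbind(ref, new[c("snp_id", "chr", "pos", "effect_allele", "other_allele")])
  }
  ref <- ref[match(all_ids, ref$snp_id), , drop = FALSE]
  E <- SE <- matrix(NA_real_, length(all_ids), k)
  dropped <- 0L
  for (s in seq_len(k)) {
    st <- per_study_stats[[s]]
    i <- match(st$snp_id, all_ids)
    same <- st$effect_allele == ref$effect_allele[i] &
            st$other_allele == ref$other_allele[i]
    flip <- st$effect_allele == ref$other_allele[i] &
            st$other_allele == ref$effect_allele[i]
    bad <- !(same | flip)
    dropped <- dropped + sum(bad)
    E[i[same], s] <- st$beta[same]
    E[i[flip], s] <- -st$beta[flip]
    SE[i[same], s] <- st$se[same]
    SE[i[flip], s] <- st$se[flip]
  }
  if (dropped > 0)
    pr_log("meta_gwas: dropped %d study-records with irreconcilable alleles",
           dropped)
  n_st <- rowSums(!is.na(E))
  keep <- n_st >= min_studies & n_st >= 1
  # vectorized DerSimonian-Laird across variants
  W <- 1 / SE^2
  W1 <- rowSums(W, na.rm = TRUE)
  pooled_f <- rowSums(W * E, na.rm = TRUE) / W1
  Q <- rowSums(W * (E - pooled_f)^2, na.rm = TRUE)
  W2 <- rowSums(W^2, na.rm = TRUE)
  tau2 <- pmax(0, (Q - (n_st - 1)) / (W1 - W2 / W1))
  tau2[n_st <= 1] <- 0
  WS <- 1 / sweep(SE^2, 1, tau2, `+`)
  pooled <- rowSums(WS * E, na.rm = TRUE) / rowSums(WS, na.rm = TRUE)
  se <- 1 / sqrt(rowSums(WS, na.rm = TRUE))
  direction <- apply(E, 1, function(e)
    paste(ifelse(is.na(e), "?", ifelse(e >= 0, "+", "-")), collapse = ""))
  out <- summary_stats(data.frame(
    snp_id = all_ids, chr = ref$chr, pos = ref$pos,
    effect_allele = ref$effect_allele, other_allele = ref$other_allele,
    beta = pooled, se = se, p = p_from_z(pooled / se),
    n_studies = n_st, direction = direction,
    stringsAsFactors = FALSE)[keep, , drop = FALSE])
  attr(out, "lambda") <- lambdas
  out
}

#' Pool per-study variance explained
#'
#' Weighted mean of per-study R2 values using the weights from the
#' (random-effects) meta-analysis of the corresponding lnORs.
#'
#' @param r2_values Per-study R2 values, aligned with `meta_weights`.
#' @param meta_weights Meta-analysis weights (e.g. `meta$per_study$weight`).
#' @return The pooled R2.
#' @export
pool_r2 <- function(r2_values, meta_weights) {
  if (length(r2_values) != length(meta_weights))
    stopf("r2_values and meta_weights must align")
  if (!length(r2_values)) return(NA_real_)
  sum(meta_weights * r2_values) / sum(meta_weights)
}
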