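#' Linkage-disequilibrium reference panel
#'
#' Caches column-standardized dosages so pairwise r-squared (squared Pearson
#' correlation of dosage vectors) reduces to an inner product. Pairs farther
#' apart than `window_bp` (same-chromosome distance, inclusive) are treated
#' as r2 = 0 by the pruning/clumping routines. Zero-variance variants are
#' flagged and excluded from LD computations with a log line.
#'
#' @param study A [genotype_study()] (for simulated runs, typically the
#'   row-bound union of the discovery studies; see [bind_studies()]).
#' @param window_bp Distance bound in base pairs (default 1 Mb).
#' @return An `ld_panel`.
#' @export
ld_panel <- function(study, window_bp = 1e6) {
  stopifnot(inherits(study, "genotype_study"))
  d <- study$dosages
  n <- nrow(d)
  mu <- colMeans(d)
  sdv <- sqrt(colMeans(d^2) - mu^2)
  zero <- sdv <= 0
  if (any(zero))
    pr_log("ld_panel: %d zero-variance variants excluded from LD", sum(zero))
  Z <- sweep(d, 2, mu)
  Z <- sweep(Z, 2, ifelse(zero, 1, sdv * sqrt(n)), `/`)
  Z[, zero] <- NA_real_
  structure(list(Z = Z, variants = study$variants, n = n,
                 zero_variance = zero, window_bp = window_bp),
            class = "ld_panel")
}

#' Row-bind several studies sharing a variant map
#'
#' @param studies List of [genotype_study()] objects with identical variant
#'   tables.
#' @param study_id Label for the combined study.
#' @return A [genotype_study()].
#' @export
bind_studies <- function(studies, study_id = "POOLED") {
  stopifnot(length(studies) >= 1)
  v <- studies[[1]]$variants
  for (s in studies[-1]) {
    if (!identical(s$variants$snp_id, v$snp_id))
      stopf("studies have differing variant maps")
  }
  genotype_study(study_id, v,
                 do.call(rbind, lapply(studies, `[[`, "dosages")),
                 do.call(rbind, lapply(studies, `[[`, "samples")))
}

#' Pairwise dosage r-squared
#'
#' Composite (genotypic) r2: the squared Pearson correlation of the two
#' dosage columns in the reference panel.
#'
#' @param panel An [ld_panel()].
#' @param v1,v2 Variant IDs.
#' @return r2 in \[0, 1\], or `NA` if either variant has zero variance.
#' @export
ld_r2 <- function(panel, v1, v2) {
  i <- match(c(v1, v2), panel$variants$snp_id)
  if (anyNA(i)) stopf("variant not in LD panel")
  if (any(panel$zero_variance[i])) {
    pr_log("ld_r2: zero-variance variant; r2 undefined")
    return(NA_real_)
  }
  r <- sum(panel$Z[, i[1]] * panel$Z[, i[2]])
  min(r^2, 1)
}

# r2 of one standardized column against a set of columns
r2_vec <- function(panel, j, js) {
  r <- drop(crossprod(panel$Z[, j], panel$Z[, js, drop = FALSE]))
  pmin(r^2, 1)
}

#' Exclude risk-associated variants and their LD partners
#'
#' Risk-orthogonality filter: removes from `candidates` (a) every variant
#' whose risk-GWAS association has `P < risk_p`, and (b) every remaining
#' variant with `r2 >= r2_max` to any rule-(a) risk variant within
#' `window_bp` on the same chromosome. Candidates absent from the risk GWAS
#' are retained by rule (a) with a separate logged count but remain subject
#' to rule (b).
#'
#' @param candidates [summary_stats()] of resilience associations.
#' @param risk [summary_stats()] of the prior risk GWAS.
#' @param panel An [ld_panel()] covering the variants.
#' @param risk_p Risk P-value bound (default 0.5).
#' @param r2_max LD bound (default 0.2).
#' @param window_bp Window in bp (default 1 Mb, inclusive).
#' @return Surviving [summary_stats()] with counts in attribute `exclusion`;
#'   an empty survivor set is fatal.
#' @export
exclude_risk_variants <- function(candidates, risk, panel, risk_p = 0.5,
                                  r2_max = 0.2, window_bp = 1e6) {
  stopifnot(inherits(candidates, "summary_stats"),
            inherits(risk, "summary_stats"), inherits(panel, "ld_panel"))
  risk_p_of <- risk$p[match(candidates$snp_id, risk$snp_id)]
  unknown <- is.na(risk_p_of)
  if (any(unknown))
    pr_log("exclude_risk_variants: %d candidates missing from the risk GWAS; retained by rule (a)",
           sum(unknown))
  rule_a <- !unknown & risk_p_of < risk_p
  surv <- candidates[!rule_a, , drop = FALSE]

  # rule (b): LD to any risk-associated variant (P < risk_p) in the window
  riskset <- risk[risk$p < risk_p, , drop = FALSE]
  pv <- panel$variants
  risk_in_panel <- riskset[riskset$snp_id %in%
                             pv$snp_id[!panel$zero_variance], , drop = FALSE]
  removed_b <- logical(nrow(surv))
  cand_j <- match(surv$snp_id, pv$snp_id)
  for (cc in unique(surv$chr)) {
    rsub <- risk_in_panel[risk_in_panel$chr == cc, , drop = FALSE]
    if (!nrow(rsub)) next
    ord <- order(rsub$pos)
    rpos <- rsub$pos[ord]
    rj <- match(rsub$snp_id[ord], pv$snp_id)
    ci <- which(surv$chr == cc)
    for (i in ci) {
      j <- cand_j[i]
      if (is.na(j) || panel$zero_variance[j]) next
      lo <- findInterval(surv$pos[i] - window_bp, rpos) + 1L
      hi <- findInterval(surv$pos[i] + window_bp, rpos)
      if (lo > hi) next
      jw <- setdiff(rj[lo:hi], j)
      if (!length(jw)) next
      if (any(r2_vec(panel, j, jw) >= r2_max, na.rm = TRUE)) removed_b[i] <- TRUE
    }
  }
  out <- surv[!removed_b, , drop = FALSE]
  counts <- c(n_input = nrow(candidates), removed_rule_a = sum(rule_a),
              removed_rule_b = sum(removed_b),
              unknown_risk_p = sum(unknown), n_survivors = nrow(out))
  pr_log("exclude_risk_variants: %d in, %d removed by risk P < %g, %d by LD (r2 >= %g within %g kb), %d survive",
         counts[1], counts[2], risk_p, counts[3], r2_max, window_bp / 1e3,
         counts[5])
  if (!nrow(out))
    stopf("no variants survive risk exclusion (of %d candidates: %d removed by rule a, %d by rule b)",
          counts[1], counts[2], counts[3])
  out <- summary_stats(out)
  attr(out, "exclusion") <- counts
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclaimed variant with the smallest P-value as an
#' index SNP and claims every unclaimed variant with `r2 >= r2_max` within
#' `window_bp` of it; the index SNPs form the output. Ties on P are broken
#' by (chromosome, position).
#'
#' @param candidates [summary_stats()] carrying P-values.
#' @param panel An [ld_panel()].
#' @param r2_max,window_bp Clumping thresholds (defaults 0.2 and 1 Mb,
#'   matching the risk-exclusion step).
#' @return [summary_stats()] of index variants, in (chr, pos) order.
#' @export
clump <- function(candidates, panel, r2_max = 0.2, window_bp = 1e6) {
  stopifnot(inherits(candidates, "summary_stats"), inherits(panel, "ld_panel"))
  if (!nrow(candidates)) return(candidates)
  ord <- order(candidates$p, candidates$chr, candidates$pos)
  cand <- candidates[ord, , drop = FALSE]
  pj <- match(cand$snp_id, panel$variants$snp_id)
  claimed <- logical(nrow(cand))
  index <- logical(nrow(cand))
  pos <- cand$pos
  chr <- cand$chr
  for (i in seq_len(nrow(cand))) {
    if (claimed[i]) next
    index[i] <- TRUE
    claimed[i] <- TRUE
    j <- pj[i]
    if (is.na(j) || panel$zero_variance[j]) next
    nb <- which(!claimed & chr == chr[i] & abs(pos - pos[i]) <= window_bp)
    if (!length(nb)) next
    jn <- pj[nb]
    usable <- !is.na(jn) & !panel$zero_variance[jn]
    if (!any(usable)) next
    hit <- nb[usable][r2_vec(panel, j, jn[usable]) >= r2_max]
    claimed[hit] <- TRUE
  }
  out <- cand[index, , drop = FALSE]
  out <- out[order(as.character(out$chr), out$pos), , drop = FALSE]
  pr_log("clump: %d index variants from %d candidates", nrow(out), nrow(cand))
  summary_stats(out)
}

#' Risk-orthogonality certificate
#'
#' Post-hoc hard check that no variant in `survivors` has a risk association
#' `P < risk_p` nor `r2 >= r2_max` within `window_bp` of any such risk
#' variant. Used as an assertion after every pipeline run.
#'
#' @inheritParams exclude_risk_variants
#' @param survivors [summary_stats()] or a [score_weights()] set (checked by
#'   `snp_id`).
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_risk_orthogonality <- function(survivors, risk, panel, risk_p = 0.5,
                                     r2_max = 0.2, window_bp = 1e6) {
  ids <- survivors$snp_id
  rp <- risk$p[match(ids, risk$snp_id)]
  if (any(!is.na(rp) & rp < risk_p))
    stopf("certificate violated: %d scored variants have risk P < %g",
          sum(!is.na(rp) & rp < risk_p), risk_p)
  pv <- panel$variants
  riskset <- risk[risk$p < risk_p & risk$snp_id %in%
                    pv$snp_id[!panel$zero_variance], , drop = FALSE]
  jj <- match(ids, pv$snp_id)
  for (i in seq_along(ids)) {
    j <- jj[i]
    if (is.na(j) || panel$zero_variance[j]) next
    w <- riskset[riskset$chr == pv$chr[j] &
                   abs(riskset$pos - pv$pos[j]) <= window_bp &
                   riskset$snp_id != ids[i], , drop = FALSE]
    if (!nrow(w)) next
    r2 <- r2_vec(panel, j, match(w$snp_id, pv$snp_id))
    if (any(r2 >= r2_max, na.rm = TRUE))
      stopf("certificate violated: %s has r2 = %.3f to risk variant %s",
            ids[i], max(r2, na.rm = TRUE), w$snp_id[which.max(r2)])
  }
  invisible(TRUE)
}
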