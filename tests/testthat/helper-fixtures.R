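# Fixture builders shared across test files. Everything is generated in code.

toy_variants <- function(m, chr = "1", start = 1e6, step = 5e4,
                         effect = "A", other = "G") {
  data.frame(snp_id = sprintf("v%03d", seq_len(m)),
             chr = rep(chr, length.out = m),
             pos = start + (seq_len(m) - 1) * step,
             effect_allele = rep(effect, length.out = m),
             other_allele = rep(other, length.out = m),
             stringsAsFactors = FALSE)
}

toy_samples <- function(n, status = rep(c("case", "control"), length.out = n),
                        n_pcs = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- data.frame(sample_id = sprintf("s%04d", seq_len(n)), status = status,
                  sex = rep(1:2, length.out = n),
                  age = round(runif(n, 60, 90), 1), stringsAsFactors = FALSE)
  if (n_pcs > 0) {
    pcs <- matrix(rnorm(n * n_pcs), n)
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    s <- cbind(s, pcs)
  }
  s
}

toy_study <- function(n = 40, m = 6, seed = 1, maf = NULL, study_id = "TOY",
                      n_pcs = 0, dosages = NULL, variants = NULL,
                      samples = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.2, 0.5)
  if (is.null(dosages))
    dosages <- sapply(maf, function(p) rbinom(n, 2, p))
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = n)
  storage.mode(dosages) <- "double"
  if (is.null(variants)) variants <- toy_variants(ncol(dosages))
  if (is.null(samples)) samples <- toy_samples(nrow(dosages), n_pcs = n_pcs)
  colnames(dosages) <- variants$snp_id
  rownames(dosages) <- samples$sample_id
  genotype_study(study_id, variants, dosages, samples)
}

toy_stats <- function(m = 6, seed = 1, variants = toy_variants(m),
                      beta = NULL, se = NULL, p = NULL) {
  set.seed(seed)
  beta <- beta %||% rnorm(nrow(variants), 0, 0.2)
  se <- se %||% runif(nrow(variants), 0.05, 0.2)
  p <- p %||% (2 * pnorm(-abs(beta / se)))
  summary_stats(cbind(variants,
                      data.frame(beta = beta, se = se, p = p)))
}

toy_cohort <- function(resilient_ids, case_ids, study_id = "TOY",
                       design = 1L) {
  polyresilience:::new_stratified_cohort(
    study_id, design, resilient_ids, case_ids, NA_real_, NA_real_,
    length(resilient_ids), length(case_ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast small config for pipeline-level tests
tiny_config <- function(seed = 1, ...) {
  args <- list(n_studies = 3L, n_cases_per_study = 250L,
               n_controls_per_study = 250L, n_variants = 400L,
               n_risk_snps = 30L, n_resilience_snps = 10L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
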