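#' Simulation configuration for multi-study case-control cohorts
#'
#' Defines the generative world used throughout the test-bench: a
#' liability-threshold disease model with additive common risk variants, one
#' major-effect biallelic locus standing in for *APOE*-e4 (placed at
#' chr19:45,400,000, inside the conventional *APOE* flanking region), and
#' resilience variants whose protective effect operates only in individuals
#' above a genetic-risk quantile.
#'
#' Liability of individual *i* is \eqn{L_i = G_i + \epsilon_i} with
#' \eqn{G_i = \sum_j \beta_j g_{ij} + \beta_M g_{iM}} and
#' \eqn{\epsilon_i \sim N(0,1)}. If \eqn{G_i} exceeds the
#' `risk_quantile_for_resilience` quantile of \eqn{G}, the per-allele
#' resilience reduction \eqn{\gamma} is subtracted as a centered allele load:
#' \eqn{L'_i = L_i - I[G_i > q]\sum_k \gamma (g_{ik} - 2p_k)}. Centering on
#' the expected allele count keeps the per-allele protective effect
#' \eqn{\gamma} while leaving the mean liability of the high-risk stratum
#' (and hence the calibrated prevalence structure) unchanged. Disease iff
#' \eqn{L'_i > T}, with *T* calibrated by Monte Carlo so that the
#' *pre-resilience* affection rate equals `disease_prevalence`.
#'
#' @param n_studies Number of case-control studies.
#' @param n_cases_per_study,n_controls_per_study Per-study sample counts,
#'   achieved by rejection sampling (capped at 1000x the requested total).
#' @param n_variants Total biallelic variants on the 22 autosomes.
#' @param maf_range Range of effect-allele frequencies, within (0, 0.5].
#' @param n_risk_snps Number of additive risk variants.
#' @param risk_beta_sd SD of the normal distribution of risk effects on the
#'   standardized-liability scale.
#' @param major_locus_beta,major_locus_freq Liability-scale effect and allele
#'   frequency of the *APOE*-e4-like locus.
#' @param n_resilience_snps Number of resilience variants (risk-orthogonal:
#'   they carry no risk effect).
#' @param resilience_gamma Per-allele liability reduction among high-risk
#'   individuals. The default (0.21) was calibrated once by simulation so the
#'   per-allele odds ratio contrasting unaffected vs affected individuals in
#'   the high-risk stratum is about 1.3.
#' @param risk_quantile_for_resilience Genetic-risk quantile above which
#'   resilience effects operate.
#' @param disease_prevalence Population prevalence *K* of the pre-resilience
#'   liability model.
#' @param age_range Uniform range for age at onset (cases) / age at last
#'   examination (controls), in years.
#' @param sex_ratio Probability of sex code 2.
#' @param n_pcs Number of principal-component covariates; simulated as pure
#'   standard-normal noise (no population structure), retained to exercise
#'   covariate plumbing.
#' @param ld_block_size Variants per linkage-disequilibrium block (1 =
#'   independent variants).
#' @param ld_block_r Within-block latent haplotype correlation in [0, 1).
#' @param seed Integer seed; identical configurations give byte-identical
#'   simulations.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_studies = 4L,
                       n_cases_per_study = 1000L,
                       n_controls_per_study = 1000L,
                       n_variants = 5000L,
                       maf_range = c(0.05, 0.5),
                       n_risk_snps = 60L,
                       risk_beta_sd = 0.15,
                       major_locus_beta = 1.0,
                       major_locus_freq = 0.2,
                       n_resilience_snps = 20L,
                       resilience_gamma = 0.21,
                       risk_quantile_for_resilience = 0.8,
                       disease_prevalence = 0.15,
                       age_range = c(60, 90),
                       sex_ratio = 0.5,
                       n_pcs = 4L,
                       ld_block_size = 4L,
                       ld_block_r = 0.4,
                       seed = 1L) {
  cfg <- list(
    n_studies = as.integer(n_studies),
    n_cases_per_study = as.integer(n_cases_per_study),
    n_controls_per_study = as.integer(n_controls_per_study),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    n_risk_snps = as.integer(n_risk_snps),
    risk_beta_sd = as.numeric(risk_beta_sd),
    major_locus_beta = as.numeric(major_locus_beta),
    major_locus_freq = as.numeric(major_locus_freq),
    n_resilience_snps = as.integer(n_resilience_snps),
    resilience_gamma = as.numeric(resilience_gamma),
    risk_quantile_for_resilience = as.numeric(risk_quantile_for_resilience),
    disease_prevalence = as.numeric(disease_prevalence),
    age_range = as.numeric(age_range),
    sex_ratio = as.numeric(sex_ratio),
    n_pcs = as.integer(n_pcs),
    ld_block_size = as.integer(ld_block_size),
    ld_block_r = as.numeric(ld_block_r),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_studies < 1 || n_cases_per_study < 1 || n_controls_per_study < 1 ||
        n_variants < 1) stopf("sample/variant counts must be positive")
    if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2]) stopf("maf_range must lie within (0, 0.5]")
    if (disease_prevalence <= 0 || disease_prevalence >= 1)
      stopf("disease_prevalence must be in (0,1)")
    if (risk_quantile_for_resilience <= 0 || risk_quantile_for_resilience >= 1)
      stopf("risk_quantile_for_resilience must be in (0,1)")
    if (major_locus_freq <= 0 || major_locus_freq >= 1)
      stopf("major_locus_freq must be in (0,1)")
    if (n_risk_snps + n_resilience_snps + 1 > n_variants)
      stopf("risk + resilience SNPs + major locus exceed n_variants")
    if (n_risk_snps < 0 || n_resilience_snps < 0 || n_pcs < 0 ||
        risk_beta_sd < 0 || resilience_gamma < 0)
      stopf("negative parameter where a non-negative value is required")
    if (ld_block_size < 1 || ld_block_r < 0 || ld_block_r >= 1)
      stopf("ld_block_size >= 1 and ld_block_r in [0,1) required")
    if (sex_ratio < 0 || sex_ratio > 1) stopf("sex_ratio must be in [0,1]")
  })
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; missing keys take defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

# Deterministic variant map: ids, coordinates, alleles, MAFs and causal roles.
# Non-palindromic allele pairs only, so strand-ambiguity filtering never
# removes simulated variants. The major locus sits at chr19:45,400,000.
variant_map <- function(config) {
  M <- config$n_variants
  set.seed(derive_seed(config$seed, 1L))
  per_chr <- ceiling(M / 22)
  chr <- rep(1:22, each = per_chr)[seq_len(M)]
  idx_in_chr <- unlist(lapply(unname(table(chr))[order(unique(chr))], seq_len),
                       use.names = FALSE)
  pos <- 1e6 + (idx_in_chr - 1) * 5e4
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pk <- sample.int(nrow(pairs), M, replace = TRUE)
  maf <- runif(M, config$maf_range[1], config$maf_range[2])

  # major locus: the chr19 variant closest to 45.4 Mb (or the last variant,
  # relabelled, when the map is too small to reach chr19)
  on19 <- which(chr == 19)
  if (length(on19)) {
    major <- on19[which.min(abs(pos[on19] - 45.4e6))]
  } else {
    major <- M
    chr[major] <- 19L
  }
  pos[major] <- 45.4e6
  maf[major] <- config$major_locus_freq

  role <- rep("null", M)
  role[major] <- "major"
  free <- setdiff(seq_len(M), major)
  risk_idx <- sort(sample(free, config$n_risk_snps))
  res_idx <- sort(sample(setdiff(free, risk_idx), config$n_resilience_snps))
  role[risk_idx] <- "risk"
  role[res_idx] <- "resilience"

  beta <- numeric(M)
  beta[risk_idx] <- rnorm(config$n_risk_snps, 0, config$risk_beta_sd)
  beta[major] <- config$major_locus_beta
  gamma <- numeric(M)
  gamma[res_idx] <- config$resilience_gamma

  # LD blocks: runs of consecutive variants within a chromosome
  block <- integer(M)
  b <- 0L
  for (cc in unique(chr)) {
    ii <- which(chr == cc)
    block[ii] <- b + ((seq_along(ii) - 1L) %/% config$ld_block_size) + 1L
    b <- max(block[ii])
  }

  data.frame(
    snp_id = sprintf("rs%d_%d", chr, pos),
    chr = as.character(chr), pos = pos,
    effect_allele = pairs[pk, 1], other_allele = pairs[pk, 2],
    maf = maf, role = role, beta = beta, gamma = gamma, block = block,
    stringsAsFactors = FALSE
  )
}

# Draw an n x M dosage matrix in Hardy-Weinberg proportions with optional
# block LD (Gaussian-copula haplotypes: within a block, latent normals share
# a common factor with loading sqrt(r)). Sampling is in compiled code on
# R's RNG stream.
draw_dosages <- function(n, map, ld_r) {
  if (nrow(map) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (max(table(map$block)) == 1L) ld_r <- 0
  dos <- draw_dosages_cpp(n, qnorm(map$maf), map$block, ld_r)
  colnames(dos) <- map$snp_id
  dos
}

# Monte-Carlo calibration of the liability threshold and the genetic-risk
# quantile. Only causal-variant genotypes are needed, so this stays cheap.
calibrate_truth <- function(config, map, n_cal = 50000L) {
  set.seed(derive_seed(config$seed, 2L))
  causal <- map$role %in% c("risk", "major")
  blocks_needed <- unique(map$block[causal])
  sub <- map[map$block %in% blocks_needed, , drop = FALSE]
  g <- draw_dosages(n_cal, sub, config$ld_block_r)
  G <- if (nrow(sub)) {
    drop(g %*% ifelse(sub$role %in% c("risk", "major"), sub$beta, 0))
  } else {
    numeric(n_cal)
  }
  eps <- rnorm(n_cal)
  list(
    liability_threshold = unname(quantile(G + eps, 1 - config$disease_prevalence)),
    risk_quantile_value = unname(quantile(G, config$risk_quantile_for_resilience))
  )
}

#' Simulate a reference genotype panel
#'
#' Unrelated genotypes in Hardy-Weinberg proportions at every variant of the
#' configuration's variant map, with the configured block-LD structure; no
#' phenotype model is applied. Used as the allele-frequency / LD reference.
#'
#' @param config A [sim_config()].
#' @param n_samples Panel size.
#' @return A [genotype_study()] with all samples labelled `control`.
#' @export
simulate_reference_panel <- function(config,
                                     n_samples = config$n_cases_per_study +
                                       config$n_controls_per_study) {
  stopifnot(inherits(config, "sim_config"))
  if (n_samples < 1) stopf("n_samples must be positive")
  map <- variant_map(config)
  set.seed(derive_seed(config$seed, 3L))
  dos <- draw_dosages(n_samples, map, config$ld_block_r)
  samples <- data.frame(
    sample_id = sprintf("REF_%05d", seq_len(n_samples)),
    status = "control",
    sex = rbinom(n_samples, 1L, config$sex_ratio) + 1L,
    age = round(runif(n_samples, config$age_range[1], config$age_range[2]), 1),
    stringsAsFactors = FALSE
  )
  rownames(dos) <- samples$sample_id
  genotype_study("REF", map[, c("snp_id", "chr", "pos", "effect_allele",
                                "other_allele")], dos, samples)
}

#' Simulate multi-study case-control cohorts under the resilience model
#'
#' Each study is filled to its requested case/control counts by rejection
#' sampling from the liability-threshold model described in [sim_config()].
#' AAO (cases) and AAE (controls) are uniform on `age_range`; principal
#' components are standard-normal noise covariates.
#'
#' @param config A [sim_config()].
#' @return A list with `studies` (list of [genotype_study()] objects) and
#'   `truth` (variant map with true effects, liability threshold, risk-quantile
#'   cutoff, and per-sample true liability components).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- variant_map(config)
  cal <- calibrate_truth(config, map)
  # rejection sampling only needs causal-block genotypes; genotypes at the
  # remaining (phenotype-independent) blocks are drawn for accepted samples
  # afterwards, which cuts simulation cost severalfold
  causal_blocks <- unique(map$block[map$role != "null"])
  cmap <- map[map$block %in% causal_blocks, , drop = FALSE]
  rmap <- map[!(map$block %in% causal_blocks), , drop = FALSE]
  col_order <- match(map$snp_id, c(cmap$snp_id, rmap$snp_id))
  studies <- vector("list", config$n_studies)
  truth_samples <- vector("list", config$n_studies)
  n_case <- config$n_cases_per_study
  n_ctrl <- config$n_controls_per_study
  cap <- 1000 * (n_case + n_ctrl)

  for (s in seq_len(config$n_studies)) {
    set.seed(derive_seed(config$seed, 100L + s))
    got_case <- got_ctrl <- 0L
    keep_dos <- vector("list", 0L)
    keep_info <- vector("list", 0L)
    drawn <- 0L
    while (got_case < n_case || got_ctrl < n_ctrl) {
      if (drawn >= cap) {
        stopf("study %d: rejection sampling exhausted after %d draws (%d/%d cases, %d/%d controls); prevalence %.3g is infeasible for the requested counts",
              s, drawn, got_case, n_case, got_ctrl, n_ctrl,
              config$disease_prevalence)
      }
      m <- min(4000L, cap - drawn)
      drawn <- drawn + m
      dos <- draw_dosages(m, cmap, config$ld_block_r)
      if (nrow(cmap)) {
        G <- drop(dos %*% cmap$beta)
        # centered load: per-allele effect gamma, zero mean in the population
        resil <- drop(dos %*% cmap$gamma) - sum(cmap$gamma * 2 * cmap$maf)
      } else {
        G <- resil <- numeric(m)
      }
      high <- G > cal$risk_quantile_value
      L <- G + rnorm(m) - ifelse(high, resil, 0)
      affected <- L > cal$liability_threshold
      want <- (affected & got_case + cumsum(affected) <= n_case) |
              (!affected & got_ctrl + cumsum(!affected) <= n_ctrl)
      if (any(want)) {
        keep_dos[[length(keep_dos) + 1L]] <- dos[want, , drop = FALSE]
        keep_info[[length(keep_info) + 1L]] <- data.frame(
          affected = affected[want], g_risk = G[want],
          high_risk = high[want], resilience_load = resil[want])
      }
      got_case <- got_case + sum(affected & want)
      got_ctrl <- got_ctrl + sum(!affected & want)
    }
    info <- do.call(rbind, keep_info)
    n <- nrow(info)
    dos <- cbind(do.call(rbind, keep_dos),
                 draw_dosages(n, rmap, config$ld_block_r))[, col_order,
                                                           drop = FALSE]
    study_id <- sprintf("STUDY%d", s)
    samples <- data.frame(
      sample_id = sprintf("S%d_%05d", s, seq_len(n)),
      status = ifelse(info$affected, "case", "control"),
      sex = rbinom(n, 1L, config$sex_ratio) + 1L,
      age = round(runif(n, config$age_range[1], config$age_range[2]), 1),
      stringsAsFactors = FALSE
    )
    if (config$n_pcs > 0) {
      pcs <- matrix(rnorm(n * config$n_pcs), n)
      colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
      samples <- cbind(samples, pcs)
    }
    rownames(dos) <- samples$sample_id
    studies[[s]] <- genotype_study(
      study_id, map[, c("snp_id", "chr", "pos", "effect_allele", "other_allele")],
      dos, samples)
    truth_samples[[s]] <- cbind(study_id = study_id,
                                sample_id = samples$sample_id, info)
  }

  truth <- structure(list(
    map = map,
    risk_snp_ids = map$snp_id[map$role == "risk"],
    resilience_snp_ids = map$snp_id[map$role == "resilience"],
    major_locus_id = map$snp_id[map$role == "major"],
    liability_threshold = cal$liability_threshold,
    risk_quantile_value = cal$risk_quantile_value,
    samples = do.call(rbind, truth_samples),
    config = config
  ), class = "truth_set")
  list(studies = studies, truth = truth)
}

#' Emulate an external risk-GWAS summary-statistics file
#'
#' Per-variant estimates are the true liability-scale effects plus Gaussian
#' noise with standard deviation equal to the standard error implied by the
#' effective sample size and the panel allele frequency,
#' \eqn{SE = 1/\sqrt{2p(1-p)\,n}}; P-values come from the Wald statistic.
#' Null variants (including the risk-orthogonal resilience variants) have
#' true effect zero.
#'
#' @param panel A reference [genotype_study()] covering all variants.
#' @param truth The `truth` element returned by [simulate_cohorts()].
#' @param n_effective Effective sample size of the emulated risk GWAS.
#' @param seed Optional integer seed for the estimation noise.
#' @return A [summary_stats()] table; zero-variance variants are excluded
#'   with a logged warning.
#' @export
make_prior_risk_gwas <- function(panel, truth, n_effective = 50000,
                                 seed = NULL) {
  stopifnot(inherits(panel, "genotype_study"), inherits(truth, "truth_set"))
  if (n_effective <= 1) stopf("n_effective must exceed 1")
  map <- truth$map
  miss <- setdiff(map$snp_id, panel$variants$snp_id)
  if (length(miss)) stopf("panel does not cover %d truth variants", length(miss))
  if (!is.null(seed)) set.seed(seed)
  p_hat <- colMeans(panel$dosages[, map$snp_id, drop = FALSE]) / 2
  mono <- p_hat <= 0 | p_hat >= 1
  if (any(mono)) {
    warning(sprintf("excluding %d zero-variance variants from the prior risk GWAS",
                    sum(mono)), call. = FALSE)
    pr_log("prior risk GWAS: excluded %d zero-variance variants", sum(mono))
  }
  keep <- which(!mono)
  se <- 1 / sqrt(2 * p_hat[keep] * (1 - p_hat[keep]) * n_effective)
  beta_hat <- map$beta[keep] + rnorm(length(keep), 0, se)
  z <- beta_hat / se
  summary_stats(data.frame(
    snp_id = map$snp_id[keep], chr = map$chr[keep], pos = map$pos[keep],
    effect_allele = map$effect_allele[keep], other_allele = map$other_allele[keep],
    beta = beta_hat, se = se, p = p_from_z(z),
    n_studies = 1L, stringsAsFactors = FALSE
  ))
}
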