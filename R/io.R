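#' Construct a per-study genotype container
#'
#' The central in-memory container: an ordered variant table, a sample x
#' variant effect-allele dosage matrix, and a sample table with status, sex,
#' age (AAO for cases / AAE for controls) and covariates.
#'
#' @param study_id Study label.
#' @param variants Data frame with columns `snp_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele` (positions 1-based).
#' @param dosages Numeric matrix, samples x variants, values in \[0, 2\].
#' @param samples Data frame with `sample_id`, `status` (`"case"`/`"control"`),
#'   `sex`, `age`, plus any covariate columns (e.g. `PC1..PCk`).
#' @return A validated object of class `genotype_study`.
#' @export
genotype_study <- function(study_id, variants, dosages, samples) {
  obj <- structure(list(study_id = study_id,
                        variants = as.data.frame(variants),
                        dosages = dosages,
                        samples = as.data.frame(samples)),
                   class = "genotype_study")
  validate_genotype_study(obj)
}

validate_genotype_study <- function(x) {
  v <- x$variants; s <- x$samples; d <- x$dosages
  need_v <- c("snp_id", "chr", "pos", "effect_allele", "other_allele")
  if (!all(need_v %in% names(v))) stopf("variants table lacks: %s",
    paste(setdiff(need_v, names(v)), collapse = ", "))
  if (anyDuplicated(v$snp_id)) stopf("duplicate variant IDs in study %s", x$study_id)
  if (!all(c("sample_id", "status", "sex", "age") %in% names(s)))
    stopf("sample table lacks required columns")
  if (nrow(d) != nrow(s) || ncol(d) != nrow(v))
    stopf("dosage matrix is %d x %d but %d samples / %d variants given",
          nrow(d), ncol(d), nrow(s), nrow(v))
  if (anyNA(s$status) || !all(s$status %in% c("case", "control")))
    stopf("every sample needs status 'case' or 'control'")
  if (anyNA(s$age)) stopf("every sample needs a non-missing age")
  rng <- range(d)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 2)
    stopf("dosages must be non-missing and within [0, 2]")
  if (is.null(colnames(d))) colnames(x$dosages) <- v$snp_id
  x
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("<genotype_study %s: %d samples (%d cases / %d controls), %d variants>\n",
              x$study_id, nrow(x$samples), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"), nrow(x$variants)))
  invisible(x)
}

pc_columns <- function(samples) grep("^PC[0-9]+$", names(samples), value = TRUE)

#' Write a study as VCF plus sample table
#'
#' VCFv4.2 with one ALT per record (`REF` = other allele, `ALT` = effect
#' allele) and a `GT:DS` FORMAT; `DS` is the ALT-allele dosage. The sample
#' table is a TSV with `sample_id, study_id, status (1=control, 2=case),
#' sex (1/2), age, PC1..PCk`.
#'
#' @param study A [genotype_study()].
#' @param vcf_path,sample_path Output paths.
#' @return Invisibly, the VCF path.
#' @export
write_genotype_study <- function(study, vcf_path, sample_path) {
  v <- study$variants
  d <- study$dosages
  n <- nrow(d)
  gt_of <- function(ds) {
    out <- rep("./.", length(ds))
    intish <- abs(ds - round(ds)) < 1e-9
    out[intish & round(ds) == 0] <- "0/0"
    out[intish & round(ds) == 1] <- "0/1"
    out[intish & round(ds) == 2] <- "1/1"
    out
  }
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- d[, j]
    paste(paste0(gt_of(ds), ":", formatC(ds, format = "g", digits = 6)),
          collapse = "\t")
  }, character(1))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=polyresilience",
    sprintf("##contig=<ID=%s>", unique(v$chr)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect (ALT) allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", study$samples$sample_id), collapse = "\t"),
    paste(v$chr, format(v$pos, scientific = FALSE, trim = TRUE), v$snp_id,
          v$other_allele, v$effect_allele, ".", ".", ".", "GT:DS", body,
          sep = "\t")
  )
  writeLines(lines, vcf_path)
  s <- study$samples
  tab <- data.frame(sample_id = s$sample_id, study_id = study$study_id,
                    status = ifelse(s$status == "case", 2L, 1L),
                    sex = s$sex, age = s$age, stringsAsFactors = FALSE)
  pcs <- pc_columns(s)
  if (length(pcs)) tab <- cbind(tab, s[pcs])
  write.table(tab, sample_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Read a study from VCF plus sample table
#'
#' Dosages are taken from the `DS` FORMAT field when present, otherwise from
#' `GT` as the effect (ALT) allele count. Multi-allelic records are fatal.
#' Missing genotypes are mean-imputed to twice the effect-allele frequency,
#' with a logged count.
#'
#' @param vcf_path,sample_table_path Input paths; sample IDs must match.
#' @return A [genotype_study()].
#' @export
read_genotype_study <- function(vcf_path, sample_table_path) {
  if (!file.exists(vcf_path)) stopf("no such file: %s", vcf_path)
  if (!file.exists(sample_table_path)) stopf("no such file: %s", sample_table_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1)) {
    bad <- names(vcf)[which(lengths(alt) != 1)[1]]
    stopf("multi-allelic variant not supported: %s", bad)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    snp_id = names(vcf),
    chr = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    effect_allele = as.character(unlist(alt)),
    other_allele = as.character(VariantAnnotation::ref(vcf)),
    stringsAsFactors = FALSE
  )
  g <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(g)) {
    dos <- t(g$DS)
  } else if ("GT" %in% names(g)) {
    gt <- g$GT
    cnt <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    lut <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2)
    cnt[] <- lut[gt]
    dos <- t(cnt)
  } else {
    stopf("VCF has neither DS nor GT genotype fields")
  }
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    af2 <- colMeans(dos, na.rm = TRUE)  # = 2 * effect-allele frequency
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- if (is.finite(af2[j])) af2[j] else 0
    }
    pr_log("read_genotype_study: imputed %d missing genotypes to 2*AF", n_missing)
  }
  tab <- read.delim(sample_table_path, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!setequal(tab$sample_id, rownames(dos)))
    stopf("sample IDs in VCF and sample table do not match")
  tab <- tab[match(rownames(dos), tab$sample_id), , drop = FALSE]
  samples <- data.frame(sample_id = tab$sample_id,
                        status = ifelse(tab$status == 2, "case", "control"),
                        sex = tab$sex, age = tab$age, stringsAsFactors = FALSE)
  pcs <- pc_columns(tab)
  if (length(pcs)) samples <- cbind(samples, tab[pcs])
  genotype_study(tab$study_id[1] %||% "STUDY", variants, dos, samples)
}

#' Construct/validate a summary-statistics table
#'
#' Per-variant association records: `snp_id, chr, pos, effect_allele,
#' other_allele, beta, se, p` (optionally `n_studies`, `direction`). Rows with
#' non-positive SE, P outside (0, 1] or non-finite beta are rejected with a
#' logged count; rejection of more than 10% of rows is fatal, as are
#' duplicate variant IDs.
#'
#' @param df Data frame of records.
#' @return A validated `summary_stats` data frame.
#' @export
summary_stats <- function(df) {
  need <- c("snp_id", "chr", "pos", "effect_allele", "other_allele",
            "beta", "se", "p")
  if (!all(need %in% names(df))) stopf("summary stats lack columns: %s",
    paste(setdiff(need, names(df)), collapse = ", "))
  df$chr <- as.character(df$chr)
  n0 <- nrow(df)
  ok <- is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    is.finite(df$p) & df$p > 0 & df$p <= 1
  if (any(!ok)) {
    pr_log("summary_stats: rejected %d of %d rows failing validity checks",
           sum(!ok), n0)
    if (sum(!ok) > 0.1 * n0)
      stopf("more than 10%% of summary-statistic rows are invalid (%d of %d)",
            sum(!ok), n0)
    df <- df[ok, , drop = FALSE]
  }
  if (anyDuplicated(df$snp_id)) stopf("duplicate snp_id in summary statistics")
  rownames(df) <- NULL
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Read summary statistics from TSV
#'
#' @param path TSV path with a header.
#' @param col_map Optional named character vector mapping file column names to
#'   canonical names, e.g. `c("P-value" = "p", "SNP" = "snp_id")`.
#' @return A [summary_stats()] table.
#' @export
read_summary_stats <- function(path, col_map = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- unname(col_map[names(df)[hit]])
  }
  summary_stats(df)
}

#' Write summary statistics to TSV
#'
#' @param stats A [summary_stats()] table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a polygenic score weight set
#'
#' @param df Data frame with `snp_id`, `effect_allele`, `weight` (log-odds
#'   toward the effect allele).
#' @param p_threshold Upper P bound that produced the set (metadata).
#' @param excluded_region Optional excised region (metadata), see
#'   [parse_region()] format.
#' @param provenance Free-text label.
#' @return A `score_weights` data frame with metadata attributes.
#' @export
score_weights <- function(df, p_threshold = NA_real_, excluded_region = NULL,
                          provenance = "") {
  need <- c("snp_id", "effect_allele", "weight")
  if (!all(need %in% names(df))) stopf("weights lack columns: %s",
    paste(setdiff(need, names(df)), collapse = ", "))
  if (any(!is.finite(df$weight))) stopf("non-finite score weight")
  if (anyDuplicated(df$snp_id)) stopf("duplicate snp_id in score weights")
  structure(df[need], p_threshold = p_threshold,
            excluded_region = parse_region(excluded_region),
            provenance = provenance,
            class = c("score_weights", "data.frame"))
}

#' Write/read score weights as TSV
#'
#' Metadata (`p_threshold`, `excluded_region`, `provenance`) round-trips via
#' `#key=value` header comments.
#'
#' @param weights A [score_weights()] set.
#' @param path File path.
#' @return `write_score_weights`: invisibly `path`; `read_score_weights`:
#'   a [score_weights()] set.
#' @export
write_score_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  reg <- attr(weights, "excluded_region")
  writeLines(c(sprintf("#p_threshold=%.17g", attr(weights, "p_threshold")),
               sprintf("#excluded_region=%s",
                       if (is.null(reg)) "" else
                         sprintf("%s:%d-%d", reg$chr, reg$start, reg$end)),
               sprintf("#provenance=%s", attr(weights, "provenance"))), con)
  write.table(as.data.frame(weights), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_weights
#' @export
read_score_weights <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, "="))]
    if (!length(ln)) return("")
    sub(paste0("^#", key, "="), "", ln[1])
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  reg <- get("excluded_region")
  score_weights(df,
                p_threshold = suppressWarnings(as.numeric(get("p_threshold"))),
                excluded_region = if (nzchar(reg)) reg else NULL,
                provenance = get("provenance"))
}

#' Harmonize summary-statistic alleles to a study's orientation
#'
#' For each variant shared between `stats` and `study`: if the effect alleles
#' agree the record is kept as is; if the stats effect allele equals the
#' study's other allele, beta is negated and the alleles swapped;
#' strand-ambiguous palindromic variants (A/T, C/G) and irreconcilable allele
#' pairs are dropped with logged counts. `|beta|` is never changed.
#'
#' @param stats A [summary_stats()] table.
#' @param study A [genotype_study()].
#' @return A [summary_stats()] table in the study's orientation, with counts
#'   in attribute `harmonization`.
#' @export
harmonize_alleles <- function(stats, study) {
  v <- study$variants
  idx <- match(stats$snp_id, v$snp_id)
  shared <- which(!is.na(idx))
  if (!length(shared)) stopf("no overlapping variants between stats and study %s",
                             study$study_id)
  st <- stats[shared, , drop = FALSE]
  sv <- v[idx[shared], , drop = FALSE]
  pal <- (st$effect_allele == "A" & st$other_allele == "T") |
         (st$effect_allele == "T" & st$other_allele == "A") |
         (st$effect_allele == "C" & st$other_allele == "G") |
         (st$effect_allele == "G" & st$other_allele == "C")
  same <- st$effect_allele == sv$effect_allele & st$other_allele == sv$other_allele
  flip <- st$effect_allele == sv$other_allele & st$other_allele == sv$effect_allele
  keep <- !pal & (same | flip)
  counts <- c(n_shared = length(shared), n_kept = sum(keep),
              n_flipped = sum(flip & !pal),
              n_palindromic_dropped = sum(pal),
              n_mismatch_dropped = sum(!pal & !same & !flip))
  if (counts["n_palindromic_dropped"] > 0 || counts["n_mismatch_dropped"] > 0)
    pr_log("harmonize_alleles: dropped %d palindromic and %d allele-mismatch variants",
           counts["n_palindromic_dropped"], counts["n_mismatch_dropped"])
  out <- st[keep, , drop = FALSE]
  fl <- flip[keep]
  out$beta[fl] <- -out$beta[fl]
  tmp <- out$effect_allele[fl]
  out$effect_allele[fl] <- out$other_allele[fl]
  out$other_allele[fl] <- tmp
  out <- summary_stats(out)
  attr(out, "harmonization") <- counts
  out
}
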