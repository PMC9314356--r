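#' @useDynLib polyresilience, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif qnorm pnorm dnorm quantile sd cor
#'   cor.test median glm binomial logLik coef qchisq setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Emit a pipeline log message
#'
#' Messages go to `stderr` via [message()]. Silence them with
#' `options(polyresilience.verbose = FALSE)`.
#'
#' @param fmt `sprintf` format string.
#' @param ... Values interpolated into `fmt`.
#' @return Invisibly, the formatted string.
#' @export
pr_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (isTRUE(getOption("polyresilience.verbose", TRUE))) {
    message("[polyresilience] ", msg)
  }
  invisible(msg)
}

# Deterministic child seed below 2^31, for independent simulation streams.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + 97 * k) %% 2147483559) + 1L
}

# Parse "chr19:44400000-46500000" (or list(chr=,start=,end=)) into a region.
parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  if (is.list(region)) {
    stopifnot(all(c("chr", "start", "end") %in% names(region)))
  } else {
    m <- regmatches(region, regexec("^(chr)?([0-9XYM]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) == 0) stopf("cannot parse region '%s'", region)
    region <- list(chr = m[3], start = as.numeric(m[4]), end = as.numeric(m[5]))
  }
  region$chr <- sub("^chr", "", as.character(region$chr))
  if (!(region$start < region$end)) stopf("malformed region: start must be < end")
  region
}

# two-sided normal P from a Wald z, guarded against underflow to zero
# (validation requires p > 0)
p_from_z <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)

in_region <- function(chr, pos, region) {
  if (is.null(region)) return(rep(FALSE, length(chr)))
  sub("^chr", "", as.character(chr)) == region$chr &
    pos >= region$start & pos <= region$end
}
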