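# Internal helpers shared across modules.

REGIONS <- c("normal", "central", "peripheral")
TUMOR_REGIONS <- c("central", "peripheral")
SNV_CONSEQUENCES <- c("missense", "nonsense", "splice_site", "silent")
INDEL_CONSEQUENCES <- c("frameshift", "inframe_indel")
NONSYN_CONSEQUENCES <- c("missense", "nonsense", "splice_site",
                         "frameshift", "inframe_indel")

#' Variant allele frequency from read counts
#'
#' Always recomputed from counts; a site with zero depth has VAF 0.
#'
#' @param var_reads integer vector of variant-supporting reads
#' @param depth integer vector of total reads
#' @return numeric vector in \[0, 1\]
#' @export
vaf <- function(var_reads, depth) {
  out <- ifelse(depth > 0, var_reads / depth, 0)
  as.numeric(out)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; descriptive statistics here follow the
#' half-up convention (7.05 -> 7.1 at one decimal).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Polynomial rolling hash of a deparsed R object; provenance checksum for
# output headers (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(config = NULL, seed = NULL) {
  ver <- as.character(utils::packageVersion("ithexome"))
  h <- if (is.null(config)) "none" else config_hash(config)
  s <- if (is.null(seed)) "" else paste0(" seed=", seed)
  sprintf("#ithexome %s config=%s%s", ver, h, s)
}

# Negative-binomial draw parameterised by mean and extra-Poisson dispersion
# alpha (var = mu + alpha * mu^2). alpha = 0 is the noise-free limit and
# returns the mean exactly.
rdepth <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rep(mu, n))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ith <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}
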