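# Rule-based somatic filtering with machine-readable reject reasons.
#
# SNV rules (all inclusive, evaluated per tumor region, reasons accumulated
# without short-circuiting): MAPQ, VAF, DEPTH, TUMOR_VAR, NORMAL_VAR,
# NEAR_INDEL, WINDOW; plus POLYMORPHISM and NON_EXONIC annotation filters.
# Indel rules: INDEL_DEPTH, INDEL_VAF, INDEL_VAR, INDEL_NORMAL.

new_decisions <- function(variants, region, reasons) {
  passed <- !nzchar(reasons)
  data.frame(
    patient = variants$patient, chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt, gene = variants$gene,
    consequence = variants$consequence,
    region = rep(region, nrow(variants)),
    passed = passed, reasons = reasons, stringsAsFactors = FALSE
  )
}

join_reason <- function(reasons, add, hit) {
  ifelse(hit, ifelse(nzchar(reasons), paste(reasons, add, sep = ","), add),
         reasons)
}

#' Flag SNVs violating the 10-bp window rule
#'
#' A site is flagged iff some window of `window_bp` consecutive positions
#' (p..p+window_bp-1, 1-based inclusive) contains more than `max_snvs`
#' candidate SNVs including it.
#'
#' @param positions sorted integer positions of candidate SNVs on one
#'   chromosome of one sample
#' @param window_bp window width in bp
#' @param max_snvs maximum SNVs tolerated per window
#' @return logical vector aligned with `positions`
#' @export
apply_window_rule <- function(positions, window_bp = 10, max_snvs = 2) {
  n <- length(positions)
  flagged <- rep(FALSE, n)
  if (n <= max_snvs) return(flagged)
  if (is.unsorted(positions)) stop("positions must be sorted")
  k <- max_snvs # a violating window holds >= k+1 sites
  for (i in seq_len(n - k)) {
    if (positions[i + k] - positions[i] <= window_bp - 1) {
      flagged[i:(i + k)] <- TRUE
    }
  }
  flagged
}

#' Apply the somatic SNV cut-offs to one tumor region
#'
#' Evaluates mapping quality, tumor VAF, depth in tumor and non-tumor,
#' tumor/non-tumor variant reads, proximity to candidate indels, and the
#' SNV-density window rule. Every failed rule appears in the reason string;
#' thresholds are inclusive exactly as published.
#'
#' @param variants canonical variant data.frame (one patient)
#' @param region `"central"` or `"peripheral"`
#' @param config a [filter_config()]
#' @param extra_indels optional data.frame chrom/pos of additional candidate
#'   indels (beyond the indel rows of `variants` themselves)
#' @return decisions data.frame (one row per SNV record) with passed and
#'   reasons
#' @export
filter_snvs <- function(variants, region = c("central", "peripheral"),
                        config = filter_config(), extra_indels = NULL) {
  region <- match.arg(region)
  is_snv <- variants$consequence %in% SNV_CONSEQUENCES
  snv <- variants[is_snv, , drop = FALSE]
  if (any(is.na(snv$normal_depth)))
    stop("missing normal evidence: somatic status undecidable")
  n <- nrow(snv)
  reasons <- character(n)
  if (n == 0) return(new_decisions(snv, region, reasons))

  t_depth <- snv[[paste0(region, "_depth")]]
  t_var <- snv[[paste0(region, "_var")]]
  t_mapq <- snv[[paste0(region, "_mapq")]]
  t_vaf <- vaf(t_var, t_depth)

  reasons <- join_reason(reasons, "MAPQ", t_mapq < config$snv_min_mapq)
  reasons <- join_reason(reasons, "VAF", t_vaf < config$snv_min_tumor_vaf)
  reasons <- join_reason(reasons, "DEPTH",
                         t_depth < config$snv_min_depth |
                           snv$normal_depth < config$snv_min_depth)
  reasons <- join_reason(reasons, "TUMOR_VAR",
                         t_var < config$snv_min_tumor_var_reads)
  reasons <- join_reason(reasons, "NORMAL_VAR",
                         snv$normal_var > config$snv_max_normal_var_reads)

  indels <- variants[variants$consequence %in% INDEL_CONSEQUENCES,
                     c("chrom", "pos"), drop = FALSE]
  if (!is.null(extra_indels) && nrow(extra_indels))
    indels <- rbind(indels, extra_indels[, c("chrom", "pos")])
  near <- rep(FALSE, n)
  if (nrow(indels)) {
    for (i in seq_len(n)) {
      same <- indels$chrom == snv$chrom[i]
      near[i] <- any(abs(indels$pos[same] - snv$pos[i]) <=
                       config$snv_indel_exclusion_bp)
    }
  }
  reasons <- join_reason(reasons, "NEAR_INDEL", near)

  winhit <- rep(FALSE, n)
  for (chrom in unique(snv$chrom)) {
    idx <- which(snv$chrom == chrom)
    ord <- idx[order(snv$pos[idx])]
    winhit[ord] <- apply_window_rule(snv$pos[ord], config$snv_window_bp,
                                     config$snv_window_max)
  }
  reasons <- join_reason(reasons, "WINDOW", winhit)
  new_decisions(snv, region, reasons)
}

#' Apply the four-rule indel filter to one tumor region
#'
#' Coverage >= 20 in both tumor and non-tumor sample, tumor allele frequency
#' >= 10%, at least 5 independent variant reads, and no variant read in the
#' non-tumor sample; all evaluated inclusively and accumulated.
#'
#' @inheritParams filter_snvs
#' @return decisions data.frame (one row per indel record)
#' @export
filter_indels <- function(variants, region = c("central", "peripheral"),
                          config = filter_config()) {
  region <- match.arg(region)
  ind <- variants[variants$consequence %in% INDEL_CONSEQUENCES, , drop = FALSE]
  if (any(is.na(ind$normal_depth)))
    stop("missing normal evidence: somatic status undecidable")
  n <- nrow(ind)
  reasons <- character(n)
  if (n == 0) return(new_decisions(ind, region, reasons))
  t_depth <- ind[[paste0(region, "_depth")]]
  t_var <- ind[[paste0(region, "_var")]]
  t_vaf <- vaf(t_var, t_depth)
  reasons <- join_reason(reasons, "INDEL_DEPTH",
                         t_depth < config$indel_min_depth |
                           ind$normal_depth < config$indel_min_depth)
  reasons <- join_reason(reasons, "INDEL_VAF", t_vaf < config$indel_min_vaf)
  reasons <- join_reason(reasons, "INDEL_VAR",
                         t_var < config$indel_min_var_reads)
  reasons <- join_reason(reasons, "INDEL_NORMAL",
                         ind$normal_var > config$indel_max_normal_var_reads)
  new_decisions(ind, region, reasons)
}

#' Exclude known polymorphisms from a decision set
#'
#' Records matching a (chrom, pos, ref, alt) in the polymorphism fixture
#' gain reason POLYMORPHISM; same position with a different alt is not
#' excluded.
#'
#' @param decisions decisions data.frame from [filter_snvs()]/[filter_indels()]
#' @param polymorphisms data.frame with chrom, pos, ref, alt
#' @return updated decisions
#' @export
exclude_polymorphisms <- function(decisions, polymorphisms) {
  if (is.null(polymorphisms) || nrow(polymorphisms) == 0) return(decisions)
  key <- paste(decisions$chrom, decisions$pos, decisions$ref, decisions$alt)
  pkey <- paste(polymorphisms$chrom, polymorphisms$pos, polymorphisms$ref,
                polymorphisms$alt)
  hit <- key %in% pkey
  decisions$reasons <- join_reason(decisions$reasons, "POLYMORPHISM", hit)
  decisions$passed <- !nzchar(decisions$reasons)
  decisions
}

#' Restrict decisions to exonic/splice-site intervals
#'
#' Sites outside every annotation interval gain reason NON_EXONIC. An empty
#' annotation marks every record NON_EXONIC.
#'
#' @param decisions decisions data.frame
#' @param exons data.frame with chrom, start, end (1-based inclusive)
#' @return updated decisions
#' @export
restrict_to_exonic <- function(decisions, exons) {
  if (nrow(decisions) == 0) return(decisions)
  if (is.null(exons) || nrow(exons) == 0) {
    outside <- rep(TRUE, nrow(decisions))
  } else {
    site_gr <- GenomicRanges::GRanges(
      decisions$chrom, IRanges::IRanges(decisions$pos, decisions$pos))
    ex_gr <- GenomicRanges::GRanges(
      exons$chrom, IRanges::IRanges(exons$start, exons$end))
    outside <- !IRanges::overlapsAny(site_gr, ex_gr)
  }
  decisions$reasons <- join_reason(decisions$reasons, "NON_EXONIC", outside)
  decisions$passed <- !nzchar(decisions$reasons)
  decisions
}

#' Run the full filter cascade for one tumor region
#'
#' SNV and indel rule sets, then polymorphism exclusion and the
#' exon/splice-site restriction when fixtures are supplied; returns one
#' decision row per record with exhaustively accumulated reasons.
#'
#' @inheritParams filter_snvs
#' @param polymorphisms optional polymorphism fixture (chrom/pos/ref/alt)
#' @param exons optional exon/splice-site intervals (chrom/start/end)
#' @return decisions data.frame sorted by (chrom, pos)
#' @export
filter_region <- function(variants, region = c("central", "peripheral"),
                          config = filter_config(), polymorphisms = NULL,
                          exons = NULL, extra_indels = NULL) {
  region <- match.arg(region)
  dec <- rbind(filter_snvs(variants, region, config, extra_indels),
               filter_indels(variants, region, config))
  dec <- exclude_polymorphisms(dec, polymorphisms)
  if (!is.null(exons)) dec <- restrict_to_exonic(dec, exons)
  dec <- dec[order(dec$patient, dec$chrom, dec$pos), , drop = FALSE]
  rownames(dec) <- NULL
  dec$passed <- !nzchar(dec$reasons)
  dec
}
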