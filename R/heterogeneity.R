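# Common/private clonality classification and ITH summary statistics.
#
# A mutation passing filters in both tumor regions is common without
# further interrogation. One passing in a single region is checked for
# supporting reads in the other region (cross-interrogation); if absent
# there it becomes a private candidate and is confirmed against orthogonal
# AF re-measurements: the harboring region must exceed the non-tumor AF by
# >= 5 percentage points while the other region does not.

#' Cross-interrogate the other tumor region for supporting reads
#'
#' Presence requires at least `min_reads` variant reads and `min_depth`
#' total depth; zero-depth evidence is absent with a low-coverage flag.
#'
#' @param var_reads variant reads in the other region
#' @param depth total depth in the other region
#' @param min_reads presence threshold on variant reads
#' @param min_depth minimum depth to assert presence or absence
#' @return data.frame with status ("present"/"absent") and low_coverage flag
#' @export
cross_interrogate <- function(var_reads, depth, min_reads = 2,
                              min_depth = 10) {
  present <- var_reads >= min_reads & depth >= min_depth
  low <- depth < min_depth
  data.frame(status = ifelse(present, "present", "absent"),
             low_coverage = low, stringsAsFactors = FALSE)
}

#' Confirm a private candidate against orthogonal AF measurements
#'
#' Confirmed iff the harboring region's measured AF exceeds the non-tumor AF
#' by at least `min_diff` and the other region's does not; refuted (present
#' in both regions, relabel common) iff both exceed; failed iff the
#' harboring region itself does not exceed (likely artifact); untested when
#' a measurement is missing.
#'
#' @param harboring_af measured AF in the region harboring the candidate
#' @param other_af measured AF in the other tumor region
#' @param normal_af measured AF in the non-tumor sample
#' @param min_diff required AF excess over normal (default 0.05)
#' @return character vector in {confirmed, refuted, failed, untested}
#' @export
confirm_private <- function(harboring_af, other_af, normal_af,
                            min_diff = 0.05) {
  out <- rep("untested", length(harboring_af))
  ok <- !(is.na(harboring_af) | is.na(other_af) | is.na(normal_af))
  harb <- harboring_af - normal_af >= min_diff
  oth <- other_af - normal_af >= min_diff
  out[ok & harb & !oth] <- "confirmed"
  out[ok & harb & oth] <- "refuted"
  out[ok & !harb] <- "failed"
  out
}

#' Classify a patient's mutations as common, private or unresolved
#'
#' Combines per-region filter decisions, cross-interrogation of the
#' non-passing region, and orthogonal-AF confirmation of private
#' candidates. Candidates whose other-region evidence lacks the depth to
#' assert absence are labeled unresolved; refuted candidates are relabeled
#' common; failed confirmations are relabeled unresolved.
#'
#' @param variants canonical variant data.frame (one patient)
#' @param decisions_central decisions from [filter_region()] for the central
#'   region
#' @param decisions_peripheral same for the peripheral region
#' @param pyro optional orthogonal AF table (patient, chrom, pos,
#'   af_central, af_peripheral, af_normal); missing sites are untested
#' @param presence list with min_reads and min_depth for cross-interrogation
#' @return clonality calls data.frame: one row per mutation passing filters
#'   in at least one region, with label, confirmation and per-region VAFs
#' @export
classify_cohort <- function(variants, decisions_central, decisions_peripheral,
                            pyro = NULL,
                            presence = list(min_reads = 2, min_depth = 10)) {
  key <- function(df) paste(df$patient, df$chrom, df$pos, df$alt)
  vk <- key(variants)
  pass_c <- vk %in% key(decisions_central[decisions_central$passed, ])
  pass_p <- vk %in% key(decisions_peripheral[decisions_peripheral$passed, ])
  keep <- pass_c | pass_p
  v <- variants[keep, , drop = FALSE]
  pass_c <- pass_c[keep]
  pass_p <- pass_p[keep]
  n <- nrow(v)
  label <- character(n)
  confirmation <- rep("not_required", n)

  pyro_af <- function(region, i) {
    if (is.null(pyro)) return(NA_real_)
    hit <- which(pyro$patient == v$patient[i] & pyro$chrom == v$chrom[i] &
                   pyro$pos == v$pos[i])
    if (!length(hit)) return(NA_real_)
    pyro[[paste0("af_", region)]][hit[1]]
  }

  for (i in seq_len(n)) {
    if (pass_c[i] && pass_p[i]) {
      label[i] <- "common"
      next
    }
    harb <- if (pass_c[i]) "central" else "peripheral"
    other <- setdiff(TUMOR_REGIONS, harb)
    ci <- cross_interrogate(v[[paste0(other, "_var")]][i],
                            v[[paste0(other, "_depth")]][i],
                            presence$min_reads, presence$min_depth)
    if (ci$low_coverage) {
      label[i] <- "unresolved"
      next
    }
    if (ci$status == "present") {
      label[i] <- "common"
      next
    }
    st <- confirm_private(pyro_af(harb, i), pyro_af(other, i),
                          pyro_af("normal", i))
    confirmation[i] <- st
    label[i] <- switch(st,
                       confirmed = paste0("private_", harb),
                       untested = paste0("private_", harb),
                       refuted = "common",
                       failed = "unresolved")
  }
  out <- data.frame(
    patient = v$patient, chrom = v$chrom, pos = v$pos, ref = v$ref,
    alt = v$alt, gene = v$gene, consequence = v$consequence,
    aa_change = v$aa_change, context = v$context,
    label = label, confirmation = confirmation,
    vaf_central = vaf(v$central_var, v$central_depth),
    vaf_peripheral = vaf(v$peripheral_var, v$peripheral_depth),
    vaf_normal = vaf(v$normal_var, v$normal_depth),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Paired substitution class of an SNV
#'
#' Strand-collapsed pairing of the 12 ordered single-base substitutions onto
#' 6 classes; G>A maps to C>T/G>A, G>T to C>A/G>T, and so on.
#'
#' @param ref,alt single-base reference and alternate alleles (vectorized)
#' @return character vector of paired class labels
#' @export
substitution_class <- function(ref, alt) {
  if (any(nchar(ref) != 1 | nchar(alt) != 1 | ref == alt))
    stop("substitution_class requires single-base ref != alt")
  key <- paste0(ref, ">", alt)
  lut <- character()
  for (cls in SUBSTITUTION_CLASSES) {
    ra <- CLASS_PYR[[cls]]
    lut[paste0(ra[1], ">", ra[2])] <- cls
    lut[paste0(COMPLEMENT[ra[1]], ">", COMPLEMENT[ra[2]])] <- cls
  }
  out <- unname(lut[key])
  if (any(is.na(out))) stop("non-ACGT substitution")
  out
}

#' Fraction of C>T/G>A events at CpG sites
#'
#' A C>T event is at CpG when its plus-strand context carries G immediately
#' 3' of the mutated C; a G>A event when C lies immediately 5' of the
#' mutated G. Records lacking context are excluded from numerator and
#' denominator and counted separately.
#'
#' @param ref,alt single-base alleles of C>T/G>A-class events
#' @param context plus-strand trinucleotide contexts (NA allowed)
#' @return list with fraction, n_used, n_missing
#' @export
cpg_fraction <- function(ref, alt, context) {
  cls <- substitution_class(ref, alt)
  keep <- cls == "C>T/G>A"
  ref <- ref[keep]
  context <- context[keep]
  missing <- is.na(context)
  ref_u <- ref[!missing]
  ctx <- context[!missing]
  is_cpg <- (ref_u == "C" & substr(ctx, 3, 3) == "G") |
    (ref_u == "G" & substr(ctx, 1, 1) == "C")
  list(fraction = if (length(is_cpg)) mean(is_cpg) else NA_real_,
       n_used = length(is_cpg), n_missing = sum(missing))
}

#' Summarize intratumoral heterogeneity from clonality calls
#'
#' Per sample (patient x tumor region): counts of common and private
#' mutations, private fraction, and median VAFs (private mutations use the
#' harboring region's VAF; common mutations the mean of both regions').
#' Per patient: the 6-class substitution spectrum split by clonality, CpG
#' fraction among C>T/G>A events, and functional-category tallies.
#'
#' @param calls clonality calls from [classify_cohort()] (any number of
#'   patients, rbind-ed)
#' @param nonsyn_only restrict counts to non-synonymous consequences
#' @return list with samples, spectrum, cpg and categories data.frames
#' @export
summarize_ith <- function(calls, nonsyn_only = TRUE) {
  counted <- if (nonsyn_only) calls[calls$consequence %in% NONSYN_CONSEQUENCES, ,
                                    drop = FALSE] else calls
  samples <- list()
  for (p in unique(calls$patient)) {
    cp <- counted[counted$patient == p, , drop = FALSE]
    for (r in TUMOR_REGIONS) {
      common <- cp$label == "common"
      private <- cp$label == paste0("private_", r)
      n_common <- sum(common)
      n_private <- sum(private)
      vaf_common <- (cp$vaf_central[common] + cp$vaf_peripheral[common]) / 2
      vaf_private <- cp[[paste0("vaf_", r)]][private]
      vaf_sample <- cp[[paste0("vaf_", r)]][common | private]
      samples[[paste(p, r)]] <- data.frame(
        patient = p, region = r, n_common = n_common, n_private = n_private,
        private_fraction = if (n_common + n_private > 0)
          n_private / (n_common + n_private) else NA_real_,
        median_vaf_common = stats::median(vaf_common),
        median_vaf_private = if (n_private) stats::median(vaf_private)
          else NA_real_,
        median_vaf_sample = stats::median(vaf_sample),
        stringsAsFactors = FALSE
      )
    }
  }
  samples <- do.call(rbind, c(samples, make.row.names = FALSE))

  snv <- calls[nchar(calls$ref) == 1 & nchar(calls$alt) == 1 &
                 calls$ref != calls$alt, , drop = FALSE]
  spectrum <- list()
  cpg <- list()
  for (p in unique(calls$patient)) {
    sp <- snv[snv$patient == p, , drop = FALSE]
    cls <- substitution_class(sp$ref, sp$alt)
    grp <- ifelse(sp$label == "common", "common",
                  ifelse(startsWith(sp$label, "private"), "private",
                         "unresolved"))
    tab <- table(factor(cls, levels = SUBSTITUTION_CLASSES),
                 factor(grp, levels = c("common", "private", "unresolved")))
    spectrum[[p]] <- data.frame(patient = p,
                                class = rownames(tab)[row(tab)],
                                clonality = colnames(tab)[col(tab)],
                                n = as.vector(tab), stringsAsFactors = FALSE)
    cf <- cpg_fraction(sp$ref, sp$alt, sp$context)
    cpg[[p]] <- data.frame(patient = p, cpg_fraction = cf$fraction,
                           n_used = cf$n_used, n_missing = cf$n_missing,
                           stringsAsFactors = FALSE)
  }
  cats <- as.data.frame(table(patient = calls$patient,
                              consequence = calls$consequence),
                        stringsAsFactors = FALSE)
  names(cats)[3] <- "n"
  list(samples = samples,
       spectrum = do.call(rbind, c(spectrum, make.row.names = FALSE)),
       cpg = do.call(rbind, c(cpg, make.row.names = FALSE)),
       categories = cats)
}
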