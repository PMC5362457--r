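# Builders and independent oracles shared across the test files.

# One canonical variant row with sensible passing defaults; any field
# overridable.
make_variant <- function(patient = "P1", chrom = "chr1", pos = 1000L,
                         ref = "C", alt = "T", gene = "GENE1",
                         consequence = "missense", aa_change = "Ala10Val",
                         context = "ACA",
                         normal_depth = 60L, normal_var = 0L, normal_mapq = 60,
                         central_depth = 100L, central_var = 25L,
                         central_mapq = 60,
                         peripheral_depth = 100L, peripheral_var = 25L,
                         peripheral_mapq = 60) {
  data.frame(patient = patient, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene, consequence = consequence,
             aa_change = aa_change, context = context,
             normal_depth = normal_depth, normal_var = normal_var,
             normal_mapq = normal_mapq,
             central_depth = central_depth, central_var = central_var,
             central_mapq = central_mapq,
             peripheral_depth = peripheral_depth,
             peripheral_var = peripheral_var,
             peripheral_mapq = peripheral_mapq,
             stringsAsFactors = FALSE)
}

make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Independent brute-force re-implementation of the published SNV rule
# cascade for a single record (plain if-statements, no shared code with the
# package implementation).
brute_force_snv_reasons <- function(row, region, indel_positions = NULL,
                                    all_snv_positions = NULL) {
  reasons <- character()
  td <- row[[paste0(region, "_depth")]]
  tv <- row[[paste0(region, "_var")]]
  tq <- row[[paste0(region, "_mapq")]]
  tvaf <- if (td > 0) tv / td else 0
  if (tq < 20) reasons <- c(reasons, "MAPQ")
  if (tvaf < 0.05) reasons <- c(reasons, "VAF")
  if (td < 10 || row$normal_depth < 10) reasons <- c(reasons, "DEPTH")
  if (tv < 2) reasons <- c(reasons, "TUMOR_VAR")
  if (row$normal_var > 1) reasons <- c(reasons, "NORMAL_VAR")
  if (!is.null(indel_positions) && length(indel_positions) &&
      any(abs(indel_positions - row$pos) <= 5)) {
    reasons <- c(reasons, "NEAR_INDEL")
  }
  if (!is.null(all_snv_positions)) {
    flagged <- FALSE
    for (p in (row$pos - 9):row$pos) {
      inwin <- sum(all_snv_positions >= p & all_snv_positions <= p + 9)
      if (inwin >= 3 && row$pos >= p && row$pos <= p + 9) flagged <- TRUE
    }
    if (flagged) reasons <- c(reasons, "WINDOW")
  }
  reasons
}

# Exhaustive window-rule oracle: a site is flagged iff some 10-bp window
# holds >= 3 candidate SNVs including it.
brute_force_window <- function(positions, window_bp = 10, max_snvs = 2) {
  flagged <- rep(FALSE, length(positions))
  if (length(positions) == 0) return(flagged)
  for (p in (min(positions) - window_bp):max(positions)) {
    inwin <- positions >= p & positions <= p + window_bp - 1
    if (sum(inwin) > max_snvs) flagged <- flagged | inwin
  }
  flagged
}

# Tiny genome for fast generator-backed tests.
tiny_genome <- function(n_chrom = 1, chrom_length = 10e6) {
  genome_model(n_chrom = n_chrom, chrom_length = chrom_length,
               bin_bp = 1e5, exon_bp = 300, exon_spacing = 1e4)
}

# Single-trio plan with explicit mutation counts and no planted CNVs or
# drivers; used for parameter-recovery tests.
single_trio_plan <- function(n_common = 36, n_private_peripheral = 4,
                             n_private_central = 0, purity_central = 0.45,
                             purity_peripheral = 0.50,
                             hypermutator = FALSE) {
  trios <- data.frame(
    patient = "S1", purity_central = purity_central,
    purity_peripheral = purity_peripheral,
    n_common_nonsyn = n_common, n_common_silent = 0,
    n_private_central = n_private_central,
    n_private_peripheral = n_private_peripheral,
    hypermutator_peripheral = hypermutator, stringsAsFactors = FALSE
  )
  empty_cnv <- data.frame(patient = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          copy_number = integer(), region = character(),
                          stringsAsFactors = FALSE)
  empty_drv <- data.frame(patient = character(), gene = character(),
                          aa_change = character(), consequence = character(),
                          clonality = character(), stringsAsFactors = FALSE)
  cohort_plan(trios = trios, cnv = empty_cnv, drivers = empty_drv)
}

# Load the packaged synthetic driver knowledge base and Table-style driver
# mutation fixture.
load_packaged_kb <- function() {
  compile_driver_list(ithexome_extdata("driver_genes_synthetic.tsv"),
                      ithexome_extdata("known_mutations_synthetic.tsv"),
                      ithexome_extdata("sift_scores_synthetic.tsv"))
}

load_driver_fixture <- function() {
  utils::read.delim(ithexome_extdata("table1_mutations.tsv"),
                    comment.char = "#", na.strings = c("NA", "."),
                    stringsAsFactors = FALSE)
}

load_promotions <- function() {
  utils::read.delim(ithexome_extdata("promotions_synthetic.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
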