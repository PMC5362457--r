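# Driver-mutation tiering against a curated knowledge base.
#
# Tiers: high_confidence (exact known amino-acid change, SIFT < 0.05, or
# manual-review promotion) > putative (amino-acid change within 5 residues
# of a known mutation in the same gene) > unknown (gene in the list, no
# closer evidence). Genes outside the list are non_driver. The packaged
# knowledge-base fixtures are synthetic stand-ins for the study's curated
# COSMIC/SIFT extracts, constructed so the published driver table re-derives
# its printed tiers.

DRIVER_TIERS <- c("high_confidence", "putative", "unknown", "non_driver")
DRIVER_SOURCES <- c("recurrent_iCCA_study", "cosmic_ge3pct_biliary",
                    "cancer_gene_census")

#' Parse the residue position out of a protein-change string
#'
#' Handles missense/nonsense ("Gly12Asp", "Cys262Ter") and frameshift
#' ("Thr524HisfsTer52") notation; unparseable strings (including splice-site
#' "NA") give NA.
#'
#' @param aa_change character vector of protein changes
#' @return integer residue positions (NA where unparseable)
#' @export
parse_aa_position <- function(aa_change) {
  pos <- rep(NA_integer_, length(aa_change))
  ok <- !is.na(aa_change) & grepl("^[A-Z][a-z]{2}[0-9]+", aa_change)
  pos[ok] <- as.integer(sub("^[A-Z][a-z]{2}([0-9]+).*$", "\\1", aa_change[ok]))
  pos
}

#' Compile the driver knowledge base from fixture files
#'
#' Reads the gene list (gene, source), known amino-acid-level mutations
#' (gene, aa_position, aa_change) and SIFT scores (gene, aa_change, score).
#' Genes are uppercased and deduplicated with all provenance tags retained.
#'
#' @param genes_path TSV with columns gene, source
#' @param known_path TSV with columns gene, aa_position, aa_change
#' @param sift_path TSV with columns gene, aa_change, score
#' @return list of class `driver_kb` with genes, known, sift and per-source
#'   counts
#' @export
compile_driver_list <- function(genes_path, known_path, sift_path) {
  read_fixture <- function(path, cols) {
    df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop(sprintf("malformed fixture %s: missing column(s) %s", path,
                   paste(missing_cols, collapse = ", ")))
    for (i in seq_len(nrow(df))) {
      if (any(is.na(df[i, cols]) | df[i, cols] == ""))
        stop(sprintf("malformed fixture row at line %d of %s", i + 2, path))
    }
    df
  }
  genes <- read_fixture(genes_path, c("gene", "source"))
  genes$gene <- toupper(genes$gene)
  if (!all(genes$source %in% DRIVER_SOURCES))
    stop("unknown provenance tag in gene list: ",
         paste(setdiff(genes$source, DRIVER_SOURCES), collapse = ", "))
  genes <- unique(genes)
  known <- read_fixture(known_path, c("gene", "aa_position", "aa_change"))
  known$gene <- toupper(known$gene)
  known$aa_position <- as.integer(known$aa_position)
  if (any(known$aa_position < 1)) stop("known mutation aa_position must be >= 1")
  sift <- read_fixture(sift_path, c("gene", "aa_change", "score"))
  sift$gene <- toupper(sift$gene)
  sift$score <- as.numeric(sift$score)
  if (any(sift$score < 0 | sift$score > 1)) stop("SIFT scores must be in [0, 1]")
  structure(list(genes = genes, known = known, sift = sift,
                 source_counts = table(genes$source)),
            class = "driver_kb")
}

#' Assign driver tiers to non-synonymous mutations
#'
#' Precedence: exact known (gene, aa_change) match or SIFT < 0.05 (strict)
#' gives high_confidence; otherwise a parseable residue within 5 (inclusive)
#' of any known mutation in the same gene gives putative; otherwise a gene
#' match gives unknown; genes outside the knowledge base are non_driver.
#' Tier assignment is a pure function of (record, knowledge base).
#'
#' @param muts data.frame with patient, clonality, gene, consequence,
#'   aa_change (non-synonymous records)
#' @param kb a [compile_driver_list()] knowledge base
#' @param proximity_aa residue-distance threshold for the putative tier
#' @return data.frame of driver calls with tier and reason columns; an
#'   attribute `position_matches` counts known-position (not exact-change)
#'   coincidences
#' @export
categorize_drivers <- function(muts, kb, proximity_aa = 5) {
  n <- nrow(muts)
  tier <- rep("non_driver", n)
  reason <- rep("no_gene_match", n)
  gene <- toupper(muts$gene)
  aa_pos <- parse_aa_position(muts$aa_change)
  position_matches <- 0L
  for (i in seq_len(n)) {
    if (!gene[i] %in% kb$genes$gene) next
    known_g <- kb$known[kb$known$gene == gene[i], , drop = FALSE]
    exact <- !is.na(muts$aa_change[i]) &&
      muts$aa_change[i] %in% known_g$aa_change
    sift_i <- kb$sift[kb$sift$gene == gene[i] &
                        kb$sift$aa_change %in% muts$aa_change[i], , drop = FALSE]
    sift_hit <- nrow(sift_i) > 0 && any(sift_i$score < 0.05)
    near <- !is.na(aa_pos[i]) && nrow(known_g) > 0 &&
      any(abs(known_g$aa_position - aa_pos[i]) <= proximity_aa)
    if (!exact && !is.na(aa_pos[i]) && aa_pos[i] %in% known_g$aa_position)
      position_matches <- position_matches + 1L
    if (exact) {
      tier[i] <- "high_confidence"
      reason[i] <- "known_mutation"
    } else if (sift_hit) {
      tier[i] <- "high_confidence"
      reason[i] <- "sift_lt_0.05"
    } else if (near) {
      tier[i] <- "putative"
      reason[i] <- "proximity_le_5"
    } else {
      if (!is.na(muts$aa_change[i]) && is.na(aa_pos[i]))
        warning("unparseable aa_change '", muts$aa_change[i], "' in ",
                gene[i], "; tier limited to unknown", call. = FALSE)
      tier[i] <- "unknown"
      reason[i] <- "gene_match_only"
    }
  }
  out <- cbind(muts, data.frame(tier = tier, reason = reason,
                                stringsAsFactors = FALSE))
  attr(out, "position_matches") <- position_matches
  out
}

#' Promote manually reviewed mutations to high confidence
#'
#' Mutations listed in the promotions fixture (gene, aa_change,
#' justification) are raised to high_confidence / manual_review regardless
#' of their knowledge-base status; promotions referencing mutations absent
#' from the cohort raise a warning and are ignored.
#'
#' @param calls driver calls from [categorize_drivers()]
#' @param promotions data.frame with gene, aa_change, justification
#' @return updated driver calls
#' @export
flag_manual_review <- function(calls, promotions) {
  if (is.null(promotions) || nrow(promotions) == 0) return(calls)
  for (k in seq_len(nrow(promotions))) {
    hit <- toupper(calls$gene) == toupper(promotions$gene[k]) &
      !is.na(calls$aa_change) & calls$aa_change == promotions$aa_change[k]
    if (!any(hit)) {
      warning("promotion for absent mutation ", promotions$gene[k], " ",
              promotions$aa_change[k], " ignored", call. = FALSE)
      next
    }
    calls$tier[hit] <- "high_confidence"
    calls$reason[hit] <- "manual_review"
  }
  calls
}

#' Summarize driver calls per patient
#'
#' Potential drivers are the tiers high_confidence, putative and unknown.
#' Returns the sorted driver table, per-patient counts (with mean and
#' range), totals, and the private-driver fraction.
#'
#' @param calls driver calls (after any promotions), including a clonality
#'   column with values common/private_central/private_peripheral
#' @return list with table, per_patient, n_total, n_private,
#'   private_fraction, mean_per_patient, range_per_patient
#' @export
summarize_drivers <- function(calls) {
  pot <- calls[calls$tier %in% c("high_confidence", "putative", "unknown"), ,
               drop = FALSE]
  if (nrow(pot) == 0) {
    return(list(table = pot, per_patient = integer(), n_total = 0L,
                n_private = 0L, private_fraction = NA_real_,
                mean_per_patient = NA_real_, range_per_patient = c(NA, NA)))
  }
  tier_rank <- match(pot$tier, DRIVER_TIERS)
  pot <- pot[order(pot$patient, tier_rank, pot$gene), , drop = FALSE]
  rownames(pot) <- NULL
  per_patient <- table(pot$patient)
  is_private <- startsWith(pot$clonality, "private")
  list(
    table = pot,
    per_patient = per_patient,
    n_total = nrow(pot),
    n_private = sum(is_private),
    private_fraction = mean(is_private),
    mean_per_patient = mean(per_patient),
    range_per_patient = range(per_patient)
  )
}

#' Path to a packaged fixture file
#'
#' @param file fixture filename under `inst/extdata`
#' @return absolute path
#' @export
ithexome_extdata <- function(file) {
  p <- system.file("extdata", file, package = "ithexome")
  if (p == "") stop("no packaged fixture named ", file)
  p
}
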