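# Orchestration: simulate -> filter -> classify -> drivers -> cnv -> report
# as one reproducible run. Rerunning with the same config and seed gives
# byte-identical tabular outputs; every output carries the config hash in
# its provenance header.

#' Default pipeline run configuration
#'
#' Collects the seed, generator plan, noise model, filter thresholds,
#' presence rule, driver knowledge-base paths and CNV parameters into a
#' single serializable object whose hash is embedded in every output
#' header.
#'
#' @param seed integer seed for the whole run
#' @param genome a [genome_model()]
#' @param plan a [cohort_plan()]
#' @param noise a [noise_params()]
#' @param filter a [filter_config()]
#' @param presence cross-interrogation rule (min_reads, min_depth)
#' @param n_reference reference panel size
#' @param kb_paths named list of driver fixture paths (genes, known, sift,
#'   promotions); defaults to the packaged synthetic knowledge base
#' @param clinical_path clinical characteristics fixture
#' @param cnv list of CNV-calling parameters (min_sd, min_bins)
#' @return list of class `run_config`
#' @export
default_config <- function(seed = 1, genome = genome_model(),
                           plan = cohort_plan(), noise = noise_params(),
                           filter = filter_config(),
                           presence = list(min_reads = 2, min_depth = 10),
                           n_reference = 10, kb_paths = NULL,
                           clinical_path = NULL,
                           cnv = list(min_sd = 2, min_bins = 5)) {
  if (is.null(kb_paths)) {
    kb_paths <- list(
      genes = ithexome_extdata("driver_genes_synthetic.tsv"),
      known = ithexome_extdata("known_mutations_synthetic.tsv"),
      sift = ithexome_extdata("sift_scores_synthetic.tsv"),
      promotions = ithexome_extdata("promotions_synthetic.tsv")
    )
  }
  if (is.null(clinical_path))
    clinical_path <- ithexome_extdata("clinical_table.tsv")
  structure(list(seed = seed, genome = genome, plan = plan, noise = noise,
                 filter = filter, presence = presence,
                 n_reference = n_reference, kb_paths = kb_paths,
                 clinical_path = clinical_path, cnv = cnv),
            class = "run_config")
}

write_tsv_artifact <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config$filter, config$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Run the full ITH analysis pipeline on a synthetic cohort
#'
#' Stage order: simulate, filter (both tumor regions per patient), classify,
#' drivers, cnv, report. Every stage writes its tabular artifact under
#' `outdir`; the returned report's numbers all reconcile with recounts over
#' those files. Any stage hard error aborts with the stage name.
#'
#' @param config a [default_config()]
#' @param outdir output directory (created if absent)
#' @return invisibly, the cohort report list (counts, summaries, file paths)
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  if (config$n_reference < 10)
    stop_ith("cnv", "reference panel size %d below the required 10",
             config$n_reference)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, paste0(...))

  sim <- simulate_cohort(config$genome, config$plan, config$noise,
                         seed = config$seed,
                         n_reference = config$n_reference)
  patients <- names(sim$variants)
  for (p in patients) {
    write_variant_table(sim$variants[[p]], fp("variants_", p, ".tsv"),
                        "tsv", config$filter)
  }
  write_tsv_artifact(sim$truth$mutations, fp("truth_mutations.tsv"), config)
  write_tsv_artifact(sim$truth$cnv, fp("truth_cnv.tsv"), config)

  decisions <- list()
  calls <- list()
  for (p in patients) {
    dc <- filter_region(sim$variants[[p]], "central", config$filter,
                        exons = sim$genome$exons)
    dp <- filter_region(sim$variants[[p]], "peripheral", config$filter,
                        exons = sim$genome$exons)
    decisions[[p]] <- rbind(dc, dp)
    calls[[p]] <- classify_cohort(sim$variants[[p]], dc, dp,
                                  pyro = sim$pyro[[p]],
                                  presence = config$presence)
  }
  decisions <- do.call(rbind, c(decisions, make.row.names = FALSE))
  calls <- do.call(rbind, c(calls, make.row.names = FALSE))
  write_tsv_artifact(decisions, fp("filter_decisions.tsv"), config)
  write_tsv_artifact(calls, fp("clonality.tsv"), config)

  ith <- summarize_ith(calls)
  write_tsv_artifact(ith$samples, fp("ith_samples.tsv"), config)
  write_tsv_artifact(ith$spectrum, fp("ith_spectrum.tsv"), config)
  write_tsv_artifact(ith$cpg, fp("ith_cpg.tsv"), config)

  kb <- compile_driver_list(config$kb_paths$genes, config$kb_paths$known,
                            config$kb_paths$sift)
  promotions <- utils::read.delim(config$kb_paths$promotions,
                                  comment.char = "#",
                                  stringsAsFactors = FALSE)
  nonsyn <- calls[calls$consequence %in% NONSYN_CONSEQUENCES, , drop = FALSE]
  drv_in <- data.frame(patient = nonsyn$patient, clonality = nonsyn$label,
                       gene = nonsyn$gene, consequence = nonsyn$consequence,
                       aa_change = nonsyn$aa_change, stringsAsFactors = FALSE)
  drv <- flag_manual_review(categorize_drivers(drv_in, kb), promotions)
  drv_summary <- summarize_drivers(drv)
  write_tsv_artifact(drv, fp("driver_calls.tsv"), config)

  model <- build_reference_model(sim$coverage$panel)
  cnv_ith <- list()
  for (p in patients) {
    trio <- config$plan$trios[config$plan$trios$patient == p, ]
    cov <- sim$coverage$patients[[p]]
    segsets <- list()
    for (r in REGIONS) {
      tc <- switch(r, normal = 1, central = trio$purity_central,
                   peripheral = trio$purity_peripheral)
      prof <- deviation_profile(cov[[r]], model)
      segs <- call_regions(prof, model, tumor_content = tc,
                           min_sd = config$cnv$min_sd,
                           min_bins = config$cnv$min_bins)
      segsets[[r]] <- segs
      write_segments(segs[, c("chrom", "start", "end",
                              "mean_deviation_pct", "call")],
                     fp("cnv_", p, "_", r), config$filter)
      sm <- smooth_median(prof)
      write_tsv_artifact(sm, fp("cnv_smoothed_", p, "_", r, ".tsv"), config)
    }
    disc <- compare_regions(segsets$central, segsets$peripheral)
    if (nrow(disc)) disc <- cbind(patient = p, disc)
    cnv_ith[[p]] <- disc
  }
  cnv_ith <- do.call(rbind, c(cnv_ith[vapply(cnv_ith, nrow, 1L) > 0],
                              make.row.names = FALSE))
  if (is.null(cnv_ith))
    cnv_ith <- data.frame(patient = character(), chrom = character(),
                          start = integer(), end = integer(),
                          call_central = character(),
                          call_peripheral = character(),
                          status = character(), stringsAsFactors = FALSE)
  write_tsv_artifact(cnv_ith, fp("cnv_ith.tsv"), config)

  clinical <- utils::read.delim(config$clinical_path, comment.char = "#",
                                stringsAsFactors = FALSE)
  clin_stats <- descriptive_stats(clinical, c("Diameter_cm", "Distance_cm"))
  write_tsv_artifact(clin_stats, fp("clinical_descriptives.tsv"), config)

  report <- list(
    n_candidates = vapply(patients, function(p)
      nrow(sim$variants[[p]]), integer(1)),
    n_pass = table(decisions$region[decisions$passed]),
    clonality_counts = table(calls$label),
    ith = ith$samples,
    drivers = drv_summary,
    cnv_ith = cnv_ith,
    clinical = clin_stats,
    outdir = outdir,
    config_hash = config_hash(config$filter)
  )
  invisible(report)
}

#' Descriptive statistics of a clinical table
#'
#' Arithmetic mean (rounded half-up to one decimal) and min-max range of
#' the requested numeric columns; a non-numeric cell is a hard error.
#'
#' @param clinical data.frame of the clinical characteristics table
#' @param columns character vector of numeric column names
#' @return data.frame with column, mean, min, max
#' @export
descriptive_stats <- function(clinical, columns) {
  missing_cols <- setdiff(columns, names(clinical))
  if (length(missing_cols))
    stop("clinical table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- lapply(columns, function(col) {
    v <- clinical[[col]]
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num)))
      stop("non-numeric cell in clinical column '", col, "'")
    data.frame(column = col, mean = round_half_up(mean(num), 1),
               min = min(num), max = max(num), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Overlay the three samples' smoothed CNV deviation tracks
#'
#' One panel per chromosome with the non-tumor, central and peripheral
#' smoothed deviation tracks and +/-50% guide lines (the pure heterozygous
#' duplication/deletion expectations).
#'
#' @param profiles named list of [deviation_profile()]s for normal, central
#'   and peripheral
#' @param window_mb smoothing window in megabases
#' @param main plot title
#' @return invisibly, the smoothed tracks
#' @export
plot_cnv_overlay <- function(profiles, window_mb = 5, main = "") {
  sm <- lapply(profiles, smooth_median, window_mb = window_mb)
  chroms <- unique(sm[[1]]$chrom)
  cols <- c(normal = "black", central = "red", peripheral = "blue")
  old <- graphics::par(mfrow = c(length(chroms), 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (chrom in chroms) {
    first <- TRUE
    for (r in names(sm)) {
      s <- sm[[r]][sm[[r]]$chrom == chrom, ]
      x <- (s$start + s$end) / 2e6
      if (first) {
        plot(x, s$deviation_pct, type = "l", col = cols[[r]],
             ylim = c(-80, 80), xlab = "Mb", ylab = "deviation (%)",
             main = paste(main, chrom))
        graphics::abline(h = c(-50, 50), lty = 3)
        first <- FALSE
      } else {
        graphics::lines(x, s$deviation_pct, col = cols[[r]])
      }
    }
  }
  invisible(sm)
}
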