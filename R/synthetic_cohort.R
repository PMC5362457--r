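# Synthetic multiregion cohort generator.
#
# Emulates the study design: per patient a trio of exomes (non-tumor,
# central tumor, peripheral tumor), with planted common/private somatic
# mutations under purity dilution, a C>T/G>A-dominated substitution spectrum
# with CpG enrichment (optionally a C>A/G>T-dominated hypermutator region),
# planted copy-number segments in binned coverage, a reference coverage
# panel sharing the capture bias field, and noisy orthogonal AF
# re-measurements for the validation step. Every cohort carries its full
# ground truth so downstream stages can be scored without re-running the
# generator.

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

SUBSTITUTION_CLASSES <- c("C>T/G>A", "C>A/G>T", "C>G/G>C",
                          "T>C/A>G", "T>A/A>T", "T>G/A>C")

# pyrimidine-strand (ref, alt) for each paired class
CLASS_PYR <- list(
  "C>T/G>A" = c("C", "T"), "C>A/G>T" = c("C", "A"), "C>G/G>C" = c("C", "G"),
  "T>C/A>G" = c("T", "C"), "T>A/A>T" = c("T", "A"), "T>G/A>C" = c("T", "G")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Synthetic genome model
#'
#' A small multi-chromosome genome with a constant-width coverage-bin tiling
#' and regularly spaced exon intervals; stands in for a real reference build
#' at a scale where tests run in seconds. Trinucleotide contexts are
#' assigned at mutation-planting time, so no base-level sequence is stored.
#'
#' @param n_chrom number of chromosomes
#' @param chrom_length length of each chromosome (bp)
#' @param bin_bp coverage bin width (bp)
#' @param exon_bp exon width (bp)
#' @param exon_spacing distance between consecutive exon starts (bp)
#' @return list of class `genome_model` with chromosomes, bins and exons
#' @export
genome_model <- function(n_chrom = 3, chrom_length = 60e6, bin_bp = 1e5,
                         exon_bp = 300, exon_spacing = 1e4) {
  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = rep(as.numeric(chrom_length), n_chrom),
                       stringsAsFactors = FALSE)
  bins <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    starts <- seq(1, chrom_length, by = bin_bp)
    data.frame(chrom = chroms$name[i], start = as.integer(starts),
               end = as.integer(pmin(starts + bin_bp - 1, chrom_length)),
               stringsAsFactors = FALSE)
  }))
  exons <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    starts <- seq(1, chrom_length - exon_bp, by = exon_spacing)
    data.frame(chrom = chroms$name[i], start = as.integer(starts),
               end = as.integer(starts + exon_bp - 1),
               stringsAsFactors = FALSE)
  }))
  structure(list(chromosomes = chroms, bins = bins, exons = exons,
                 bin_bp = bin_bp), class = "genome_model")
}

#' Substitution-spectrum parameters
#'
#' Defaults reflect the observed cohort spectrum: 48% of point mutations in
#' the paired class C>T/G>A, with 45% of those at CpG sites. Hypermutator
#' mode switches the dominant class to C>A/G>T, emulating the
#' mismatch-repair-deficient tumor region.
#'
#' @param weights named numeric of length 6 over the paired substitution
#'   classes; must sum to 1
#' @param cpg_enrichment fraction of C>T/G>A events placed at CpG sites
#' @param hypermutator logical; use the C>A/G>T-dominated weights
#' @return list of class `spectrum_params`
#' @export
spectrum_params <- function(weights = NULL, cpg_enrichment = 0.45,
                            hypermutator = FALSE) {
  if (is.null(weights)) {
    weights <- if (hypermutator) {
      c("C>T/G>A" = 0.15, "C>A/G>T" = 0.45, "C>G/G>C" = 0.08,
        "T>C/A>G" = 0.18, "T>A/A>T" = 0.07, "T>G/A>C" = 0.07)
    } else {
      c("C>T/G>A" = 0.48, "C>A/G>T" = 0.12, "C>G/G>C" = 0.08,
        "T>C/A>G" = 0.18, "T>A/A>T" = 0.07, "T>G/A>C" = 0.07)
    }
  }
  if (!setequal(names(weights), SUBSTITUTION_CLASSES))
    stop("weights must be named by the six paired substitution classes")
  if (abs(sum(weights) - 1) > 1e-8) stop("substitution weights must sum to 1")
  if (cpg_enrichment < 0 || cpg_enrichment > 1)
    stop("cpg_enrichment must be in [0, 1]")
  structure(list(weights = weights[SUBSTITUTION_CLASSES],
                 cpg_enrichment = cpg_enrichment,
                 hypermutator = hypermutator),
            class = "spectrum_params")
}

#' Sequencing-noise parameters
#'
#' `mean_depth` defaults to the cohort's mean target coverage of 109.
#' Dispersions are extra-Poisson negative-binomial dispersions
#' (var = mu + dispersion * mu^2); zero is the noise-free limit in which
#' draws equal their means exactly. `coverage_dispersion` applies to binned
#' read counts (many reads per 100-kb bin, so a small value), and
#' `depth_dispersion` to per-site depths. `pyro_sd` is the SD of the
#' truncated-Gaussian orthogonal AF re-measurement.
#'
#' @param mean_depth target per-site coverage
#' @param depth_dispersion NB dispersion of per-site depths
#' @param coverage_dispersion NB dispersion of per-bin read counts
#' @param sequencing_error_rate per-base rate of spurious variant reads
#' @param pyro_sd SD of the orthogonal AF measurement noise
#' @param read_length read length used to convert depth to per-bin counts
#' @return list of class `noise_params`
#' @export
noise_params <- function(mean_depth = 109, depth_dispersion = 0.01,
                         coverage_dispersion = 0.001,
                         sequencing_error_rate = 0.001, pyro_sd = 0.02,
                         read_length = 100) {
  p <- list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
            coverage_dispersion = coverage_dispersion,
            sequencing_error_rate = sequencing_error_rate,
            pyro_sd = pyro_sd, read_length = read_length)
  if (any(unlist(p) < 0)) stop("noise parameters must be non-negative")
  structure(p, class = "noise_params")
}

#' Cohort plan: the planted truth for a synthetic multiregion cohort
#'
#' Defaults mirror the study's magnitudes: four patient trios, ~24-41 common
#' non-synonymous mutations per sample, 0-14 private mutations, tumor purity
#' 0.35-0.55 with the peripheral sample slightly purer than the central one,
#' planted heterozygous duplications/deletions, and one hypermutator
#' peripheral region (patient 4) whose private mutations follow the
#' C>A/G>T-dominated spectrum.
#'
#' @param trios data.frame with patient, purity_central, purity_peripheral,
#'   n_common_nonsyn, n_common_silent, n_private_central,
#'   n_private_peripheral, hypermutator_peripheral
#' @param cnv data.frame with patient, chrom, start, end, copy_number and
#'   region in both/central_only/peripheral_only
#' @param drivers data.frame of planted driver mutations (patient, gene,
#'   aa_change, consequence, clonality); may be empty
#' @param spectrum default [spectrum_params()] for non-hypermutator samples
#' @return list of class `cohort_plan`
#' @export
cohort_plan <- function(trios = NULL, cnv = NULL, drivers = NULL,
                        spectrum = spectrum_params()) {
  if (is.null(trios)) {
    trios <- data.frame(
      patient = paste0("P", 1:4),
      purity_central = c(0.40, 0.45, 0.40, 0.35),
      purity_peripheral = c(0.50, 0.55, 0.45, 0.50),
      n_common_nonsyn = c(33, 36, 31, 10),
      n_common_silent = c(13, 12, 14, 9),
      n_private_central = c(2, 3, 3, 1),
      n_private_peripheral = c(2, 1, 0, 14),
      hypermutator_peripheral = c(FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(cnv)) {
    cnv <- data.frame(
      patient = c("P1", "P1", "P2", "P3", "P4", "P4"),
      chrom = c("chr1", "chr2", "chr1", "chr2", "chr1", "chr3"),
      start = c(10e6 + 1, 30e6 + 1, 5e6 + 1, 10e6 + 1, 20e6 + 1, 1),
      end = c(25e6, 45e6, 20e6, 22e6, 35e6, 50e6),
      copy_number = c(3L, 1L, 1L, 3L, 3L, 3L),
      region = c("both", "both", "both", "both", "both", "peripheral_only"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(drivers)) {
    drivers <- data.frame(
      patient = c("P1", "P1", "P2", "P3", "P4", "P4"),
      gene = c("KRAS", "SRC", "EPHA2", "IDH1", "BAP1", "MSH6"),
      aa_change = c("Gly12Asp", "Thr524HisfsTer52", "Arg861Cys", "Arg132Cys",
                    "Asn133GlnfsTer10", "Arg33Cys"),
      consequence = c("missense", "frameshift", "missense", "missense",
                      "frameshift", "missense"),
      clonality = c("common", "common", "common", "common", "common",
                    "private_peripheral"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(trios$purity_central > 0), all(trios$purity_central <= 1),
            all(trios$purity_peripheral > 0), all(trios$purity_peripheral <= 1))
  if (!all(cnv$copy_number %in% 0:4))
    stop("planted copy_number must be in {0,1,2,3,4}")
  structure(list(trios = trios, cnv = cnv, drivers = drivers,
                 spectrum = spectrum), class = "cohort_plan")
}

#' Expected variant allele frequency under purity dilution
#'
#' For a mutation at cancer-cell fraction `ccf` on `multiplicity` of
#' `local_cn` tumor copies in a sample of tumor purity `purity` (normal
#' cells diploid):
#' `purity * ccf * multiplicity / (purity * local_cn + (1 - purity) * 2)`.
#'
#' @param purity tumor cell fraction in (0, 1]
#' @param ccf cancer cell fraction in (0, 1]
#' @param local_cn local tumor copy number (>= 1)
#' @param multiplicity mutated copies (<= local_cn)
#' @return expected VAF
#' @export
expected_vaf <- function(purity, ccf = 1, local_cn = 2, multiplicity = 1) {
  if (any(local_cn < 1)) stop("local_cn must be >= 1")
  if (any(multiplicity > local_cn)) stop("multiplicity must be <= local_cn")
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(ccf <= 0 | ccf > 1)) stop("ccf must be in (0, 1]")
  purity * ccf * multiplicity / (purity * local_cn + (1 - purity) * 2)
}

#' Draw substitutions from a spectrum
#'
#' Samples paired substitution classes by weight, picks the pyrimidine or
#' purine strand representation with equal probability, and writes a
#' plus-strand trinucleotide context centered on the reference base; C>T/G>A
#' events are placed at CpG sites with probability `cpg_enrichment`.
#'
#' @param n number of substitutions
#' @param spectrum a [spectrum_params()] object
#' @return data.frame with class, ref, alt, context
#' @export
simulate_substitutions <- function(n, spectrum = spectrum_params()) {
  cls <- sample(SUBSTITUTION_CLASSES, n, replace = TRUE,
                prob = spectrum$weights)
  pyr <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ref <- alt <- up <- down <- character(n)
  at_cpg <- stats::runif(n) < spectrum$cpg_enrichment
  for (i in seq_len(n)) {
    ra <- CLASS_PYR[[cls[i]]]
    if (!pyr[i]) ra <- unname(COMPLEMENT[ra])
    ref[i] <- ra[1]
    alt[i] <- ra[2]
    if (cls[i] == "C>T/G>A" && at_cpg[i]) {
      if (pyr[i]) { # mutated C with G 3'
        up[i] <- sample(c("A", "C", "G", "T"), 1)
        down[i] <- "G"
      } else {      # mutated G with C 5'
        up[i] <- "C"
        down[i] <- sample(c("A", "C", "G", "T"), 1)
      }
    } else if (cls[i] == "C>T/G>A") {
      # keep non-CpG C>T/G>A off CpG so the enrichment is exact
      if (pyr[i]) {
        up[i] <- sample(c("A", "C", "G", "T"), 1)
        down[i] <- sample(c("A", "C", "T"), 1)
      } else {
        up[i] <- sample(c("A", "G", "T"), 1)
        down[i] <- sample(c("A", "C", "G", "T"), 1)
      }
    } else {
      up[i] <- sample(c("A", "C", "G", "T"), 1)
      down[i] <- sample(c("A", "C", "G", "T"), 1)
    }
  }
  data.frame(class = cls, ref = ref, alt = alt,
             context = paste0(up, ref, down), stringsAsFactors = FALSE)
}

#' Orthogonal allele-frequency re-measurement
#'
#' Gaussian perturbation of the true AF, truncated to \[0, 1\]; models a
#' per-site pyrosequencing-style assay. `pyro_sd = 0` is the identity.
#'
#' @param true_af true allele fraction(s) in \[0, 1\]
#' @param pyro_sd measurement SD
#' @return measured fraction(s) in \[0, 1\]
#' @export
simulate_orthogonal_af <- function(true_af, pyro_sd = 0.02) {
  if (any(true_af < 0 | true_af > 1)) stop("true_af must be in [0, 1]")
  if (pyro_sd <= 0) return(true_af)
  pmin(1, pmax(0, stats::rnorm(length(true_af), true_af, pyro_sd)))
}

#' Simulate a per-bin coverage profile
#'
#' Expected count in a bin is `bias * bin_mean * f` where the copy-number
#' factor is `f = purity * (cn / 2) + (1 - purity)` over planted CNV bins
#' and 1 elsewhere; counts are negative-binomial with the coverage
#' dispersion (exactly the mean when the dispersion is zero).
#'
#' @param genome a [genome_model()]
#' @param noise a [noise_params()]
#' @param bias per-bin multiplicative bias field (default flat 1); shared
#'   across all samples of a cohort to emulate capture bias
#' @param cnv optional data.frame chrom/start/end/copy_number of events
#'   carried by this sample
#' @param purity tumor purity of the sample (1 for normal/reference)
#' @return data.frame chrom, start, end, count
#' @export
simulate_coverage <- function(genome, noise = noise_params(), bias = NULL,
                              cnv = NULL, purity = 1) {
  bins <- genome$bins
  nb <- nrow(bins)
  if (is.null(bias)) bias <- rep(1, nb)
  stopifnot(length(bias) == nb)
  bin_mean <- noise$mean_depth * genome$bin_bp / noise$read_length
  factor <- rep(1, nb)
  if (!is.null(cnv) && nrow(cnv)) {
    mid <- (bins$start + bins$end) / 2
    for (k in seq_len(nrow(cnv))) {
      hit <- bins$chrom == cnv$chrom[k] & mid >= cnv$start[k] & mid <= cnv$end[k]
      factor[hit] <- purity * (cnv$copy_number[k] / 2) + (1 - purity)
    }
  }
  mu <- bias * bin_mean * factor
  counts <- numeric(nb)
  if (noise$coverage_dispersion <= 0) {
    counts <- mu
  } else {
    counts <- stats::rnbinom(nb, mu = mu, size = 1 / noise$coverage_dispersion)
  }
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             count = counts, stringsAsFactors = FALSE)
}

# Map sampled exonic site indices to (chrom, pos).
exonic_sites <- function(genome, n, used = integer()) {
  ex <- genome$exons
  widths <- ex$end - ex$start + 1
  total <- sum(widths)
  if (n + length(used) > total)
    stop("requested mutation count exceeds available exome sites")
  pool <- setdiff(seq_len(total), used)
  idx <- sample(pool, n)
  cum <- cumsum(widths)
  exon_i <- findInterval(idx - 1, cum) + 1
  offset <- idx - c(0, cum)[exon_i] - 1
  list(idx = idx,
       sites = data.frame(chrom = ex$chrom[exon_i],
                          pos = as.integer(ex$start[exon_i] + offset),
                          stringsAsFactors = FALSE))
}

local_cn_at <- function(cnv, patient, region, chrom, pos) {
  cn <- rep(2L, length(pos))
  if (is.null(cnv) || !nrow(cnv)) return(cn)
  keep <- cnv$patient == patient &
    (cnv$region == "both" | cnv$region == paste0(region, "_only"))
  cnv <- cnv[keep, , drop = FALSE]
  for (k in seq_len(nrow(cnv))) {
    hit <- chrom == cnv$chrom[k] & pos >= cnv$start[k] & pos <= cnv$end[k]
    cn[hit] <- cnv$copy_number[k]
  }
  cn
}

sim_site_evidence <- function(n, true_af, noise) {
  depth <- round(rdepth(n, noise$mean_depth, noise$depth_dispersion))
  real <- stats::rbinom(n, depth, true_af)
  spurious <- if (noise$sequencing_error_rate > 0) {
    stats::rpois(n, depth * noise$sequencing_error_rate)
  } else rep(0L, n)
  list(depth = as.integer(depth),
       var = as.integer(pmin(depth, real + spurious)),
       mapq = pmin(93, pmax(0, round(stats::rnorm(n, 60, 3)))))
}

plant_trio <- function(genome, plan, noise, trio, used_sites) {
  clonalities <- c(rep("common", trio$n_common_nonsyn + trio$n_common_silent),
                   rep("private_central", trio$n_private_central),
                   rep("private_peripheral", trio$n_private_peripheral))
  silent <- c(rep(FALSE, trio$n_common_nonsyn), rep(TRUE, trio$n_common_silent),
              rep(FALSE, trio$n_private_central + trio$n_private_peripheral))
  n <- length(clonalities)
  picked <- exonic_sites(genome, n, used_sites)
  sites <- picked$sites

  hyper <- spectrum_params(hypermutator = TRUE,
                           cpg_enrichment = plan$spectrum$cpg_enrichment)
  use_hyper <- trio$hypermutator_peripheral &
    clonalities == "private_peripheral"
  subs <- simulate_substitutions(n, plan$spectrum)
  if (any(use_hyper)) {
    subs[use_hyper, ] <- simulate_substitutions(sum(use_hyper), hyper)
  }

  consequence <- ifelse(silent, "silent",
                        sample(c("missense", "nonsense", "splice_site"), n,
                               replace = TRUE, prob = c(0.85, 0.08, 0.07)))
  aa_change <- ifelse(
    consequence == "missense",
    paste0(sample(AA3, n, replace = TRUE), sample(800, n, replace = TRUE),
           sample(AA3, n, replace = TRUE)),
    NA_character_)
  gene <- sprintf("G%s_%03d", trio$patient, seq_len(n))
  ref <- subs$ref
  alt <- subs$alt
  context <- subs$context

  # planted driver mutations override gene/aa/consequence (and become
  # indels where the driver is a frameshift)
  drv <- plan$drivers[plan$drivers$patient == trio$patient, , drop = FALSE]
  if (nrow(drv)) {
    taken <- integer()
    for (k in seq_len(nrow(drv))) {
      cand <- setdiff(which(clonalities == drv$clonality[k] & !silent), taken)
      if (!length(cand))
        stop("no free slot to plant driver ", drv$gene[k], " (",
             drv$clonality[k], ") in trio ", trio$patient)
      slot <- cand[1]
      taken <- c(taken, slot)
      gene[slot] <- drv$gene[k]
      aa_change[slot] <- drv$aa_change[k]
      consequence[slot] <- drv$consequence[k]
      if (drv$consequence[k] %in% INDEL_CONSEQUENCES) {
        ref[slot] <- "AT"
        alt[slot] <- "A"
        context[slot] <- NA_character_
      }
    }
  }

  df <- data.frame(
    patient = trio$patient, chrom = sites$chrom, pos = sites$pos,
    ref = ref, alt = alt, gene = gene, consequence = consequence,
    aa_change = aa_change, context = context, stringsAsFactors = FALSE
  )
  purity <- c(central = trio$purity_central, peripheral = trio$purity_peripheral)
  true_af <- list()
  for (r in TUMOR_REGIONS) {
    carrier <- clonalities %in% c("common", paste0("private_", r))
    cn <- local_cn_at(plan$cnv, trio$patient, r, df$chrom, df$pos)
    af <- ifelse(carrier & cn >= 1,
                 expected_vaf(purity[[r]], 1, pmax(cn, 1), 1), 0)
    true_af[[r]] <- af
    ev <- sim_site_evidence(n, af, noise)
    df[[paste0(r, "_depth")]] <- ev$depth
    df[[paste0(r, "_var")]] <- ev$var
    df[[paste0(r, "_mapq")]] <- ev$mapq
  }
  evn <- sim_site_evidence(n, 0, noise)
  df$normal_depth <- evn$depth
  df$normal_var <- evn$var
  df$normal_mapq <- evn$mapq
  df <- df[, VARIANT_COLUMNS]

  pyro <- data.frame(
    patient = trio$patient, chrom = df$chrom, pos = df$pos,
    af_central = simulate_orthogonal_af(true_af$central, noise$pyro_sd),
    af_peripheral = simulate_orthogonal_af(true_af$peripheral, noise$pyro_sd),
    af_normal = simulate_orthogonal_af(rep(0, n), noise$pyro_sd),
    stringsAsFactors = FALSE
  )
  truth <- cbind(df[, c("patient", "chrom", "pos", "ref", "alt", "gene",
                        "consequence", "aa_change", "context")],
                 data.frame(clonality = clonalities, ccf = 1,
                            true_af_central = true_af$central,
                            true_af_peripheral = true_af$peripheral,
                            stringsAsFactors = FALSE))
  ord <- order(df$chrom, df$pos)
  list(variants = df[ord, ], pyro = pyro[ord, ], truth = truth[ord, ],
       used = picked$idx)
}

#' Simulate a full multiregion cohort with ground truth
#'
#' Generates, per patient trio, a candidate somatic variant table with
#' per-sample evidence, orthogonal AF re-measurements for every planted
#' site, and per-sample binned coverage profiles (normal, central,
#' peripheral) plus a reference coverage panel sharing the cohort's capture
#' bias field. Identical seeds give identical outputs.
#'
#' @param genome a [genome_model()]
#' @param plan a [cohort_plan()]
#' @param noise a [noise_params()]
#' @param seed integer seed (required; the generator owns its RNG stream)
#' @param n_reference reference panel size (>= 10)
#' @return list with genome, plan, noise, truth, variants (per patient),
#'   pyro (per patient), coverage (panel + per-patient trios), bias
#' @export
simulate_cohort <- function(genome = genome_model(), plan = cohort_plan(),
                            noise = noise_params(), seed, n_reference = 10) {
  if (missing(seed)) stop("simulate_cohort requires an explicit seed")
  if (n_reference < 10)
    stop("reference panel size must be at least 10 samples")
  set.seed(seed)
  nb <- nrow(genome$bins)
  sdlog <- 0.1
  bias <- stats::rlnorm(nb, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  variants <- list()
  pyro <- list()
  truth_mut <- list()
  used <- integer()
  for (i in seq_len(nrow(plan$trios))) {
    trio <- plan$trios[i, ]
    res <- plant_trio(genome, plan, noise, trio, used)
    used <- c(used, res$used)
    variants[[trio$patient]] <- res$variants
    pyro[[trio$patient]] <- res$pyro
    truth_mut[[trio$patient]] <- res$truth
  }

  panel <- lapply(seq_len(n_reference), function(i)
    simulate_coverage(genome, noise, bias))
  names(panel) <- sprintf("REF%02d", seq_len(n_reference))

  patients_cov <- list()
  for (i in seq_len(nrow(plan$trios))) {
    trio <- plan$trios[i, ]
    cnv_p <- plan$cnv[plan$cnv$patient == trio$patient, , drop = FALSE]
    cnv_for <- function(region) {
      keep <- cnv_p$region == "both" | cnv_p$region == paste0(region, "_only")
      cnv_p[keep, , drop = FALSE]
    }
    patients_cov[[trio$patient]] <- list(
      normal = simulate_coverage(genome, noise, bias),
      central = simulate_coverage(genome, noise, bias, cnv_for("central"),
                                  trio$purity_central),
      peripheral = simulate_coverage(genome, noise, bias, cnv_for("peripheral"),
                                     trio$purity_peripheral)
    )
  }

  truth <- list(mutations = do.call(rbind, c(truth_mut, make.row.names = FALSE)),
                cnv = plan$cnv, trios = plan$trios)
  structure(list(genome = genome, plan = plan, noise = noise, seed = seed,
                 truth = truth, variants = variants, pyro = pyro,
                 coverage = list(panel = panel, patients = patients_cov),
                 bias = bias),
            class = "ith_cohort")
}
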