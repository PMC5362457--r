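# Panel-of-normals read-depth CNV calling with tumor-purity adjustment.
#
# A reference panel (>= 10 samples) scaled to a common total count gives
# per-bin expected coverage mean and SD, absorbing capture/GC/library
# biases. A sample's percent deviation from expectation is screened at
# >= 2 SD per bin; runs of concordant bins become segments, interpreted
# against biologically possible copy states: a clonal event of copy number
# cn at tumor content t shifts coverage by 100 * t * (cn - 2) / 2 percent.
# Germline calling is the t = 1 case. Median smoothing over 5-Mb windows is
# presentation-only; calling operates on unsmoothed deviations.

CN_CALLS <- c(`0` = "hom_del", `1` = "het_del", `3` = "het_dup",
              `4` = "hom_dup")

#' Build the expected-coverage model from a reference panel
#'
#' Each profile is scaled to the panel's mean total count, then per-bin mean
#' and SD are taken across the panel. Bins with near-zero panel coverage or
#' zero SD (degenerate panel) are masked.
#'
#' @param panel list of >= 10 coverage data.frames (chrom, start, end,
#'   count) on an identical bin tiling
#' @param min_panel minimum panel size
#' @param mean_floor_frac bins with mean below this fraction of the median
#'   bin mean are masked
#' @return list of class `reference_coverage_model`
#' @export
build_reference_model <- function(panel, min_panel = 10,
                                  mean_floor_frac = 0.1) {
  if (length(panel) < min_panel)
    stop_ith("cnv", "reference panel must hold at least %d samples (got %d)",
             min_panel, length(panel))
  bins <- panel[[1]][, c("chrom", "start", "end")]
  for (p in panel) {
    if (nrow(p) != nrow(bins) || !all(p$chrom == bins$chrom) ||
        !all(p$start == bins$start) || !all(p$end == bins$end))
      stop_ith("cnv", "reference panel bin tilings do not match")
  }
  totals <- vapply(panel, function(p) sum(p$count), numeric(1))
  target <- mean(totals)
  mat <- vapply(seq_along(panel),
                function(i) panel[[i]]$count / totals[i] * target,
                numeric(nrow(bins)))
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  mask_mean <- m < mean_floor_frac * stats::median(m)
  mask <- mask_mean | s == 0 | !is.finite(s)
  if (any(s == 0 & m > 0))
    warning("degenerate panel: zero coverage SD in ", sum(s == 0),
            " bin(s); masked", call. = FALSE)
  structure(list(bins = bins, expected_mean = m, expected_sd = s,
                 mask = mask, mask_mean = mask_mean,
                 n_reference = length(panel), target_total = target),
            class = "reference_coverage_model")
}

#' Per-bin percent deviation of a sample from the expected coverage
#'
#' The sample is scaled to the model's target total (correcting for total
#' read count) and then recentered by the median per-bin ratio to the
#' expected mean, so that large copy-number events cannot drag the diploid
#' baseline off zero through their contribution to the total count (the
#' diploid majority of bins defines the baseline). Deviation is
#' `100 * (normalized / expected_mean - 1)` and the z-score
#' `(normalized - expected_mean) / expected_sd`. Bins masked for low panel
#' coverage propagate NA deviations; bins masked for zero panel SD keep
#' their deviation but carry NA z-scores (unusable for calling).
#'
#' @param sample coverage data.frame on the model's tiling
#' @param model a [build_reference_model()]
#' @return data.frame chrom, start, end, normalized, deviation_pct, z
#' @export
deviation_profile <- function(sample, model) {
  bins <- model$bins
  if (nrow(sample) != nrow(bins) || !all(sample$chrom == bins$chrom) ||
      !all(sample$start == bins$start))
    stop_ith("cnv", "sample bin tiling does not match the reference model")
  norm <- sample$count / sum(sample$count) * model$target_total
  ratio <- norm / model$expected_mean
  baseline <- stats::median(ratio[!model$mask_mean], na.rm = TRUE)
  if (is.finite(baseline) && baseline > 0) norm <- norm / baseline
  dev <- 100 * (norm / model$expected_mean - 1)
  z <- (norm - model$expected_mean) / model$expected_sd
  dev[model$mask_mean] <- NA_real_
  z[model$mask] <- NA_real_
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             normalized = norm, deviation_pct = dev, z = z,
             stringsAsFactors = FALSE)
}

#' Expected percent coverage deviation of a clonal copy-number state
#'
#' `100 * tumor_content * (copy_number - 2) / 2`: +50% for a heterozygous
#' duplication in pure material, +30% at 60% tumor content, -50% for a
#' heterozygous deletion. Linear in tumor content and odd around the
#' diploid state.
#'
#' @param copy_number integer copy state in {0, 1, 2, 3, 4} (vectorized)
#' @param tumor_content tumor cell fraction in (0, 1]
#' @return signed percent deviation
#' @export
expected_deviation <- function(copy_number, tumor_content) {
  if (any(!copy_number %in% 0:4))
    stop("copy_number must be in {0, 1, 2, 3, 4}")
  if (any(tumor_content <= 0 | tumor_content > 1))
    stop("tumor_content must be in (0, 1]")
  100 * tumor_content * (copy_number - 2) / 2
}

#' Interpret an observed deviation against possible copy states
#'
#' If exactly one clonal state (copy number at the sample's full tumor
#' content) matches the observed deviation within the concordance
#' tolerance, that state is called. If none does, every mathematically
#' consistent interpretation at a smaller clonal fraction is listed --
#' subclonal events in the tumor and events carried by the non-tumor
#' fraction -- and the call is ambiguous. With no consistent interpretation
#' the call is none.
#'
#' @param deviation_pct observed mean percent deviation
#' @param tumor_content tumor cell fraction in (0, 1]; 1 for germline
#' @param tol_pct concordance tolerance in percentage points (strict)
#' @return list with call and an interpretations data.frame (copy_number,
#'   fraction, origin, expected_deviation_pct)
#' @export
interpret_deviation <- function(deviation_pct, tumor_content, tol_pct = 10) {
  states <- c(0L, 1L, 3L, 4L)
  interp <- data.frame(copy_number = integer(), fraction = numeric(),
                       origin = character(),
                       expected_deviation_pct = numeric(),
                       stringsAsFactors = FALSE)
  clonal_dev <- expected_deviation(states, tumor_content)
  clonal_fit <- abs(deviation_pct - clonal_dev) < tol_pct
  if (any(clonal_fit)) {
    interp <- data.frame(copy_number = states[clonal_fit],
                         fraction = tumor_content, origin = "tumor_clonal",
                         expected_deviation_pct = clonal_dev[clonal_fit],
                         stringsAsFactors = FALSE)
    call <- if (sum(clonal_fit) == 1)
      unname(CN_CALLS[as.character(states[clonal_fit])]) else "ambiguous"
    return(list(call = call, interpretations = interp))
  }
  for (cn in states) {
    f <- 2 * deviation_pct / (100 * (cn - 2))
    if (!is.finite(f) || f <= 0 || f > 1) next
    if (f < tumor_content) {
      interp <- rbind(interp, data.frame(
        copy_number = cn, fraction = f, origin = "tumor_subclonal",
        expected_deviation_pct = deviation_pct, stringsAsFactors = FALSE))
    }
    if (f <= 1 - tumor_content + 1e-9) {
      interp <- rbind(interp, data.frame(
        copy_number = cn, fraction = f, origin = "non_tumor",
        expected_deviation_pct = deviation_pct, stringsAsFactors = FALSE))
    }
  }
  call <- if (nrow(interp) == 0) "none" else "ambiguous"
  list(call = call, interpretations = interp)
}

#' Call copy-number segments from a deviation profile
#'
#' A maximal run of at least `min_bins` consecutive bins, each deviating by
#' at least `min_sd` standard deviations from the model mean with a
#' consistent sign, forms a segment; each segment's mean deviation is
#' interpreted via [interpret_deviation()] at the sample's tumor content.
#' The default concordance tolerance couples to panel noise:
#' `max(10, mean(100 * min_sd * sd / mean))` over the segment's bins.
#'
#' @param profile a [deviation_profile()]
#' @param model the reference model the profile was computed against
#' @param tumor_content tumor cell fraction; must be given for tumor
#'   samples (use 1 for germline calling)
#' @param min_sd per-bin z-score threshold
#' @param min_bins minimum run length
#' @param concordance_tol_pct fixed tolerance overriding the default
#' @return data.frame of segments with call, mean_deviation_pct, n_bins and
#'   an `interpretations` list-column
#' @export
call_regions <- function(profile, model, tumor_content, min_sd = 2,
                         min_bins = 5, concordance_tol_pct = NULL) {
  if (missing(tumor_content) || is.null(tumor_content) || is.na(tumor_content))
    stop_ith("cnv", "tumor_content must be set (1 for germline calling)")
  n <- nrow(profile)
  exceed <- !is.na(profile$z) & abs(profile$z) >= min_sd
  sgn <- sign(profile$deviation_pct)
  newrun <- rep(TRUE, n)
  if (n > 1) {
    same <- profile$chrom[-1] == profile$chrom[-n] &
      exceed[-1] & exceed[-n] & sgn[-1] == sgn[-n]
    newrun[-1] <- !same
  }
  run_id <- cumsum(newrun)
  segs <- list()
  for (id in unique(run_id[exceed])) {
    idx <- which(run_id == id & exceed)
    if (length(idx) < min_bins) next
    mean_dev <- mean(profile$deviation_pct[idx])
    tol <- concordance_tol_pct %||%
      max(10, mean(100 * min_sd * model$expected_sd[idx] /
                     model$expected_mean[idx]))
    it <- interpret_deviation(mean_dev, tumor_content, tol)
    segs[[length(segs) + 1]] <- data.frame(
      chrom = profile$chrom[idx[1]], start = profile$start[idx[1]],
      end = profile$end[idx[length(idx)]], n_bins = length(idx),
      mean_deviation_pct = mean_dev, call = it$call,
      stringsAsFactors = FALSE)
    segs[[length(segs)]]$interpretations <- list(it$interpretations)
  }
  if (!length(segs)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_bins = integer(),
                      mean_deviation_pct = numeric(), call = character(),
                      stringsAsFactors = FALSE)
    out$interpretations <- list()
    return(out)
  }
  out <- do.call(rbind, c(segs, make.row.names = FALSE))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Median-smooth a deviation track over tumbling megabase windows
#'
#' Non-overlapping windows of `window_mb` megabases per chromosome; each
#' window's value is the median of its non-masked bin deviations, NA when
#' the window holds no data. Used for visual overlays only -- calling
#' operates on the unsmoothed profile.
#'
#' @param profile a [deviation_profile()]
#' @param window_mb window width in megabases
#' @return data.frame chrom, start, end, deviation_pct
#' @export
smooth_median <- function(profile, window_mb = 5) {
  wbp <- window_mb * 1e6
  out <- list()
  for (chrom in unique(profile$chrom)) {
    p <- profile[profile$chrom == chrom, , drop = FALSE]
    win <- floor((p$start - 1) / wbp)
    for (w in unique(win)) {
      rows <- win == w
      vals <- p$deviation_pct[rows]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = as.integer(w * wbp + 1),
        end = as.integer(max(p$end[rows])),
        deviation_pct = if (all(is.na(vals))) NA_real_
          else stats::median(vals, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Compare central and peripheral CNV calls for ITH
#'
#' Intersects the two segment sets over the genome; every interval where
#' the called states differ is flagged, as `discordant_ambiguous` when
#' either side's call is ambiguous.
#'
#' @param central_segments segments from [call_regions()] for the central
#'   sample
#' @param peripheral_segments same for the peripheral sample (same model)
#' @return data.frame of discordant intervals with both calls; zero rows
#'   when the samples agree everywhere
#' @export
compare_regions <- function(central_segments, peripheral_segments) {
  to_gr <- function(s) {
    if (nrow(s) == 0)
      return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start, s$end),
                           call = s$call)
  }
  gc <- to_gr(central_segments)
  gp <- to_gr(peripheral_segments)
  all_gr <- GenomicRanges::disjoin(c(GenomicRanges::granges(gc),
                                     GenomicRanges::granges(gp)))
  if (length(all_gr) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), call_central = character(),
                      call_peripheral = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  call_at <- function(gr, g) {
    hits <- GenomicRanges::findOverlaps(all_gr, g)
    out <- rep("none", length(all_gr))
    out[S4Vectors::queryHits(hits)] <- g$call[S4Vectors::subjectHits(hits)]
    out
  }
  cc <- call_at(all_gr, gc)
  cp <- call_at(all_gr, gp)
  disc <- cc != cp
  res <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(all_gr))[disc],
    start = GenomicRanges::start(all_gr)[disc],
    end = GenomicRanges::end(all_gr)[disc],
    call_central = cc[disc], call_peripheral = cp[disc],
    stringsAsFactors = FALSE
  )
  res$status <- ifelse(res$call_central == "ambiguous" |
                         res$call_peripheral == "ambiguous",
                       "discordant_ambiguous", "discordant")
  res
}
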