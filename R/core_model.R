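# Core domain model: the canonical variant table, filter configuration, and
# readers/writers for the tabular and genomic formats every stage touches.
#
# Conventions: all in-memory coordinates are 1-based inclusive (VCF-facing);
# BED/bedGraph exports are 0-based half-open, converted only at the file
# boundary.

VARIANT_COLUMNS <- c(
  "patient", "chrom", "pos", "ref", "alt", "gene", "consequence", "aa_change",
  "context",
  "normal_depth", "normal_var", "normal_mapq",
  "central_depth", "central_var", "central_mapq",
  "peripheral_depth", "peripheral_var", "peripheral_mapq"
)

#' Filter configuration with the study's published cut-offs
#'
#' Somatic SNV rules: mapping quality >= 20, tumor VAF >= 5%, depth >= 10 in
#' both tumor and non-tumor, tumor variant reads >= 2, non-tumor variant
#' reads <= 1, no indel within 5 bp, not more than 2 SNVs in any 10-bp
#' window. Indel rules: depth >= 20 in both samples, VAF >= 10%, >= 5
#' variant reads, zero variant reads in the non-tumor sample. All thresholds
#' are inclusive exactly as stated.
#'
#' @param ... named overrides of any default threshold
#' @return a list of class `filter_config`
#' @export
filter_config <- function(...) {
  cfg <- list(
    snv_min_mapq = 20,
    snv_min_tumor_vaf = 0.05,
    snv_min_depth = 10,
    snv_min_tumor_var_reads = 2,
    snv_max_normal_var_reads = 1,
    snv_indel_exclusion_bp = 5,
    snv_window_bp = 10,
    snv_window_max = 2,
    indel_min_depth = 20,
    indel_min_vaf = 0.10,
    indel_min_var_reads = 5,
    indel_max_normal_var_reads = 0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown filter_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (any(unlist(cfg) < 0)) stop("all filter thresholds must be non-negative")
  if (cfg$snv_window_max < 1) stop("snv_window_max must be >= 1")
  structure(cfg, class = "filter_config")
}

#' Validate a variant table against the domain invariants
#'
#' Checks column presence, positive 1-based positions, `ref != alt`, ACGT
#' alleles, `var_reads <= depth` for every sample, trinucleotide context
#' centered on the reference base (SNVs), and uniqueness of
#' (patient, chrom, pos, alt). Violations are hard errors naming the
#' offending row.
#'
#' @param df a variant data.frame in canonical layout
#' @return the validated data.frame, invisibly sorted by (chrom, pos)
#' @export
validate_variants <- function(df) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("variant table missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  row_fail <- function(i, msg) {
    stop(sprintf("variant table row %d (%s:%d %s>%s): %s",
                 i, df$chrom[i], df$pos[i], df$ref[i], df$alt[i], msg))
  }
  for (i in seq_len(nrow(df))) {
    if (is.na(df$pos[i]) || df$pos[i] < 1) row_fail(i, "pos must be >= 1")
    if (df$ref[i] == df$alt[i]) row_fail(i, "ref_allele equals alt_allele")
    if (!grepl("^[ACGT]+$", df$ref[i]) || !grepl("^[ACGT]+$", df$alt[i]))
      row_fail(i, "alleles must be ACGT strings")
    for (r in REGIONS) {
      d <- df[[paste0(r, "_depth")]][i]
      v <- df[[paste0(r, "_var")]][i]
      if (is.na(d) || is.na(v) || d < 0 || v < 0)
        row_fail(i, paste0(r, " evidence has negative or missing counts"))
      if (v > d) row_fail(i, paste0("var_reads > depth in ", r, " sample"))
    }
    ctx <- df$context[i]
    if (!is.na(ctx) && nchar(df$ref[i]) == 1L && nchar(df$alt[i]) == 1L) {
      if (nchar(ctx) != 3L || substr(ctx, 2, 2) != df$ref[i])
        row_fail(i, "trinucleotide context middle base must equal ref_allele")
    }
  }
  key <- paste(df$patient, df$chrom, df$pos, df$alt)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    row_fail(d, "duplicate (chrom, pos, alt) within one patient")
  }
  df <- df[order(df$patient, df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  invisible(df)
}

#' Read a variant table (TSV or minimal-VCF dialect)
#'
#' The TSV dialect is the canonical 18-column layout; the minimal-VCF dialect
#' is a VCF v4.2 subset with a single ALT per row, INFO keys
#' PT/GENE/CSQ/AA/CTX and per-sample FORMAT fields DP (depth), VD (variant
#' reads), MQ (mapping quality) for samples NORMAL, CENTRAL, PERIPHERAL.
#' VAFs are never read from the file; downstream always recomputes them from
#' counts.
#'
#' @param path input file
#' @param dialect `"tsv"` or `"vcf_min"`
#' @return a validated variant data.frame sorted by (chrom, pos)
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (dialect == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
  df <- df[order(df$patient, df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  validate_variants(df)
  df
}

read_variant_tsv <- function(path) {
  lines <- readLines(path)
  n_comment <- 0
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1], "#"))
    n_comment <- n_comment + 1
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", "."))
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("variant TSV missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, VARIANT_COLUMNS]
  # report malformed rows with their file line numbers
  num_cols <- grep("_(depth|var|mapq)$|^pos$", names(df), value = TRUE)
  for (col in num_cols) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at file line %d of %s",
                   col, bad[1] + n_comment + 1, path))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  df$pos <- as.integer(df$pos)
  for (ch in c("patient", "chrom", "ref", "alt", "gene", "consequence",
               "aa_change", "context"))
    df[[ch]] <- as.character(df[[ch]])
  df
}

read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(VARIANT_COLUMNS)),
                                        VARIANT_COLUMNS))
    df$pos <- integer()
    for (col in grep("_(depth|var|mapq)$", VARIANT_COLUMNS, value = TRUE))
      df[[col]] <- numeric()
    return(df)
  }
  info1 <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    ifelse(val == "." | val == "", NA_character_, val)
  }
  gt <- function(el, sample) {
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    as.numeric(m[, sample])
  }
  needed <- c("NORMAL", "CENTRAL", "PERIPHERAL")
  if (!all(needed %in% colnames(v@gt)[-1])) {
    stop("minimal VCF must carry samples NORMAL, CENTRAL, PERIPHERAL")
  }
  df <- data.frame(
    patient = info1("PT"), chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    gene = info1("GENE"), consequence = info1("CSQ"),
    aa_change = info1("AA"), context = info1("CTX"),
    stringsAsFactors = FALSE
  )
  for (r in REGIONS) {
    sample <- toupper(r)
    df[[paste0(r, "_depth")]] <- gt("DP", sample)
    df[[paste0(r, "_var")]] <- gt("VD", sample)
    df[[paste0(r, "_mapq")]] <- gt("MQ", sample)
  }
  df
}

#' Write a variant table (TSV or minimal-VCF dialect)
#'
#' Both writers emit a provenance header line with tool version and config
#' hash. Round-trips through [read_variant_table()] are the identity.
#'
#' @param df canonical variant data.frame
#' @param path output file
#' @param dialect `"tsv"` or `"vcf_min"`
#' @param config optional configuration object folded into the header hash
#' @return `path`, invisibly
#' @export
write_variant_table <- function(df, path, dialect = c("tsv", "vcf_min"),
                                config = NULL) {
  dialect <- match.arg(dialect)
  validate_variants(df)
  df <- df[order(df$patient, df$chrom, df$pos), , drop = FALSE]
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenance_header(config), con)
    out <- df
    out$aa_change[is.na(out$aa_change)] <- "."
    out$context[is.na(out$context)] <- "."
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_variant_vcf(df, path, config)
  }
  invisible(path)
}

write_variant_vcf <- function(df, path, config = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", sub("^#", "", provenance_header(config))),
    "##INFO=<ID=PT,Number=1,Type=String,Description=\"Patient identifier\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Amino acid change\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Trinucleotide context (plus strand)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=VD,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    "##FORMAT=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "CENTRAL", "PERIPHERAL", sep = "\t")
  )
  dot <- function(x) ifelse(is.na(x), ".", x)
  fmt_sample <- function(r) {
    sprintf("%d:%d:%g",
            as.integer(df[[paste0(r, "_depth")]]),
            as.integer(df[[paste0(r, "_var")]]),
            df[[paste0(r, "_mapq")]])
  }
  body <- if (nrow(df) == 0) character() else {
    info <- sprintf("PT=%s;GENE=%s;CSQ=%s;AA=%s;CTX=%s",
                    dot(df$patient), dot(df$gene), dot(df$consequence),
                    dot(df$aa_change), dot(df$context))
    paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", info,
          "DP:VD:MQ", fmt_sample("normal"), fmt_sample("central"),
          fmt_sample("peripheral"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write CNV segments as BED6 plus a bedGraph deviation track
#'
#' Internal 1-based inclusive segment coordinates are converted to BED
#' 0-based half-open at the file boundary. The bedGraph value is the
#' segment's mean percent deviation from expected coverage. Overlapping
#' segments are a hard error.
#'
#' @param segments data.frame with chrom, start, end (1-based inclusive),
#'   mean_deviation_pct and call columns
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.bedGraph`
#' @param config optional configuration folded into the provenance header
#' @return named character vector of the two file paths, invisibly
#' @export
write_segments <- function(segments, prefix, config = NULL) {
  needed <- c("chrom", "start", "end", "mean_deviation_pct", "call")
  missing_cols <- setdiff(needed, names(segments))
  if (length(missing_cols))
    stop("segments missing field(s): ", paste(missing_cols, collapse = ", "))
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", chrom)
  }
  bed <- paste0(prefix, ".bed")
  bg <- paste0(prefix, ".bedGraph")
  hdr <- provenance_header(config)
  bed_lines <- c(hdr, if (nrow(segments)) {
    paste(segments$chrom, segments$start - 1L, segments$end, segments$call,
          0L, ".", sep = "\t")
  })
  bg_lines <- c(hdr, "track type=bedGraph name=coverage_deviation_pct",
                if (nrow(segments)) {
                  paste(segments$chrom, segments$start - 1L, segments$end,
                        format(segments$mean_deviation_pct, digits = 10,
                               scientific = FALSE, trim = TRUE),
                        sep = "\t")
                })
  writeLines(bed_lines, bed)
  writeLines(bg_lines, bg)
  invisible(c(bed = bed, bedGraph = bg))
}

#' Read segments back from a BED/bedGraph pair written by [write_segments()]
#'
#' @param prefix path prefix used when writing
#' @return data.frame with 1-based inclusive chrom/start/end,
#'   mean_deviation_pct and call
#' @export
read_segments <- function(prefix) {
  bed <- readLines(paste0(prefix, ".bed"))
  bg <- readLines(paste0(prefix, ".bedGraph"))
  bed <- bed[!startsWith(bed, "#") & !startsWith(bed, "track")]
  bg <- bg[!startsWith(bg, "#") & !startsWith(bg, "track")]
  if (length(bed) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_deviation_pct = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  b <- do.call(rbind, strsplit(bed, "\t"))
  g <- do.call(rbind, strsplit(bg, "\t"))
  data.frame(
    chrom = b[, 1], start = as.integer(b[, 2]) + 1L, end = as.integer(b[, 3]),
    mean_deviation_pct = as.numeric(g[, 4]), call = b[, 4],
    stringsAsFactors = FALSE
  )
}

#' Write a per-bin coverage table
#'
#' Tab-separated chrom/start/end/count with 1-based inclusive coordinates
#' and a provenance header.
#'
#' @param df data.frame with chrom, start, end, count
#' @param path output file
#' @param config optional configuration folded into the header
#' @return `path`, invisibly
#' @export
write_coverage_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df[, c("chrom", "start", "end", "count")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-bin coverage table written by [write_coverage_table()]
#'
#' @param path input file
#' @return data.frame with chrom, start, end, count
#' @export
read_coverage_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("coverage table missing field(s): ", paste(missing_cols, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$count <- as.numeric(df$count)
  df
}
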