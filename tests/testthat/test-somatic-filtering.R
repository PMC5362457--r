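# The published SNV cut-offs, indel rules, window rule, polymorphism and
# exon restriction, checked against independent brute-force oracles.

test_that("SNV boundary values of all five evidence cut-offs pass inclusively", {
  row <- make_variant(central_depth = 100L, central_var = 5L,
                      central_mapq = 20, normal_depth = 50L, normal_var = 1L)
  dec <- filter_snvs(row, "central")
  expect_true(dec$passed)
  expect_identical(dec$reasons, "")
})

test_that("each violated SNV rule contributes its reason code, accumulated", {
  cases <- list(
    list(args = list(central_mapq = 19), reasons = "MAPQ"),
    list(args = list(central_var = 4L, central_depth = 100L),
         reasons = "VAF"), # 4% just below the 5% cut-off, var reads still >= 2
    list(args = list(central_depth = 9L, central_var = 2L),
         reasons = "DEPTH"),
    list(args = list(normal_depth = 9L), reasons = "DEPTH"),
    list(args = list(central_var = 1L, central_depth = 100L),
         reasons = c("VAF", "TUMOR_VAR")),
    list(args = list(normal_var = 2L), reasons = "NORMAL_VAR"),
    list(args = list(central_depth = 8L, central_var = 0L, central_mapq = 10,
                     normal_var = 5L),
         reasons = c("MAPQ", "VAF", "DEPTH", "TUMOR_VAR", "NORMAL_VAR"))
  )
  for (case in cases) {
    row <- do.call(make_variant, case$args)
    dec <- filter_snvs(row, "central")
    expect_false(dec$passed)
    expect_setequal(strsplit(dec$reasons, ",")[[1]], case$reasons)
  }
})

test_that("an indel within 5 bp flags NEAR_INDEL; 6 bp away does not", {
  for (d in c(1L, 5L, 6L, 10L)) {
    tbl <- make_variants(
      make_variant(pos = 1000L),
      make_variant(pos = 1000L + d, ref = "AT", alt = "A", context = NA,
                   consequence = "frameshift", aa_change = NA)
    )
    dec <- filter_snvs(tbl, "central")
    hit <- grepl("NEAR_INDEL", dec$reasons)
    expect_identical(hit, d <= 5L)
  }
})

test_that("the 10-bp window rule matches exhaustive enumeration", {
  expect_identical(apply_window_rule(c(100L, 105L, 109L)), rep(TRUE, 3))
  expect_identical(apply_window_rule(c(100L, 105L, 110L)), rep(FALSE, 3))
  expect_identical(apply_window_rule(123L), FALSE)
  set.seed(31)
  for (i in 1:100) {
    pos <- sort(sample(1:60, sample(1:15, 1)))
    expect_identical(apply_window_rule(pos), brute_force_window(pos),
                     info = paste(pos, collapse = ","))
  }
})

test_that("indel rules evaluate inclusively at their printed boundaries", {
  base <- list(consequence = "frameshift", ref = "AT", alt = "A",
               context = NA, aa_change = NA)
  pass <- do.call(make_variant, c(base, list(
    central_depth = 20L, central_var = 5L, normal_depth = 20L,
    normal_var = 0L)))
  dec <- filter_indels(pass, "central")
  expect_true(dec$passed)

  one_read <- do.call(make_variant, c(base, list(
    central_depth = 20L, central_var = 5L, normal_depth = 20L,
    normal_var = 1L)))
  expect_match(filter_indels(one_read, "central")$reasons, "INDEL_NORMAL")

  low_vaf <- do.call(make_variant, c(base, list(
    central_depth = 56L, central_var = 5L, normal_depth = 30L,
    normal_var = 0L))) # 5/56 = 8.9% < 10% with 5 reads
  dec3 <- filter_indels(low_vaf, "central")
  expect_match(dec3$reasons, "INDEL_VAF")
  expect_false(grepl("INDEL_VAR", dec3$reasons))

  thin <- do.call(make_variant, c(base, list(
    central_depth = 19L, central_var = 5L, normal_depth = 20L,
    normal_var = 0L)))
  expect_match(filter_indels(thin, "central")$reasons, "INDEL_DEPTH")
})

test_that("polymorphism exclusion matches on the full allele identity", {
  dec <- filter_snvs(make_variant(pos = 1000L, ref = "C", alt = "T"),
                     "central")
  expect_identical(exclude_polymorphisms(dec, NULL), dec)

  poly_hit <- data.frame(chrom = "chr1", pos = 1000L, ref = "C", alt = "T")
  out <- exclude_polymorphisms(dec, poly_hit)
  expect_match(out$reasons, "POLYMORPHISM")
  expect_false(out$passed)

  poly_other_alt <- data.frame(chrom = "chr1", pos = 1000L, ref = "C",
                               alt = "G")
  expect_identical(exclude_polymorphisms(dec, poly_other_alt), dec)
})

test_that("sites outside every exon interval gain NON_EXONIC", {
  exons <- data.frame(chrom = "chr1", start = 900L, end = 1100L)
  inside <- filter_snvs(make_variant(pos = 1000L), "central")
  expect_true(restrict_to_exonic(inside, exons)$passed)
  edge_in <- filter_snvs(make_variant(pos = 1100L), "central")
  expect_true(restrict_to_exonic(edge_in, exons)$passed)
  outside <- filter_snvs(make_variant(pos = 1101L), "central")
  expect_match(restrict_to_exonic(outside, exons)$reasons, "NON_EXONIC")
  empty <- restrict_to_exonic(inside, exons[0, ])
  expect_match(empty$reasons, "NON_EXONIC")
})

test_that("the rule cascade matches a brute-force re-implementation on random evidence", {
  set.seed(17)
  n <- 400
  for (i in seq_len(n)) {
    row <- make_variant(
      pos = sample(1000:2000, 1),
      central_depth = sample(0:40, 1),
      central_mapq = sample(c(10, 19, 20, 21, 60), 1),
      normal_depth = sample(0:40, 1),
      normal_var = sample(0:3, 1)
    )
    row$central_var <- sample(0:row$central_depth, 1)
    indel_pos <- if (stats::runif(1) < 0.5)
      row$pos + sample(-8:8, 1) else integer()
    tbl <- row
    if (length(indel_pos)) {
      tbl <- rbind(tbl, make_variant(pos = indel_pos, ref = "AT", alt = "A",
                                     consequence = "frameshift",
                                     context = NA, aa_change = NA))
    }
    dec <- filter_snvs(tbl, "central")
    got <- setdiff(strsplit(dec$reasons[1], ",")[[1]], "")
    want <- brute_force_snv_reasons(row, "central", indel_positions = indel_pos)
    expect_setequal(got, want)
  }
})

test_that("raising any minimum threshold never converts a reject into a pass", {
  set.seed(23)
  rows <- do.call(rbind, lapply(1:200, function(i) {
    d <- sample(5:60, 1)
    make_variant(pos = 1000L + 20L * i, central_depth = d,
                 central_var = sample(0:d, 1),
                 central_mapq = sample(15:40, 1),
                 normal_depth = sample(5:60, 1),
                 normal_var = sample(0:2, 1))
  }))
  lax <- filter_snvs(rows, "central")
  stricter <- list(
    filter_config(snv_min_mapq = 30),
    filter_config(snv_min_tumor_vaf = 0.10),
    filter_config(snv_min_depth = 20),
    filter_config(snv_min_tumor_var_reads = 4),
    filter_config(snv_max_normal_var_reads = 0)
  )
  for (cfg in stricter) {
    tight <- filter_snvs(rows, "central", cfg)
    expect_true(all(tight$passed <= lax$passed))
  }
})

test_that("with noise at zero the filter passes exactly the planted somatic set", {
  quiet <- noise_params(depth_dispersion = 0, coverage_dispersion = 0,
                        sequencing_error_rate = 0, pyro_sd = 0)
  sim <- simulate_cohort(tiny_genome(), single_trio_plan(n_common = 30,
                                                         n_private_peripheral = 5,
                                                         n_private_central = 3),
                         quiet, seed = 13)
  tm <- sim$truth$mutations
  for (r in c("central", "peripheral")) {
    dec <- filter_region(sim$variants$S1, r, exons = sim$genome$exons)
    planted <- tm[tm$clonality %in% c("common", paste0("private_", r)), ]
    expect_setequal(paste(dec$chrom[dec$passed], dec$pos[dec$passed]),
                    paste(planted$chrom, planted$pos))
  }
})
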