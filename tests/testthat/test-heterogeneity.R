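# Clonality classification, spectra and ITH summaries.

test_that("cross-interrogation presence rule and low-coverage handling", {
  expect_equal(cross_interrogate(10, 40)$status, "present")
  expect_equal(cross_interrogate(0, 80)$status, "absent")
  expect_equal(cross_interrogate(1, 80)$status, "absent")
  zero <- cross_interrogate(0, 0)
  expect_equal(zero$status, "absent")
  expect_true(zero$low_coverage)
})

test_that("orthogonal confirmation applies the 5% AF-difference rule", {
  expect_equal(confirm_private(0.25, 0.00, 0.00), "confirmed")
  expect_equal(confirm_private(0.20, 0.20, 0.00), "refuted")
  expect_equal(confirm_private(0.04, 0.00, 0.00), "failed")
  expect_equal(confirm_private(0.06, 0.00, 0.02), "failed") # only 4% above
  expect_equal(confirm_private(NA, 0.00, 0.00), "untested")
  expect_equal(confirm_private(0.07, 0.00, 0.02), "confirmed") # exactly 5%
})

test_that("classification combines filters, interrogation and confirmation", {
  both <- make_variant(pos = 100L)
  central_only <- make_variant(pos = 300L, peripheral_var = 0L)
  low_cov <- make_variant(pos = 500L, peripheral_var = 0L,
                          peripheral_depth = 5L)
  refuted <- make_variant(pos = 700L, peripheral_var = 0L)
  v <- make_variants(both, central_only, low_cov, refuted)
  dc <- filter_region(v, "central")
  dp <- filter_region(v, "peripheral")
  pyro <- data.frame(
    patient = "P1", chrom = "chr1", pos = c(300L, 700L),
    af_central = c(0.25, 0.20), af_peripheral = c(0.00, 0.20),
    af_normal = c(0.00, 0.00), stringsAsFactors = FALSE
  )
  calls <- classify_cohort(v, dc, dp, pyro)
  lab <- stats::setNames(calls$label, calls$pos)
  expect_equal(lab[["100"]], "common")
  expect_equal(lab[["300"]], "private_central")
  expect_equal(lab[["500"]], "unresolved")
  expect_equal(lab[["700"]], "common") # refuted -> relabeled common
  expect_equal(calls$confirmation[calls$pos == 700], "refuted")
  # untested without orthogonal data stays private
  calls2 <- classify_cohort(v, dc, dp, pyro = NULL)
  expect_equal(calls2$label[calls2$pos == 300], "private_central")
  expect_equal(calls2$confirmation[calls2$pos == 300], "untested")
})

test_that("classification is symmetric in region naming", {
  v <- make_variants(
    make_variant(pos = 100L),
    make_variant(pos = 300L, peripheral_var = 0L),
    make_variant(pos = 500L, central_var = 0L)
  )
  pyro <- data.frame(patient = "P1", chrom = "chr1", pos = c(300L, 500L),
                     af_central = c(0.25, 0.00),
                     af_peripheral = c(0.00, 0.25),
                     af_normal = c(0, 0), stringsAsFactors = FALSE)
  calls <- classify_cohort(v, filter_region(v, "central"),
                           filter_region(v, "peripheral"), pyro)
  swap <- v
  for (f in c("depth", "var", "mapq")) {
    c_col <- paste0("central_", f)
    p_col <- paste0("peripheral_", f)
    tmp <- swap[[c_col]]
    swap[[c_col]] <- swap[[p_col]]
    swap[[p_col]] <- tmp
  }
  pyro_sw <- pyro
  pyro_sw$af_central <- pyro$af_peripheral
  pyro_sw$af_peripheral <- pyro$af_central
  calls_sw <- classify_cohort(swap, filter_region(swap, "central"),
                              filter_region(swap, "peripheral"), pyro_sw)
  flip <- c(common = "common", private_central = "private_peripheral",
            private_peripheral = "private_central",
            unresolved = "unresolved")
  expect_identical(unname(flip[calls$label]), calls_sw$label)
})

test_that("the 12 ordered substitutions collapse onto 6 paired classes", {
  expect_equal(substitution_class("C", "T"), "C>T/G>A")
  expect_equal(substitution_class("G", "A"), "C>T/G>A")
  expect_equal(substitution_class("G", "T"), "C>A/G>T")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- substitution_class(pairs$ref, pairs$alt)
  expect_equal(sort(unname(table(cls))), rep(2L, 6), ignore_attr = TRUE)
  expect_error(substitution_class("C", "C"), "single-base")
})

test_that("CpG fraction follows the strand-aware context definition", {
  cf <- cpg_fraction(c("C", "C", "G", "G", "C"),
                     c("T", "T", "A", "A", "T"),
                     c("ACG", "ACA", "CGA", "TGA", NA))
  # ACG C>T and CGA G>A are CpG; ACA and TGA are not; NA excluded
  expect_equal(cf$fraction, 0.5)
  expect_equal(cf$n_used, 4)
  expect_equal(cf$n_missing, 1)
  # non-C>T/G>A classes never enter the denominator
  cf2 <- cpg_fraction(c("C", "C"), c("A", "T"), c("ACG", "ACG"))
  expect_equal(cf2$n_used, 1)
})

test_that("ITH summary arithmetic and partition reconcile with the calls", {
  calls <- data.frame(
    patient = "P1", chrom = "chr1", pos = 1:10 * 100L, ref = "C", alt = "T",
    gene = paste0("G", 1:10), consequence = "missense",
    aa_change = NA_character_, context = "ACG",
    label = c(rep("common", 9), "private_central"),
    confirmation = "not_required",
    vaf_central = 0.2, vaf_peripheral = 0.3, vaf_normal = 0,
    stringsAsFactors = FALSE
  )
  s <- summarize_ith(calls)
  central <- s$samples[s$samples$region == "central", ]
  expect_equal(central$n_common, 9)
  expect_equal(central$n_private, 1)
  expect_equal(central$private_fraction, 0.10)
  expect_equal(central$median_vaf_common, 0.25) # mean of both regions
  expect_equal(central$median_vaf_private, 0.2) # harboring region only
  peripheral <- s$samples[s$samples$region == "peripheral", ]
  expect_equal(peripheral$n_private, 0)
  expect_equal(peripheral$private_fraction, 0)
  # partition: labels account for every call
  expect_equal(sum(central$n_common, central$n_private,
                   peripheral$n_private,
                   sum(calls$label == "unresolved")), nrow(calls))
})

test_that("cohort classification recovers the planted truth with high recall", {
  sim <- simulate_cohort(seed = 29)
  confusion <- list()
  for (p in names(sim$variants)) {
    dc <- filter_region(sim$variants[[p]], "central",
                        exons = sim$genome$exons)
    dp <- filter_region(sim$variants[[p]], "peripheral",
                        exons = sim$genome$exons)
    calls <- classify_cohort(sim$variants[[p]], dc, dp, sim$pyro[[p]])
    tm <- sim$truth$mutations[sim$truth$mutations$patient == p, ]
    m <- merge(calls, tm[, c("chrom", "pos", "clonality")],
               by = c("chrom", "pos"))
    confusion[[p]] <- m[, c("label", "clonality")]
  }
  confusion <- do.call(rbind, confusion)
  for (cls in c("common", "private_central", "private_peripheral")) {
    truth_n <- sum(confusion$clonality == cls)
    if (truth_n == 0) next
    recall <- sum(confusion$label == cls & confusion$clonality == cls) / truth_n
    expect_gte(recall, 0.95)
  }
})
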