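# Reference coverage model, deviation profiles, purity-adjusted calling,
# smoothing and center/periphery comparison.

make_panel <- function(genome, n = 10, noise = noise_params(), bias = NULL,
                       seed = 1) {
  set.seed(seed)
  if (is.null(bias)) {
    bias <- stats::rlnorm(nrow(genome$bins), -0.005, 0.1)
  }
  list(panel = lapply(seq_len(n), function(i)
    simulate_coverage(genome, noise, bias)), bias = bias)
}

test_that("the reference model demands 10 samples on one tiling", {
  g <- tiny_genome()
  p <- make_panel(g, 9)
  expect_error(build_reference_model(p$panel), "at least 10")
  p10 <- make_panel(g, 10)
  shifted <- p10$panel
  shifted[[3]]$start <- shifted[[3]]$start + 1L
  expect_error(build_reference_model(shifted), "tiling")
})

test_that("an identical-profile panel is masked as degenerate", {
  g <- tiny_genome()
  quiet <- noise_params(coverage_dispersion = 0)
  panel <- lapply(1:10, function(i) simulate_coverage(g, quiet))
  expect_warning(model <- build_reference_model(panel), "degenerate")
  expect_true(all(model$mask))
  # deviations remain defined (zero), but nothing is callable
  prof <- deviation_profile(simulate_coverage(g, quiet), model)
  expect_true(all(prof$deviation_pct == 0))
  expect_true(all(is.na(prof$z)))
  expect_equal(nrow(call_regions(prof, model, 1)), 0)
})

test_that("panel means track the planted bias field", {
  g <- tiny_genome()
  p <- make_panel(g, 10, noise_params(coverage_dispersion = 0))
  model <- suppressWarnings(build_reference_model(p$panel))
  ratio <- model$expected_mean / p$bias
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-12)
})

test_that("deviation is zero at expectation and +50% at 1.5x expected", {
  g <- tiny_genome()
  p <- make_panel(g, 12)
  model <- build_reference_model(p$panel)
  flat <- p$panel[[1]]
  flat$count <- model$expected_mean
  prof <- deviation_profile(flat, model)
  expect_true(all(abs(prof$deviation_pct) < 1e-9))

  dup <- flat
  hit <- seq_len(10)
  dup$count[hit] <- dup$count[hit] * 1.5
  prof2 <- deviation_profile(dup, model)
  expect_true(all(abs(prof2$deviation_pct[hit] - 50) < 1e-6))
  expect_true(all(abs(prof2$deviation_pct[-hit]) < 1e-6))
})

test_that("deviation profiles are invariant to uniform count scaling", {
  g <- tiny_genome()
  p <- make_panel(g, 10)
  model <- build_reference_model(p$panel)
  set.seed(4)
  s <- simulate_coverage(g, noise_params(), p$bias)
  prof1 <- deviation_profile(s, model)
  s3 <- s
  s3$count <- s3$count * 3
  expect_equal(deviation_profile(s3, model), prof1)
})

test_that("expected deviation matches the copy-state closed form", {
  expect_equal(expected_deviation(3, 1.0), 50)
  expect_equal(expected_deviation(1, 1.0), -50)
  expect_equal(expected_deviation(3, 0.6), 30)
  expect_equal(expected_deviation(2, 0.37), 0)
  expect_equal(expected_deviation(4, 0.5), 50)
  # linear in tumor content, odd around the diploid state
  tc <- seq(0.1, 1, by = 0.1)
  expect_equal(expected_deviation(3, tc), 25 * tc / 0.5)
  expect_equal(expected_deviation(1, tc), -expected_deviation(3, tc))
  expect_error(expected_deviation(5, 1), "copy_number")
  expect_error(expected_deviation(3, 0), "tumor_content")
})

test_that("a +20% deviation at 60% purity is ambiguous with both readings", {
  it <- interpret_deviation(20, 0.6)
  expect_equal(it$call, "ambiguous")
  ints <- it$interpretations
  sub <- ints[ints$origin == "tumor_subclonal" & ints$copy_number == 3, ]
  expect_equal(nrow(sub), 1)
  expect_equal(sub$fraction, 0.4)
  non <- ints[ints$origin == "non_tumor" & ints$copy_number == 3, ]
  expect_equal(nrow(non), 1)

  clonal <- interpret_deviation(30, 0.6)
  expect_equal(clonal$call, "het_dup")
  expect_equal(clonal$interpretations$origin, "tumor_clonal")
  expect_equal(interpret_deviation(0, 0.6)$call, "none")
  # a small residual deviation still admits low-fraction readings
  expect_equal(interpret_deviation(2, 0.6)$call, "ambiguous")
})

test_that("planted events are called with the right state at 60% purity", {
  g <- genome_model(n_chrom = 1, chrom_length = 30e6, bin_bp = 1e5)
  p <- make_panel(g, 10, seed = 8)
  set.seed(9)
  cnv <- data.frame(chrom = "chr1", start = 8e6 + 1, end = 18e6,
                    copy_number = 3L)
  tumor <- simulate_coverage(g, noise_params(), p$bias, cnv, purity = 0.6)
  model <- build_reference_model(p$panel)
  segs <- call_regions(deviation_profile(tumor, model), model, 0.6)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$call, "het_dup")
  expect_lt(abs(segs$mean_deviation_pct - 30), 5)
  expect_lte(abs(segs$start - (8e6 + 1)), 1e5)
  expect_lte(abs(segs$end - 18e6), 1e5)
  expect_error(call_regions(deviation_profile(tumor, model), model, NULL),
               "tumor_content")
})

test_that("median smoothing uses tumbling windows and resists spikes", {
  g <- tiny_genome()
  p <- make_panel(g, 10)
  model <- build_reference_model(p$panel)
  prof <- deviation_profile(p$panel[[1]], model)
  const <- prof
  const$deviation_pct <- 7
  sm <- smooth_median(const)
  expect_true(all(sm$deviation_pct == 7))

  spiked <- const
  spiked$deviation_pct[10] <- 400
  expect_true(all(smooth_median(spiked)$deviation_pct == 7))

  set.seed(2)
  rand <- prof
  rand$deviation_pct <- stats::rnorm(nrow(prof), 0, 20)
  sm2 <- smooth_median(rand)
  for (k in seq_len(nrow(sm2))) {
    rows <- rand$chrom == sm2$chrom[k] & rand$start >= sm2$start[k] &
      rand$end <= sm2$end[k]
    expect_equal(sm2$deviation_pct[k], stats::median(rand$deviation_pct[rows]))
  }
})

test_that("center/periphery comparison flags only discordant intervals", {
  seg <- function(start, end, call) {
    data.frame(chrom = "chr1", start = start, end = end, n_bins = 5L,
               mean_deviation_pct = 30, call = call, stringsAsFactors = FALSE)
  }
  same <- seg(1e6 + 1, 5e6, "het_dup")
  expect_equal(nrow(compare_regions(same, same)), 0)

  only_p <- compare_regions(same[0, ], same)
  expect_equal(nrow(only_p), 1)
  expect_equal(only_p$call_central, "none")
  expect_equal(only_p$call_peripheral, "het_dup")
  expect_equal(only_p$status, "discordant")

  amb <- compare_regions(seg(1e6 + 1, 5e6, "het_dup"),
                         seg(1e6 + 1, 5e6, "ambiguous"))
  expect_equal(amb$status, "discordant_ambiguous")
})

test_that("a peripheral-only duplication is recovered as CNV-ITH", {
  sim <- simulate_cohort(seed = 33)
  model <- build_reference_model(sim$coverage$panel)
  trio <- sim$plan$trios[sim$plan$trios$patient == "P4", ]
  segs_c <- call_regions(deviation_profile(sim$coverage$patients$P4$central,
                                           model), model,
                         trio$purity_central)
  segs_p <- call_regions(deviation_profile(sim$coverage$patients$P4$peripheral,
                                           model), model,
                         trio$purity_peripheral)
  disc <- compare_regions(segs_c, segs_p)
  planted <- sim$plan$cnv[sim$plan$cnv$region == "peripheral_only", ]
  hit <- disc[disc$chrom == planted$chrom &
                disc$call_peripheral == "het_dup" &
                disc$call_central == "none", ]
  covered <- sum(pmin(hit$end, planted$end) - pmax(hit$start, planted$start) + 1)
  expect_gte(covered / (planted$end - planted$start + 1), 0.9)
})

test_that("germline calling on a fresh panel-like sample stays quiet", {
  g <- tiny_genome()
  p <- make_panel(g, 15, seed = 19)
  model <- build_reference_model(p$panel[1:10])
  set.seed(20)
  fresh <- simulate_coverage(g, noise_params(), p$bias)
  prof <- deviation_profile(fresh, model)
  exceed <- mean(abs(prof$z) >= 2, na.rm = TRUE)
  # per-bin exceedance near the tail mass implied by the 2-SD rule with an
  # SD estimated from 10 samples; run-length requirement kills segments
  expect_gt(exceed, 0.005)
  expect_lt(exceed, 0.20)
  expect_lte(nrow(call_regions(prof, model, 1)), 1)
})
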