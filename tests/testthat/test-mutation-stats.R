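test_that("spontaneous-expectation arithmetic is an exact product", {
  expect_equal(expected_dnm_count(5.4e-9, 2.7e9, 2), 29.16)
  expect_equal(expected_dnm_count(0, 2.7e9, 2), 0)
  expect_equal(expected_dnm_count(1.2e-8, 3.2e9, 2), 76.8)
  # linear in each argument
  set.seed(2)
  r <- runif(5, 1e-9, 1e-8)
  g <- runif(5, 1e9, 4e9)
  expect_equal(expected_dnm_count(2 * r, g, 2), 2 * expected_dnm_count(r, g, 2))
  expect_equal(expected_dnm_count(r, 3 * g, 2), 3 * expected_dnm_count(r, g, 2))
})

test_that("fold increase relates observed means to the expectation", {
  e <- expected_dnm_count(5.4e-9, 2.7e9, 2)
  expect_equal(fold_increase(87.6, e), 87.6 / 29.16)
  expect_equal(fold_increase(e, e), 1)
  expect_equal(fold_increase(211, e), 211 / 29.16)
  expect_error(fold_increase(10, 0), "positive")
})

test_that("the 12 raw substitutions collapse into 6 strand-symmetric classes", {
  raw <- tibble::tribble(
    ~ref, ~alt, ~class,
    "C", "T", "G:C>A:T",  "G", "A", "G:C>A:T",
    "T", "C", "A:T>G:C",  "A", "G", "A:T>G:C",
    "C", "A", "G:C>T:A",  "G", "T", "G:C>T:A",
    "C", "G", "G:C>C:G",  "G", "C", "G:C>C:G",
    "T", "A", "A:T>T:A",  "A", "T", "A:T>T:A",
    "T", "G", "A:T>C:G",  "A", "C", "A:T>C:G"
  )
  expect_equal(substitution_class(raw$ref, raw$alt), raw$class)
  # complement symmetry
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(substitution_class(comp[raw$ref], comp[raw$alt]), raw$class)
  expect_error(substitution_class("C", "C"), "differ")
  expect_error(substitution_class("N", "A"), "single-nucleotide")

  spec <- build_spectrum(raw)
  expect_true(all(spec$count == 2))
  # invariance under reverse-complementing every input
  spec_rc <- build_spectrum(tibble::tibble(ref = unname(comp[raw$ref]),
                                           alt = unname(comp[raw$alt])))
  expect_equal(spec_rc$count, spec$count)

  empty <- build_spectrum(raw[0, ])
  expect_equal(empty$count, rep(0L, 6))
  expect_equal(empty$proportion, rep(0, 6))
})

test_that("sampled spectra recover the configured class probabilities", {
  set.seed(97)
  g <- mouse_genome_model()
  tr <- inject_dnms("s", 0, 0.466, control_spectrum(), g, n = 20000)
  spec <- build_spectrum(tr)
  expect_equal(sum(spec$proportion), 1)
  p <- spec$proportion[spec$class == "G:C>A:T"]
  expect_lt(abs(p - 0.53), 3 * sqrt(0.53 * 0.47 / 20000) + 0.005)
  expect_equal(sum(spec$count), 20000L)
})

test_that("window counting tiles chromosomes and conserves every mutation", {
  g <- tiny_genome(1e6)  # windows of 1e5: 10 per autosome
  d <- tibble::tibble(chrom = "chr1", pos = rep(12345, 7))
  wc <- window_counts(d, g, window_size = 1e5)
  expect_equal(sum(wc$count), 7)
  expect_equal(wc$count[wc$chrom == "chr1" & wc$start == 0], 7)

  # 1-based pos equal to the window size falls in the first window;
  # pos window_size + 1 opens the second
  d2 <- tibble::tibble(chrom = "chr1", pos = c(1e5, 1e5 + 1))
  wc2 <- window_counts(d2, g, window_size = 1e5)
  expect_equal(wc2$count[wc2$start == 0][1], 1)
  expect_equal(wc2$count[wc2$start == 1e5][1], 1)

  wc0 <- window_counts(d[0, ], g, window_size = 1e5)
  expect_true(all(wc0$count == 0))
  expect_equal(nrow(wc0), 20)  # two 1-Mb autosomes
  expect_error(window_counts(tibble::tibble(chrom = "chr1", pos = 2e6), g,
                             window_size = 1e5), "outside")

  # terminal partial windows keep their true width
  g2 <- genome_model(tibble::tibble(chrom = "c", length = 250),
                     x_name = NA, y_name = NA)
  wc3 <- window_counts(tibble::tibble(chrom = "c", pos = 249), g2,
                       window_size = 100)
  expect_equal(wc3$width, c(100, 100, 50))
  expect_equal(wc3$count, c(0L, 0L, 1L))
})

test_that("the dispersion test flags spiked windows and reports direction", {
  set.seed(103)
  counts <- rpois(60, 3)
  counts[10] <- 30  # one window at 10x the mean
  fit <- poisson_hotspot_test(counts, hotspot_threshold = 14)
  expect_true(fit$reject)
  expect_equal(fit$dispersion$direction, "overdispersed")
  expect_equal(nrow(fit$hotspots), 1)
  expect_equal(fit$hotspots$count, 30)
  expect_equal(glance(fit)$n_hotspots, 1)
  expect_equal(nrow(tidy(fit)), 60)

  flat <- poisson_hotspot_test(rep(3, 20))
  expect_equal(flat$dispersion$direction, "underdispersed")
  expect_error(poisson_hotspot_test(rpois(5, 3)), "at least 10")
  expect_error(poisson_hotspot_test(rep(0, 20)), "no mutations")
})

test_that("spectrum KS comparison distinguishes shifted class fractions", {
  set.seed(107)
  n_i <- rep(80, 20)
  null_frac <- tibble::tibble(sample_id = as.character(1:20), n = n_i,
                              fraction = rbinom(20, n_i, 0.53) / n_i)
  same <- compare_spectrum(null_frac, reference_p = 0.53)
  expect_gt(same$p_value, 0.01)
  shifted <- dplyr::mutate(null_frac, fraction = pmax(fraction - 0.2, 0))
  diff <- compare_spectrum(shifted, reference_p = 0.53)
  expect_lt(diff$p_value, 0.05)
  expect_error(compare_spectrum(null_frac[1, ]), ">= 2 samples")
  expect_s3_class(tidy(diff), "tbl_df")
})

test_that("sex-bias KS test reports D, p and group medians", {
  same <- sex_bias_test(c(80, 90, 100), c(80, 90, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$median_male, 90)
  b <- sex_bias_test(c(63, 70, 82.5, 90, 133), c(62, 70, 76, 80, 94))
  expect_equal(b$median_male, 82.5)
  expect_equal(b$median_female, 76)
  expect_error(sex_bias_test(numeric(), 1:3), "non-empty")

  # power: doubling the Poisson mean is detected almost always at n = 10
  set.seed(109)
  hits <- mean(replicate(1000, {
    sex_bias_test(rpois(10, 80), rpois(10, 160))$p_value < 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("red-cell folate follows the cell-fraction correction formula", {
  expect_equal(rbc_folate(10, 0, 100), 10)
  expect_equal(rbc_folate(10, 10, 50), 10)  # 20 - 10
  expect_warning(out <- rbc_folate(0, 5, 40), "negative")
  expect_equal(out, -7.5)
  expect_error(rbc_folate(10, 5, 0), "hct")
})
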