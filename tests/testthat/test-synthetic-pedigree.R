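test_that("pedigree structure matches the cross design", {
  cfg <- sim_config(n_sibships = 1, n_f1_per_sibship = 1,
                    n_f2_per_sibship = 5, n_controls = 0)
  ped <- build_pedigree(cfg)
  # 2 F0 + 2 F1 (focal + folate-sufficient mate) + 5 F2
  expect_equal(nrow(ped), 9)
  expect_equal(sum(ped$generation == "F0"), 2)
  expect_equal(sum(ped$generation == "F1"), 2)
  expect_equal(sum(ped$generation == "F2"), 5)
  # group C: both F0 on the deficient diet
  pc <- build_pedigree(sim_config(groups = "C", n_controls = 0))
  expect_true(all(pc$diet[pc$generation == "F0"] == "FD"))
  # group A: dam only; group B: sire only
  pa <- build_pedigree(sim_config(groups = "A", n_controls = 0))
  expect_equal(pa$diet[pa$generation == "F0"], c("FD", "FS"))
  pb <- build_pedigree(sim_config(groups = "B", n_controls = 0))
  expect_equal(pb$diet[pb$generation == "F0"], c("FS", "FD"))
})

test_that("every F2 has two parents present in the pedigree", {
  ped <- build_pedigree(sim_config(n_sibships = 3, groups = c("A", "B", "C"),
                                   n_f1_per_sibship = 2,
                                   n_f2_per_sibship = 7))
  f2 <- ped[ped$generation == "F2", ]
  # brute-force graph validation
  for (i in seq_len(nrow(f2))) {
    expect_true(f2$father_id[i] %in% ped$sample_id)
    expect_true(f2$mother_id[i] %in% ped$sample_id)
    expect_equal(ped$generation[ped$sample_id == f2$father_id[i]], "F1")
    expect_equal(ped$generation[ped$sample_id == f2$mother_id[i]], "F1")
  }
  expect_error(sim_config(n_sibships = 0), "sibship")
  expect_error(sim_config(n_f2_per_sibship = 0), "F2")
})

test_that("founder variants transmit at Mendelian frequency", {
  cfg <- sim_config(n_founder_snvs = 0, n_shared_ancestral_snvs = 0,
                    n_controls = 0)
  ped <- build_pedigree(cfg)
  empty <- simulate_inherited_variants(ped, cfg)
  expect_equal(nrow(empty$sites), 0)
  expect_equal(nrow(empty$carriers), 0)

  # one het founder site per replicate: the focal F1 inherits w.p. 1/2
  cfg1 <- sim_config(n_founder_snvs = 1, n_shared_ancestral_snvs = 0,
                     n_controls = 0, n_f2_per_sibship = 1)
  ped1 <- build_pedigree(cfg1)
  set.seed(101)
  n_rep <- 2000
  f1_carrier <- vapply(seq_len(n_rep), function(i) {
    inh <- simulate_inherited_variants(ped1, cfg1)
    "S1_F1_1" %in% inh$carriers$sample_id
  }, logical(1))
  freq <- mean(f1_carrier)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / n_rep))
})

test_that("ancestral variants are carried by every sample", {
  cfg <- small_config(n_founder_snvs = 0, n_shared_ancestral_snvs = 4)
  ped <- build_pedigree(cfg)
  set.seed(3)
  inh <- simulate_inherited_variants(ped, cfg)
  per_site <- table(paste(inh$carriers$chrom, inh$carriers$pos))
  expect_equal(length(per_site), 4)
  expect_true(all(per_site == nrow(ped)))
})

test_that("injected DNM counts are Poisson and timing labels Bernoulli", {
  g <- mouse_genome_model()
  expect_equal(nrow(inject_dnms("s", 0, 0.5, fd_spectrum(), g)), 0)

  set.seed(17)
  all13 <- inject_dnms("s", 0, p_mismatch = 1, fd_spectrum(), g, n = 200)
  expect_true(all(all13$true_vaf == 0.25))
  expect_true(all(all13$timing == "unrepaired_mismatch"))
  all22 <- inject_dnms("s", 0, p_mismatch = 0, fd_spectrum(), g, n = 50)
  expect_true(all(all22$true_vaf == 0.5))

  # mean and variance both ~ lambda over many samples
  lambda <- 30
  n_samp <- 1000
  tr <- inject_dnms(sprintf("s%d", seq_len(n_samp)), lambda, 0.466,
                    fd_spectrum(), g)
  counts <- as.numeric(table(factor(tr$sample_id,
                                    levels = sprintf("s%d", seq_len(n_samp)))))
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / n_samp))
  expect_lt(abs(stats::var(counts) - lambda),
            3 * lambda * sqrt(2 / (n_samp - 1)))
  frac <- mean(tr$true_vaf == 0.25)
  expect_lt(abs(frac - 0.466), 3 * sqrt(0.466 * 0.534 / nrow(tr)))

  # positions never collide with the avoid set, the mask, or each other
  expect_false(any(duplicated(paste(tr$chrom, tr$pos))))
  expect_false(any(in_mask(tr$chrom, tr$pos - 1, g$repeat_mask)))
  tiny <- genome_model(tibble::tibble(chrom = "c", length = 100),
                       x_name = NA, y_name = NA)
  expect_error(inject_dnms("s", 0, 0.5, fd_spectrum(), tiny, n = 500),
               "too small")
})

test_that("read sampling is binomial at the true allele fraction", {
  g <- mouse_genome_model()
  set.seed(23)
  none <- simulate_reads(
    tibble::tibble(sample_id = "s", chrom = "chr1", pos = 1:500,
                   ref = "C", alt = "T", true_vaf = 0),
    depth_mean = 30
  )
  expect_true(all(none$alt_depth == 0))

  het <- simulate_reads(
    tibble::tibble(sample_id = "s", chrom = "chr1", pos = 1:10000,
                   ref = "C", alt = "T", true_vaf = 0.5),
    depth_mean = 30
  )
  expect_lt(abs(mean(het$alt_depth / het$total_depth) - 0.5), 0.01)

  # at fixed depth 30 the exceedance P(VAF >= 0.30) matches the exact tail
  q13 <- simulate_reads(
    tibble::tibble(sample_id = "s", chrom = "chr1", pos = 1:10000,
                   ref = "C", alt = "T", true_vaf = 0.25),
    depth_mean = 30, depth_model = "fixed"
  )
  expect_true(all(q13$total_depth == 30))
  emp <- mean(q13$alt_depth / 30 >= 0.30)
  exact <- stats::pbinom(8, 30, 0.25, lower.tail = FALSE)  # P(X >= 9)
  expect_lt(abs(emp - exact), 3 * sqrt(exact * (1 - exact) / 10000))
})

test_that("observed VAF distribution at fixed depth is binomial (chi-square)", {
  set.seed(31)
  rd <- simulate_reads(
    tibble::tibble(sample_id = "s", chrom = "chr1", pos = 1:10000,
                   ref = "C", alt = "T", true_vaf = 0.5),
    depth_mean = 30, depth_model = "fixed"
  )
  obs <- tabulate(rd$alt_depth + 1L, nbins = 31L)
  expected <- 10000 * stats::dbinom(0:30, 30, 0.5)
  keep <- expected >= 5
  obs2 <- c(sum(obs[!keep & 0:30 < 15]), obs[keep],
            sum(obs[!keep & 0:30 > 15]))
  exp2 <- c(sum(expected[!keep & 0:30 < 15]), expected[keep],
            sum(expected[!keep & 0:30 > 15]))
  stat <- sum((obs2 - exp2)^2 / exp2)
  p <- stats::pchisq(stat, length(obs2) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("a fixed seed reproduces the study byte for byte", {
  cfg <- small_config(seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixtures(simulate_study(cfg), d1)
  write_fixtures(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
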