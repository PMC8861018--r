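sv_candidate <- function(sample_id, region, flank, genome_mean,
                         sibship = "S1", chrom = "chr1", start = 1000,
                         end = 1200, type = "DEL") {
  tibble::tibble(sample_id = sample_id, sibship_id = sibship, chrom = chrom,
                 start = start, end = end, sv_type = type,
                 region_depth = region, flank_depth = flank,
                 genome_mean_depth = genome_mean)
}

test_that("depth normalization brings sibship members to a common mean", {
  cand <- dplyr::bind_rows(
    sv_candidate("a", 10, 18, 20),
    sv_candidate("b", 20, 36, 40)
  )
  norm <- normalize_depths(cand)
  expect_equal(norm$depth_scale, c(1.5, 0.75))
  expect_equal(norm$genome_mean_depth, c(30, 30))
  expect_equal(norm$region_depth, c(15, 15))

  solo <- normalize_depths(sv_candidate("a", 10, 18, 20))
  expect_equal(solo$depth_scale, 1)
  expect_error(normalize_depths(sv_candidate("a", 10, 18, 0)), "depth")
})

test_that("SV filtering enforces the half-depth deviation from both references", {
  kept <- filter_sv_candidates(sv_candidate("a", 10, 28, 30))
  expect_equal(nrow(kept), 1)  # |10-30| >= 15 and |10-28| >= 14
  # equal to the genome mean: dropped
  expect_equal(nrow(filter_sv_candidates(sv_candidate("a", 30, 10, 30))), 0)
  # deviates from the genome mean but not the flank: dropped
  expect_equal(nrow(filter_sv_candidates(sv_candidate("a", 10, 12, 30))), 0)
  # boundary inclusive on both clauses
  expect_equal(nrow(filter_sv_candidates(sv_candidate("a", 15, 30, 30))), 1)

  # candidates overlapping excluded chromosome ends are ignored
  ends <- tibble::tibble(chrom = "chr1", start = 0, end = 1100)
  expect_equal(nrow(filter_sv_candidates(sv_candidate("a", 10, 28, 30),
                                         excluded_regions = ends)), 0)
  beside <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  expect_equal(nrow(filter_sv_candidates(sv_candidate("a", 10, 28, 30),
                                         excluded_regions = beside)), 1)
})

test_that("de novo SV flags fire on a half-depth parent-offspring difference", {
  f2 <- dplyr::bind_rows(
    sv_candidate("k1", 15, 10, 30), # vs father 30: |15-30| = 15 >= 15
    sv_candidate("k2", 30, 10, 30), # matches both parents
    sv_candidate("k3", 46, 10, 30)  # |46-30| = 16 >= 15
  )
  f2$father_depth <- 30
  f2$mother_depth <- 30
  flagged <- flag_de_novo_svs(f2)
  expect_equal(flagged$de_novo_flag, c(TRUE, FALSE, TRUE))
  # one divergent parent suffices
  one <- sv_candidate("k", 30, 10, 30)
  one$father_depth <- 30
  one$mother_depth <- 12
  expect_true(flag_de_novo_svs(one)$de_novo_flag)
  expect_error(flag_de_novo_svs(sv_candidate("k", 30, 10, 30)), "father_depth")
})

test_that("screening decisions are invariant to the absolute depth scale", {
  set.seed(113)
  cand <- tibble::tibble(
    sample_id = sample(letters[1:4], 50, replace = TRUE),
    sibship_id = "S1", chrom = "chr1",
    start = seq(0, by = 2000, length.out = 50),
    end = seq(0, by = 2000, length.out = 50) + sample(50:500, 50, TRUE),
    sv_type = sample(c("DEL", "DUP"), 50, TRUE),
    region_depth = runif(50, 1, 60),
    flank_depth = runif(50, 10, 50),
    genome_mean_depth = 30
  )
  cand$father_depth <- runif(50, 5, 60)
  cand$mother_depth <- runif(50, 5, 60)
  key <- function(x) paste(x$sample_id, x$start)
  for (c_mult in c(0.2, 5)) {
    scaled <- dplyr::mutate(cand, dplyr::across(
      c(region_depth, flank_depth, genome_mean_depth,
        father_depth, mother_depth), ~ .x * c_mult))
    expect_equal(key(filter_sv_candidates(scaled)),
                 key(filter_sv_candidates(cand)))
    expect_equal(flag_de_novo_svs(scaled)$de_novo_flag,
                 flag_de_novo_svs(cand)$de_novo_flag)
  }
  kept <- filter_sv_candidates(cand)
  expect_true(all(key(kept) %in% key(cand)))
})

test_that("size histograms conserve counts within type", {
  expect_equal(nrow(size_distribution(sv_candidate("a", 1, 1, 1)[0, ])), 0)
  set.seed(127)
  lens <- sample(50:200, 40, replace = TRUE)
  dels <- tibble::tibble(sample_id = "a", sibship_id = "S1", chrom = "chr1",
                         start = 0, end = lens, sv_type = "DEL")
  dups <- tibble::tibble(sample_id = "a", sibship_id = "S1", chrom = "chr1",
                         start = 0, end = sample(100:1000, 15, TRUE),
                         sv_type = "DUP")
  h <- size_distribution(dplyr::bind_rows(dels, dups))
  expect_equal(sum(h$count[h$sv_type == "DEL"]), 40)
  expect_equal(sum(h$count[h$sv_type == "DUP"]), 15)
  # all deletion mass lies in bins covering [50, 200]
  del_bins <- h[h$sv_type == "DEL" & h$count > 0, ]
  expect_true(all(del_bins$bin_start >= 50 & del_bins$bin_end <= 500))
})
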