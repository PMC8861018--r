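caller_pedigree <- function() {
  build_pedigree(sim_config(n_sibships = 1, n_f1_per_sibship = 1,
                            n_f2_per_sibship = 1, n_controls = 1))
}

test_that("the lenient presence criterion behaves at its thresholds", {
  expect_true(variant_present(5, 30))
  expect_false(variant_present(0, 30))
  expect_false(variant_present(1, 40))   # 1 read, VAF 0.025: absent
  expect_true(variant_present(2, 40))    # 2 reads alone establish presence
  expect_true(variant_present(1, 10))    # VAF 0.10 >= 0.05 at depth >= 10
  expect_false(variant_present(1, 9))    # depth below the VAF route
})

test_that("DNMs are called only when absent from parents and grandparents", {
  ped <- caller_pedigree()
  samples <- ped$sample_id
  v <- dplyr::bind_rows(
    site_calls(100, samples, carriers = "S1_F2_1"),                 # true DNM
    site_calls(200, samples, carriers = c("S1_F2_1", "S1_F1_1")),   # in father
    site_calls(300, samples, carriers = c("S1_F2_1", "S1_F0_dam"))  # in F0
  )
  dnms <- call_dnms(v, ped)
  expect_equal(dnms$pos, 100)
  expect_equal(dnms$sample_id, "S1_F2_1")
  expect_equal(dnms$vaf, 12 / 30)
  expect_equal(dnms$genotype_class, "2:2")
  expect_equal(dnms$substitution_class, "G:C>A:T")

  # output invariant to the order of the variant table
  set.seed(7)
  shuffled <- v[sample.int(nrow(v)), ]
  expect_equal(dplyr::arrange(call_dnms(shuffled, ped), .data$pos), dnms)

  # a parent that merely fails QC still blocks the call (1 read at the
  # VAF route's depth): presence is lenient by design
  v2 <- dplyr::bind_rows(
    site_calls(400, setdiff(samples, "S1_mate_1"), carriers = "S1_F2_1"),
    make_call("S1_mate_1", 400, alt_depth = 2, total_depth = 12, qual = 20)
  )
  expect_equal(nrow(call_dnms(v2, ped)), 0)
})

test_that("calling fails loudly when a parent has no variant table", {
  ped <- caller_pedigree()
  v <- site_calls(100, setdiff(ped$sample_id, "S1_mate_1"),
                  carriers = "S1_F2_1")
  expect_error(call_dnms(v, ped), "S1_mate_1")
  expect_error(call_dnms(site_calls(1, ped$sample_id), ped,
                         samples = "nobody"), "nobody")
})

test_that("F1 calling screens against F0 but not against F1 sibs", {
  ped <- build_pedigree(sim_config(n_f1_per_sibship = 2,
                                   n_f2_per_sibship = 2, n_controls = 0))
  samples <- ped$sample_id
  v <- dplyr::bind_rows(
    site_calls(100, samples, carriers = "S1_F1_1"),                  # F1 DNM
    site_calls(200, samples, carriers = c("S1_F1_1", "S1_F0_sire"))  # inherited
  )
  dnms <- call_dnms(v, ped, samples = "S1_F1_1")
  expect_equal(dnms$pos, 100)
})

test_that("shared-variant removal drops ancestral and control-borne variants", {
  ped <- build_pedigree(sim_config(n_sibships = 2, n_f2_per_sibship = 1,
                                   n_controls = 1))
  samples <- ped$sample_id
  v <- dplyr::bind_rows(
    # present in both sibships and the control: ancestral
    site_calls(100, samples, carriers = c("S1_F2_1", "S2_F0_dam", "CTRL_1")),
    # private to one F2: genuine candidate
    site_calls(200, samples, carriers = "S1_F2_1"),
    # in the control only (plus the focal candidate): ancestral
    site_calls(300, samples, carriers = c("S1_F2_1", "CTRL_1"))
  )
  cand <- v[v$sample_id == "S1_F2_1" & v$alt_depth > 0, ]
  kept <- remove_shared_snvs(cand, v, ped)
  expect_equal(kept$pos, 200)

  # shared across sibships but absent from controls is still removed
  v2 <- site_calls(500, samples, carriers = c("S1_F2_1", "S2_F2_1"))
  cand2 <- v2[v2$sample_id == "S1_F2_1" & v2$alt_depth > 0, ]
  expect_equal(nrow(remove_shared_snvs(cand2, v2, ped)), 0)

  expect_error(
    remove_shared_snvs(cand, v,
                       ped[ped$sibship_id == "S1" & ped$group != "control", ]),
    "sibships"
  )
})

test_that("shared-variant removal never touches sample-private variants", {
  ped <- build_pedigree(sim_config(n_sibships = 3, n_f2_per_sibship = 2,
                                   n_controls = 2))
  samples <- ped$sample_id
  set.seed(53)
  for (rep in 1:20) {
    carriers <- sample(samples, sample(1:4, 1))
    v <- site_calls(1000 + rep, samples, carriers = carriers)
    cand <- v[v$sample_id %in% carriers, ]
    kept <- remove_shared_snvs(cand, v, ped)
    # membership oracle: removed iff in a control or in every sibship
    sib <- unique(ped$sibship_id[ped$group != "control"])
    covered <- unique(ped$sibship_id[match(carriers, ped$sample_id)])
    in_ctrl <- any(ped$group[match(carriers, ped$sample_id)] == "control")
    should_drop <- in_ctrl || all(sib %in% covered)
    expect_equal(nrow(kept), if (should_drop) 0 else nrow(cand))
    if (length(carriers) == 1 && !in_ctrl) expect_gt(nrow(kept), 0)
  }
})

test_that("sex inference follows the X/Y coverage ratio thresholds", {
  g <- tiny_genome()
  prof <- function(id, x, y) {
    tibble::tibble(sample_id = id, chrom = c("chr1", "chr2", "chrX", "chrY"),
                   mean_depth = c(30, 30, 30 * x, 30 * y))
  }
  cov <- dplyr::bind_rows(prof("m", 0.5, 0.5), prof("f", 1.0, 0.01),
                          prof("amb", 0.9, 0.15))
  res <- infer_sex(cov, g)
  expect_equal(res$inferred_sex[match(c("m", "f", "amb"), res$sample_id)],
               c("male", "female", "ambiguous"))
  no_sex <- genome_model(tibble::tibble(chrom = "chr1", length = 1e6),
                         x_name = NA, y_name = NA)
  expect_error(infer_sex(cov, no_sex), "sex chromosomes")
})

test_that("count summaries partition DNMs by sample, sibship and sex", {
  ped <- build_pedigree(small_config())
  empty <- count_dnms_by_sample(tibble::tibble(sample_id = character()), ped)
  expect_true(all(empty$per_sample$n_dnms == 0))

  cfg <- small_config(seed = 61, n_f2_per_sibship = 23,
                      n_founder_snvs = 5, n_shared_ancestral_snvs = 2)
  sim <- simulate_study(cfg)
  kept <- dplyr::filter(
    filter_variants(sim$variants, mask = cfg$genome$repeat_mask), .data$pass
  )
  dnms <- call_dnms(kept, sim$pedigree)
  counts <- count_dnms_by_sample(dnms, sim$pedigree)
  # group mean within the 95% Poisson CI of the simulated rate
  grp <- counts$per_group[counts$per_group$group == "B", ]
  expect_lt(abs(grp$mean - 87.6), 1.96 * sqrt(87.6 / grp$n_samples) + 3)

  # counts split by coverage-inferred sex agree with the pedigree truth
  sexes <- infer_sex(sim$coverage, cfg$genome)
  joined <- dplyr::inner_join(counts$per_sample, sexes, by = "sample_id")
  expect_equal(joined$inferred_sex, joined$sex)
  by_inferred <- tapply(joined$n_dnms, joined$inferred_sex, sum)
  by_truth <- tapply(joined$n_dnms, joined$sex, sum)
  expect_equal(as.numeric(by_inferred[c("female", "male")]),
               as.numeric(by_truth[c("female", "male")]))
})
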