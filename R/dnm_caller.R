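#' Lenient presence criterion for a variant in a sample
#'
#' Used to decide whether a candidate DNM was "observed" in a parent or
#' grandparent.  Deliberately more lenient than the candidate qualification
#' filter: a variant that merely failed QC in a parent must still block a
#' de novo call in the child.
#'
#' @param alt_depth,total_depth Read counts.
#' @param min_alt_reads Alternate reads that alone establish presence
#'   (default 2).
#' @param min_vaf,min_depth Alternatively, observed VAF of at least
#'   `min_vaf` at depth of at least `min_depth` establishes presence.
#' @return Logical vector.
#' @export
variant_present <- function(alt_depth, total_depth, min_alt_reads = 2,
                            min_vaf = 0.05, min_depth = 10) {
  alt_depth >= min_alt_reads |
    (total_depth >= min_depth & alt_depth / pmax(total_depth, 1) >= min_vaf)
}

#' Call de novo mutations in F1/F2 samples
#'
#' A variant is called de novo in a focal sample when it carries adequate
#' alternate support in that sample and is absent — under the lenient
#' [variant_present()] criterion — from both parents and from every
#' sequenced earlier-generation member of the focal sample's sibship (F0 for
#' an F1 focal; F0 and F1 for an F2 focal).  Using all three generations of
#' a sibship, not just the parents, is what drives the false-positive rate
#' down in this design.
#'
#' @param variants Variant-call tibble, normally the kept set from
#'   [filter_variants()].
#' @param pedigree Pedigree tibble (see [build_pedigree()]).
#' @param samples Focal sample ids; defaults to every F2 in the pedigree.
#' @param min_alt_reads Minimum alternate reads in the focal sample for a
#'   candidate (default 3, matching the qualification filter).
#' @param rule [genotype_rule()] used to classify each call's VAF.
#' @param present_args List of arguments forwarded to [variant_present()]
#'   for the relatives.
#' @param presence_variants Variant table used to judge presence in
#'   relatives; pass the *unfiltered* table here when `variants` is the
#'   QC-kept set, so a parental variant that merely failed QC still blocks
#'   the call.  Defaults to `variants`.
#' @return A DNM tibble: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `total_depth`, `alt_depth`, `vaf`, `genotype_class`,
#'   `substitution_class`.
#' @export
call_dnms <- function(variants, pedigree, samples = NULL, min_alt_reads = 3,
                      rule = genotype_rule(), present_args = list(),
                      presence_variants = variants) {
  if (is.null(samples)) {
    samples <- pedigree$sample_id[pedigree$generation == "F2"]
  }
  unknown <- setdiff(samples, pedigree$sample_id)
  if (length(unknown)) {
    stop("focal sample(s) not in pedigree: ", paste(unknown, collapse = ", "))
  }
  sequenced <- unique(presence_variants$sample_id)
  present <- presence_variants[
    do.call(variant_present,
            c(list(presence_variants$alt_depth, presence_variants$total_depth),
              present_args)),
    c("sample_id", "chrom", "pos", "alt")
  ]
  gen_rank <- c(F0 = 0, F1 = 1, F2 = 2)
  out <- lapply(samples, function(s) {
    row <- pedigree[pedigree$sample_id == s, ]
    parents <- stats::na.omit(c(row$father_id, row$mother_id))
    missing <- setdiff(parents, sequenced)
    if (length(missing)) {
      stop("no variant table for parent(s) of ", s, ": ",
           paste(missing, collapse = ", "))
    }
    elders <- pedigree$sample_id[
      pedigree$sibship_id == row$sibship_id &
        gen_rank[pedigree$generation] < gen_rank[row$generation]
    ]
    relatives <- union(parents, intersect(elders, sequenced))
    cand <- variants[variants$sample_id == s &
                       variants$alt_depth >= min_alt_reads, ]
    if (nrow(cand) == 0) return(cand)
    seen <- present[present$sample_id %in% relatives, ]
    cand[!paste(cand$chrom, cand$pos, cand$alt) %in%
           paste(seen$chrom, seen$pos, seen$alt), ]
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(), pos = numeric(),
      ref = character(), alt = character(), total_depth = integer(),
      alt_depth = integer(), vaf = numeric(), genotype_class = character(),
      substitution_class = character()
    ))
  }
  out |>
    dplyr::mutate(
      vaf = vaf(.data$alt_depth, .data$total_depth),
      genotype_class = classify_genotype(.data$vaf, rule),
      substitution_class = substitution_class(.data$ref, .data$alt)
    ) |>
    dplyr::select("sample_id", "chrom", "pos", "ref", "alt", "total_depth",
                  "alt_depth", "vaf", "genotype_class", "substitution_class")
}

#' Remove ancestrally shared variants from DNM candidates
#'
#' Variants that are present in at least one sample of *every* sibship, or
#' present in any unrelated control sample, are treated as ancestral strain
#' variation rather than de novo events and removed from all candidate
#' sets.  This is a deterministic, presence-based restatement of rooting a
#' phylogeny on all samples and discarding the root-shared variants.
#'
#' @param candidates DNM candidate tibble (any tibble with `chrom`, `pos`,
#'   `alt`).
#' @param variants Full variant-call tibble across all sequenced samples.
#' @param pedigree Pedigree tibble; samples with `group == "control"` (or in
#'   `control_samples`) form the control set, all others are grouped by
#'   `sibship_id`.
#' @param control_samples Optional explicit control sample ids.
#' @param present_args Arguments forwarded to [variant_present()].
#' @return `candidates` with shared/control variants removed.
#' @export
remove_shared_snvs <- function(candidates, variants, pedigree,
                               control_samples = NULL, present_args = list()) {
  if (is.null(control_samples)) {
    control_samples <- pedigree$sample_id[pedigree$group == "control"]
  }
  sib <- pedigree[!pedigree$sample_id %in% control_samples, ]
  sibships <- unique(sib$sibship_id)
  if (length(sibships) < 2 && length(control_samples) == 0) {
    stop("shared-variant removal needs >= 2 sibships or a control set")
  }
  pres <- variants[
    do.call(variant_present,
            c(list(variants$alt_depth, variants$total_depth), present_args)), ]
  pres$key <- paste(pres$chrom, pres$pos, pres$alt)
  pres$sibship_id <- sib$sibship_id[match(pres$sample_id, sib$sample_id)]
  in_control <- unique(pres$key[pres$sample_id %in% control_samples])
  shared_all <- character(0)
  if (length(sibships) >= 2) {
    per_sib <- unique(pres[!is.na(pres$sibship_id), c("key", "sibship_id")])
    tab <- table(per_sib$key)
    shared_all <- names(tab)[tab == length(sibships)]
  }
  drop <- union(in_control, shared_all)
  candidates[!paste(candidates$chrom, candidates$pos, candidates$alt) %in% drop, ]
}

#' Infer sample sex from sex-chromosome coverage
#'
#' Males carry one X and one Y, so both sex chromosomes sit near half the
#' autosomal depth; females show full-depth X and essentially no Y
#' coverage.  Classified by Y:autosome and X:autosome mean-depth ratios;
#' profiles matching neither pattern are `ambiguous`.
#'
#' @param coverage Tibble `sample_id`, `chrom`, `mean_depth` (e.g. the
#'   `coverage` element of [simulate_study()]).
#' @param genome A [genome_model()] naming the sex chromosomes.
#' @param y_male_min Minimum Y ratio for a male call (default 0.25).
#' @param x_male_max Maximum X ratio for a male call (default 0.75).
#' @param y_female_max Maximum Y ratio for a female call (default 0.05).
#' @param x_female_min Minimum X ratio for a female call (default 0.75).
#' @return Tibble `sample_id`, `x_ratio`, `y_ratio`, `inferred_sex`
#'   (`male`/`female`/`ambiguous`).
#' @export
infer_sex <- function(coverage, genome, y_male_min = 0.25, x_male_max = 0.75,
                      y_female_max = 0.05, x_female_min = 0.75) {
  if (is.na(genome$x_name) || is.na(genome$y_name) ||
      !all(c(genome$x_name, genome$y_name) %in% genome$chromosomes$chrom)) {
    stop("genome model lacks sex chromosomes")
  }
  coverage |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      auto = mean(.data$mean_depth[.data$chrom %in% genome$autosomes]),
      x = mean(.data$mean_depth[.data$chrom == genome$x_name]),
      y = mean(.data$mean_depth[.data$chrom == genome$y_name]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      x_ratio = .data$x / .data$auto,
      y_ratio = .data$y / .data$auto,
      inferred_sex = dplyr::case_when(
        .data$y_ratio >= y_male_min & .data$x_ratio <= x_male_max ~ "male",
        .data$y_ratio <= y_female_max & .data$x_ratio >= x_female_min ~ "female",
        TRUE ~ "ambiguous"
      )
    ) |>
    dplyr::select("sample_id", "x_ratio", "y_ratio", "inferred_sex")
}

#' Summarise DNM counts per sample, sibship and sex
#'
#' @param dnms DNM tibble from [call_dnms()].
#' @param pedigree Pedigree tibble.
#' @param samples Samples to report (zero counts included); defaults to the
#'   pedigree's F2 samples plus any sample appearing in `dnms`.
#' @return List of class `dnm_counts` with tibbles `per_sample`
#'   (`sample_id`, `sibship_id`, `group`, `sex`, `n_dnms`), `per_sibship`
#'   (mean and total per sibship), `per_group`, and `per_sex`.
#' @export
count_dnms_by_sample <- function(dnms, pedigree, samples = NULL) {
  if (is.null(samples)) {
    samples <- union(pedigree$sample_id[pedigree$generation == "F2"],
                     unique(dnms$sample_id))
  }
  per_sample <- pedigree |>
    dplyr::filter(.data$sample_id %in% samples) |>
    dplyr::select("sample_id", "sibship_id", "group", "sex") |>
    dplyr::left_join(dplyr::count(dnms, .data$sample_id, name = "n_dnms"),
                     by = "sample_id") |>
    dplyr::mutate(n_dnms = dplyr::coalesce(.data$n_dnms, 0L))
  summarise_by <- function(key) {
    per_sample |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::summarise(n_samples = dplyr::n(), total = sum(.data$n_dnms),
                       mean = mean(.data$n_dnms),
                       median = stats::median(.data$n_dnms), .groups = "drop")
  }
  structure(
    list(per_sample = per_sample, per_sibship = summarise_by("sibship_id"),
         per_group = summarise_by("group"), per_sex = summarise_by("sex")),
    class = "dnm_counts"
  )
}

#' @export
print.dnm_counts <- function(x, ...) {
  cat("<dnm_counts>\nPer-sample:\n")
  print(x$per_sample)
  cat("Per-sibship:\n")
  print(x$per_sibship)
  invisible(x)
}
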