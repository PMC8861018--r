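#' Single-nucleotide variant qualification rules
#'
#' The five rules a candidate SNV must pass, applied by [filter_variants()]:
#'
#' 1. **Depth**: total depth inside the hard 20–60x window *and* within
#'    three standard deviations of the sample's mean coverage.
#' 2. **Alternate support**: three or more reads carry the mutant allele.
#' 3. **Site quality**: phred site quality of at least 30 (inclusive).
#' 4. **Mapping quality**: mean mapping quality of both alleles strictly
#'    above 30.
#' 5. **Repeat mask**: the position does not fall in a tandem-repeat
#'    interval.
#'
#' The two quality thresholds deliberately differ in strictness ("minimum of
#' 30" is inclusive, "exceeds 30" is strict); both are parameters.
#'
#' @param total_depth,alt_depth Read counts.
#' @param mean_depth,sd_depth Per-sample coverage mean and standard
#'   deviation; an `NA` standard deviation disables the 3-SD band.
#' @param lo,hi Hard depth window (default 20–60).
#' @param n_sd Width of the coverage band in standard deviations.
#' @param min_reads Minimum alternate-supporting reads (default 3,
#'   inclusive).
#' @param qual,mq_ref,mq_alt Site quality and per-allele mean mapping
#'   qualities.
#' @param min_qual Site-quality threshold (inclusive, default 30).
#' @param min_mq Mapping-quality threshold (strict, default 30).
#' @return Logical vector.
#' @name variant_rules
NULL

#' @rdname variant_rules
#' @export
passes_depth <- function(total_depth, mean_depth, sd_depth,
                         lo = 20, hi = 60, n_sd = 3) {
  stopifnot(all(mean_depth > 0, na.rm = TRUE), all(sd_depth >= 0, na.rm = TRUE))
  band <- ifelse(is.na(sd_depth), TRUE,
                 abs(total_depth - mean_depth) <= n_sd * sd_depth)
  total_depth >= lo & total_depth <= hi & band
}

#' @rdname variant_rules
#' @export
passes_alt_support <- function(alt_depth, min_reads = 3) {
  alt_depth >= min_reads
}

#' @rdname variant_rules
#' @export
passes_quality <- function(qual, mq_ref, mq_alt, min_qual = 30, min_mq = 30) {
  qual >= min_qual & mq_ref > min_mq & mq_alt > min_mq
}

#' Remove variants overlapping a tandem-repeat mask
#'
#' Mask intervals are 0-based half-open; variant positions are 1-based, so a
#' variant at `pos` is removed when `pos - 1` lies inside an interval.
#' Record order is preserved.
#'
#' @param variants Variant-call tibble with `chrom` and `pos`.
#' @param mask Interval tibble (`chrom`, `start`, `end`).
#' @param genome Optional [genome_model()]; when given, mask intervals are
#'   validated against chromosome bounds.
#' @return The surviving rows of `variants`.
#' @export
apply_repeat_mask <- function(variants, mask, genome = NULL) {
  if (!is.null(genome)) {
    mask <- validate_intervals(mask, genome$chromosomes, "mask")
  }
  variants[!in_intervals(variants$chrom, variants$pos - 1, mask), ]
}

#' Per-sample coverage statistics
#'
#' Mean and standard deviation of total depth per sample, computed over the
#' sample's variant records (supply a genome-wide profile instead if you
#' have one — [filter_variants()] accepts either).
#'
#' @param variants Variant-call tibble.
#' @return Tibble `sample_id`, `mean_depth`, `sd_depth`, `n_records`.
#' @export
coverage_stats <- function(variants) {
  variants |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mean_depth = mean(.data$total_depth),
      sd_depth = stats::sd(.data$total_depth),
      n_records = dplyr::n(),
      .groups = "drop"
    )
}

#' Apply all qualification rules to a variant table
#'
#' Annotates every record with a pass flag and, for rejected records, the
#' first failing rule (`depth`, `alt_support`, `site_quality`,
#' `mapping_quality`, `repeat_mask`).  Membership of the kept set is the
#' order-independent conjunction of all rules; only the reported reason
#' depends on the evaluation order.
#'
#' @param variants Variant-call tibble.
#' @param coverage Per-sample coverage tibble (`sample_id`, `mean_depth`,
#'   `sd_depth`); computed from `variants` via [coverage_stats()] when
#'   `NULL`.  Every sample in `variants` must appear.
#' @param mask Tandem-repeat interval tibble; `NULL` disables rule 5.
#' @param genome Optional [genome_model()] for mask validation.
#' @inheritParams variant_rules
#' @return The input tibble with logical `pass` and character
#'   `reject_reason` (`NA` for kept records) columns appended.
#' @examples
#' v <- tibble::tibble(sample_id = "s1", chrom = "chr1", pos = c(100, 200),
#'                     ref = "C", alt = "T", qual = c(50, 20),
#'                     total_depth = 30L, alt_depth = 10L,
#'                     mq_ref = 55, mq_alt = 55)
#' filter_variants(v, coverage = tibble::tibble(sample_id = "s1",
#'                                              mean_depth = 30, sd_depth = 5))
#' @export
filter_variants <- function(variants, coverage = NULL, mask = NULL,
                            genome = NULL, lo = 20, hi = 60, n_sd = 3,
                            min_reads = 3, min_qual = 30, min_mq = 30) {
  if (is.null(coverage)) coverage <- coverage_stats(variants)
  missing <- setdiff(unique(variants$sample_id), coverage$sample_id)
  if (length(missing)) {
    stop("no coverage statistics for sample(s): ",
         paste(missing, collapse = ", "))
  }
  idx <- match(variants$sample_id, coverage$sample_id)
  ok_depth <- passes_depth(variants$total_depth,
                           coverage$mean_depth[idx], coverage$sd_depth[idx],
                           lo = lo, hi = hi, n_sd = n_sd)
  ok_alt <- passes_alt_support(variants$alt_depth, min_reads = min_reads)
  ok_qual <- variants$qual >= min_qual
  ok_mq <- variants$mq_ref > min_mq & variants$mq_alt > min_mq
  ok_mask <- if (is.null(mask)) rep(TRUE, nrow(variants)) else {
    if (!is.null(genome)) mask <- validate_intervals(mask, genome$chromosomes, "mask")
    !in_intervals(variants$chrom, variants$pos - 1, mask)
  }
  reason <- rep(NA_character_, nrow(variants))
  reason[!ok_mask] <- "repeat_mask"
  reason[!ok_mq] <- "mapping_quality"
  reason[!ok_qual] <- "site_quality"
  reason[!ok_alt] <- "alt_support"
  reason[!ok_depth] <- "depth"
  dplyr::mutate(variants, pass = is.na(reason), reject_reason = reason)
}
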