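#' Normalize SV candidate depths within sibships
#'
#' Structural-variant calls from read depth are only comparable across a
#' sibship after each sample's depths are scaled to a common sibship mean:
#' a sample with genome-wide mean depth `m_s` in a sibship with mean of
#' means `m_sib` has all three depth fields multiplied by `m_sib / m_s`.
#'
#' @param candidates SV candidate tibble: `sample_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `sv_type` (`DEL`/`DUP`), `region_depth`,
#'   `flank_depth`, `genome_mean_depth`, and a `sibship_id` column (join
#'   one in from the pedigree if absent).
#' @return `candidates` with depths rescaled and a `depth_scale` column.
#' @export
normalize_depths <- function(candidates) {
  stopifnot("sibship_id" %in% names(candidates))
  if (any(candidates$genome_mean_depth <= 0)) {
    stop("zero or negative genome mean depth")
  }
  sample_means <- candidates |>
    dplyr::distinct(.data$sibship_id, .data$sample_id, .data$genome_mean_depth)
  if (anyDuplicated(sample_means[, c("sibship_id", "sample_id")])) {
    stop("inconsistent genome_mean_depth within a sample")
  }
  scales <- sample_means |>
    dplyr::mutate(depth_scale = mean(.data$genome_mean_depth) / .data$genome_mean_depth,
                  .by = "sibship_id") |>
    dplyr::select("sample_id", "sibship_id", "depth_scale")
  candidates |>
    dplyr::left_join(scales, by = c("sample_id", "sibship_id")) |>
    dplyr::mutate(
      region_depth = .data$region_depth * .data$depth_scale,
      flank_depth = .data$flank_depth * .data$depth_scale,
      genome_mean_depth = .data$genome_mean_depth * .data$depth_scale
    )
}

#' Filter SV candidates by excluded regions and depth deviation
#'
#' Candidates overlapping centromere/telomere exclusion intervals are
#' dropped.  A surviving candidate is kept only when its region depth
#' deviates by at least half from *both* references: `|region - genome_mean|
#' >= 0.5 * genome_mean` and `|region - flank| >= 0.5 * flank` (boundaries
#' inclusive).  Decisions depend only on depth ratios, never on the
#' absolute depth scale.
#'
#' @param candidates SV candidate tibble (see [normalize_depths()]).
#' @param excluded_regions Interval tibble (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. `genome$excluded_ends`.
#' @param min_dev Minimum relative depth deviation (default 0.5).
#' @return The kept candidates.
#' @export
filter_sv_candidates <- function(candidates, excluded_regions = empty_intervals(),
                                 min_dev = 0.5) {
  if (nrow(candidates) == 0) return(candidates)
  overlaps <- rep(FALSE, nrow(candidates))
  if (nrow(excluded_regions) > 0) {
    for (i in seq_len(nrow(excluded_regions))) {
      e <- excluded_regions[i, ]
      overlaps <- overlaps | (candidates$chrom == e$chrom &
                                candidates$start < e$end &
                                candidates$end > e$start)
    }
  }
  dev_genome <- abs(candidates$region_depth - candidates$genome_mean_depth) >=
    min_dev * candidates$genome_mean_depth
  dev_flank <- abs(candidates$region_depth - candidates$flank_depth) >=
    min_dev * candidates$flank_depth
  candidates[!overlaps & dev_genome & dev_flank, ]
}

#' Flag putative de novo SVs by parent-offspring depth difference
#'
#' An F2 candidate is flagged when its region depth differs from the depth
#' of the same region in at least one parent by half the parental depth or
#' more: `|f2 - parent| >= 0.5 * parent` (inclusive).
#'
#' @param f2_candidates Kept F2 SV candidates with `region_depth` and
#'   columns `father_depth` and `mother_depth` (parental read depth over
#'   the candidate region).
#' @param min_diff Minimum relative depth difference (default 0.5).
#' @return `f2_candidates` with a logical `de_novo_flag` column.
#' @export
flag_de_novo_svs <- function(f2_candidates, min_diff = 0.5) {
  need <- c("father_depth", "mother_depth")
  if (!all(need %in% names(f2_candidates))) {
    stop("missing parental depth column(s): ",
         paste(setdiff(need, names(f2_candidates)), collapse = ", "))
  }
  if (anyNA(f2_candidates$father_depth) || anyNA(f2_candidates$mother_depth)) {
    stop("missing parental depth values")
  }
  diff_f <- abs(f2_candidates$region_depth - f2_candidates$father_depth) >=
    min_diff * f2_candidates$father_depth
  diff_m <- abs(f2_candidates$region_depth - f2_candidates$mother_depth) >=
    min_diff * f2_candidates$mother_depth
  dplyr::mutate(f2_candidates, de_novo_flag = diff_f | diff_m)
}

#' Length histogram of SV candidates by type
#'
#' @param candidates SV candidate tibble with `sv_type`, `start`, `end`.
#' @param breaks Histogram breakpoints in bp (right-open bins; values
#'   outside the range are pooled into the flanking bins).
#' @return Tibble `sv_type`, `bin` (label), `bin_start`, `bin_end`,
#'   `count`; per-type counts sum to the input count.
#' @export
size_distribution <- function(candidates,
                              breaks = c(0, 50, 100, 200, 500, 1000, Inf)) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(sv_type = character(), bin = character(),
                          bin_start = numeric(), bin_end = numeric(),
                          count = integer()))
  }
  len <- candidates$end - candidates$start
  stopifnot(all(len > 0))
  bin <- cut(len, breaks = breaks, right = FALSE, include.lowest = TRUE)
  tibble::tibble(sv_type = candidates$sv_type, bin = bin) |>
    dplyr::count(.data$sv_type, .data$bin, .drop = FALSE, name = "count") |>
    dplyr::mutate(
      bin_start = breaks[as.integer(.data$bin)],
      bin_end = breaks[as.integer(.data$bin) + 1L],
      bin = as.character(.data$bin)
    ) |>
    dplyr::select("sv_type", "bin", "bin_start", "bin_end", "count")
}
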