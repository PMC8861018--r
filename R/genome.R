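#' Genome model
#'
#' A lightweight description of the reference genome the pipeline operates on:
#' ordered chromosome names and lengths, which chromosomes are autosomes and
#' which are the sex chromosomes, a tandem-repeat mask, and per-chromosome
#' centromere/telomere exclusion intervals.  All interval tables use 0-based
#' half-open coordinates (BED convention); variant positions elsewhere in the
#' package are 1-based (VCF convention).
#'
#' @param chromosomes A data frame with columns `chrom` (character) and
#'   `length` (positive integer, bp), in the order the genome should be
#'   reported in.
#' @param x_name,y_name Names of the sex chromosomes; use `NA` if absent.
#'   Every other chromosome is treated as an autosome.
#' @param repeat_mask,excluded_ends Interval tables (`chrom`, `start`, `end`;
#'   0-based half-open) for tandem repeats and for centromere/telomere ends.
#'   Defaults are empty.
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes`, `autosomes`, `x_name`, `y_name`, `repeat_mask`,
#'   `excluded_ends`.
#' @examples
#' g <- genome_model(tibble::tibble(chrom = c("chr1", "chrX"),
#'                                  length = c(2e6, 1e6)),
#'                   x_name = "chrX", y_name = NA)
#' genome_size(g)
#' @export
genome_model <- function(chromosomes, x_name = "chrX", y_name = "chrY",
                         repeat_mask = empty_intervals(),
                         excluded_ends = empty_intervals()) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0) stop("genome must contain at least one chromosome")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  repeat_mask <- validate_intervals(repeat_mask, chromosomes, "repeat_mask")
  excluded_ends <- validate_intervals(excluded_ends, chromosomes, "excluded_ends")
  sex <- c(x_name, y_name)
  structure(
    list(
      chromosomes = chromosomes,
      autosomes = setdiff(chromosomes$chrom, sex[!is.na(sex)]),
      x_name = x_name,
      y_name = y_name,
      repeat_mask = repeat_mask,
      excluded_ends = excluded_ends
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model: %d chromosomes, %s bp (%d autosomes)>\n",
              nrow(x$chromosomes), format(genome_size(x), big.mark = ","),
              length(x$autosomes)))
  invisible(x)
}

#' @rdname genome_model
#' @param genome A `genome_model`.
#' @export
genome_size <- function(genome) sum(genome$chromosomes$length)

#' An empty 0-based half-open interval table
#' @return A zero-row tibble with columns `chrom`, `start`, `end`.
#' @export
empty_intervals <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric())
}

validate_intervals <- function(x, chromosomes, what = "intervals") {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(x)
  if (any(x$start < 0) || any(x$end < x$start)) {
    stop(what, ": intervals must satisfy 0 <= start <= end")
  }
  lens <- chromosomes$length[match(x$chrom, chromosomes$chrom)]
  if (anyNA(lens)) stop(what, ": interval on unknown chromosome")
  if (any(x$end > lens)) stop(what, ": interval extends beyond chromosome end")
  x
}

#' Desk-scale mouse genome model
#'
#' The 19 mouse autosomes plus X and Y at their GRCm38 relative lengths,
#' uniformly scaled (default 1/100, ~27 Mb total) so that uniform position
#' draws and window statistics run in seconds.  All rate arithmetic in the
#' package takes genome size as an explicit argument, so the scale never
#' leaks into mutation-rate results.
#'
#' @param scale Multiplier applied to the true chromosome lengths.
#' @param repeat_frac Fraction of each chromosome covered by a single
#'   deterministic tandem-repeat mask block (placed at 1/4 of the
#'   chromosome).  0 disables the mask.
#' @param end_frac Fraction of each chromosome end marked as
#'   centromere/telomere exclusion territory.  0 disables.
#' @return A [genome_model()].
#' @export
mouse_genome_model <- function(scale = 0.01, repeat_frac = 0.01, end_frac = 0.005) {
  full <- c(
    chr1 = 195471971, chr2 = 182113224, chr3 = 160039680, chr4 = 156508116,
    chr5 = 151834684, chr6 = 149736546, chr7 = 145441459, chr8 = 129401213,
    chr9 = 124595110, chr10 = 130694993, chr11 = 122082543, chr12 = 120129022,
    chr13 = 120421639, chr14 = 124902244, chr15 = 104043685, chr16 = 98207768,
    chr17 = 94987271, chr18 = 90702639, chr19 = 61431566,
    chrX = 171031299, chrY = 91744698
  )
  lens <- floor(full * scale)
  chroms <- tibble::tibble(chrom = names(lens), length = unname(lens))
  mask <- empty_intervals()
  if (repeat_frac > 0) {
    start <- floor(chroms$length / 4)
    mask <- tibble::tibble(chrom = chroms$chrom, start = start,
                           end = start + floor(chroms$length * repeat_frac))
  }
  ends <- empty_intervals()
  if (end_frac > 0) {
    w <- floor(chroms$length * end_frac)
    ends <- dplyr::bind_rows(
      tibble::tibble(chrom = chroms$chrom, start = 0, end = w),
      tibble::tibble(chrom = chroms$chrom, start = chroms$length - w,
                     end = chroms$length)
    )
  }
  genome_model(chroms, x_name = "chrX", y_name = "chrY",
               repeat_mask = mask, excluded_ends = ends)
}

# TRUE for each (chrom, pos0) falling inside any interval; pos0 is 0-based.
in_intervals <- function(chrom, pos0, intervals) {
  hit <- rep(FALSE, length(chrom))
  if (nrow(intervals) == 0) return(hit)
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                    pos0 >= intervals$start[i] & pos0 < intervals$end[i])
  }
  hit
}
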