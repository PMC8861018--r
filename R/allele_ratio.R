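#' Genotype-class rule for mutation timing
#'
#' Observed VAF intervals mapping each DNM to a timing class:
#' `[lo_11, hi_11]` (default \[0.30, 0.70\]) is the `2:2` class — the
#' mutation was fixed on one parental haplotype before gamete formation, so
#' half the reads carry it; `[lo_13, lo_11)` (default \[0.10, 0.30)) is the
#' `1:3` class — an unrepaired mismatch segregating on one of the four
#' post-replication strands, so a quarter of the reads carry it.  The two
#' published ranges meet at 0.30; the boundary is assigned to `2:2` by the
#' half-open convention, and everything outside \[0.10, 0.70\] is
#' `unclassified`.
#'
#' @param lo_13 Lower VAF bound of the `1:3` class.
#' @param lo_11 Boundary between the classes (lower bound of `2:2`).
#' @param hi_11 Upper VAF bound of the `2:2` class.
#' @return An object of class `genotype_rule`.
#' @export
genotype_rule <- function(lo_13 = 0.10, lo_11 = 0.30, hi_11 = 0.70) {
  if (!(0 < lo_13 && lo_13 < lo_11 && lo_11 < hi_11 && hi_11 < 1)) {
    stop("require 0 < lo_13 < lo_11 < hi_11 < 1")
  }
  structure(list(lo_13 = lo_13, lo_11 = lo_11, hi_11 = hi_11),
            class = "genotype_rule")
}

#' Variant allele fraction
#'
#' @param alt_depth,total_depth Read counts; `total_depth` must be positive.
#' @return `alt_depth / total_depth`.
#' @export
vaf <- function(alt_depth, total_depth) {
  if (any(total_depth <= 0)) stop("total_depth must be positive")
  if (any(alt_depth < 0) || any(alt_depth > total_depth)) {
    stop("require 0 <= alt_depth <= total_depth")
  }
  alt_depth / total_depth
}

#' Classify an observed VAF into a timing class
#'
#' @param x Observed VAF values in \[0, 1\].
#' @param rule A [genotype_rule()].
#' @return Character vector over `"2:2"`, `"1:3"`, `"unclassified"`.
#' @examples
#' classify_genotype(c(0.5, 0.25, 0.30, 0.05))
#' @export
classify_genotype <- function(x, rule = genotype_rule()) {
  stopifnot(inherits(rule, "genotype_rule"), all(x >= 0), all(x <= 1))
  dplyr::case_when(
    x >= rule$lo_11 & x <= rule$hi_11 ~ "2:2",
    x >= rule$lo_13 & x < rule$lo_11 ~ "1:3",
    TRUE ~ "unclassified"
  )
}

#' Timing-class summary of a set of DNMs
#'
#' @param dnms DNM tibble with a `genotype_class` column (see
#'   [call_dnms()]), or with a `vaf` column to classify on the fly.
#' @param rule A [genotype_rule()] used when classification is needed.
#' @return A tibble with one row per class (`genotype_class`, `n`,
#'   `fraction`), all three classes always present; the per-sample
#'   breakdown is attached as attribute `"per_sample"`.
#' @examples
#' d <- tibble::tibble(sample_id = "f1",
#'                     vaf = c(rep(0.5, 56), rep(0.25, 21)))
#' timing_summary(d)  # 2:2 fraction 72.7%
#' @export
timing_summary <- function(dnms, rule = genotype_rule()) {
  if (!"genotype_class" %in% names(dnms)) {
    dnms <- dplyr::mutate(dnms, genotype_class = classify_genotype(.data$vaf, rule))
  }
  lv <- c("2:2", "1:3", "unclassified")
  total <- nrow(dnms)
  out <- dnms |>
    dplyr::count(genotype_class = factor(.data$genotype_class, levels = lv),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(genotype_class = as.character(.data$genotype_class),
                  fraction = if (total > 0) .data$n / total else 0)
  per_sample <- if ("sample_id" %in% names(dnms)) {
    dnms |>
      dplyr::count(.data$sample_id,
                   genotype_class = factor(.data$genotype_class, levels = lv),
                   .drop = FALSE, name = "n") |>
      dplyr::mutate(genotype_class = as.character(.data$genotype_class))
  } else NULL
  attr(out, "per_sample") <- per_sample
  out
}

#' Exact misclassification probability under binomial read sampling
#'
#' For a DNM whose true VAF is `true_vaf` sequenced at integer depth
#' `depth`, the observed alternate count is Binomial(depth, true_vaf); this
#' returns the exact probability that the observed VAF falls outside the
#' interval of the true timing class.  Provided for error analysis — the
#' classifier itself always uses the raw observed VAF.
#'
#' @param true_vaf True allele fraction (0.5 for `2:2`, 0.25 for `1:3`; any
#'   value in (0,1) classifiable by `rule` is accepted).
#' @param depth Integer sequencing depth (>= 1).
#' @param rule A [genotype_rule()].
#' @return Probability in \[0, 1\].
#' @examples
#' expected_misclassification(0.25, 30)  # P(X >= 9) + P(X <= 2), X ~ Bin(30, .25)
#' @export
expected_misclassification <- function(true_vaf, depth, rule = genotype_rule()) {
  stopifnot(depth >= 1, depth == round(depth), true_vaf >= 0, true_vaf <= 1)
  true_class <- classify_genotype(true_vaf, rule)
  if (true_class == "unclassified") {
    stop("true_vaf ", true_vaf, " has no timing class under this rule")
  }
  k <- 0:depth
  wrong <- classify_genotype(k / depth, rule) != true_class
  sum(stats::dbinom(k[wrong], depth, true_vaf))
}
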