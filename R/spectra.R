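#' The six strand-collapsed substitution classes
#'
#' Point mutations are conventionally reported on the base *pair*, so the 12
#' raw single-nucleotide substitutions collapse into six strand-symmetric
#' classes: a C>T on one strand and a G>A on the other are the same event,
#' written `G:C>A:T`.
#'
#' @return Character vector of the six class labels, in the package's
#'   canonical reporting order.
#' @export
substitution_classes <- function() {
  c("G:C>A:T", "A:T>G:C", "G:C>T:A", "G:C>C:G", "A:T>T:A", "A:T>C:G")
}

.sub_class_map <- c(
  "C>T" = "G:C>A:T", "G>A" = "G:C>A:T",
  "T>C" = "A:T>G:C", "A>G" = "A:T>G:C",
  "C>A" = "G:C>T:A", "G>T" = "G:C>T:A",
  "C>G" = "G:C>C:G", "G>C" = "G:C>C:G",
  "T>A" = "A:T>T:A", "A>T" = "A:T>T:A",
  "T>G" = "A:T>C:G", "A>C" = "A:T>C:G"
)

#' Strand-collapsed class of a single-nucleotide substitution
#'
#' @param ref,alt Single bases in `A`, `C`, `G`, `T`; vectors are recycled
#'   to common length.  `ref != alt` elementwise.
#' @return Character vector of class labels (see [substitution_classes()]).
#' @examples
#' substitution_class("C", "T")  # "G:C>A:T"
#' substitution_class("G", "A")  # same class, opposite strand
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!all(ref %in% c("A", "C", "G", "T")) || !all(alt %in% c("A", "C", "G", "T"))) {
    stop("substitution_class() is defined for single-nucleotide A/C/G/T alleles")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  unname(.sub_class_map[paste0(ref, ">", alt)])
}

# shape of the non-focal classes, relative proportions from reported
# spontaneous C57BL/6J germline spectra (renormalised against 1 - gc_at)
.spectrum_shape <- c(
  "A:T>G:C" = 0.17, "G:C>T:A" = 0.11, "G:C>C:G" = 0.06,
  "A:T>T:A" = 0.07, "A:T>C:G" = 0.06
)

#' Substitution-spectrum probability vectors
#'
#' Six-class probability vectors used by the synthetic generator.  Only the
#' focal G:C>A:T proportion differs between arms: 53% for mice on the normal
#' (folate-sufficient) diet versus 35.4% under folate deficiency; the
#' remaining five classes keep the relative shape of reported spontaneous
#' C57BL/6J spectra, renormalised to `1 - gc_at`.
#'
#' @param gc_at Probability assigned to the `G:C>A:T` class.
#' @return Named numeric vector over [substitution_classes()], summing to 1.
#' @export
mutation_spectrum <- function(gc_at) {
  stopifnot(gc_at >= 0, gc_at < 1)
  rest <- .spectrum_shape * (1 - gc_at) / sum(.spectrum_shape)
  out <- c("G:C>A:T" = gc_at, rest)[substitution_classes()]
  out
}

#' @rdname mutation_spectrum
#' @export
control_spectrum <- function(gc_at = 0.53) mutation_spectrum(gc_at)

#' @rdname mutation_spectrum
#' @export
fd_spectrum <- function(gc_at = 0.354) mutation_spectrum(gc_at)

# draw (ref, alt) pairs for given class labels, picking one of the two
# strand orientations uniformly
draw_alleles_for_class <- function(class) {
  pairs <- split(names(.sub_class_map), unname(.sub_class_map))
  raw <- vapply(class, function(cl) {
    opts <- pairs[[cl]]
    opts[sample.int(2L, 1L)]
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    ref = substr(raw, 1, 1),
    alt = substr(raw, 3, 3)
  )
}

check_spectrum <- function(spectrum) {
  if (is.null(names(spectrum)) || !setequal(names(spectrum), substitution_classes())) {
    stop("spectrum must be a named vector over the six substitution classes")
  }
  if (any(spectrum < 0) || abs(sum(spectrum) - 1) > 1e-8) {
    stop("spectrum probabilities must be non-negative and sum to 1")
  }
  spectrum[substitution_classes()]
}
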