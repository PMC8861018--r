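# Small deterministic fixtures shared across test files.

tiny_genome <- function(len = 1e6) {
  genome_model(
    tibble::tibble(chrom = c("chr1", "chr2", "chrX", "chrY"),
                   length = c(len, len, len / 2, len / 4)),
    x_name = "chrX", y_name = "chrY"
  )
}

# one variant-call row with passing defaults; override any field
make_call <- function(sample_id, pos, alt_depth, total_depth = 30L,
                      chrom = "chr1", ref = "C", alt = "T", qual = 50,
                      mq_ref = 55, mq_alt = 55) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = qual, total_depth = as.integer(total_depth),
    alt_depth = as.integer(alt_depth), mq_ref = mq_ref, mq_alt = mq_alt
  )
}

# calls for one site across a set of samples; carriers get alt reads
site_calls <- function(pos, samples, carriers = character(), alt_depth = 12L,
                       ...) {
  dplyr::bind_rows(lapply(samples, function(s) {
    make_call(s, pos, alt_depth = if (s %in% carriers) alt_depth else 0L, ...)
  }))
}

# flat coverage table so the depth band never interferes unless a test
# wants it to
flat_coverage <- function(samples, mean_depth = 30, sd_depth = 10) {
  tibble::tibble(sample_id = samples, mean_depth = mean_depth,
                 sd_depth = sd_depth)
}

# brute-force interval membership oracle (0-based half-open), independent
# of the package's own interval code
in_mask <- function(chrom, pos0, intervals) {
  vapply(seq_along(chrom), function(i) {
    any(intervals$chrom == chrom[i] & intervals$start <= pos0[i] &
          pos0[i] < intervals$end)
  }, logical(1))
}

small_config <- function(...) {
  defaults <- list(n_f2_per_sibship = 3, n_founder_snvs = 20,
                   n_shared_ancestral_snvs = 5, n_controls = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
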