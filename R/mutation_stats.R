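#' Expected de novo mutation count per generation
#'
#' The spontaneous expectation is the per-nucleotide per-generation rate
#' times the haploid genome size times the ploidy.  For the mouse
#' (rate 5.4e-9, genome ~2.7e9 bp, diploid) this gives 29.16, usually
#' quoted as "approximately 29".
#'
#' @param rate_per_nt_per_gen Mutation rate per nucleotide per generation.
#' @param haploid_genome_size Genome size in bp.
#' @param ploidy Number of genome copies (default 2).
#' @return Expected DNM count (numeric, unrounded).
#' @examples
#' expected_dnm_count(5.4e-9, 2.7e9)          # 29.16
#' expected_dnm_count(1.2e-8, 3.2e9)          # 76.8 (human)
#' @export
expected_dnm_count <- function(rate_per_nt_per_gen, haploid_genome_size,
                               ploidy = 2) {
  stopifnot(rate_per_nt_per_gen >= 0, haploid_genome_size > 0, ploidy > 0)
  rate_per_nt_per_gen * haploid_genome_size * ploidy
}

#' Fold increase of an observed mean over the spontaneous expectation
#'
#' @param observed_mean Observed mean DNM count.
#' @param expected_count Expected spontaneous count (> 0).
#' @return `observed_mean / expected_count`.
#' @examples
#' fold_increase(87.6, expected_dnm_count(5.4e-9, 2.7e9))  # ~3.0
#' @export
fold_increase <- function(observed_mean, expected_count) {
  if (any(expected_count <= 0)) stop("expected_count must be positive")
  observed_mean / expected_count
}

#' Build a strand-collapsed substitution spectrum
#'
#' Counts and proportions over the six classes of [substitution_classes()].
#'
#' @param dnms Tibble with `ref` and `alt` columns (or a precomputed
#'   `substitution_class` column); an optional `sample_id` column yields a
#'   per-sample breakdown in attribute `"per_sample"`.
#' @return A tibble of class `spectrum_table` (`class`, `count`,
#'   `proportion`), all six classes always present in canonical order.
#' @export
build_spectrum <- function(dnms) {
  if (!"substitution_class" %in% names(dnms)) {
    dnms <- dplyr::mutate(dnms,
                          substitution_class = substitution_class(.data$ref, .data$alt))
  }
  lv <- substitution_classes()
  total <- nrow(dnms)
  out <- dnms |>
    dplyr::count(class = factor(.data$substitution_class, levels = lv),
                 .drop = FALSE, name = "count") |>
    dplyr::mutate(class = as.character(.data$class),
                  proportion = if (total > 0) .data$count / total else 0)
  if ("sample_id" %in% names(dnms)) {
    attr(out, "per_sample") <- dnms |>
      dplyr::count(.data$sample_id,
                   class = factor(.data$substitution_class, levels = lv),
                   .drop = FALSE, name = "count") |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(class = as.character(.data$class),
                    n_total = sum(.data$count),
                    fraction = ifelse(.data$n_total > 0,
                                      .data$count / .data$n_total, 0)) |>
      dplyr::ungroup()
  }
  class(out) <- c("spectrum_table", class(out))
  out
}

#' Per-sample fractions of one spectrum class
#'
#' @param dnms DNM tibble with `sample_id` and `ref`/`alt` (or
#'   `substitution_class`).
#' @param focal_class Class of interest (default `"G:C>A:T"`).
#' @return Tibble `sample_id`, `n` (sample's DNM count), `fraction`.
#' @export
spectrum_fractions <- function(dnms, focal_class = "G:C>A:T") {
  per_sample <- attr(build_spectrum(dnms), "per_sample")
  if (is.null(per_sample)) stop("dnms must carry a sample_id column")
  per_sample |>
    dplyr::filter(.data$class == focal_class) |>
    dplyr::transmute(sample_id = .data$sample_id, n = .data$n_total,
                     fraction = .data$fraction)
}

#' Compare per-sample spectrum fractions against a reference proportion
#'
#' Two-sample Kolmogorov–Smirnov test of the per-sample focal-class
#' fractions against bootstrap reference fractions drawn
#' Binomial(n_i, `reference_p`) / n_i at the observed per-sample DNM counts
#' (recycled over `n_boot` draws).  The KS construction for categorical
#' spectrum data is a modelling choice of this package: it is the natural
#' way to put a KS test on a per-sample fraction against a reference
#' proportion, and the reference side inherits the samples' count-dependent
#' sampling noise.
#'
#' @param fractions Tibble from [spectrum_fractions()] (`n`, `fraction`),
#'   at least two samples.
#' @param reference_p Reference class proportion (e.g. 0.53 for G:C>A:T in
#'   normal-diet mice).
#' @param n_boot Number of bootstrap reference draws.
#' @return Object of class `ks_comparison` with the KS statistic `D` and
#'   `p_value`; see [tidy.ks_comparison()].
#' @export
compare_spectrum <- function(fractions, reference_p = 0.53, n_boot = 2000) {
  if (nrow(fractions) < 2) stop("need fractions from >= 2 samples")
  stopifnot(reference_p >= 0, reference_p <= 1)
  n_i <- rep_len(fractions$n, n_boot)
  ref <- stats::rbinom(n_boot, n_i, reference_p) / n_i
  kt <- suppressWarnings(stats::ks.test(fractions$fraction, ref))
  structure(
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         n1 = nrow(fractions), n2 = n_boot, reference_p = reference_p,
         method = "Two-sample KS: per-sample class fractions vs bootstrap reference"),
    class = "ks_comparison"
  )
}

#' Test for sex bias in per-sample DNM counts
#'
#' Two-sample Kolmogorov–Smirnov test on male versus female per-sample DNM
#' counts, with group medians reported.
#'
#' @param male_counts,female_counts Non-empty numeric vectors of per-sample
#'   DNM counts.
#' @return Object of class `ks_comparison` carrying `D`, `p_value` and the
#'   two medians.
#' @export
sex_bias_test <- function(male_counts, female_counts) {
  if (length(male_counts) == 0 || length(female_counts) == 0) {
    stop("both groups must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(male_counts, female_counts))
  structure(
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         n1 = length(male_counts), n2 = length(female_counts),
         median_male = stats::median(male_counts),
         median_female = stats::median(female_counts),
         method = "Two-sample KS: male vs female DNM counts"),
    class = "ks_comparison"
  )
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("<%s>\n  D = %.4f, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  if (!is.null(x$median_male)) {
    cat(sprintf("  medians: male %.1f, female %.1f\n",
                x$median_male, x$median_female))
  }
  invisible(x)
}

#' Count DNMs in fixed-size genomic windows
#'
#' Tiles each chromosome with non-overlapping windows of `window_size` bp
#' (0-based half-open); the terminal window of each chromosome may be
#' shorter and keeps its true width for exposure adjustment.  A 1-based
#' variant position `pos` falls in the window containing `pos - 1`.
#'
#' @param dnms DNM tibble with `chrom` and `pos`.
#' @param genome A [genome_model()].
#' @param window_size Window width in bp (default 1e7, the conventional
#'   10-Mb reporting scale; scale it with the genome model).
#' @param chroms Chromosomes to tile (default: the autosomes).
#' @return Tibble `chrom`, `start`, `end`, `width`, `count`.  Positions on
#'   untiled chromosomes raise an error; every in-range DNM is counted
#'   exactly once.
#' @export
window_counts <- function(dnms, genome, window_size = 1e7,
                          chroms = genome$autosomes) {
  stopifnot(window_size >= 1)
  chrom_tbl <- dplyr::filter(genome$chromosomes, .data$chrom %in% chroms)
  windows <- chrom_tbl |>
    dplyr::reframe(start = seq(0, .data$length - 1, by = window_size),
                   length = .data$length, .by = "chrom") |>
    dplyr::mutate(end = pmin(.data$start + window_size, .data$length),
                  width = .data$end - .data$start) |>
    dplyr::select("chrom", "start", "end", "width")
  if (nrow(dnms)) {
    bad <- !dnms$chrom %in% chrom_tbl$chrom |
      dnms$pos < 1 |
      dnms$pos > chrom_tbl$length[match(dnms$chrom, chrom_tbl$chrom)]
    if (any(bad)) {
      stop(sum(bad), " DNM position(s) outside the tiled chromosomes")
    }
    hits <- dplyr::count(
      tibble::tibble(chrom = dnms$chrom,
                     start = floor((dnms$pos - 1) / window_size) * window_size),
      .data$chrom, .data$start, name = "count"
    )
    windows <- dplyr::left_join(windows, hits, by = c("chrom", "start")) |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  } else {
    windows$count <- 0L
  }
  windows
}

#' Poisson goodness-of-fit and hotspot flagging for window counts
#'
#' Under uniform mutation the window counts are Poisson with mean
#' proportional to window width.  The fit is assessed two ways: a Pearson
#' dispersion chi-square (`sum((O - E)^2 / E)` on `n - 1` df, two-sided;
#' for equal-width windows this is the classical `(n-1) s^2 / lambda_hat`
#' variance test) which drives the `reject` decision, and — for equal-width
#' tilings — a binned goodness-of-fit chi-square on the count distribution
#' (bins with expectation < 5 pooled).  Windows with `count >=
#' hotspot_threshold` are flagged; the conventional threshold of 14
#' mutations refers to 10-Mb windows on the full mouse genome.
#'
#' @param windows Output of [window_counts()], or a bare numeric vector of
#'   counts (treated as equal-width windows).  At least 10 windows.
#' @param hotspot_threshold Count at or above which a window is flagged.
#' @param alpha Significance level for `reject`.
#' @return Object of class `hotspot_fit`; see [tidy.hotspot_fit()] and
#'   [glance.hotspot_fit()].
#' @export
poisson_hotspot_test <- function(windows, hotspot_threshold = 14,
                                 alpha = 0.05) {
  if (is.numeric(windows)) {
    windows <- tibble::tibble(chrom = "w", start = (seq_along(windows) - 1),
                              end = seq_along(windows), width = 1,
                              count = windows)
  }
  n <- nrow(windows)
  if (n < 10) stop("need at least 10 windows")
  rate <- sum(windows$count) / sum(windows$width)
  windows$expected <- rate * windows$width
  if (all(windows$expected == 0)) stop("no mutations in any window")
  disp_stat <- sum((windows$count - windows$expected)^2 / windows$expected)
  df <- n - 1
  p_upper <- stats::pchisq(disp_stat, df, lower.tail = FALSE)
  p_lower <- stats::pchisq(disp_stat, df)
  dispersion <- list(
    statistic = disp_stat, df = df,
    p_value = min(1, 2 * min(p_upper, p_lower)),
    direction = if (disp_stat >= df) "overdispersed" else "underdispersed",
    ratio = disp_stat / df
  )
  gof <- NULL
  if (length(unique(windows$width)) == 1) {
    lambda <- mean(windows$count)
    kmax <- max(windows$count, stats::qpois(0.9999, lambda))
    probs <- c(stats::dpois(0:(kmax - 1), lambda),
               stats::ppois(kmax - 1, lambda, lower.tail = FALSE))
    exp_n <- n * probs
    obs <- tabulate(pmin(windows$count, kmax) + 1L, nbins = kmax + 1L)
    # pool adjacent bins until every expected count is >= 5
    grp <- integer(length(exp_n))
    g <- 1L
    acc <- 0
    for (i in seq_along(exp_n)) {
      grp[i] <- g
      acc <- acc + exp_n[i]
      if (acc >= 5 && i < length(exp_n)) {
        g <- g + 1L
        acc <- 0
      }
    }
    if (g > 1L && sum(exp_n[grp == g]) < 5) grp[grp == g] <- g - 1L
    pooled_obs <- tapply(obs, grp, sum)
    pooled_exp <- tapply(exp_n, grp, sum)
    if (length(pooled_obs) >= 3) {
      stat <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
      gdf <- length(pooled_obs) - 2  # one estimated parameter
      gof <- list(statistic = unname(stat), df = gdf,
                  p_value = stats::pchisq(stat, max(gdf, 1), lower.tail = FALSE),
                  n_bins = length(pooled_obs))
    }
  }
  windows$hotspot <- windows$count >= hotspot_threshold
  structure(
    list(windows = windows, lambda_per_bp = rate,
         mean_count = mean(windows$count), n_windows = n,
         dispersion = dispersion, gof = gof,
         hotspots = windows[windows$hotspot, ],
         hotspot_threshold = hotspot_threshold, alpha = alpha,
         reject = dispersion$p_value < alpha),
    class = "hotspot_fit"
  )
}

#' @export
print.hotspot_fit <- function(x, ...) {
  cat(sprintf(
    "<hotspot_fit: %d windows, mean count %.2f>\n  dispersion X2 = %.1f on %d df (%s), p = %.3g -> %s Poisson at alpha = %g\n  %d hotspot window(s) with count >= %d\n",
    x$n_windows, x$mean_count, x$dispersion$statistic, x$dispersion$df,
    x$dispersion$direction, x$dispersion$p_value,
    if (x$reject) "reject" else "do not reject", x$alpha,
    nrow(x$hotspots), x$hotspot_threshold
  ))
  invisible(x)
}

#' Red-blood-cell folate from whole-blood and plasma folate
#'
#' Whole-blood folate is a cell-fraction-weighted mixture of red-cell and
#' plasma folate, so the red-cell concentration is recovered as
#' `fa_whole / hct * 100 - fa_plasma * (100 - hct) / hct`, with `hct` the
#' cell-fraction percentage.  A negative result is physically impossible
#' and triggers a warning (it indicates inconsistent inputs).
#'
#' @param fa_whole_blood,fa_plasma Folate concentrations (same units).
#' @param hct_pct Cell-fraction percentage in (0, 100].
#' @return Red-cell folate concentration.
#' @examples
#' rbc_folate(10, 10, 50)  # 10
#' @export
rbc_folate <- function(fa_whole_blood, fa_plasma, hct_pct) {
  if (any(hct_pct <= 0) || any(hct_pct > 100)) {
    stop("hct_pct must lie in (0, 100]")
  }
  stopifnot(all(fa_whole_blood >= 0), all(fa_plasma >= 0))
  out <- fa_whole_blood / hct_pct * 100 - fa_plasma * (100 - hct_pct) / hct_pct
  if (any(out < 0)) {
    warning("negative red-cell folate: whole-blood and plasma inputs are inconsistent")
  }
  out
}
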