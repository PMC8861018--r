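#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for hotspot fits
#'
#' `tidy()` returns the per-window table (with expected counts and hotspot
#' flags); `glance()` returns a one-row model summary.
#'
#' @param x A `hotspot_fit` from [poisson_hotspot_test()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hotspot_fit
#' @export
tidy.hotspot_fit <- function(x, ...) {
  tibble::as_tibble(x$windows)
}

#' @rdname tidy.hotspot_fit
#' @method glance hotspot_fit
#' @export
glance.hotspot_fit <- function(x, ...) {
  tibble::tibble(
    n_windows = x$n_windows,
    mean_count = x$mean_count,
    dispersion_statistic = x$dispersion$statistic,
    dispersion_df = x$dispersion$df,
    dispersion_ratio = x$dispersion$ratio,
    p_value = x$dispersion$p_value,
    direction = x$dispersion$direction,
    gof_statistic = if (is.null(x$gof)) NA_real_ else x$gof$statistic,
    gof_p_value = if (is.null(x$gof)) NA_real_ else x$gof$p_value,
    n_hotspots = nrow(x$hotspots),
    hotspot_threshold = x$hotspot_threshold,
    reject_poisson = x$reject
  )
}

#' Tidy and glance methods for KS comparisons
#'
#' @param x A `ks_comparison` from [compare_spectrum()] or
#'   [sex_bias_test()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy ks_comparison
#' @export
tidy.ks_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    n1 = x$n1, n2 = x$n2,
    median_male = x$median_male %||% NA_real_,
    median_female = x$median_female %||% NA_real_,
    method = x$method
  )
}

#' @rdname tidy.ks_comparison
#' @method glance ks_comparison
#' @export
glance.ks_comparison <- function(x, ...) tidy(x)
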