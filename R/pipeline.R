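#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate → filter → call → classify → stats as one reproducible
#' run: generates the study from `config`, applies the SNV qualification
#' rules, calls DNMs against the three-generation pedigree, removes
#' ancestrally shared variants, classifies mutation timing, and computes
#' the summary statistics (per-sample/group counts, fold increase over the
#' spontaneous expectation, substitution spectrum and its comparison to the
#' normal-diet reference, window hotspot test, coverage-based sex inference
#' and sex-bias test).
#'
#' @param config A [sim_config()]; set `config$seed` for a fully
#'   reproducible run.
#' @param out_dir Optional directory; when given, all stage artifacts
#'   (fixtures, DNM TSV, spectrum TSV, window TSV, `report.json`,
#'   `report.md`, `manifest.json`) are written there.
#' @param window_size Hotspot window width in bp.  The default 1e5 matches
#'   the 1/100-scale default genome (the conventional full-genome width is
#'   10 Mb).
#' @param hotspot_threshold Count at or above which a window is flagged.
#' @param rule A [genotype_rule()].
#' @param spontaneous_rate,reference_genome_size,ploidy Parameters of the
#'   spontaneous expectation (defaults: 5.4e-9 per nt per generation, the
#'   ~2.7e9-bp mouse genome, diploid), giving the 29.16 baseline the fold
#'   increases are measured against.
#' @param reference_gc_at Normal-diet reference G:C>A:T proportion for the
#'   spectrum comparison (default 0.53).
#' @param n_boot Bootstrap draws for [compare_spectrum()].
#' @return A list of class `dnm_run`: `report` (plain summary list),
#'   `dnms`, `timing`, `spectrum`, `windows`, `hotspot_fit`, `sexes`,
#'   `counts`, `sim`, `kept_variants`.
#' @export
run_dnm_pipeline <- function(config = sim_config(), out_dir = NULL,
                             window_size = 1e5, hotspot_threshold = 14,
                             rule = genotype_rule(),
                             spontaneous_rate = 5.4e-9,
                             reference_genome_size = 2.7e9, ploidy = 2,
                             reference_gc_at = 0.53, n_boot = 2000) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  genome <- config$genome

  message("stage simulate: generating synthetic study")
  sim <- stage("simulate", simulate_study(config))

  message("stage filter: applying SNV qualification rules")
  filtered <- stage("filter", filter_variants(
    sim$variants, mask = genome$repeat_mask, genome = genome
  ))
  kept <- dplyr::filter(filtered, .data$pass)

  message("stage call: calling DNMs against the pedigree")
  dnms <- stage("call", {
    d <- call_dnms(kept, sim$pedigree, rule = rule,
                   presence_variants = sim$variants)
    # presence for shared-variant removal is judged on the unfiltered
    # table so QC dropouts cannot hide an ancestral variant
    remove_shared_snvs(d, sim$variants, sim$pedigree)
  })

  message("stage classify/stats: timing, spectrum, hotspots, sex")
  timing <- stage("classify", timing_summary(dnms, rule))
  spectrum <- stage("stats", build_spectrum(dnms))
  spectrum_ks <- if (nrow(dnms) > 0 &&
                       dplyr::n_distinct(dnms$sample_id) >= 2) {
    compare_spectrum(spectrum_fractions(dnms), reference_p = reference_gc_at,
                     n_boot = n_boot)
  }
  windows <- stage("stats", window_counts(dnms, genome, window_size))
  hotspot_fit <- if (sum(windows$count) > 0 && nrow(windows) >= 10) {
    poisson_hotspot_test(windows, hotspot_threshold = hotspot_threshold)
  }
  sexes <- stage("stats", infer_sex(sim$coverage, genome))
  counts <- stage("stats", count_dnms_by_sample(dnms, sim$pedigree))
  by_sex <- counts$per_sample |>
    dplyr::left_join(sexes[, c("sample_id", "inferred_sex")], by = "sample_id")
  sex_ks <- {
    m <- by_sex$n_dnms[by_sex$inferred_sex == "male"]
    f <- by_sex$n_dnms[by_sex$inferred_sex == "female"]
    if (length(m) > 0 && length(f) > 0) sex_bias_test(m, f)
  }

  expected <- expected_dnm_count(spontaneous_rate, reference_genome_size,
                                 ploidy)
  group_means <- counts$per_group |>
    dplyr::filter(.data$group != "control" | .data$total > 0)
  report <- list(
    seed = config$seed,
    n_samples = nrow(sim$pedigree),
    n_dnms = nrow(dnms),
    per_sample_counts = counts$per_sample,
    group_means = group_means[, c("group", "n_samples", "mean", "median")],
    expected_spontaneous = expected,
    fold_increase = dplyr::transmute(
      group_means, group = .data$group, observed_mean = .data$mean,
      fold = fold_increase(.data$mean, expected)
    ),
    timing = timing,
    spectrum = spectrum,
    spectrum_ks = if (!is.null(spectrum_ks)) {
      list(D = spectrum_ks$statistic, p_value = spectrum_ks$p_value,
           reference_p = reference_gc_at)
    },
    hotspot = if (!is.null(hotspot_fit)) {
      list(n_windows = hotspot_fit$n_windows,
           mean_count = hotspot_fit$mean_count,
           dispersion_p = hotspot_fit$dispersion$p_value,
           direction = hotspot_fit$dispersion$direction,
           reject_poisson = hotspot_fit$reject,
           n_hotspots = nrow(hotspot_fit$hotspots),
           threshold = hotspot_fit$hotspot_threshold)
    },
    sex_bias = if (!is.null(sex_ks)) {
      list(D = sex_ks$statistic, p_value = sex_ks$p_value,
           median_male = sex_ks$median_male,
           median_female = sex_ks$median_female)
    }
  )
  run <- structure(
    list(report = report, dnms = dnms, timing = timing, spectrum = spectrum,
         spectrum_ks = spectrum_ks, windows = windows,
         hotspot_fit = hotspot_fit, sexes = sexes, counts = counts,
         sim = sim, kept_variants = kept),
    class = "dnm_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fixtures(run$sim, file.path(out_dir, "fixtures"))
  readr::write_tsv(run$dnms, file.path(out_dir, "dnms.tsv"))
  readr::write_tsv(run$spectrum, file.path(out_dir, "spectrum.tsv"))
  readr::write_tsv(run$windows, file.path(out_dir, "windows.tsv"))
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  writeLines(render_report(run$report), file.path(out_dir, "report.md"))
  jsonlite::write_json(
    list(package = "dnmlineage",
         version = as.character(utils::packageVersion("dnmlineage")),
         seed = run$report$seed),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, null = "null",
    pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.dnm_run <- function(x, ...) {
  cat(sprintf("<dnm_run: %d DNMs across %d samples, seed %s>\n",
              x$report$n_dnms, x$report$n_samples,
              if (is.null(x$report$seed)) "unset" else x$report$seed))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Render a pipeline report as markdown text
#'
#' Every "approximately" quantity is shown in both raw and rounded
#' (half-up) form; rounding is applied only here, never to stored values.
#'
#' @param report The `report` element of a [run_dnm_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  lines <- c(
    "# De novo mutation pipeline report", "",
    sprintf("Seed: %s; samples: %d; DNMs called: %d",
            if (is.null(report$seed)) "unset" else report$seed,
            report$n_samples, report$n_dnms), ""
  )
  if (report$n_dnms == 0) {
    return(c(lines, "No DNMs were called; all downstream tests skipped."))
  }
  lines <- c(lines, "## Mutation burden", "",
    sprintf("Expected spontaneous DNMs per diploid generation: %.2f (~%d)",
            report$expected_spontaneous,
            round_half_up(report$expected_spontaneous)))
  for (i in seq_len(nrow(report$fold_increase))) {
    r <- report$fold_increase[i, ]
    lines <- c(lines, sprintf(
      "- group %s: observed mean %.1f DNMs -> fold increase %.2f (~%d-fold)",
      r$group, r$observed_mean, r$fold, round_half_up(r$fold)))
  }
  lines <- c(lines, "", "## Mutation timing", "")
  for (i in seq_len(nrow(report$timing))) {
    r <- report$timing[i, ]
    lines <- c(lines, sprintf("- class %s: %d (%.1f%%)",
                              r$genotype_class, r$n, 100 * r$fraction))
  }
  lines <- c(lines, "", "## Substitution spectrum", "")
  for (i in seq_len(nrow(report$spectrum))) {
    r <- report$spectrum[i, ]
    lines <- c(lines, sprintf("- %s: %d (%.1f%%)",
                              r$class, r$count, 100 * r$proportion))
  }
  if (!is.null(report$spectrum_ks)) {
    lines <- c(lines, "", sprintf(
      "KS vs reference G:C>A:T proportion %.1f%%: D = %.3f, p = %.3g",
      100 * report$spectrum_ks$reference_p, report$spectrum_ks$D,
      report$spectrum_ks$p_value))
  }
  if (!is.null(report$hotspot)) {
    h <- report$hotspot
    lines <- c(lines, "", "## Hotspots", "", sprintf(
      "%d windows, mean count %.2f; dispersion p = %.3g (%s); %d window(s) at count >= %d; Poisson %s",
      h$n_windows, h$mean_count, h$dispersion_p, h$direction, h$n_hotspots,
      h$threshold, if (h$reject_poisson) "rejected" else "not rejected"))
  } else {
    lines <- c(lines, "", "## Hotspots", "", "Hotspot test skipped (too few windows or mutations).")
  }
  if (!is.null(report$sex_bias)) {
    s <- report$sex_bias
    lines <- c(lines, "", "## Sex bias", "", sprintf(
      "KS D = %.3f, p = %.3g; medians: male %.1f, female %.1f",
      s$D, s$p_value, s$median_male, s$median_female))
  } else {
    lines <- c(lines, "", "## Sex bias", "", "Sex-bias test skipped (one sex absent).")
  }
  lines
}
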