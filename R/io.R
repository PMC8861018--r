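#' Read and write multi-sample variant tables as VCF 4.2
#'
#' The package's long variant-call tibble (one row per sample x site) maps
#' onto a multi-sample VCF with `FORMAT GT:DP:AD` and site-level
#' `QUAL`/`INFO MQREF`/`INFO MQALT`.  `write_variant_vcf()` emits plain-text
#' VCF; `read_variant_vcf()` parses through \pkg{vcfR} and returns the long
#' tibble (rows where a sample has no observation, `GT = ./.`, are dropped).
#' VCF positions are 1-based.
#'
#' @param variants Variant-call tibble (`sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `total_depth`, `alt_depth`, `mq_ref`, `mq_alt`).
#' @param path File path.
#' @param genome Optional [genome_model()]; adds `##contig` header lines.
#' @param samples Sample column order; defaults to order of appearance.
#' @return `write_variant_vcf()` returns `path` invisibly;
#'   `read_variant_vcf()` returns the variant-call tibble.
#' @export
write_variant_vcf <- function(variants, path, genome = NULL, samples = NULL) {
  if (is.null(samples)) samples <- unique(variants$sample_id)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dnmlineage",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", genome$chromosomes$chrom,
              genome$chromosomes$length)
    },
    '##INFO=<ID=MQREF,Number=1,Type=Float,Description="Mean mapping quality of reference-supporting reads">',
    '##INFO=<ID=MQALT,Number=1,Type=Float,Description="Mean mapping quality of alternate-supporting reads">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(variants) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  site <- variants |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$qual, .data$mq_ref, .data$mq_alt) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  if (anyDuplicated(site[, c("chrom", "pos", "alt")])) {
    stop("conflicting site-level fields for the same chrom/pos/alt")
  }
  cell <- variants |>
    dplyr::mutate(
      gt = sprintf("%s:%d:%d,%d",
                   ifelse(.data$alt_depth > 0, "0/1", "0/0"),
                   .data$total_depth,
                   .data$total_depth - .data$alt_depth, .data$alt_depth)
    ) |>
    dplyr::select("sample_id", "chrom", "pos", "alt", "gt") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "gt")
  for (s in setdiff(samples, names(cell))) cell[[s]] <- NA_character_
  body <- site |>
    dplyr::left_join(cell, by = c("chrom", "pos", "alt")) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(samples),
                                ~ dplyr::coalesce(.x, "./.:.:.")))
  lines <- paste(
    body$chrom, body$pos, ".", body$ref, body$alt,
    format(body$qual, trim = TRUE), "PASS",
    sprintf("MQREF=%s;MQALT=%s", format(body$mq_ref, trim = TRUE),
            format(body$mq_alt, trim = TRUE)),
    "GT:DP:AD",
    do.call(paste, c(unname(as.list(body[samples])), list(sep = "\t"))),
    sep = "\t"
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  empty <- tibble::tibble(
    sample_id = character(), chrom = character(), pos = numeric(),
    ref = character(), alt = character(), qual = numeric(),
    total_depth = integer(), alt_depth = integer(),
    mq_ref = numeric(), mq_alt = numeric()
  )
  if (nrow(fix) == 0) return(empty)
  mqref <- as.numeric(vcfR::extract.info(v, "MQREF"))
  mqalt <- as.numeric(vcfR::extract.info(v, "MQALT"))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  site <- tibble::tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, qual = as.numeric(fix$QUAL),
    mq_ref = mqref, mq_alt = mqalt
  )
  out <- lapply(colnames(gt), function(s) {
    keep <- !is.na(gt[, s]) & gt[, s] != "./."
    if (!any(keep)) return(NULL)
    alt_d <- as.integer(vapply(strsplit(ad[keep, s], ",", fixed = TRUE),
                               function(x) x[2], character(1)))
    dplyr::mutate(site[keep, ], sample_id = s,
                  total_depth = as.integer(dp[keep, s]), alt_depth = alt_d)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty)
  dplyr::select(out, "sample_id", "chrom", "pos", "ref", "alt", "qual",
                "total_depth", "alt_depth", "mq_ref", "mq_alt")
}

#' Read and write the pedigree as a PED-like table
#'
#' Whitespace-separated, eight columns: family (sibship), sample id, father,
#' mother, sex (1 = male, 2 = female, 0 = unknown), phenotype (1 = normal,
#' 2 = abnormal, 0 = missing), generation, diet.  Missing parents are `0`.
#' The diet-arm `group` column is reconstructed on read from the F0 diets of
#' each sibship (`CTRL` family or all-FS founders with no offspring map to
#' `"control"`).
#'
#' @param pedigree Pedigree tibble (see [build_pedigree()]).
#' @param path File path.
#' @return `write_ped()` returns `path` invisibly; `read_ped()` returns the
#'   pedigree tibble.
#' @export
write_ped <- function(pedigree, path) {
  out <- tibble::tibble(
    family = pedigree$sibship_id,
    id = pedigree$sample_id,
    father = dplyr::coalesce(pedigree$father_id, "0"),
    mother = dplyr::coalesce(pedigree$mother_id, "0"),
    sex = dplyr::case_match(pedigree$sex, "male" ~ 1L, "female" ~ 2L,
                            .default = 0L),
    phenotype = dplyr::case_match(pedigree$phenotype, "normal" ~ 1L,
                                  "abnormal" ~ 2L, .default = 0L),
    generation = pedigree$generation,
    diet = pedigree$diet
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("family", "id", "father", "mother", "sex", "phenotype",
                  "generation", "diet"),
    col_types = "cccciicc", progress = FALSE
  )
  ped <- tibble::tibble(
    sample_id = raw$id,
    generation = raw$generation,
    sex = dplyr::case_match(raw$sex, 1L ~ "male", 2L ~ "female",
                            .default = "unknown"),
    father_id = dplyr::na_if(raw$father, "0"),
    mother_id = dplyr::na_if(raw$mother, "0"),
    sibship_id = raw$family,
    diet = raw$diet,
    phenotype = dplyr::case_match(raw$phenotype, 1L ~ "normal",
                                  2L ~ "abnormal", .default = NA_character_)
  )
  grp <- ped |>
    dplyr::group_by(.data$sibship_id) |>
    dplyr::summarise(
      dam_fd = any(.data$generation == "F0" & .data$sex == "female" &
                     .data$diet == "FD"),
      sire_fd = any(.data$generation == "F0" & .data$sex == "male" &
                      .data$diet == "FD"),
      has_offspring = any(.data$generation != "F0")
    ) |>
    dplyr::mutate(group = dplyr::case_when(
      !.data$has_offspring & !.data$dam_fd & !.data$sire_fd ~ "control",
      .data$dam_fd & .data$sire_fd ~ "C",
      .data$dam_fd ~ "A",
      .data$sire_fd ~ "B",
      TRUE ~ "control"
    ))
  ped |>
    dplyr::left_join(grp[, c("sibship_id", "group")], by = "sibship_id") |>
    dplyr::select("sample_id", "generation", "sex", "father_id", "mother_id",
                  "sibship_id", "diet", "group", "phenotype")
}

#' Read and write interval tables as BED
#'
#' Three columns (`chrom`, `start`, `end`), 0-based half-open, no header —
#' the standard BED convention.
#'
#' @param intervals Interval tibble.
#' @param path File path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` the tibble.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cdd", progress = FALSE)
}

#' Write all fixtures for a simulated study
#'
#' Emits the artifacts a real study would start from: a multi-sample VCF,
#' a PED-like pedigree file, BED masks (tandem repeats and excluded
#' chromosome ends), a genome table, the DNM truth table (TSV), and a
#' `manifest.json` recording the seed.  With a fixed seed in the
#' [sim_config()], re-running produces byte-identical files.
#'
#' @param sim A `dnm_simulation` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "dnm_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    ped = file.path(dir, "pedigree.ped"),
    repeat_mask = file.path(dir, "repeat_mask.bed"),
    excluded_ends = file.path(dir, "excluded_ends.bed"),
    truth = file.path(dir, "truth.tsv"),
    genome = file.path(dir, "genome.tsv"),
    coverage = file.path(dir, "coverage.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_variant_vcf(sim$variants, paths["vcf"], genome = sim$genome,
                    samples = sim$pedigree$sample_id)
  write_ped(sim$pedigree, paths["ped"])
  write_bed(sim$genome$repeat_mask, paths["repeat_mask"])
  write_bed(sim$genome$excluded_ends, paths["excluded_ends"])
  readr::write_tsv(sim$truth, paths["truth"])
  readr::write_tsv(sim$genome$chromosomes, paths["genome"])
  readr::write_tsv(sim$coverage, paths["coverage"])
  jsonlite::write_json(
    list(seed = sim$seed, n_samples = nrow(sim$pedigree),
         n_sites = nrow(sim$sites), x_name = sim$genome$x_name,
         y_name = sim$genome$y_name),
    paths["manifest"], auto_unbox = TRUE, null = "null", pretty = TRUE
  )
  invisible(paths)
}
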