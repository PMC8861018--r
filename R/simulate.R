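#' Configuration for the synthetic three-generation study
#'
#' Bundles everything the generator needs to emulate the study design: a
#' genome model, the pedigree layout (sibships of F0 pairs, folate-deficient
#' F1 mice crossed to folate-sufficient mates, F2 embryos), the expected DNM
#' count per diet arm, the mutation-timing mixture, per-arm substitution
#' spectra, and the read-sampling model.
#'
#' Defaults encode the study conditions: Poisson DNM means of 29.16
#' (spontaneous expectation for a mouse diploid generation), 87.6 (one
#' grandparent pair folate-deficient) and 211 (both pairs deficient); a
#' 1:3-class (unrepaired mismatch, true VAF 0.25) probability of 0.466; and
#' ~30x sequencing depth with binomial allele sampling.
#'
#' @param genome A [genome_model()]; default [mouse_genome_model()].
#' @param n_sibships Number of three-generation sibships.
#' @param groups Diet-arm label per sibship: `"A"` (F0 dam deficient), `"B"`
#'   (F0 sire deficient), `"C"` (both).  Recycled to `n_sibships`.
#' @param n_f1_per_sibship Folate-deficient F1 mice per sibship; each is
#'   paired with one folate-sufficient mate.
#' @param n_f2_per_sibship F2 embryos per sibship (split round-robin across
#'   the sibship's F1 pairs).
#' @param dnm_mean Named vector `c(control=, one_fd=, both_fd=)` of expected
#'   DNM counts per sample per diet arm.
#' @param p_mismatch Probability that an injected DNM is an unrepaired
#'   mismatch (1:3 class, true VAF 0.25) rather than fixed before gamete
#'   formation (2:2 class, true VAF 0.5).
#' @param spectrum_fd,spectrum_control Six-class substitution-spectrum
#'   probability vectors (see [fd_spectrum()], [control_spectrum()]).
#' @param depth_mean Mean sequencing depth.
#' @param depth_dispersion Extra-Poisson dispersion of depth; 0 keeps the
#'   Poisson model, larger values switch to negative binomial with
#'   `size = 1/depth_dispersion`.
#' @param qual_range,mq_range Uniform ranges for site quality and per-allele
#'   mean mapping quality; defaults comfortably pass the qualification
#'   filters so tests reject only when they intend to.
#' @param n_founder_snvs Heterozygous founder (F0) variants per sibship,
#'   transmitted by fair Mendelian draws.
#' @param n_shared_ancestral_snvs Variants present in every sequenced sample
#'   (including controls), emulating ancestral strain variation; these are
#'   the targets of [remove_shared_snvs()].
#' @param n_controls Unrelated folate-sufficient control samples.
#' @param inject_f1 Also inject DNMs into the focal F1 mice (their DNMs can
#'   then transmit to F2 with probability equal to their true VAF).
#' @param seed Integer seed recorded in the simulation output; `NULL` leaves
#'   the RNG state alone.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome = mouse_genome_model(),
                       n_sibships = 1,
                       groups = "B",
                       n_f1_per_sibship = 1,
                       n_f2_per_sibship = 5,
                       dnm_mean = c(control = 29.16, one_fd = 87.6, both_fd = 211),
                       p_mismatch = 0.466,
                       spectrum_fd = fd_spectrum(),
                       spectrum_control = control_spectrum(),
                       depth_mean = 30,
                       depth_dispersion = 0,
                       qual_range = c(40, 60),
                       mq_range = c(50, 60),
                       n_founder_snvs = 50,
                       n_shared_ancestral_snvs = 10,
                       n_controls = 4,
                       inject_f1 = TRUE,
                       seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_sibships < 1) stop("need at least one sibship")
  if (n_f2_per_sibship < 1) stop("need at least one F2 embryo per sibship")
  if (n_f1_per_sibship < 1) stop("need at least one F1 per sibship")
  groups <- rep_len(as.character(groups), n_sibships)
  if (!all(groups %in% c("A", "B", "C"))) stop("groups must be 'A', 'B' or 'C'")
  if (!all(c("control", "one_fd", "both_fd") %in% names(dnm_mean))) {
    stop("dnm_mean must name control, one_fd and both_fd arms")
  }
  if (any(dnm_mean < 0)) stop("dnm_mean values must be >= 0")
  if (p_mismatch < 0 || p_mismatch > 1) stop("p_mismatch must lie in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  structure(
    list(
      genome = genome, n_sibships = n_sibships, groups = groups,
      n_f1_per_sibship = n_f1_per_sibship, n_f2_per_sibship = n_f2_per_sibship,
      dnm_mean = dnm_mean, p_mismatch = p_mismatch,
      spectrum_fd = check_spectrum(spectrum_fd),
      spectrum_control = check_spectrum(spectrum_control),
      depth_mean = depth_mean, depth_dispersion = depth_dispersion,
      qual_range = qual_range, mq_range = mq_range,
      n_founder_snvs = n_founder_snvs,
      n_shared_ancestral_snvs = n_shared_ancestral_snvs,
      n_controls = n_controls, inject_f1 = inject_f1, seed = seed
    ),
    class = "sim_config"
  )
}

#' Build the three-generation pedigree
#'
#' Deterministic (no RNG): each sibship gets an F0 pair, `n_f1_per_sibship`
#' folate-deficient F1 mice (males, per the cross design in which deficient
#' F1 males are mated to normal-diet females), one folate-sufficient mate per
#' F1, and the sibship's F2 embryos split across the F1 pairs.  Unrelated
#' control samples are appended with `group = "control"`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per sample: `sample_id`, `generation`
#'   (`F0`/`F1`/`F2`), `sex`, `father_id`, `mother_id`, `sibship_id`, `diet`
#'   (`FD`/`FS`), `group` (`A`/`B`/`C`/`control`), `phenotype`.
#' @export
build_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (s in seq_len(config$n_sibships)) {
    sib <- sprintf("S%d", s)
    grp <- config$groups[s]
    dam <- sprintf("%s_F0_dam", sib)
    sire <- sprintf("%s_F0_sire", sib)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = c(dam, sire), generation = "F0",
      sex = c("female", "male"),
      father_id = NA_character_, mother_id = NA_character_,
      sibship_id = sib,
      diet = c(
        if (grp %in% c("A", "C")) "FD" else "FS",
        if (grp %in% c("B", "C")) "FD" else "FS"
      ),
      group = grp, phenotype = NA_character_
    )
    f1_ids <- sprintf("%s_F1_%d", sib, seq_len(config$n_f1_per_sibship))
    mate_ids <- sprintf("%s_mate_%d", sib, seq_len(config$n_f1_per_sibship))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = f1_ids, generation = "F1", sex = "male",
      father_id = sire, mother_id = dam, sibship_id = sib,
      diet = "FD", group = grp, phenotype = NA_character_
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = mate_ids, generation = "F1", sex = "female",
      father_id = NA_character_, mother_id = NA_character_, sibship_id = sib,
      diet = "FS", group = grp, phenotype = NA_character_
    )
    f2_idx <- seq_len(config$n_f2_per_sibship)
    pair <- ((f2_idx - 1L) %% config$n_f1_per_sibship) + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("%s_F2_%d", sib, f2_idx), generation = "F2",
      sex = ifelse(f2_idx %% 2L == 1L, "male", "female"),
      father_id = f1_ids[pair], mother_id = mate_ids[pair],
      sibship_id = sib, diet = "FS", group = grp, phenotype = NA_character_
    )
  }
  if (config$n_controls > 0) {
    idx <- seq_len(config$n_controls)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("CTRL_%d", idx), generation = "F0",
      sex = ifelse(idx %% 2L == 1L, "male", "female"),
      father_id = NA_character_, mother_id = NA_character_,
      sibship_id = "CTRL", diet = "FS", group = "control",
      phenotype = NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

# uniform positions over the unmasked part of the given chromosomes,
# without replacement, avoiding the 1-based keys in `avoid`
draw_positions <- function(genome, n, chroms = genome$autosomes, avoid = NULL) {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric()))
  }
  chrom_tbl <- dplyr::filter(genome$chromosomes, .data$chrom %in% chroms)
  masked_bp <- sum(pmax(genome$repeat_mask$end - genome$repeat_mask$start, 0)[
    genome$repeat_mask$chrom %in% chroms
  ])
  usable <- sum(chrom_tbl$length) - masked_bp
  if (n > usable) {
    stop("genome too small after masking for ", n, " distinct positions")
  }
  out_chrom <- character(0)
  out_pos <- numeric(0)
  seen <- if (is.null(avoid)) character(0) else avoid
  for (iter in seq_len(1000)) {
    need <- n - length(out_pos)
    if (need == 0) break
    ci <- sample.int(nrow(chrom_tbl), need, replace = TRUE,
                     prob = chrom_tbl$length)
    chrom <- chrom_tbl$chrom[ci]
    pos0 <- floor(stats::runif(need) * chrom_tbl$length[ci])
    ok <- !in_intervals(chrom, pos0, genome$repeat_mask)
    key <- paste(chrom, pos0 + 1)
    ok <- ok & !(key %in% seen) & !duplicated(key)
    out_chrom <- c(out_chrom, chrom[ok])
    out_pos <- c(out_pos, pos0[ok] + 1)
    seen <- c(seen, key[ok])
  }
  if (length(out_pos) < n) stop("failed to draw distinct unmasked positions")
  tibble::tibble(chrom = out_chrom, pos = out_pos)
}

#' Simulate inherited background variants
#'
#' Founder (F0) heterozygous variants transmitted down the pedigree by
#' independent fair Mendelian draws, plus a configured number of "ancestral"
#' variants present in every sequenced sample (including unrelated controls)
#' so the shared-variant removal step has true targets.
#'
#' @param pedigree Output of [build_pedigree()].
#' @param config A [sim_config()].
#' @return List with `sites` (tibble `chrom`, `pos`, `ref`, `alt`, `origin`)
#'   and `carriers` (tibble `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `true_vaf`; heterozygous carriers at true VAF 0.5).
#' @export
simulate_inherited_variants <- function(pedigree, config) {
  genome <- config$genome
  n_f <- config$n_founder_snvs * config$n_sibships
  n_a <- config$n_shared_ancestral_snvs
  pos <- draw_positions(genome, n_f + n_a)
  ref <- sample(c("A", "C", "G", "T"), n_f + n_a, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  sites <- tibble::tibble(
    chrom = pos$chrom, pos = pos$pos, ref = ref, alt = unname(alt),
    origin = rep(c("founder", "ancestral"), c(n_f, n_a))
  )

  carriers <- list()
  if (n_f > 0) {
    founder_sites <- sites[sites$origin == "founder", ]
    founder_sites$sibship_id <- rep(sprintf("S%d", seq_len(config$n_sibships)),
                                    each = config$n_founder_snvs)
    for (i in seq_len(nrow(founder_sites))) {
      site <- founder_sites[i, ]
      f0 <- pedigree$sample_id[pedigree$sibship_id == site$sibship_id &
                                 pedigree$generation == "F0"]
      carrier0 <- sample(f0, 1)
      cur <- carrier0
      # transmit down generations: child inherits the het allele w.p. 1/2
      for (gen in c("F1", "F2")) {
        kids <- pedigree$sample_id[pedigree$generation == gen &
                                     (pedigree$father_id %in% cur |
                                        pedigree$mother_id %in% cur)]
        inherited <- kids[stats::runif(length(kids)) < 0.5]
        cur <- c(cur, inherited)
      }
      carriers[[length(carriers) + 1L]] <- tibble::tibble(
        sample_id = cur, chrom = site$chrom, pos = site$pos,
        ref = site$ref, alt = site$alt, true_vaf = 0.5,
        origin = "founder"
      )
    }
  }
  if (n_a > 0) {
    anc <- sites[sites$origin == "ancestral", ]
    carriers[[length(carriers) + 1L]] <- tidyr::crossing(
      tibble::tibble(sample_id = pedigree$sample_id),
      anc[, c("chrom", "pos", "ref", "alt")]
    ) |>
      dplyr::mutate(true_vaf = 0.5, origin = "ancestral")
  }
  carriers <- if (length(carriers)) dplyr::bind_rows(carriers) else
    tibble::tibble(sample_id = character(), chrom = character(),
                   pos = numeric(), ref = character(), alt = character(),
                   true_vaf = numeric(), origin = character())
  list(sites = sites, carriers = carriers)
}

#' Inject de novo mutations of known timing class
#'
#' For each sample the DNM count is drawn Poisson(`lambda`) (or fixed via
#' `n`), positions are uniform over the unmasked autosomes, the timing label
#' is Bernoulli(`p_mismatch`) — unrepaired mismatch with true VAF 0.25,
#' otherwise fixed before gamete formation with true VAF 0.5 — and the
#' substitution class is drawn from `spectrum`.
#'
#' @param sample_ids Character vector of samples to mutate.
#' @param lambda Expected DNM count per sample (recycled).
#' @param p_mismatch Probability of the 1:3 (true VAF 0.25) class.
#' @param spectrum Six-class probability vector, e.g. [fd_spectrum()].
#' @param genome A [genome_model()].
#' @param n Optional exact count per sample (recycled), overriding the
#'   Poisson draw.
#' @param avoid Character vector of `"chrom pos"` keys (1-based) that
#'   injected mutations must not collide with.
#' @return A truth tibble: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `timing` (`pgc_fixed`/`unrepaired_mismatch`), `true_vaf` (0.5/0.25),
#'   `substitution_class`.
#' @export
inject_dnms <- function(sample_ids, lambda, p_mismatch, spectrum, genome,
                        n = NULL, avoid = NULL) {
  stopifnot(all(lambda >= 0))
  spectrum <- check_spectrum(spectrum)
  counts <- if (is.null(n)) stats::rpois(length(sample_ids), rep_len(lambda, length(sample_ids)))
            else rep_len(n, length(sample_ids))
  total <- sum(counts)
  if (total == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = numeric(), ref = character(),
                          alt = character(), timing = character(),
                          true_vaf = numeric(),
                          substitution_class = character()))
  }
  pos <- draw_positions(genome, total, chroms = genome$autosomes, avoid = avoid)
  cls <- sample(names(spectrum), total, replace = TRUE, prob = spectrum)
  alleles <- draw_alleles_for_class(cls)
  mismatch <- stats::runif(total) < p_mismatch
  tibble::tibble(
    sample_id = rep(sample_ids, counts),
    chrom = pos$chrom, pos = pos$pos,
    ref = alleles$ref, alt = alleles$alt,
    timing = ifelse(mismatch, "unrepaired_mismatch", "pgc_fixed"),
    true_vaf = ifelse(mismatch, 0.25, 0.5),
    substitution_class = cls
  )
}

#' Simulate read-level observations at variant sites
#'
#' Depth is Poisson(`depth_mean`) truncated at 1 (negative binomial when
#' `depth_dispersion > 0`, or exactly `depth_mean` under `depth_model =
#' "fixed"`); the alternate-read count is Binomial(depth, `true_vaf`).  Site
#' quality and per-allele mean mapping quality are drawn uniformly per site
#' from ranges whose defaults pass the qualification filters; `noisy = TRUE`
#' draws them across the filter boundaries instead (25–35) for filter tests.
#'
#' @param sites Tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `true_vaf`, and optionally `depth_scale` (per-row depth multiplier).
#' @param depth_mean,depth_dispersion,qual_range,mq_range See [sim_config()].
#' @param depth_model `"poisson"` (default) or `"fixed"`.
#' @param noisy Draw qualities across the filter boundaries.
#' @return A variant-call tibble: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `total_depth`, `alt_depth`, `mq_ref`, `mq_alt`.
#' @export
simulate_reads <- function(sites, depth_mean = 30, depth_dispersion = 0,
                           depth_model = c("poisson", "fixed"),
                           qual_range = c(40, 60), mq_range = c(50, 60),
                           noisy = FALSE) {
  depth_model <- match.arg(depth_model)
  stopifnot(all(sites$true_vaf >= 0), all(sites$true_vaf <= 1))
  n <- nrow(sites)
  scale <- if ("depth_scale" %in% names(sites)) sites$depth_scale else rep(1, n)
  mu <- depth_mean * scale
  depth <- switch(depth_model,
    poisson = if (depth_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / depth_dispersion)
    } else {
      stats::rpois(n, mu)
    },
    fixed = round(mu)
  )
  depth <- pmax(depth, 1L)
  alt_depth <- stats::rbinom(n, depth, sites$true_vaf)
  if (noisy) {
    qual_range <- c(25, 35)
    mq_range <- c(25, 35)
  }
  # site-level attributes shared by all samples observed at a site
  key <- paste(sites$chrom, sites$pos)
  uk <- !duplicated(key)
  site_qual <- stats::runif(sum(uk), qual_range[1], qual_range[2])
  site_mqr <- stats::runif(sum(uk), mq_range[1], mq_range[2])
  site_mqa <- stats::runif(sum(uk), mq_range[1], mq_range[2])
  idx <- match(key, key[uk])
  tibble::tibble(
    sample_id = sites$sample_id, chrom = sites$chrom, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    qual = round(site_qual[idx], 2),
    total_depth = as.integer(depth), alt_depth = as.integer(alt_depth),
    mq_ref = round(site_mqr[idx], 2), mq_alt = round(site_mqa[idx], 2)
  )
}

# per-sample x chromosome mean depth, scaled by sex-chromosome copy number
simulate_coverage <- function(pedigree, genome, depth_mean) {
  tidyr::crossing(
    pedigree[, c("sample_id", "sex")],
    genome$chromosomes["chrom"]
  ) |>
    dplyr::mutate(
      scale = dplyr::case_when(
        .data$chrom == genome$y_name & .data$sex == "female" ~ 0.01,
        .data$chrom %in% c(genome$x_name, genome$y_name) &
          .data$sex == "male" ~ 0.5,
        TRUE ~ 1
      ),
      mean_depth = depth_mean * .data$scale * stats::runif(dplyr::n(), 0.97, 1.03)
    ) |>
    dplyr::select("sample_id", "chrom", "mean_depth")
}

#' Run the full synthetic study
#'
#' Builds the pedigree, simulates inherited background variants, injects
#' DNMs per diet arm (F1 DNMs can transmit to F2 with probability equal to
#' their true VAF), samples reads for every sequenced sample at every
#' variant site (non-carriers are observed at true VAF 0), and emits a
#' per-chromosome coverage profile for sex inference.
#'
#' @param config A [sim_config()].  If `config$seed` is set the RNG is
#'   seeded, making the whole study reproducible.
#' @return An object of class `dnm_simulation`: a list with `pedigree`,
#'   `variants` (long variant-call tibble over all samples and sites),
#'   `truth` (injected DNMs with timing labels), `carriers` (all inherited
#'   and transmitted carrier states), `sites`, `coverage`, `genome`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pedigree <- build_pedigree(config)
  inherited <- simulate_inherited_variants(pedigree, config)
  avoid <- paste(inherited$sites$chrom, inherited$sites$pos)

  arm_of <- c(A = "one_fd", B = "one_fd", C = "both_fd", control = "control")
  focal_f1 <- pedigree$sample_id[pedigree$generation == "F1" &
                                   !is.na(pedigree$father_id)]
  f2 <- pedigree$sample_id[pedigree$generation == "F2"]
  lam <- function(ids) {
    unname(config$dnm_mean[arm_of[pedigree$group[match(ids, pedigree$sample_id)]]])
  }
  truth <- list()
  if (config$inject_f1 && length(focal_f1)) {
    truth$f1 <- inject_dnms(focal_f1, lam(focal_f1), config$p_mismatch,
                            config$spectrum_fd, config$genome, avoid = avoid)
    avoid <- c(avoid, paste(truth$f1$chrom, truth$f1$pos))
  }
  truth$f2 <- inject_dnms(f2, lam(f2), config$p_mismatch,
                          config$spectrum_fd, config$genome, avoid = avoid)
  truth <- dplyr::bind_rows(truth)

  # F1 DNMs transmit to each F2 child with probability = true VAF; in the
  # child the variant is an ordinary heterozygote (true VAF 0.5)
  transmitted <- tibble::tibble()
  f1_truth <- truth[truth$sample_id %in% focal_f1, ]
  if (nrow(f1_truth)) {
    kids <- pedigree[pedigree$generation == "F2", c("sample_id", "father_id")]
    transmitted <- dplyr::inner_join(
      f1_truth, kids, by = c(sample_id = "father_id"),
      suffix = c("", "_kid"), relationship = "many-to-many"
    ) |>
      dplyr::filter(stats::runif(dplyr::n()) < .data$true_vaf) |>
      dplyr::transmute(sample_id = .data$sample_id_kid, chrom = .data$chrom,
                       pos = .data$pos, ref = .data$ref, alt = .data$alt,
                       true_vaf = 0.5, origin = "transmitted_dnm")
  }

  carriers <- dplyr::bind_rows(
    inherited$carriers,
    dplyr::transmute(truth, sample_id = .data$sample_id, chrom = .data$chrom,
                     pos = .data$pos, ref = .data$ref, alt = .data$alt,
                     true_vaf = .data$true_vaf, origin = "dnm"),
    transmitted
  )
  sites <- dplyr::bind_rows(
    inherited$sites,
    dplyr::transmute(truth, chrom = .data$chrom, pos = .data$pos,
                     ref = .data$ref, alt = .data$alt, origin = "dnm")
  )

  grid <- tidyr::crossing(
    tibble::tibble(sample_id = pedigree$sample_id),
    sites[, c("chrom", "pos", "ref", "alt")]
  ) |>
    dplyr::left_join(
      carriers[, c("sample_id", "chrom", "pos", "ref", "alt", "true_vaf")],
      by = c("sample_id", "chrom", "pos", "ref", "alt")
    ) |>
    dplyr::mutate(true_vaf = dplyr::coalesce(.data$true_vaf, 0)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$sample_id)

  variants <- simulate_reads(grid, depth_mean = config$depth_mean,
                             depth_dispersion = config$depth_dispersion,
                             qual_range = config$qual_range,
                             mq_range = config$mq_range)
  coverage <- simulate_coverage(pedigree, config$genome, config$depth_mean)
  structure(
    list(pedigree = pedigree, variants = variants, truth = truth,
         carriers = carriers, sites = sites, coverage = coverage,
         genome = config$genome, config = config, seed = config$seed),
    class = "dnm_simulation"
  )
}

#' @export
print.dnm_simulation <- function(x, ...) {
  cat(sprintf(
    "<dnm_simulation: %d samples, %d variant sites, %d injected DNMs, seed %s>\n",
    nrow(x$pedigree), nrow(x$sites), nrow(x$truth),
    if (is.null(x$seed)) "unset" else x$seed
  ))
  invisible(x)
}
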