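---
title: "Methods: de novo mutation calling and timing classification in three-generation pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo mutation calling and timing classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmlineage)
```

# The question and the design

A germline de novo mutation (DNM) is a variant carried by an offspring but
absent from both parents.  Counting DNMs accurately from ~30× whole-genome
sequencing is hard because a candidate can be de novo, an inherited variant
the parent's sequencing missed, or an artifact.  The design this package
implements attacks that with *three* generations: F0 grandparents, F1
parents (one of them exposed — here to a folate-deficient diet), and F2
embryos.  A candidate DNM in an F2 must be absent not only from its two
parents but from every sequenced F0/F1 member of its sibship, and variants
seen in *all* sibships or in unrelated control animals are discarded as
ancestral strain variation.  The deeper question is not just *how many*
DNMs but *when* they arose, which the variant allele fraction (VAF)
encodes, as described below.

# SNV qualification

`filter_variants()` applies five rules; a record must pass all of them:

| rule | predicate | default |
|---|---|---|
| depth | `20 <= DP <= 60` **and** `|DP - mean| <= 3 * sd` | hard window 20–60×, 3-SD band |
| alternate support | `alt reads >= 3` | inclusive |
| site quality | `QUAL >= 30` | inclusive |
| mapping quality | `MQ(ref) > 30` and `MQ(alt) > 30` | strict |
| repeat mask | position not in a tandem-repeat interval | BED mask |

Two deliberate asymmetries: the site-quality threshold is inclusive while
the mapping-quality threshold is strict — the two criteria are phrased
differently ("a minimum of 30" vs "exceeds 30") and we read each literally
— and the depth rule is a *conjunction* of the fixed window and the
coverage band, since both are stated as one clause.  Coverage mean/SD are
computed per sample over its variant records unless a genome-wide profile
is supplied; with a single record the SD is undefined and the band is
disabled rather than guessed.  Rejections carry the first failing rule in
evaluation order (depth, alt support, site quality, mapping quality, mask),
but membership of the kept set is an order-independent conjunction — the
test suite checks it against a brute-force oracle and for idempotence.

Coordinates follow the field's two conventions: variant positions are
1-based (VCF), interval masks 0-based half-open (BED), so a variant at
position $p$ is masked when $p-1$ falls in an interval.  Indels are not
handled by these SNV rules; the pipeline is SNV-centric.

# DNM calling

For a focal sample, `call_dnms()` takes the QC-kept records with ≥ 3
alternate reads as candidates and removes any whose site shows *presence*
in a parent or earlier-generation sibship member.  Presence
(`variant_present()`) is deliberately lenient — ≥ 2 alternate reads, or
VAF ≥ 0.05 at depth ≥ 10 — and is judged on the **unfiltered** variant
table (`presence_variants`): an inherited variant that merely failed QC in
the parent must still block the call.  This asymmetry (strict to call,
lenient to block) trades a little sensitivity for a large specificity
gain, which is the point of the three-generation design.

`remove_shared_snvs()` replaces a phylogenetic rooting step with
deterministic set logic: a variant present in at least one sample of every
sibship, or in any unrelated control, is ancestral.  Rooting a maximum
likelihood tree on all samples identifies exactly the variants shared by
everyone; the set formulation computes that membership directly and
reproducibly.  The final manual-inspection step of a real study is out of
scope; calls remain machine-auditable tables instead.

Sample sex is inferred from coverage (`infer_sex()`): males carry one X
and one Y (both near half the autosomal depth), females two X and no Y.
The thresholds — male iff Y:autosome ≥ 0.25 and X:autosome ≤ 0.75, female
iff Y ≤ 0.05 and X ≥ 0.75, otherwise ambiguous — are this package's
choice; the comparison itself is standard but no published cutoffs exist
for it.  The margins are wide because real ratios cluster near 0.5/0.5 and
1.0/0.0.

# Mutation timing: the 2:2 / 1:3 model

A point mutation in a primordial germ cell that is resolved by mitotic
repair before gamete formation sits on both strands of one parental
haplotype in the zygote: half of all reads over the locus carry it
(genotype 2:2, expected VAF 0.5).  A mismatch that *escapes* repair until
after zygotic genome replication is carried by one of the four strands:
a quarter of reads carry it (genotype 1:3, expected VAF 0.25).  The
observed VAF therefore timestamps the mutation.

`classify_genotype()` maps observed VAF to class by fixed intervals:
\[0.30, 0.70\] → 2:2, \[0.10, 0.30) → 1:3, anything else unclassified.
Numerical conventions:

- The two published ranges ("30%–70%" and "10%–30%") meet at 0.30; we
  impose a half-open convention assigning the boundary to 2:2, and expose
  all three bounds in `genotype_rule()`.
- VAF outside \[0.10, 0.70\] is reported `unclassified`, not forced into a
  class.
- Classification uses the raw observed VAF, not a posterior over the true
  VAF — it matches the descriptive procedure the design calls for.  The
  binomial machinery exists for error analysis only:
  `expected_misclassification(v, d)` returns the exact probability that a
  Binomial(d, v) draw lands outside the true class's interval.

At 30×, that exact arithmetic gives
`r round(expected_misclassification(0.25, 30), 3)` for a true 1:3 mutation
(mostly observed VAFs at or above 0.30) and
`r round(expected_misclassification(0.5, 30), 3)` for a true 2:2.  The
asymmetry matters when interpreting class fractions: at 30× a recovered
1:3 fraction *understates* the true mixture weight, and the recovered
fractions converge to the truth only as depth grows — both properties are
exercised in the test suite (depth 200 recovers the mixture within 0.05).

# Rate arithmetic, spectra, hotspots

`expected_dnm_count(rate, G, ploidy)` is the plain product — for the mouse
defaults $5.4\times10^{-9} \times 2.7\times10^9 \times 2 = 29.16$ — and
`fold_increase()` divides an observed group mean by it.  Rounding
("approximately 29", "~3-fold") is applied only in rendered report text,
never to stored values.  For the human extrapolation the package computes
the direct product $1.2\times10^{-8} \times 3.2\times10^9 \times 2 = 76.8$;
the conventional literature baseline of 70 DNMs (and 2.1 deleterious among
them) differs from that product, so the extrapolation arithmetic treats 70
and 2.1 as explicit stated constants rather than deriving them.

Substitution spectra collapse the 12 raw base changes into 6
strand-symmetric classes (`substitution_class()`), so a C>T and its
complement G>A both count as G:C>A:T; spectra are invariant under
reverse-complementing every input.  The spectrum comparison is the one
place a genuinely underdetermined method choice had to be made: a
Kolmogorov–Smirnov test on categorical spectrum data is not standard, and
the construction here — two-sample KS of the per-sample focal-class
fractions against bootstrap draws Binomial$(n_i, p_{ref})/n_i$ at the
observed per-sample DNM counts — is the one construction we found that
both is a two-sample KS test and respects the count-dependent sampling
noise of per-sample fractions.  It is flagged here prominently because a
different construction would change p-values; the focal class, reference
proportion and bootstrap size are all parameters.

`window_counts()` tiles chromosomes with fixed windows (terminal windows
keep their true width), and `poisson_hotspot_test()` asks whether the
counts look Poisson.  Two statistics are reported, since no specific test
is canonical: a Pearson dispersion chi-square
$\sum (O-E)^2/E$ on $n-1$ df (with exposure-adjusted expectations
$E_i \propto$ window width; for equal windows this is the classical
variance test $(n-1)s^2/\hat\lambda$), two-sided, which drives the
`reject` decision and a `direction` label; and, for equal-width tilings, a
binned goodness-of-fit chi-square with expected bins pooled to ≥ 5.  The
dispersion test's type-I error is calibrated by simulation in the test
suite (1,000 null datasets of 270 windows at mean 3; rejection within
Monte-Carlo error of α = 0.05).  Windows with ≥ 14 mutations are flagged
as hotspots by default — a threshold meaningful at the conventional 10-Mb
scale on a full genome and exposed as a parameter.

`rbc_folate()` recovers red-cell folate from whole-blood and plasma
measurements via the cell-fraction percentage:
$\mathrm{FA_{rbc}} = \mathrm{FA_{whole}}/h \times 100 -
\mathrm{FA_{plasma}} \times (100-h)/h$.  A negative result is physically
impossible and warns rather than silently passing.

# SV screening

The package does not call structural variants; it screens externally
produced candidates.  `normalize_depths()` rescales each sample's depths
so sibship members share a common mean (depth comparisons across a sibship
are meaningless otherwise).  `filter_sv_candidates()` keeps a candidate
only when its region depth deviates by ≥ 50% from *both* the sample's
genome-wide mean and the flanking depth, and drops candidates overlapping
excluded chromosome ends (default: the outer 0.5% of each chromosome —
"adjacent to centromere/telomere" comes with no published distance, so the
margin is a genome-model parameter).  `flag_de_novo_svs()` marks an F2
candidate whose region depth differs from either parent's by ≥ 50% of the
parental depth.  All three boundaries are inclusive, and every decision
depends only on depth *ratios* — multiplying all depths by any constant
leaves the kept set and flags unchanged, which the tests assert.

# The synthetic generator: what it emulates and what it does not

`simulate_study()` is first-class, tested code, not a throwaway fixture.
Its defaults encode the study conditions:

| parameter | default | meaning |
|---|---|---|
| `dnm_mean` | 29.16 / 87.6 / 211 | expected DNMs per sample in the control, one-deficient-grandparent, and both-deficient arms |
| `p_mismatch` | 0.466 | probability a DNM is an unrepaired mismatch (true VAF 0.25); the F2-level mixture 268/575 |
| `depth_mean` | 30 | sequencing depth (Poisson, truncated ≥ 1; negative-binomial dispersion knob available) |
| `spectrum_fd` / `spectrum_control` | G:C>A:T 35.4% / 53% | six-class substitution spectra per arm |
| `qual_range`, `mq_range` | 40–60, 50–60 | drawn so filters reject only when a test intends it; a `noisy` read mode straddles the boundaries |
| `n_founder_snvs`, `n_shared_ancestral_snvs` | 50, 10 | Mendelian background and universally shared variants |

Per-sample DNM counts are Poisson — the count distribution is not
published, and Poisson is the minimal model for "an expected number of
independent events"; the generator's mean/variance equality is itself
verified by the tests.  Positions are uniform over the unmasked autosomes,
drawn without replacement, with collisions against background variants
redrawn.  F1 DNMs transmit to each F2 with probability equal to their true
VAF (0.5 for a fixed heterozygote; 0.25 for a mismatch, which if
transmitted becomes an ordinary heterozygote in the child).  Read sampling
is Binomial(depth, true VAF) — the two germline timing classes only.  All
randomness flows through R's single seeded generator; `sim_config(seed=)`
makes fixtures byte-identical across runs.

The default genome is the 19 mouse autosomes plus X and Y at 1/100 of
their true lengths (~27 Mb total), so uniform draws and window statistics
run in seconds; *all* rate arithmetic takes genome size explicitly, so the
desk scale never contaminates mutation-rate results.  The default hotspot
window is scaled accordingly (1e5 vs the conventional 1e7).

What the generator does **not** model — and therefore what passing tests
cannot show about real data: sequencing error and mapping artifacts beyond
binomial allele sampling (no false alternate reads, so the caller's false
positives here come only from pedigree structure, not from noise);
post-zygotic somatic mosaics at VAFs below the 1:3 band (undetectable at
30× and excluded by design); recombination and linkage (sites segregate
independently); context effects such as CpG hypermutability (classes are
drawn i.i.d. from the configured spectrum); and real hotspot structure
(positions are uniform, so the Poisson test should *fail to reject* on
simulated data — its power is tested with explicitly spiked windows
instead).

# Problem sizes and reproducibility

The shipped test suite runs the whole battery in well under a minute:
10,000-draw Monte-Carlo checks for VAF recovery and misclassification,
100,000-draw spectrum recovery (in the acceptance script), 1,000-replicate
calibration of the dispersion test, and end-to-end pipelines on one or two
sibships with 3–23 F2 embryos.  These sizes were chosen so each stochastic
assertion sits at least 3 standard errors from its pass boundary under the
null.  `run_dnm_pipeline()` with a seeded `sim_config()` produces
byte-identical artifacts and reports across runs, and
`scripts/acceptance.R --seed N` reproduces the headline recovery numbers
from scratch.

# Known limitations

- The caller assumes every parent has a variant table; partially sequenced
  pedigrees error rather than degrade.
- Presence thresholds (2 reads / VAF 0.05 at depth 10) and sex-ratio
  cutoffs are sensible defaults, not fitted quantities; both are exposed
  as arguments.
- The KS construction for spectra is one defensible choice among several
  (see above); treat its p-values as conditional on that construction.
- The dispersion chi-square relies on the large-count approximation; with
  very sparse windows (mean count ≪ 1) prefer larger windows.
- `timing_summary()` fractions are biased toward 2:2 at moderate depth;
  use `expected_misclassification()` to de-bias or report depth alongside.
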