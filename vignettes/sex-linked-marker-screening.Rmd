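---
title: "Screening, confirming and using sex-linked markers from GBS genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, confirming and using sex-linked markers from GBS genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmark)
```

## The problem and the model

In taxa with young, homomorphic sex chromosomes, the sex-determining region
(SDR) is small and the X/Y (or Z/W) pair recombines over most of its length.
Reduced-representation sequencing of phenotypically sexed adults samples
thousands of short tag loci; the handful that sit in or near the SDR leave a
genotype signature that depends only on which sex is heterogametic. Taking
an XY system (ZW is the exact mirror obtained by swapping the sex labels —
the package tests this symmetry mechanically):

* an X/Y-differentiated SNP has the X allele at frequency ~1 in females
  (two X copies) and ~0.5 in males (one X, one Y), and every
  non-recombinant male is heterozygous while every female is homozygous;
* a Y-specific sequence yields a tag present in every male and absent from
  every female.

`sexmark` screens every SNP and tag with three criteria built on these
expectations and classifies the system from the balance of XY- versus
ZW-pattern tags. The criteria are deliberately simple threshold rules, not
likelihood models: they operate on per-sex summary statistics
(`site_sex_stats()`, `tag_presence_stats()`) that are trivially auditable,
and the package checks them against independently coded direct evaluations
by exhaustive enumeration of all small genotype configurations.

## Tunable parameters

All thresholds live in `detection_params()`:

| parameter | default | meaning |
|---|---|---|
| `f_fix` | 0.95 | minimum allele frequency in the homogametic sex (criterion 1); 1 minus an allowance for genotyping error |
| `d_min` | 0.4  | minimum between-sex frequency difference (criterion 1); the idealised difference is 0.5, relaxed for error and recombination |
| `het_frac` | 0.5 | minimum fraction of heterogametic-sex individuals heterozygous (criterion 2, "at least half") |
| `min_called` | 5 | called individuals per sex below which a site is uninformative |
| `max_missing_presence` | 0 | unknown-presence individuals tolerated per sex by criterion 3 |

All comparisons are inclusive (`>=`), guarded by a 1e-9 epsilon so that
frequencies like 19/20 compare as equal to the 0.95 threshold under floating
point. `min_called = 5` is an artifact-level informativeness floor, well
below the 21–22 individuals per sex of a typical discovery panel; the
criteria are meaningless on nearly empty genotype columns, and degenerate
input yields an uninformative flag rather than an error. Confirmation
thresholds (`confirmation_params()`): `e_max = 1e-20` (inclusive for the
top-hit rule, strict for the gene-matching margin rule, matching how the
two rules are stated) and `margin_orders = 5`.

## Design choices where the rules underdetermine behaviour

* **Missing genotypes.** The screening rules are silent on missing data.
  Frequencies use `2 * n_called` alleles over called individuals only, and
  "all females" / "half of the males" are evaluated over called individuals
  — the only denominators that keep the criteria well defined.
* **Signed frequency difference.** Criterion 1 requires the homogametic sex
  to carry the near-fixed allele at the higher frequency, because the
  expectation it encodes is two copies versus one. `abs_diff = TRUE`
  restores an absolute-difference reading.
* **Directional ambiguity.** Complete opposite fixation (all females
  hom-ref, all males hom-alt) satisfies criterion 1 in both the XY and the
  ZW direction. No diploid XY or ZW inheritance model produces that
  configuration, so it is treated as directionally ambiguous and yields no
  record rather than an arbitrary pattern (or an error).
* **Strict sex-limitation.** "Present in all males, absent in all females"
  is taken literally over individuals with known presence; any
  unknown-presence individual fails the tag unless `max_missing_presence`
  is raised explicitly. The strictness is visible in practice: a single
  sex-reversed individual, or presence dropout, removes a genuinely
  Y-limited tag from the criterion-3 set (the README example shows this).
* **System call.** The field reports the XY fraction; the call threshold
  (default `majority = 0.8`) is this package's own rule and is
  configurable. Tags with conflicting XY and ZW records are excluded from
  both tallies.
* **Confirmation accounting.** A tag detected by several approaches keeps
  one record per approach but counts once among distinct tags. Confirmed
  counts are reported both with multiplicity and under unique attribution
  to the highest-priority approach (frequency > heterozygosity >
  sex-limited); the published-style per-approach totals that sum exactly to
  the confirmed count correspond to the unique attribution.
* **Zero E-values.** `10^-margin` arithmetic is undefined at `E = 0`; when
  best and second hits are both exactly zero the margin is decided by
  bitscore (best must be strictly higher), and a best `E = 0` always passes
  `e_max`. Ties at identical E break by bitscore, then subject id, so best
  hits are deterministic.
* **Genotypic sexing.** Evidence is aggregated by strict majority of
  non-missing markers (`> 0.5`), uncalled on ties or below `min_markers` —
  never guessed. A single heterozygous SD marker does *not* assign genetic
  male under the default; `any_y = TRUE` restores the "one Y-evidence
  suffices" reading. Discordance is only flagged for called individuals
  with known phenotype.
* **PA primer convention.** "The male-specific base is the first base of
  the 3' end" is read as: the 3'-terminal nucleotide of each anchoring
  primer sits on its SNP and carries the male (Y) allele — complemented on
  the reverse primer, whose footprint is `[j, j + len)` so that its
  3' terminus pairs with plus-strand position `j`. Product size is the
  half-open span from the forward footprint start to the reverse footprint
  end (`j - i + 2*len - 1` for anchors `i < j`). Placements are purely
  positional; the Wallace-rule Tm (2 °C per A/T, 4 °C per G/C) is reported
  informationally, and no thermodynamic screening is attempted.
* **Configuration files.** The CLI takes JSON configs (`jsonlite` is a
  pinned dependency of the target environment; YAML is not).

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the *post-genotyping* structure the screen
consumes: phenotype labels for `n_males` / `n_females` individuals, a
planted fraction `reversal_fraction` whose genetic sex opposes the label
(`floor(rho * n)` individuals drawn without replacement), fully
differentiated sex-linked SNPs with a per-carrier recombination leakage
probability `recomb_prob` (a recombinant heterogametic carrier is
homozygous — the parameter stands in for distance from the SDR, not for a
genetic map), Y-/W-limited tags with presence dropout, autosomal SNPs in
Hardy–Weinberg proportions at frequencies drawn uniformly from
`freq_range = c(0.05, 0.95)`, a genotype-class error `genotyping_error`
that flips a call uniformly to one of the other two classes, and missing
calls at `missing_rate`. Defaults are the study-design sample sizes
(22/21) and modest noise rates typical of de-novo GBS genotyping (1%
class error, 5% missingness, 5% leakage), chosen once; the acceptance
properties override them explicitly where a clean world is specified.

Deliberately *not* modelled: read depths and depth-dependent error,
linkage disequilibrium between sites, coalescent history, allele dropout
correlated with restriction-site polymorphism, and population structure. A
green detector test on simulated data therefore establishes that the
implementation applies the stated criteria correctly and recovers planted
structure under the stated noise model — it does not establish power on
real data, where error is not uniform across genotype classes and
sex-linked divergence varies continuously along the chromosome.

The error model acts on genotype classes, not alleles: this is sufficient
to stress every threshold (it creates het females, breaking criterion 2,
and frequency perturbations, stressing criterion 1) while staying
single-parameter.

## Numerical and degenerate-input policy

Detectors never throw on data: uninformative sites and degenerate inputs
yield no record with the uninformative flag; errors are reserved for
structural problems (unknown sex tokens, duplicate samples, panel markers
missing from the dataset, non-biallelic rows are skipped and counted).
Internal coordinates are 0-based half-open; reports print 1-based
positions; VCF `POS` is handled as 1-based per the standard. Report rows
are sorted on a stable key so repeated writes are byte-identical.

## Known limitations

* Criterion 3 has tag-level resolution only; per-SNP accounting for
  sex-limited tags is not defined (they have no within-sex polymorphism to
  genotype).
* No multiple-testing control is applied; with ~10^5 autosomal sites the
  heterozygosity criterion admits a small, quantifiable false-positive set
  (the acceptance suite checks the empirical rate against the closed-form
  binomial product `P(0 het females) * P(>= n/2 het males)`), and users
  are expected to confirm candidates against a reference.
* The sexing step assumes the panel markers are valid; it propagates, and
  cannot detect, a mis-validated marker.
* Alignment is consumed, never computed: confirmation is only as good as
  the hit table supplied.
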