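---
title: "Methods: cross-species mutagen-sensitivity analysis with mutexcess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species mutagen-sensitivity analysis with mutexcess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutexcess)
```

## The question the pipeline answers

Somatic cells of long-lived mammals are thought to defend their genomes more
accurately than cells of short-lived mammals. One way to probe this is to
challenge cultured primary fibroblasts from many species with a fixed,
low-toxicity dose of a direct-acting point mutagen (ENU,
N-ethyl-N-nitrosourea, which induces almost exclusively base substitutions,
enriched for A>T transversions), sequence treated and untreated cultures with
an error-corrected single-molecule assay, and ask whether the *excess*
somatic mutation frequency — treated minus control — declines with the
species' maximum lifespan (MLS). mutexcess implements the computational half
of that design, starting from call-level data: per-sample somatic SNV call
sets, per-sample callable-base counts, per-species genome sequences, and a
species covariate table.

The pipeline stages are:

1. **Germline filtering** — remove inherited variants from call sets.
2. **Burden estimation** — per-sample SNV frequencies per Mb of callable
   sequence; per-species excess frequency ΔSNV with bootstrap uncertainty.
3. **Comparative regressions** — OLS of excess burden on MLS, body mass and
   longevity quotient (LQ), with leave-one-out sensitivity refits.
4. **Spectra** — 96-channel trinucleotide-context spectra per
   species × condition group, rescaled ("humanized") to a common genome
   composition.
5. **Signatures** — de novo non-negative matrix factorization of the grouped
   spectra, cosine matching against a reference catalog, contribution
   analysis across conditions and lifespan.

A seeded synthetic-cohort generator emulates the call-level output of the
sequencing assay so every stage is exercised end to end without any external
data.

## The synthetic-data generator

`simulate_cohort()` draws, for each species:

* a toy chromosome of i.i.d. bases (default 200 kb) with a species-specific
  expected G+C content (defaults between 0.38 and 0.46, so the
  composition-rescaling step has real differences to correct);
* a germline variant set at `germline_density_per_mb` (default 100/Mb of
  genome), shared by every sample of the species and flagged in a side
  table. Real heterozygote density is an order of magnitude higher, but on a
  0.2 Mb toy chromosome 100/Mb yields a usefully sized truth set (~20
  variants) for the filter to remove; 1/Mb would yield none.
* per sample, a Poisson number of somatic SNVs with mean
  `rate_per_mb × callable_bases / 1e6`. Callable bases (default
  5×10⁷) and the rate are properties of the assay and condition, not of the
  toy chromosome length, which only hosts the placements.

Each somatic SNV first draws its 96-context category from the condition's
signature mixture, then draws a genome position uniformly among positions
whose trinucleotide context matches the category (on either strand),
without replacement within a sample. Placement is therefore exact by
construction: re-classifying any emitted record reproduces the drawn
category, which the suite asserts record by record.

Three built-in generator signatures define the mixtures
(`generator_signatures()`): an ENU-like signature with 0.75 of its mass
uniform over the 16 T>A categories, a flat clock-like background, and a
CpG-deamination signature with 0.6 of its mass on the four `N[C>T]G`
categories. These are synthetic constructs capturing the qualitative
structure of the corresponding real processes, not copies of catalog
entries. Default mixtures: controls 0.7 flat + 0.3 CpG; treated samples
0.75 ENU + 0.175 flat + 0.075 CpG, reflecting the dominance of the mutagen
signature in treated cultures.

**The effect model.** The default cohort spans ten mammals with MLS 3 y
(mouse, hamster, rat) to 211 y (bowhead whale). Controls mutate at 0.3
SNV/Mb; the treated excess declines log-linearly in MLS from 0.8 SNV/Mb at
3 y to 0.35 SNV/Mb at 211 y (`default_effect_model()`), matching the
magnitude range the assay reports for short- versus long-lived species.
Sample sizes default to 3 control + 3 treated per species. Body masses are
literature-typical; LQ defaults are computed from the Austad–Fischer
allometry `MLS_expected = 10.67 · mass_g^0.189` via `longevity_quotient()`.

**What the generator does not emulate:** read-level errors, the rolling-
circle library structure, indels and structural variants, regional mutation-
rate heterogeneity, and any lifespan dependence of the *control* signature
composition. Consequences: passing tests demonstrate that the estimators
recover planted parameters under the model's assumptions, not that real data
satisfy those assumptions; and the signature-vs-lifespan association is null
by construction in simulated cohorts (the pipeline still computes and
reports it, as it exists for real data where it is not null).

**Seeding.** A single cohort seed fans out deterministically: species *i*
uses `seed + 101·i`; within a species, the genome uses the species seed, the
germline set `seed + 77`, and sample *j* of a condition
`seed + 1000·j + 500·[treated]`. The pipeline derives stage seeds as
`seed + 7919 · stage_index` (`stage_seed()`), so any stage can be re-run in
isolation and reproduce the full run. Identical seeds give byte-identical
output files.

## Context classification and spectra

`classify_context()` assigns each SNV its pyrimidine-strand category: if the
reference base is a purine, the substitution and its flanking trinucleotide
are reverse-complemented before lookup. The category order is fixed
(substitution-major: C>A, C>G, C>T, T>A, T>C, T>G; flanks alphabetical,
5′ slowest) and exposed by `sbs_categories()`. Records whose window runs off
the contig or contains an ambiguity code are skipped and tallied, never
imputed; a reference base disagreeing with the genome aborts, since it
indicates corrupted inputs. All 192 (flank, ref, alt) combinations fold onto
the 96 categories, each hit by exactly two strand-mates; the suite checks
this against a brute-force oracle.

`trinucleotide_frequencies()` slides a width-3 window (step 1, ambiguity
windows skipped, purine-centered windows reverse-complemented) and returns
the 32 strand-collapsed trinucleotide frequencies. The counting is delegated
to `Biostrings::trinucleotideFrequency()`. An optional BED mask restricts
counting to callable regions.

## Humanization (composition rescaling)

Trinucleotide composition differs across genomes, and context-dependent
mutagenesis makes raw category counts incomparable between species.
`humanize_counts()` rescales each category count by the ratio of target to
source genome frequency of the category's pyrimidine-strand trinucleotide:

```
count'[c] = count[c] × f_target(t(c)) / f_species(t(c))
```

Design choices, where the convention was genuinely open:

* **Ratios are per-trinucleotide (32), not per-category (96):** a
  trinucleotide's frequency is a property of the genome, not of the mutation
  type, so the three categories sharing a trinucleotide share one ratio.
* **No renormalization of the total** — the rescaled counts are generally
  non-integer and their sum changes; `preserve_total = TRUE` rescales to the
  original sum as a sensitivity option.
* **Zero source frequency with a non-zero count is an error** naming the
  trinucleotide, never a silent pseudocount.
* **Placement in the pipeline:** rescaling is applied to the grouped spectra
  before signature extraction (the cross-species analysis); burdens use raw
  counts by default, with `humanize_burdens = TRUE` as a sensitivity switch.

The operation is linear and exactly invertible by swapping the frequency
pair; the suite asserts identity, involution and linearity to 1e-9 on
randomized inputs.

## Germline filtering

Two rules, both tallied per removal
(`germline_filter()`):

* match against a provided germline variant table on
  (species, chrom, pos, ref, alt);
* cross-sample recurrence: any call recurring at identical (chrom, pos, alt)
  in ≥ 2 distinct samples of the species (threshold configurable) is
  removed, a panel-of-normals-style rule that catches germline leakage even
  without a matched set. At realistic genome sizes a coincidental somatic
  recurrence is vanishingly rare; on desk-scale toy chromosomes it can
  occur, and the filter removes such genuine recurrences by design.

## Burden and ΔSNV

`snv_frequency()` is `n_snv / callable_bases × 1e6` — per Mb, the scale on
which excess frequencies of 0.3–0.8 are readable; the factor is
configurable. `delta_snv()` computes, per species, mean treated frequency
minus mean control frequency. The study design treats samples per species as
exchangeable replicates, so the default is a difference of condition means;
`paired = TRUE` averages per-pair differences instead. Uncertainty is a
seeded percentile bootstrap (default 2000 resamples within condition, 95%
level) — reported because point estimates from 3+3 samples are noisy and no
analytic interval is natural for the small-n mean difference.

## Comparative stage

`fit_regression()` is ordinary least squares (via `lm()`) of per-sample
excess points — each treated sample's frequency minus its species' mean
control frequency — on the covariate, with the two-sided slope p-value from
the t distribution on n−2 df. Per-sample points are the default (30 points
for the default cohort) rather than 10 species means: with samples as the
unit, the uncertainty within species propagates into the fit; per-species
means remain available by aggregating before fitting. Body mass is regressed
in raw grams by default with a `log10_x` switch. `leave_one_out()` refits
after excluding, by default, human, bowhead whale and rat — the influential
extremes — and each result equals a direct fit on the retained subset.

`spearman_correlation()` uses midranks for ties; its two-sided p-value is an
exact permutation enumeration for n ≤ 9 (valid under ties) and the
t approximation otherwise. `paired_t_test()` and `wilcoxon_signed_rank()`
wrap the base R tests with explicit degenerate-case behavior: all-zero
differences error (the statistic is undefined); constant non-zero
differences yield an unbounded t (±Inf, p = 0, with a warning) and the
exact minimum Wilcoxon p for that n. The Wilcoxon null is exact for ≤ 25
non-zero tie-free pairs; with tied absolute differences an exact sign-flip
enumeration is used up to n = 16, beyond which the midrank normal
approximation applies.

## Signature extraction

`nmf_extract()` factorizes the 96 × G grouped-spectra matrix as `M ≈ W H`
by multiplicative updates minimizing the generalized Kullback–Leibler
divergence — the Brunet variant standard in mutational-signature tools —
with a Frobenius option behind a flag. Numerical choices:

* default 30 random initializations with per-restart seeds `seed + r`; the
  best final objective wins; a single restart is fully deterministic;
* updates guard denominators with 1e-12; the objective uses the
  `0 log 0 = 0` convention; the per-iteration trace is non-increasing (a
  guaranteed property of the updates, asserted in tests);
* convergence when the relative objective change drops below `tol`
  (default 1e-6); hitting `max_iter` sets a warning flag rather than
  erroring;
* afterwards W columns are normalized to sum to 1 with compensating row
  scaling of H, and signatures are renamed S1..Sk in decreasing order of
  total contribution — the ordering rule is a package convention.

Identifiability deserves a caution that shapes the tests: a perfectly flat
signature, or several signatures sharing a large flat component, can trade
mass between components with compensating contributions, so independent fits
agree only to cosine ≈ 0.98–0.99 even when they reach identical objectives.
Recovery tests therefore plant structured, well-separated signatures with
mixtures spanning the simplex boundary (the separability condition); the
exact permutation-equivariance of the updates is asserted separately with a
consistently permuted initialization.

`match_signatures()` ranks catalog entries by cosine similarity (ties broken
lexicographically). The package bundles a synthetic three-entry catalog
(`synthetic_reference_catalog()`); a COSMIC-plus-ENU TSV can be supplied via
`read_signature_catalog()` with the documented layout (a `category` column
plus one probability column per entry). `contribution_fractions()`
normalizes H columns; the pipeline compares the top signature's fraction
between conditions with a paired t test and computes the Spearman
association of a chosen signature's control-group fraction with MLS,
excluding named outlier species (default: human, which in the real data
behaves anomalously).

## Pipeline, validation, reporting

`run_pipeline()` executes the stages in order on either a simulated cohort
or a cohort directory (FASTA + VCF/TSV + metadata written by
`write_cohort()`), and emits TSV tables, optional PDF figures, a
`manifest.json` (versions, seeds, input checksums, record tallies — no
timestamps, so identical runs give identical manifests), an echoed
`config.yaml`, and a human-readable `summary.txt`. `validate_inputs()`
checks parseability, species cross-references, callable-base positivity and
REF/genome agreement without running anything, and distinguishes warnings
from errors. Stage failures abort with the stage named and leave a `FAILED`
marker beside any partial outputs.

## Problem sizes used in the shipped checks

The test suite simulates cohorts on 20–100 kb toy chromosomes (1 Mb for the
recurrence check) with the default 3+3 samples and 50 Mb callable bases;
estimator-bias and slope-sign properties use 100 replicate cohorts;
signature recovery uses 20 replicates of 20 groups at 10⁵ mutations per
group; statistical-test calibration uses 1000 null replicates of 30 pairs.
These sizes were chosen so the whole suite exercises every stage at
meaningful depth while remaining a desk-scale computation.

## Known limitations

* The generator's i.i.d. genomes lack repeats, isochores and chromatin
  structure; humanization ratios on real genomes are more extreme.
* ΔSNV assumes the callable denominator is exact; no coverage model.
* KL-NMF rank selection is not automated; k is a user choice (default 3),
  and only a divergence-vs-k inspection via repeated fits is possible.
* The comparative stage deliberately fits ordinary regressions; phylogenetic
  non-independence (PGLS, contrasts) is out of scope.
* Wilcoxon exactness with heavily tied data is limited to n ≤ 16 by
  enumeration cost.
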