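# mutexcess

Comparative analysis of mutagen-induced somatic mutation burden across
mammalian species, from call-level single-molecule sequencing data.

## The problem

Do cells of long-lived species defend their genomes more accurately than
cells of short-lived species? A direct experimental probe is to treat
primary fibroblasts from many species with a fixed low dose of ENU
(N-ethyl-N-nitrosourea) — a direct-acting point mutagen that induces almost
only base substitutions, enriched for A>T transversions — quantify somatic
SNVs in treated and untreated cultures by error-corrected sequencing, and
relate the *excess* mutation frequency per species,

```
ΔSNV = mean(treated SNV/Mb) − mean(control SNV/Mb),
```

to maximum lifespan (MLS), body mass, and longevity quotient (LQ).
`mutexcess` implements the full computational pipeline for that design, for
analysts working with per-sample somatic SNV call sets (VCF or TSV),
callable-base counts, species genome FASTAs and a covariate table:

* **96-context spectra** — pyrimidine-strand trinucleotide classification of
  SNVs, with genome trinucleotide frequencies and the cross-species
  "humanization" rescaling `count'[c] = count[c] · f_target(t(c)) / f_species(t(c))`
  that makes spectra comparable across genome compositions;
* **germline filtering** — matched-set removal plus a cross-sample
  recurrence rule, every removal tallied;
* **burden statistics** — per-sample SNV/Mb, per-species ΔSNV with a seeded
  percentile-bootstrap confidence interval;
* **comparative regressions** — OLS of per-sample excess burden on
  MLS / body mass / LQ with leave-one-out sensitivity refits, plus Spearman
  (exact permutation for small n), paired t and Wilcoxon signed-rank
  helpers;
* **de novo mutational signatures** — Kullback–Leibler NMF
  (multiplicative updates, seeded restarts) of the grouped spectra, cosine
  matching against a COSMIC-style reference catalog, contribution fractions
  by condition, and signature–lifespan association;
* **a synthetic-cohort generator** — seeded, exact down to the byte, that
  emulates call-level output of the sequencing assay (Poisson burdens,
  signature-mixture contexts, shared germline sets) for ten species with
  lifespans from 3 to 211 years, so the whole pipeline runs and is tested
  with no external data.

Everything is data-frame-first and pipe-friendly: call sets, burdens,
regressions and fractions are tibbles; the NMF fit has `tidy()`/`glance()`
methods and `autoplot()`.

## Worked example

```r
library(mutexcess)

res <- run_pipeline(pipeline_config(seed = 1))
res
```

```
mutexcess pipeline run (seed 1)
species: 10, samples: 60, calls in: 2994, somatic after filter: 1816
germline removals: set-match 1176, recurrence 2

excess mutation frequency (per Mb):
  beaver           delta = 0.600  [0.493, 0.687]
  bowhead_whale    delta = 0.253  [0.180, 0.327]
  chinchilla       delta = 0.533  [0.447, 0.620]
  cow              delta = 0.573  [0.487, 0.660]
  guinea_pig       delta = 0.733  [0.480, 0.893]
  hamster          delta = 0.860  [0.733, 1.000]
  human            delta = 0.353  [0.080, 0.593]
  mouse            delta = 0.873  [0.720, 1.013]
  naked_mole_rat   delta = 0.547  [0.420, 0.653]
  rat              delta = 0.913  [0.807, 1.020]

excess vs MLS:  slope -0.002722 per year, R^2 = 0.5448, p = 3.23e-06 (n = 30 points)
top-signature matches: S1->ENU_synthetic (cos 0.982), S2->clock_flat_synthetic (cos 0.685), S3->clock_flat_synthetic (cos 0.645)
S1 fraction treated vs control: t = 17.642, p = 2.74e-08
S3 fraction vs MLS (control groups, excl. human): rho = 0.509, p = 0.169
```

Reading the output: each species' ΔSNV is the treated-minus-control SNV
frequency per Mb with its 95% bootstrap interval — short-lived species
(mouse, hamster, rat, ~0.9/Mb) sit well above the bowhead whale (~0.25/Mb).
The regression line of per-sample excess on MLS has a negative slope
(−0.0027 SNV/Mb per year of lifespan), i.e. ENU induces fewer mutations in
cells of longer-lived species. The extracted S1 signature matches the
ENU-like reference (cosine 0.98) and dominates treated cultures (paired t,
p ≈ 3e−8), exactly as planted by the generator; the S3–lifespan association
is null in simulation, since the generator gives all species the same
control signature mixture.

With `out_dir` set, the run also writes TSV tables (burdens, ΔSNV,
regressions, spectra, signatures, matches, fractions), PDF figures, an
echoed `config.yaml`, a `manifest.json` with seeds and input checksums, and
`summary.txt`. Identical config + seed reproduce every file byte for byte.

Individual stages are plain functions on data frames if you bring your own
data:

```r
cohort  <- simulate_cohort(seed = 1)            # or read_calls()/read_genomes()
calls   <- germline_filter(cohort$calls, cohort$germline)
burdens <- sample_burdens(calls, cohort$callable)
delta   <- delta_snv(burdens, seed = 1)
fit     <- fit_regression(excess_points(burdens, cohort$metadata),
                          mls_years, excess_per_mb)
```

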