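---
title: "From untargeted LC-MS peaks to pathway activity: methods and design"
author: "peaks2func"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From untargeted LC-MS peaks to pathway activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaks2func)
```

## The problem

High-resolution LC-MS1 profiling of a biological sample yields thousands of
peaks — (m/z, retention time) pairs with per-sample intensities — of which
only a small fraction can be confidently identified. Conventional pathway
analysis requires identified compounds, so most of the signal is discarded.
`peaks2func` implements the alternative: predict pathway activity directly
from the peak table by *putative* annotation, and let a permutation scheme
absorb the annotation ambiguity. The same machinery supports meta-analysis
across datasets, joint gene-metabolite pathway analysis, and a data-driven
partial-correlation network over the features themselves.

## Putative annotation and empirical compounds

A peak with observed m/z `x` putatively matches compound `c` under adduct
rule `a` (with multiplier `n`, mass shift `d`, charge `z`) when

```
| x - (n * M_c + d) / |z| | / predicted * 1e6  <=  ppm_tol
```

The default tolerance is 5 ppm, typical for Orbitrap/TOF instruments, and
the default rule sets (7 positive-mode, 6 negative-mode adducts, shipped as
an editable TSV) use shifts that include the proton mass 1.007276 Da; the
electron mass is ignored as it contributes well under 0.5 ppm for
metabolite-sized molecules. Matching is deliberately many-to-many.
Ubiquitous "currency" metabolites (water, CO2, ATP, ...) are excluded by
default because they connect most pathways and would otherwise dominate any
overlap statistic.

Annotation of a table imported from mzTab-M falls back to the theoretical
neutral mass when no experimental m/z is present; such rows are flagged in
the table's metadata, and for them a single identity rule (zero shift,
charge 1) should replace the adduct set, since their masses are already
neutral.

The mummichog v2 refinement groups matches into **empirical compounds**:
peaks that match the same candidate compound *and* co-elute. Within each
candidate compound we cluster the matched peaks' retention times by single
linkage and cut at `rt_tol`; each cluster becomes one empirical compound,
so a compound observed at two well-separated retention times is counted
twice rather than once (distinct isomers eluting apart), while adduct
series of a single elution collapse to one unit. The tolerance defaults to
1% of the observed retention-time span — a gradient-relative choice that
adapts to run length; single linkage was chosen because adduct series form
chains, not spheres, in retention time. When every compound elutes once,
v2 reduces exactly to v1 (compound-level counting), which is tested.

## Pathway activity prediction

Given a ranked peak list (from `rankFeatures()`, a Welch t-test on
`log(x + 1)` intensities, or supplied directly), the significant set `Lsig`
is either the peaks with `p <= sig_cutoff` (default 0.05) or an explicit
index set — supporting enrichment of *any* peak group of interest, e.g. a
cluster selected from a heatmap.

Counting happens at the unit level (compounds for v1, empirical compounds
for v2). The universe `N` is the set of units annotatable **from the input
peak list**, not the whole database: the test conditions on what the
instrument could have seen. For a pathway with `K` annotatable units and
`k` of them hit by significant peaks, the overlap statistic is the
EASE-adjusted hypergeometric tail `P(X >= k - 1)` — the conservative
variant that discounts one overlapping member, with `k = 0` defined as 1.

Because a peak may annotate several units and vice versa, the analytic
hypergeometric null is misspecified; the reference algorithm's remedy is a
permutation calibration, which we follow. Each of `n_permutations`
(default 100, minimum 20) draws `|Lsig|` peaks uniformly without
replacement from the full peak list — peaks, not compounds, so annotation
multiplicity propagates into the null — and recomputes every pathway's
EASE p. Empirical compounds are built from the annotation of the *full*
peak list, and a permutation only re-selects which peaks count as
significant, so the empirical-compound structure is identical across
permutations and is computed once.

The pooled null scores `s = -ln(p_null)` are fitted with a Gamma(shape,
scale) by maximum likelihood (location 0), and the reported `gamma_p` is
the fitted upper-tail probability at the observed EASE p. One numerical
subtlety: permutation EASE p-values have a point mass at exactly 1
(pathways with zero overlap in a permutation are common in small
universes), i.e. `s = 0`, where the Gamma likelihood is unbounded. The fit
therefore uses the positive part of the null and multiplies the tail by
the positive-part proportion — a mixture that reduces to the plain Gamma
fit whenever no null value equals 1 (e.g. a uniform null recovers shape
and scale of 1, which is tested), stays monotone, and keeps the
calibration property: on null fixtures the fraction of pathways with
`gamma_p < 0.05` lands close to 0.05. Degenerate nulls (all values
identical, or MLE failure) fall back to a rank-based empirical tail with a
warning.

Results are sorted by `gamma_p`, ties by EASE p and then pathway id;
pathways with fewer than `min_pathway_hits` (default 1) annotatable
members are dropped.

## Meta-analysis

Two strategies cover the two study designs:

* **Pathway-level integration** (independent cohorts interrogating the
  same biology): enrichment runs per dataset, then per-pathway `gamma_p`
  values are combined by Fisher's method or equal-weight Stouffer (a
  weight vector is exposed for callers who want size-weighting). A
  pathway absent from a dataset contributes p = 1 — absence of evidence
  penalizes rather than silently dropping the dataset — and the per-dataset
  significance flags at `alpha` give the Venn structure.
* **Peak pooling** (the same samples measured under complementary
  conditions, e.g. both ionization modes): each list is annotated under
  its own adduct rules, annotatable compounds and significant annotations
  are pooled by set union, and one enrichment runs with permutations
  drawing from the pooled peak space. Counting is at the compound level,
  since lists may lack retention times and retention times are not
  comparable across chromatographic conditions. Identical `(mz, rt, mode)`
  triples in two lists are rejected as accidental duplication.

## Joint gene-metabolite pathway analysis

For identified hits (not putative annotations) the plain hypergeometric
ORA is used per omics — no EASE discount, since identified hits carry no
annotation ambiguity. The per-pathway gene and metabolite p-values are
combined either unweighted (Fisher) or by weighted Stouffer,

```
Z_c = (w_g Z_g + w_m Z_m) / sqrt(w_g^2 + w_m^2),   Z_i = qnorm(1 - p_i)
```

with weights the proportions of genes/metabolites in the combined universe
(`stouffer_overall`) or within the individual pathway
(`stouffer_pathway`). The weights as stated already sum to one and are
used without renormalization; the root-sum-of-squares denominator is the
standard weighted-Stouffer form. Weighting counters the tendency of
transcriptomics, with its much larger universe and hit lists, to dominate
the combined ranking. Combination is one-sided throughout — a small p
always means stronger pathway activity; effect directionality is not
modeled. A pathway with members from only one omics takes that omics'
p-value directly (running a combiner against a constant p = 1 would
distort it). The `metabolite_only` and `gene_only` library modes skip
combination; the `metabolic` and `all` modes differ only when the library
itself distinguishes metabolic from signaling pathways — the library
format carries no type flag, so they are aliases here.

## DSPC networks

The debiased sparse partial correlation network treats features (annotated
or not) as nodes. On the column-standardized data (after `log(x + 1)` by
default, consistent with the ranking module; disable for
already-transformed input) with empirical correlation `S`:

1. graphical LASSO estimates a sparse precision `Theta` at penalty
   `lambda`;
2. the de-sparsified estimator `T = Theta + Theta' - Theta' S Theta`
   removes the shrinkage bias;
3. `rho_ij = -T_ij / sqrt(T_ii T_jj)` (clamped to [-1, 1]) with asymptotic
   variance `(T_ii T_jj + T_ij^2) / n` gives each pair a two-sided
   p-value;
4. BH q-values across all pairs define the edge set at `fdr_alpha`
   (default 0.05); the full pair table is always retained.

The graphical LASSO is implemented in-package as Friedman-style block
coordinate descent. `lambda = "auto"` minimizes the extended BIC
(`gamma = 0.5`) over the grid {0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5};
at `lambda = 0` (allowed only for `p < n`) the de-biasing identity makes
`T` equal the dense inverse, reproducing classical partial correlations
exactly — a useful correctness anchor that the tests exploit. Features
with more than 20% missing values are dropped with a warning; remaining
missing entries are imputed with half the feature minimum, the common
"half-minimum" convention for values below the detection limit.

## Pre-analysis utilities

**Technical replicates** are merged per feature and biological subject:
with missing fraction `f` over the subject's `r` replicates, `f <= 1/3`
yields the mean of the observed values; `f > 1/3` (strictly "over", by
the rule's wording) triggers a coefficient-of-variation check, and
`CV > 1.0` marks the feature highly variant with a sentinel value of 0.
The CV uses the sample (n-1) standard deviation on raw intensities — the
rule predates any transformation in the workflow — and a single surviving
replicate is defined to have CV 0: discarding a lone real measurement as
"variant" would destroy signal. The missing/zero distinction matters
here, which is why the readers map empty cells, `NA` and `NaN` to missing
while a measured `0` stays zero. The optional kernel-density smoothing
sometimes applied to replicate data is not implemented: neither its
target quantity nor its bandwidth is well defined, and guessing both
would silently change users' data.

**Background features**: spectrum-wide m/z centroids are binned within 10
ppm (single-linkage on sorted m/z), and a bin whose scans contain a
consecutive run covering at least half the chromatogram
(`ceiling(run_fraction * n_scans)`) is excluded — the signature of
solvent background and contaminants that elute throughout. The run must
be *consecutive*; total occupancy does not trigger exclusion, so a
compound eluting twice broadly survives.

## The synthetic-data generators

All tests and the acceptance script run on generated data with known
truth; nothing is downloaded. The default `fixtureSpec()` emulates a
modest two-group untargeted study: 100 compounds (3 currency) uniformly
placed in 80-800 Da at > 50 ppm spacing so annotation is unambiguous at 5
ppm; 20 pathways of 8-15 compounds; 6 samples per group; log-normal
intensities with 0.5 log-units of noise; 1-3 adducts per compound with 2
ppm mass error, co-eluting within 2 s; 25% decoy peaks placed at least 10
ppm from every predicted adduct m/z, so their non-annotation is provable;
a planted log-fold-change of 2 on the members of one active pathway. The
complementary-mode generator assigns each compound to exactly one
ionization mode so that a pathway is fully visible only after pooling.

What the generators do *not* emulate: isotope envelopes, correlated noise
between co-eluting peaks, retention-time drift between samples, intensity-
dependent mass error, and chimeric peaks. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under
clean conditions, not robustness to every artifact of real spectra.

Problem sizes used by the test and acceptance runs — 200 null repetitions
at 100 permutations for the type-I check, 50 seeds for planted recovery
and pooling, 20 chain-precision simulations at n = 2000, p = 20, and 50
independence nulls at n = 200, p = 10 — were chosen as the smallest sets
at which the binomial/Monte-Carlo error of the checked rates is
comfortably below the acceptance margins.

## Worked example

```{r example}
spec <- fixtureSpec(seed = 7)
db   <- generateCompoundDb(spec)
lib  <- generatePathwayLibrary(db, spec)
gen  <- generatePeakTable(db, lib, spec)
ranked <- rankFeatures(gen$table)
res <- mummichogEnrich(ranked, db, lib, cfg = enrichmentConfig(seed = 7))
head(resultTable(res), 3)
gen$active_pathways
```

The planted pathway tops the table with a `gamma_p` orders of magnitude
below the rest.

```{r network}
net <- dspc(generateNetworkData(chainPrecision(10), n = 500, seed = 1)$X,
            log_transform = FALSE)
head(networkEdges(net), 3)
```

## Known limitations

* Annotation is adduct-only: no isotope-pattern scoring and no MS2
  evidence, so a match is a hypothesis, never an identification.
* Empirical-compound formation requires shared candidates plus RT
  proximity; complementary-adduct constraints are not imposed.
* The Gamma null is a parametric summary of the permutation distribution;
  with very few pathways or permutations the empirical-tail fallback is
  the safer route (triggered automatically on degeneracy).
* The DSPC asymptotic p-values rely on n reasonably exceeding the
  effective sparsity; with tiny n the BH edge set should be read as
  exploratory.
* `metabolic` vs `all` library modes coincide unless the library encodes
  pathway types.
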