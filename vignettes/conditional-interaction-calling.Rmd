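---
title: "Calling conditional genetic interactions from S-score screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling conditional genetic interactions from S-score screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemapr)
```

## The problem and the model

An epistatic miniarray profile (E-MAP) screen crosses query-gene deletion
mutants to a library of array deletion mutants and scores each double
mutant's fitness against the multiplicative expectation from the single
mutants. The S-score per gene pair combines interaction strength with
statistical confidence: strongly negative means synthetic sickness or
lethality, strongly positive means epistasis or suppression. A
*conditional* screen repeats the measurement under stress — here three
DNA-damaging agents (camptothecin, hydroxyurea, methyl methanesulfonate),
each at two concentrations, plus untreated controls, all in triplicate.

The question is not which interactions exist but which interactions
*change* when the DNA damage response is engaged. The model behind the
pipeline is additive on the S-score scale:

$$ S_{qa}^{c,r} = \mu_{qa} + \Delta_{qa}^{c} + \varepsilon, $$

where $\mu_{qa}$ is a condition-independent baseline interaction,
$\Delta_{qa}^{c}$ is a condition-specific shift (zero for most triples)
and $\varepsilon$ is replicate noise. Subtracting the untreated mean from
the drug mean cancels $\mu$ exactly, which is why the differential score
$D = \bar S^{drug} - \bar S^{UNT}$ isolates the conditional component.

Each (query, drug) vector of $D$ over array genes is standardized by its
own mean and sample standard deviation (denominator $n-1$) to a Z-score.
Two-sided p-values are taken against an empirical null: the null location
and scale are fit robustly as the median and the MAD ($\times 1.4826$) of
the observed Z, on the premise that true conditional interactions are a
small minority, so the bulk of the distribution *is* the null. q-values
are Benjamini–Hochberg step-up, computed across the whole experiment, and
calls require $q < 0.05$ strictly, signed by $D$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | calling threshold on q, strict `<` |
| `lo`, `hi` | −2.4, 2.0 | static S-score significance thresholds (strict), for per-condition distribution summaries only |
| `batch` | `per-batch` | standardization batch: each (query, drug) vector, or `pooled` across all |
| `fdr_batch` | `experiment` | BH correction across all rows jointly, or per (query, drug) |
| `null` | `empirical-null` | median/MAD null fit; `theoretical-null` takes Z as standard normal |
| `linkage` | `average` | profile clustering linkage |
| `universe` | 1536 | overlap-test sampling frame: the array-library size |

All thresholds are unitless (S-scores and q-values are unitless). Two of
these settle questions the screen's published description leaves open, and
both alternatives are implemented:

* **Standardization batch.** Per-(query, drug) is the default because
  S-score distributions broaden differently per condition; pooling would
  let the widest condition's spread mask the others. `batch = "pooled"`
  gives the other reading.
* **"Divided by the standard error."** Interpreted as the sample standard
  deviation of the differential-score batch. Dividing by
  $\mathrm{sd}/\sqrt{n}$ over ~1500 array genes would scale every Z by
  ~40 and make the Z-to-p conversion meaningless; standardization to unit
  variance is the only reading that produces Z-scores an FDR procedure
  can consume, and the empirical-null fit re-estimates the scale anyway.
* **FDR flavor.** The original analysis used a mixture-model FDR package;
  the variant (density-based local fdr vs tail-area q-values) is not
  recoverable. This implementation uses the transparent combination of a
  robust empirical null with BH tail-area q-values, which is testable
  against brute-force oracles and location-scale invariant; the
  theoretical-null mode exists so the BH machinery can be validated
  against its textbook definition.

## What the synthetic generator emulates

`generate_screen()` draws exactly the model above: a fraction
(`baseline_interaction_fraction`, default 0.2) of pairs get a baseline
$\mu \sim N(0, \texttt{baseline\_sd}^2)$ (default sd 2.5, so that a
realistic minority of pairs crosses the ±2 significance scale), planted
triples (default 1%) get $|\Delta| \sim N(6, 1.5^2)$ truncated positive
with random sign, and every replicate adds $N(0, 1)$ noise. The default
design is the real one: 3 queries × 1536 array genes × 3 drugs × 2
concentrations × 3 replicates, untreated controls pooled to 6 replicates.

Options off by default: a heavy-tail mixture for $\mu$ (5% of baselines
from a 3× wider normal, mimicking the heavy-tailed empirical S-score
distribution); `shared_baseline_fraction`, which makes part of the
baseline variance common to all queries (real query genes are chosen
*because* they are functionally related, which is why their untreated
profiles correlate); and `shared_effects`, which plants the same (array,
drug) effects in every query, optionally with one signed effect per array
reused across drugs (a generic damage-response module). The last two
state the world for the clustering acceptance test: with a shared module,
drug-condition profiles correlate with each other more than with the
untreated profiles, and average-linkage clustering on $1-r$ separates
untreated from treated — the qualitative structure seen in real
conditional screens.

What the generator does **not** emulate: plate spatial effects, batch
effects between concentration series, the discreteness and
variance-mean coupling of colony sizes (we start from S-scores, as the
pipeline does), linkage suppression around the query locus, and
missing-data structure (cells can be blanked in tests, but missingness is
not itself modeled). A green synthetic test therefore establishes that
the statistics recover the stated generative model at the stated design
size — not that any particular biological screen is free of artifacts.

## Numerical and degenerate-input choices

* Standardization requires ≥ 3 non-missing values and nonzero spread;
  both violations are errors, not silent NA.
* The empirical-null fit requires ≥ 50 Z-scores (a MAD on fewer is too
  unstable to define a null); theoretical-null has no minimum.
* Pairs missing either the drug or the untreated mean are reported with
  NA statistics and never called — NA is not q = 1.
* Correlations use pairwise-complete array genes with the complete-pair
  count recorded; cells with < 3 complete pairs or a zero-variance
  profile are missing, and clustering refuses matrices with missing
  cells rather than guessing.
* Profiles enter clustering in label order, fixing hclust tie-breaks;
  identical inputs give identical dendrograms.
* The KS p-value is exact when $n_x n_y \le 10^4$ and tie-free,
  asymptotic otherwise; the statistic itself is always the exact ECDF
  supremum gap.
* Hypergeometric tails come from `phyper`; the test suite checks them
  against exhaustive enumeration for every parameterization with
  $N \le 60$.
* The overlap odds ratio adds 0.5 to all cells only when a table margin
  is zero; the p-value is always the unmodified hypergeometric tail.
* In term enrichment, `fold = (k/n)/(K/N)` is 0 when k = 0 (p = 1), and
  terms with K < 2 are tested but flagged `low_power`.

## Known limitations

* The empirical-null/BH combination approximates, but is not identical
  to, mixture-model FDR fits; with per-batch standardization and an
  experiment-wide null, batches with unusually many planted effects are
  slightly conservative and batches with none slightly anticonservative.
  At the default design the realized false discovery proportion in
  simulations sits near the nominal 5% but can fluctuate toward ~10%
  across seeds when only ~140 effects are planted. In small screens where
  planting is very uneven across (query, drug) batches the effect is
  larger — a batch with no true effects keeps unit null spread while
  contaminated batches shrink below it, so the experiment-wide scale fit
  under-corrects the clean batch; `fdr_batch = "per-batch"` is the
  appropriate setting there.
* Enrichment results are functions of the annotation release supplied by
  the user; the package deliberately ships no annotation snapshot, and
  published fold-enrichment values are reproducible only with the
  original annotation version.
* The pipeline starts from S-scores; computing S-scores from raw colony
  sizes is out of scope.
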