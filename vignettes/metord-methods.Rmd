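---
title: "Methods: preprocessing and ordination of LC-MS/MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing and ordination of LC-MS/MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metord)
```

`metord` turns a feature quantification table (samples × features, peak areas
from untargeted LC-MS/MS) and its sample metadata into an ordination: blank
filtering, normalization, scaling, a dissimilarity matrix under one of twenty
measures, and classical Principal Coordinate Analysis. This vignette explains
the model behind each stage, the conventions and tolerances chosen where the
mathematics leaves freedom, and what the synthetic validation does and does
not demonstrate.

## The data model

A feature table is a dense non-negative matrix: `n` samples in rows, `p`
features in columns, peak areas in arbitrary instrument units. Untargeted
feature tables are sparse in a specific sense — a feature detected in a few
samples is simply absent (not "missing at random") elsewhere — so absent
cells are stored as 0 at ingest rather than NA. Values may only become
negative after scaling, never at ingest; readers and preprocessing stages
enforce this.

## Blank-intensity feature filtering

Blank samples (solvent/extraction controls) capture background signal:
plasticizers, solvent clusters, instrument carry-over. For feature `f` with
mean blank intensity `m_f`, the filter retains `f` iff

> fraction of non-blank samples with intensity **strictly greater** than
> `k · m_f`  ≥  `p`

with fold threshold `k > 0` and minimum fraction `p ∈ (0, 1]`.

Two boundary conventions matter and are fixed deliberately:

* The intensity comparison is strict (`>`). With an all-zero blank mean the
  threshold is 0, so any positive intensity qualifies — a feature never seen
  in blanks should never be discarded by the blank filter, no matter how
  large `k` is.
* The fraction comparison is inclusive (`≥`), evaluated as
  `qualifying / n_nonblank ≥ p` in exact arithmetic, with no rounding of the
  required count.

The filter removes features only; blank samples stay in the table, because
seeing blanks cluster apart from biology in the ordination is itself a
quality check. A separate pipeline flag (`drop_blanks`) excludes them from
the ordination afterwards.

Because feature tables are sparse and skewed, a mean-based filter with
moderate `k` and high `p` is aggressive: a feature present in fewer than
`p·n_nonblank` samples cannot pass regardless of its intensity. The filter
always reports how many features were removed, and the monotonicity the rule
implies (larger `k` or larger `p` can only shrink the retained set) is
verified as a property test against a brute-force double-loop oracle.

## Normalization

**TIC** divides each sample by its total summed intensity, making rows
probability vectors. It assumes comparable total ionization across samples
and fails loudly (naming the sample) on an all-zero row.

**PQN** corrects per-sample dilution rather than total signal. The
construction used is the standard one: (1) TIC-normalize all samples;
(2) reference spectrum `r` = per-feature median across the TIC-normalized
samples; (3) per sample, quotients `q_j = x_j / r_j` over features where
both `x_j > 0` and `r_j > 0`; (4) divide the sample by `median(q_j)`. The
defining property — multiplying one sample's row by any `c > 0` leaves its
PQN output unchanged — is tested to 1e-9 relative. PQN needs at least two
samples, and TIC-first is part of the recipe: it makes the reference and
quotients dimensionless before the median fold change is taken.

## Scaling

Both scalers center each feature column. Auto-scaling divides by the sample
standard deviation (unit variance); Pareto divides by its square root,
damping high-variance features while preserving more of the original
structure. Two conventions are declared once and used everywhere: standard
deviations use the `n − 1` denominator, and constant columns become all-zero
with a warning rather than an error — constant features are common after
filtering sparse tables, and aborting there would block otherwise valid runs.

Stage order is fixed: filter → normalize → scale. Filtering must see raw
intensities (its threshold is meaningless on scaled data), and scaling
last ensures feature variances are computed on comparable samples. Either
stage can be "none", supporting tables already normalized externally (e.g.
by internal standards).

## The dissimilarity engine

Twenty measures are registered (`?dissimilarity_metrics` documents each
formula): abundance-based (Bray-Curtis, Euclidean, squared Euclidean,
Manhattan/cityblock, Chebyshev, Canberra, cosine, correlation, Minkowski of
order 3, standardized Euclidean, Jensen-Shannon, Mahalanobis) and
presence/absence-based (Jaccard, Dice, Russell-Rao, Rogers-Tanimoto,
Sokal-Sneath, Yule, simple matching, Hamming). Conventions:

* Binary measures binarize at strictly `> 0`, the natural presence notion
  for intensity data; pairs with empty union are defined as distance 0.
* Canberra sums `|x−y| / (|x|+|y|)` with 0/0 terms contributing 0 (no
  rescaling by the number of nonzero terms, unlike `stats::dist`).
* Standardized Euclidean uses per-feature variances of the full table;
  constant features contribute 0 (their difference is necessarily 0).
* Mahalanobis uses the Moore-Penrose pseudoinverse of the feature covariance
  matrix, since `p > n` — the rule rather than the exception for feature
  tables — makes the covariance singular.
* Measures meaningful only for non-negative data (Bray-Curtis, Jaccard,
  Dice, Jensen-Shannon, Canberra) warn when applied after scaling has
  introduced negative values; the computation proceeds, since the warning —
  not a hard error — is what lets users see for themselves why that
  combination is questionable.
* Undefined pairs (e.g. Bray-Curtis between two all-zero samples, cosine
  against a zero vector) raise an error naming the pair.

Every measure is validated against an independently written per-pair formula
oracle, and against `stats::dist` / `vegan::vegdist` where definitions
coincide.

## Classical PCoA

Given dissimilarities `D`, form `A = −½ D∘D`, Gower-center `B = J A J` with
`J = I − 11ᵀ/n`, and take the symmetric eigendecomposition of `B`.
Coordinates for axis `a` are `v_a √λ_a` for `λ_a > 0`. Numerical choices:

* **Zero tolerance.** Eigenvalues within `max|λ| · 1e-12` of zero are
  treated as exactly zero, so the rank-deficient axes a centered
  configuration always produces do not surface as noise axes.
* **Negative eigenvalues.** Non-Euclidean measures can make `B` indefinite.
  Negative axes are excluded from coordinates and from the
  proportion-explained denominator (which uses the positive part only), and
  their summed magnitude is reported as `negative_eigenvalue_mass` — a
  distortion diagnostic. No Lingoes/Cailliez correction is applied; the
  diagnostic keeps the decision visible instead of silently reshaping the
  geometry.
* **Sign convention.** Eigenvectors are oriented so their largest-magnitude
  element is positive, making outputs bit-stable across runs — equality of
  repeated runs, including signs, is tested.
* **Degenerate spectra.** Axes within a tied eigenvalue block are
  rotation-arbitrary; equivalence tests on random (hence generically
  non-degenerate) configurations compare per-axis up to sign.

PCA column-centers the table and uses the SVD; scores are `U·S` and
eigenvalues the squared singular values, so their sum is `(n−1)` times the
total variance. The classical equivalence — PCoA of a Euclidean distance
matrix reproduces PCA scores and eigenvalues — is verified on 50 random
12 × 8 tables to 1e-8, and `stats::cmdscale`, `ape::pcoa` and `prcomp`
serve as independent cross-checks.

No stress statistic is computed: the embedding is the closed-form
eigendecomposition, not an iteratively stress-minimized configuration, and
reporting a stress value for it would misrepresent the method.

## The synthetic generator

`simulate_feature_table()` draws tables with the structure the pipeline
assumes, under a lognormal intensity model — the standard choice for LC-MS
peak areas, whose multiplicative errors and heavy right tail are exactly what
makes mean-based blank thresholds delicate:

* contaminant features: full lognormal intensity in blanks, attenuated
  tenfold in biological samples;
* biological features: lognormal in samples with a per-feature baseline
  `exp(N(log 1e5, 1))`, a multiplicative `effect_size` shift in that
  feature's marker group, and trace-level intensity in blanks (a
  thousandfold attenuation emulating carry-over — real blanks are dim, not
  exactly silent);
* zeros injected into the biological block at rate `sparsity`.

Defaults define the simulated study conditions: 4 blanks, 3 groups × 8
samples, 100 contaminant + 400 biological features, sparsity 0.3,
effect size 4, log-scale noise sd 0.5. These are desk-scale but
proportioned like small real designs (few blanks, ~20 % contaminant burden,
fold-4 group effects, a third of biological cells empty). One integer seed
governs all draws; ground truth labels are returned in memory and as a JSON
sidecar so tests never re-derive them.

What passing the recovery suite shows: under these conditions the filter
removes ≥ 95 % of planted contaminants while retaining ≥ 95 % of biological
features observable under the fraction rule, and Bray-Curtis PCoA on the
TIC-normalized table separates the groups (mean silhouette > 0.25 on axes
1–2 in at least 18 of 20 seeds). What it does not show: behavior under
retention-time drift, adducts and isotopes (not simulated), batch effects
beyond global dilution, correlated feature blocks, or blank sets that are
unrepresentative of the acquisition sequence. Real data can violate all of
these, which is why the filter reports its removal counts instead of being
trusted blindly.

## Validation problem sizes

The test suite exercises: filter-oracle equivalence on 100 random tables up
to 50 × 200; metric-formula agreement on 20 × 10 tables across all twenty
measures; PCoA/PCA equivalence on 50 random 12 × 8 tables; and the 20-seed
recovery study on the default 28 × 500 generator conditions. These sizes
keep the full suite in seconds while covering every code path; all scale
linearly or cubically (eigendecomposition) in ways that hold no surprises at
realistic table sizes (hundreds of samples, tens of thousands of features).

## Known limitations

* The plain-table dialect is a deliberately simple reconstruction (one id
  column, numeric body, orientation flag); exotic spreadsheet exports may
  need reshaping first.
* PCoA is computed by full eigendecomposition (`O(n³)` in samples); for
  thousands of samples a truncated solver would be preferable.
* No Lingoes/Cailliez correction, biplot loadings, or non-metric (stress
  minimizing) MDS.
* The interactive scatter is a minimal SVG renderer — per-group toggling,
  rotation, tooltips — not a full Emperor-style widget.
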