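---
title: "Methods: extreme-channel-identity features, self-organized kNN, and symbolic explanation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extreme-channel-identity features, self-organized kNN, and symbolic explanation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxfe)
```

## The model

`soxfe` classifies fixed-length multichannel EEG windows into two classes
and explains its decisions symbolically. Its core assumption is that class
information is carried by *which channel is extreme at each timepoint* —
the channel of maximal amplitude, minimal amplitude, and maximal/minimal
deviation from the instantaneous cross-channel mean — rather than by
spectral content. Everything downstream is bookkeeping over these
identities:

- **Transition tables.** For each of six ordered identity pairs, an
  `nc × nc` table counts co-occurrences over the window, then each row is
  divided by its sum (plus ε). A row of a normalized table is the
  conditional distribution of the second identity given the first.
- **Map histograms.** The same pairs, encoded `(first−1)·nc + (second−1)`,
  form six integer sequences whose histograms (raw counts, summing to the
  window length) are position-compatible with the flattened tables: bin g
  and row-major cell g both decode to the same channel pair. This is what
  makes the explainability layer's index decoding well defined across all
  15 feature vectors.
- **Concatenations.** fv7 = fv1..fv6, fv14 = fv8..fv13, fv15 = both: the
  general vector carries 12·nc² features (2352 at 14 channels).

Classification is deliberately not a single tuned model: a 60-point kNN
grid is run per feature vector, voted combinations are added (iterative
majority voting over the accuracy-sorted top r+2 outcomes, r = 1..58), the
best of the 118 candidates is kept per feature vector, and the 15 winners
are fused by another voting round (13 candidates; the final outcome is
always a voted one). The "self-organization" is this greedy,
accuracy-driven selection.

### A caveat the user must know

The greedy selections — and the cumulative-weight NCA selection, which is
computed once on the full dataset before cross-validation — are scored
against the true labels of *all* segments, including held-out ones. This is
the protocol the method defines, and the package reproduces it exactly, but
it means reported accuracies are optimistic model-selection scores, not
unbiased generalization estimates. The permutation experiment in the test
suite quantifies this: on record-permuted labels the fused "accuracy" sits
well above 0.5, the sum of (a) residual correlation between a label
permutation and the class structure (the fraction of records keeping their
label is hypergeometric around ½, and any classifier that recovers the
clusters attains the majority side of it) and (b) picking the maximum of
~118 candidate accuracies. Nested selection would remove (b) but would be a
different method; we document rather than alter it.

## Parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `distance_mode` | `"absolute"` | absolute/signed | The signed deviation provably yields `id3 ≡ id1`, `id4 ≡ id2` (argmax is shift-invariant), collapsing three tables onto the others; the absolute mode keeps six distinct tables, consistent with 15 distinct feature vectors being useful. Signed mode is retained behind the flag and its degeneracy is asserted in tests. |
| `epsilon` | 1e-10 | — | Division guard for all-zero table rows; any value ≪ 1/L leaves populated rows summing to 1 within 1e-6. |
| `threshold` | 0.99 | (0, 1] | Cumulative normalized NCA weight retained. |
| NCA `sigma` | 1 | kernel width | Softmax temperature on z-scored features; O(1) distances justify O(1) sigma. |
| NCA `lambda` | 1/n | — | L2 penalty scaling away with sample count, the usual choice for this objective. |
| NCA `iters`, `lr` | 100, 0.1 | — | Fixed-iteration gradient ascent from w = 1; deterministic, no line search. |
| kNN grid | k 1..10 × 3 distances × 2 weightings | — | The fixed 60-configuration ensemble; not user-tuned, by design. |
| `cv`, `n_folds` | kfold, 10 | — | k-fold is seeded, unstratified (stratification is not part of the method definition; the seed is exposed so both readings are reproducible). `loro` holds out whole records. |
| `positive_class` | higher label | — | In the usual coding the condition class; configurable. |

Numerical tie rules, all deterministic: argmax/argmin ties take the lowest
channel index; kNN vote/score ties fall back to the nearest neighbour's
class, then the lower label; equidistant neighbours rank by training-row
order; accuracy-sorting ties keep input order; voting ties take the lower
label; greedy ties take the earliest candidate. Cosine distance of a zero
vector is defined as 1; inverse-distance weights are clipped at 1/1e-12.

## The synthetic generator

Real clinical recordings are not distributable, so the package ships a
generator whose learnable signal matches the extractor's sufficient
statistic. Each segment is i.i.d. Gaussian noise (`noise_sd = 10`,
microvolt scale) plus a per-channel amplitude boost drawn per segment
around the class's dominance profile (`boost_sd = 1`; default profiles put
+3 on the first seven channels for one class and on the last seven for the
other), plus a per-record scalar offset (`record_offset_sd = 5`) added to
*all* channels. The scalar offset induces record-level amplitude
correlation in the raw signal while remaining invisible to
extreme-channel-identity features, which are invariant to a constant shift
across channels — so grouped and ungrouped CV can be compared without a
record-leakage confound built into the fixture.

Default sizes — 20 records per class, 4 segments per record, 15 s at
128 Hz — are the package's chosen desk-scale study condition: large enough
that the 60-outcome grid and voting stages behave as intended, small
enough that the full pipeline runs in well under a minute.

What the generator does **not** emulate: EEG rhythms and 1/f spectra,
artifacts (blinks, muscle), electrode drift, nonstationarity,
subject-specific spatial patterns beyond the class profile. Passing tests
on this fixture therefore demonstrate the pipeline's mechanics and its
sensitivity to channel-dominance structure — not clinical performance on
real EEG.

## Design choices made where the design was open

- **Histogram features are raw counts** (summing to the window length);
  only transition tables are normalized. Keeping counts preserves the
  conservation property the tests assert and changes nothing for kNN after
  z-scoring inside NCA.
- **Row-major flattening** of tables fixes the feature-index ↔ channel-pair
  correspondence used by the symbolic decoder; the decoder's block
  arithmetic (`mul`/`rem`/`first`/`second`) exactly inverts the map
  encoding, checked exhaustively for nc ∈ {3, 14}.
- **NCA variant**: diagonal-metric feature weighting with a city-block
  kernel — the standard feature-selection form of neighborhood component
  analysis. The inner loop is compiled (RcppArmadillo) over the
  n(n−1)/2 unordered pair differences; a pure-R implementation of the same
  objective and gradient is kept as an oracle and agrees with the compiled
  fit to ~1e-15, and the analytic gradient agrees with central finite
  differences to < 1e-4 relative error.
- **Out-of-fold outcome vectors**: each of the 60 configurations produces
  one full-length prediction vector assembled across folds, because the
  voting stages operate elementwise over whole outcome vectors; per-fold
  accuracies are never averaged separately.
- **Fusion selects among voted outcomes only** (13 candidates), while the
  per-feature-vector stage selects among base and voted outcomes (118) —
  the two stages are defined differently and implemented literally.
- **Entropy is base 2**, making the 8-symbol alphabet's maximum exactly
  3 bits.
- **Segment files are plain CSV** (samples × channels, header = channel
  names) written at 17 significant digits so a write/read round trip is
  bit-exact. EDF import is not provided; CSV is the interchange format.

## Problem sizes used in the tests

Structural and oracle tests run on windows of 50–1920 samples and 3–16
channels. Pipeline-level property tests (voting improvement, dominance
monotonicity) use 12 records × 2 segments with 10-fold CV; the end-to-end
separation and permutation experiments use the default 40-record
configuration, 1 + 5 pipeline runs. These sizes are the package's choice
of smallest configurations at which the assessed properties are
statistically meaningful.

## Known limitations

- Reported accuracies are self-organized model-selection scores (see the
  caveat above); for unbiased estimates the user must wrap the whole
  pipeline in an outer CV, which the package does not do.
- With near-uniform NCA weights the 0.99 cumulative threshold keeps most
  features, so the selection stage prunes little on data without sparse
  structure; the DLob strings then mostly reflect the montage's
  channel-to-lobe composition (eight of fourteen channels map to frontal
  symbols) rather than sharp localization.
- k-fold CV mixes segments of one record across training and testing;
  `loro` is the defensible scheme for subject-level claims.
- Only two-class problems are supported, matching the method's definition.
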