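---
title: "Hyperdimensional classification and backward feature elimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperdimensional classification and backward feature elimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdselect)
```

# The model

`hdselect` classifies samples described by numeric features — in the
motivating use case, microbial species profiles of stool metagenomes in a
case/control design — with a Multiply–Add–Permute (MAP) vector-symbolic
architecture, and selects discriminative features by a stepwise backward
variable elimination wrapper around that classifier.

Everything is built from bipolar hypervectors: vectors of dimensionality
$d$ (default 10 000) with components in $\{-1, +1\}$. At this
dimensionality two independent random hypervectors are quasi-orthogonal
(the cosine of their angle has standard deviation $1/\sqrt{d} = 0.01$), so
independent random vectors can stand for unrelated concepts. Three
operations manipulate them:

* **binding** — element-wise multiplication; the result is quasi-orthogonal
  to both inputs, and binding a bipolar vector with itself gives the
  all-ones identity;
* **bundling** — element-wise addition; the integer-valued result stays
  similar to each summand, which is how evidence is accumulated;
* **permutation** — cyclic rotation by $p$ positions; the rotated vector is
  quasi-orthogonal to the original, and the operation distributes exactly
  over binding and bundling, which is how feature *position* is encoded.

## Level vectors and quantization

Scalar values are represented by an ordered family of $L$ **level
vectors**. The first level is a random bipolar vector; each next level
flips $N = \lfloor d / 2L \rfloor$ further component signs. Flip positions
are consumed in consecutive disjoint blocks of one random index permutation,
so a position is flipped at most once across the family and the similarity
between any two levels has the exact closed form

$$\cos(\ell_i, \ell_j) = 1 - \frac{2N\,|i-j|}{d}.$$

Adjacent levels are therefore nearly identical while distant levels are
quasi-orthogonal — close values stay comparable, distant values become
discriminable. The open choice here was whether flip positions may repeat
across steps; we use disjoint blocks because repetition would make the
similarity profile random rather than exact, and the closed form makes the
construction testable to numerical precision. With presence/absence data
the same formula applies with $L = 2$ ($N = d/4$, adjacent cosine $0.5$);
no special casing.

A value $x$ in the quantization range $[v_{\min}, v_{\max}]$ maps to level
index $\lceil (x - v_{\min})/w \rceil - 1$ with bin width
$w = (v_{\max}-v_{\min})/L$ (index 0 at the minimum, capped at $L-1$):
right-closed bins, so with range $[0, 100]$ and $L = 100$ the values 0.1
and 1.0 share level 0. The range is the *global* min/max of the training
portion of the data — one level family describes the whole dataset, which
mirrors how relative abundances all live in $[0, 100]$ — and is fitted per
cross-validation fold on the training rows only, to avoid leakage; test
values outside the range are clamped with a warning.

## Encoding, class vectors, retraining

A sample with feature values $x_0, \dots, x_{F-1}$ is encoded as

$$\mathbf{s} = \sum_{f} \rho^{\,p_f}\!\left(\ell_{q(x_f)}\right),$$

the bundle of each value's level vector rotated by the feature's position
$p_f$. Positions are the features' *original* column indices, kept stable
across elimination rounds. The wording "position of the feature in the
dataset" could also mean the position after removals; we use original
indices because the encoding of a feature subset is then exactly the full
encoding minus the removed features' rotated level vectors, an identity the
wrapper exploits to score leave-one-out candidates incrementally (and which
the test suite asserts as exact integer equality). The discriminative
content is the same either way — both choices assign distinct rotations to
distinct features.

Each class's vector is the bundle of its training samples' encodings, and a
query is assigned the class with the highest cosine similarity (ties to the
first-declared class, deterministically). Bundling introduces crosstalk
noise, mitigated by **retraining**: passes over the training samples in
dataset order in which each misclassified sample's encoding is subtracted
from the wrongly predicted class vector and added to the true one — so the
element-wise sum of all class vectors is invariant, a conservation law the
tests check. The error count is measured by a full evaluation before the
first pass and after each pass; passes stop when the count repeats exactly
(not within a tolerance) or after $R$ passes (default 10). A class vector
can cancel to the zero vector during retraining; its cosine is then taken
as 0 rather than an error so prediction never crashes.

All vector arithmetic is integer-valued (stored in doubles well below
$2^{53}$), so fits, retraining and predictions are exactly reproducible.

## Cross-validation

Models are evaluated by stratified $k$-fold cross-validation (default
$k = 5$): within each class, samples are shuffled with a seeded RNG and
dealt into folds whose per-class counts differ by at most one. Reported
accuracy is the arithmetic mean of fold accuracies; per-class one-vs-rest
precision/recall/F1 are also computed, with zero-denominator ratios
reported as 0 plus an explicit flag. The fold plan depends only on the
labels, $k$ and the seed, so every candidate feature subset within a
selection run is scored on identical folds. The level family is likewise
generated once per run: level vectors encode values, not data, and sharing
them keeps candidate accuracies comparable.

# Backward variable elimination

Given the full feature set $S$, the wrapper first scores the full model; if
its mean accuracy is below the threshold $T$ (default 60%), it stops
immediately. Each iteration then scores all $|S|$ subsets of size $|S|-1$,
discards candidates below $T$, and computes the **acceptance band**: the
iteration's best accuracy minus its $u\%$ (relative), i.e.
$\text{best} \times (1 - u/100)$, compared without rounding (display floors
to integer percent — a best of 93% under $u = 5\%$ gives a cutoff shown as
88). *Every* feature whose exclusion scored within the band is removed in
that iteration, so several near-redundant features can leave together;
$u = 0$ recovers classic one-at-a-time backward elimination, a property the
tests assert.

The run additionally stops when an iteration's best accuracy falls below
the *previous accepted* best by more than the same relative band — the
iteration is rejected and its removals are not applied. A plain "stop on
any strict decrease" is too eager: accuracy routinely fluctuates by less
than the uncertainty between iterations, and the five-feature worked
example (93% followed by 90% followed by 75%) only terminates where it
should if small within-band drops are tolerated and the 75% iteration is
the one rejected. With $u = 0$ the band rule *is* the strict-decrease rule.
The comparison is against the previous accepted iteration's best rather
than the global best; the two coincide in every walkthrough we know of,
and the previous-iteration reading keeps the rule local. Each evaluated
subset counts once toward `models_evaluated` (its per-fold models are
detailed in the trace, one JSON-lines record per iteration).

Because near-best candidates are removed in bands, small models with
slightly sub-best accuracy accumulate in the trace. The **suboptimal
frontier** queries them: among all evaluated candidates above a floor
(default 70%), the model with the fewest features, ties broken by higher
accuracy and then by earliest evaluation. This is the readout that
identifies compact biomarker panels. A forward-inclusion mirror of the
wrapper is exposed via `direction = "forward"` for completeness, but the
elimination direction is the primary, tested surface.

# Microbiome preprocessing

`read_profiles()` ingests merged MetaPhlAn-style tables (lineage strings in
the first column, one column per sample, values in $[0, 100]$), keeping
species-level rows only (`s__` present, no strain `t__`) plus the reserved
`unclassified` row. Preprocessing follows the order: cross-study species
intersection, then low-abundance, then low-prevalence filtering —

* `merge_profiles()` keeps species detected (RA > 0 somewhere) in *every*
  study;
* `filter_species()` removes species whose **peak** abundance never reaches
  1% and species detected in fewer than 5% of samples.

"Abundance lower than 1%" is ambiguous between peak, mean and per-sample
readings; we filter on the maximum because it is the most permissive
reading consistent with "very low abundant" (a species that ever reaches 1%
is kept), and the threshold is a plain argument for users who want
otherwise. In every step the removed species' abundance is added to the
sample's `unclassified` row, so per-sample totals are conserved to
$10^{-9}$ — the invariant the acceptance tests check. "Detected" always
means strictly positive, matching `binarize()`'s rule (1 iff RA > 0).
Stratification splits by sex or by the 65-year age boundary (age $\le 65$
is adult, $> 65$ senior); adenoma samples in metadata are dropped with a
warning since the contrast is case versus control.

# Differential-abundance statistics

For species of interest the package reports per-class prevalence
(percentage of class samples with RA > 0), log2 fold change of class mean
abundances with **no pseudocount** — a zero class mean yields an explicit
`Inf`/`NaN` with an `undefined` flag rather than a silently shifted value —
and a two-sided Wilcoxon rank-sum test per species with Benjamini–Hochberg
correction (via `stats::p.adjust`; an independent hand-written step-up
serves as the oracle in the tests). The default p-value is the normal
approximation with tie correction and no continuity correction, the
conventional choice for abundance data where ties are pervasive;
`exact = TRUE` exposes the exact distribution for tie-free data. Default
significance requires both $p \le 0.05$ and FDR $\le 0.2$; the
$|\mathrm{log2FC}| \ge 1$ cut often applied before testing is available as
a reporting filter, not baked into the test.

# Synthetic data

The generators produce the statistical structure the classifier and
selector assume, so the whole stack is testable without any downloads.
`simulate_binary_profiles()` plants `n_informative` features whose presence
probability differs by class (defaults 0.85 in cases vs 0.15 in controls —
a strong prevalence contrast of the kind compact discriminative species
panels show) among background features at probability 0.5 in both classes
(maximally variable, zero class signal). The default study size is
100 + 100 samples with 50 features, 5 informative.
`simulate_ra_profiles()` reuses the same presence draws and assigns
Gamma-distributed abundances plus a Gamma-weighted `unclassified`
remainder, normalized so every sample sums to exactly 100.

What the generator deliberately does **not** emulate: compositional
correlations between species, zero inflation beyond independent Bernoulli
absence, batch/study effects, and phylogenetic structure. Passing the
planted-recovery tests therefore shows the algorithm recovers prevalence
signal under its own assumptions — it does not certify performance on real
microbiome cohorts, where cross-study heterogeneity is the dominant
difficulty.

# Numerical choices and problem sizes

* $N = \lfloor d/2L \rfloor$ (integer flips; the conservative rounding).
* Quantization bins are right-closed; bin widths are equal to within one
  float ulp.
* Retraining convergence compares integer error *counts* for equality, not
  rates against a tolerance; the cap $R$ guards against oscillation.
* Prediction ties and fold assignment are deterministic given the seed;
  two runs with the same seed produce byte-identical traces.
* The reference test scenario runs the full stack at $d = 10\,000$,
  $L = 2$, 200 samples and 50 features — selection completes in roughly a
  minute and a half on one core — and smaller cases use $d$ between 1000
  and 4000, where the geometry (cosine sd $1/\sqrt{d}$) is still
  comfortably below the effect sizes being tested.

# Limitations

The wrapper's cost grows with the square of the feature count times the
cross-validation cost, so very wide profiles benefit from the band removal
($u > 0$) which retires many features per iteration. Accuracies from
wrapper-internal cross-validation are model-selection scores, not unbiased
generalization estimates; an external validation set is the honest check.
The classifier produces no calibrated probabilities, and multi-label
problems are out of scope.
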