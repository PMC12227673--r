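---
title: "Universal signal encoding and decoding for multiplexed digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal signal encoding and decoding for multiplexed digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrcode)
```

## The encoding model

Universal-signal-encoding dPCR decouples target detection from signal
generation. Every target's allele-specific primer carries a synthetic tail
with one or two *universal* probe-binding sites; each site binds either the
low-concentration ("1i") or high-concentration ("2i") universal hydrolysis
probe of one color channel, formulated at a 2:1 intensity ratio so that
signals interpret additively. A target's **signature** is the digit string
over channels with 0 = no site, 1 = 1i site, 2 = 2i site (channel 1
leftmost). One or two sites over $C$ channels give
$\sum_{k=1}^{2}\binom{C}{k}2^k$ distinct signatures — 32 at $C=4$ — and
relaxing to sites in every channel gives $3^C-1$ (80 at $C=4$, 728 at
$C=6$); `capacity()` and `enumerate_codebook()` implement this code space.
Because no public reference fixes which signature belongs to which assay
target, the canonical lexicographic enumeration is the package's reference
ordering and user codebooks may override it via `codebook()` or
`read_codebook()`.

At end point, a partition's per-channel amplitude falls into one of four
levels: 0 (no tag touched the channel), 1 (only 1i tags), 2 (only 2i tags),
3 (both probe classes consumed). The concatenated levels are the partition's
**label**. Crucially, the mapping from occupancy to label is the
*signature-union*: a channel's level encodes the **set** of probe classes
present, not their multiplicity — two co-present tags both carrying a 1i
site in channel 1 still read level 1, because probe consumption saturates.
This is the load-bearing semantic of the whole stack: it makes the union
idempotent, commutative and associative (`signature_union()`), and it is
why labels are ambiguous (`decompositions()` lists the candidate tag
combinations of a label).

## The hierarchical deconvolution

Assume each target's molecules are distributed independently and uniformly
over the $N$ partitions, so tag $\tau$ occupies a partition with probability
$1-e^{-\lambda_\tau}$, independently across tags, with $\lambda_\tau$ its
mean copies per partition. Write $P_L$ for the observed count of label $L$
and $P_0$ for the null-label count. `decode_dpcr()` estimates tags in
ascending order of probe-site count:

1. **Single-site tags.** A partition labeled with a single-site signature
   contains exactly that tag, so
   $\hat\lambda_\tau = \ln(1 + P_\tau/P_0)$.
2. **Multi-site tags** with signature $L$. Let $A$ be the codebook tags
   strictly contained in $L$ (channel-wise, same digit on their support) —
   all of lower order, hence already estimated. First the *expected count*
   of partitions showing $L$ through co-presence alone,
   $$E_L = P_0 \sum_{S \subseteq A,\ \cup S = L}\ \prod_{t \in S}
     \left(e^{\hat\lambda_t} - 1\right),$$
   is subtracted: $P'_L = \max(P_L - E_L,\, 0)$. For the two-single-tag
   case this reduces to $E_{1100} = P_0\,(P_{1000}/P_0)(P_{0100}/P_0)$,
   since $P_t/P_0 = e^{\lambda_t}-1$ for single-site tags. Next, partitions
   genuinely containing $\tau$ may also contain members of $A$; deflating by
   $P^*_L = P'_L \prod_{t\in A} e^{-\hat\lambda_t}$ leaves the expected
   count of partitions containing *only* $\tau$, and
   $\hat\lambda_\tau = \ln(1 + P^*_L/P_0)$.

**Why this is consistent.** Under the independence assumption the exact
label distribution satisfies
$P_L/P_0 = \sum_{S \subseteq A\cup\{\tau\},\ \cup S = L} \prod_{t\in S}(e^{\lambda_t}-1)$.
Splitting the sum by whether $\tau \in S$ (any $S \ni \tau$ has union $L$
automatically, because $\tau$'s signature *is* $L$) gives
$P_L = E_L + P_0(e^{\lambda_\tau}-1)e^{\sum_{A}\lambda_t}$, and the ladder
above inverts exactly to $\lambda_\tau$. The test suite asserts this
numerically to $10^{-10}$ relative error for the full 32-tag codebook and
100 random codebooks.

Two implementation choices matter:

* **Generalized expected counts.** The subset sum over $A$ is evaluated by a
  forward dynamic program on the $4^C$-state label lattice (labels pack into
  2 bits per channel, so unions are bitwise ORs), not by explicit subset
  enumeration — the same recursion powers `label_probabilities()`, which
  scales to the 728-plex studies. The test suite checks it against an
  independent brute-force enumeration over all $2^m$ presence patterns.
* **Excluded labels.** Labels matching no signature — every label containing
  a level 3, and unions like `1110` — are ambiguous mixtures. The estimator
  never consumes them; they are reported (`fit$excluded`) and still count
  toward $N$. Discarding them loses some information relative to a joint
  maximum-likelihood fit over all labels; the hierarchical moment scheme is
  retained deliberately for its closed form and interpretability, and the ML
  alternative is noted as an extension, not implemented.

Degenerate inputs: $P_0 = 0$ (saturated reaction) is a hard error; sampling
noise can drive $P_L < E_L$, in which case $P'_L$ clamps to 0 and
$\hat\lambda = 0$ (occupancies are non-negative by construction). Ties
within an order are processed lexicographically; estimates within an order
depend only on lower orders, so the order among ties is immaterial.

## Signal processing

The preprocessing chain mirrors standard instrument practice:

* `subtract_baseline()` removes the per-channel 3rd percentile
  (per well — multi-well inputs should be corrected per well before any
  pooling). Percentiles use linear interpolation between order statistics
  (quantile type 7), fixed and documented because different stacks default
  differently. The step assumes at least ~3% of partitions are empty;
  negative post-subtraction values are kept, not clipped.
* `compensate_crosstalk()` left-multiplies each amplitude vector by the
  inverse of the crosstalk matrix (entry $(i,j)$ = fraction of channel $j$'s
  signal detected in channel $i$, diagonal 1, estimated from single-color
  controls). Singularity is a hard error.
* `calibrate()` divides each channel by its 1i cluster center so the
  reference intensity is 1; `level1_reference()` estimates the centers as
  medians of single-positive level-1 partitions from a provisional
  raw-scale classification, since no more detailed calibration procedure is
  standardized.
* `classify_partitions()` applies fixed per-channel thresholds — defaults
  0.5 / 1.5 / 2.5, the midpoints between the ideal level intensities on the
  calibrated scale. Thresholds are configuration, never auto-tuned:
  reproducibility is preferred over per-run cleverness, and no clustering or
  UMAP-style gating is attempted by design.

`call_tags()` calls a tag present when at least `min_partitions` partitions
carry its exact signature (1 by default for maximal sensitivity; 5 as the
stricter convention). `euclidean_qc()` scores each assigned partition's
distance to its ideal signature vector after zeroing channels where the
signature has digit 0, which suppresses baseline noise in undetected
channels.

## The simulator

`simulate_run()` generates ground-truth data in two stages. Loading places,
for each tag, a Poisson-distributed molecule count uniformly and
independently across partitions (`method = "bernoulli"` samples occupancy
directly with $p = 1-e^{-c/N}$, exact at the occupancy level by Poisson
thinning). Rendering maps each partition's signature-union level to an
ideal intensity and then applies, in order: incomplete-hydrolysis
attenuation (with probability `incomplete_hydrolysis_prob` the 2i
contribution shrinks by `incomplete_hydrolysis_factor`, default 0.75, so an
ideal [0,0,1,2] renders at [0,0,1,1.5]), rain substitution (with probability
`rain_fraction` a positive channel draws uniformly between its level mean
and the next lower one), Gaussian cluster noise, spectral mixing by the
crosstalk matrix, and the baseline offset.

Defaults and their rationale:

* `level_means = c(0, 1, 2, 3)`: the 2:1 probe ratio on the calibrated
  scale; the level-3 mean is taken as additive (1 + 2) since no measured
  value for it is published. Configurable.
* `cluster_sd = 0.05`, `baseline_offset = 0`, `rain_fraction = 0`,
  `incomplete_hydrolysis_prob = 0`: no quantitative noise magnitudes are
  published for any instrument, so the defaults are pragmatic — tight
  enough that default simulations classify essentially perfectly, which is
  the right regime for validating the estimator itself. Artifact studies
  should turn the knobs up explicitly.

What the simulator does *not* emulate: PCR kinetics, probe-sequence
thermodynamics and cross-binding, primer-dimer chemistry, sub-array
baseline structure, or instrument-specific partition volumes. Passing tests
on simulated data therefore validate the *statistical* pipeline — loading,
union semantics, classification, deconvolution — not assay chemistry;
published instrument-level figures (e.g. per-platform classification
accuracies) are out of reach of a simulator by construction and are not
asserted anywhere.

## Design studies

`copresence_fraction()` is the closed-form conditional Poisson probability
that an occupied partition holds two or more distinct targets — the source
of decoding ambiguity. With the conventional 5% threshold,
`copresence_threshold(728, 26000)` returns 4 copies per target, and a
32-plex tolerates on the order of 100.

`run_cv_study()` compares total-copy precision between a classic
1-channel-per-target 4-plex and the encoded 32-plex under identical loads.
Both arms assume full amplification and perfect classification, so the
encoded arm draws its label tally directly from the exact label distribution
(a multinomial over the $4^C$ lattice — precisely the distribution implied
by independent uniform placement of Poisson molecule loads, since
Poissonization makes per-partition occupancies independent) and feeds it to
`decode_dpcr()`; the classic arm draws per-channel positive counts
binomially and applies $-\ln(1-k/N)$. At low copies the encoded design's CV
is lower by about $\sqrt{32/4} = \sqrt 8$ (independent-target scaling); as
load grows, ambiguous multi-target labels are discarded and the encoded CV
crosses above the classic CV at roughly 1,100–1,200 copies per target on
this model (log-log interpolated between grid points). The default grid
spans 1–5,000 copies at 1,000 runs per point (a few seconds; 10,000 runs
match the full-fidelity study and are used by `scripts/acceptance.R`).

`run_crosstalk_study()` measures partition-call accuracy in a 728-plex when
crosstalk is applied but **not** compensated. The crosstalk level $\alpha$
is parameterized as the total bleed fraction of each channel's signal,
split evenly over the other channels on top of the unit self-signal
($M = I + \tfrac{\alpha}{C-1}(J - I)$; see `uniform_crosstalk()`). This
parameterization was chosen — over the alternative of putting $\alpha$ in
every off-diagonal entry — because it is the one under which modest bleed
is harmless: with $\alpha$ itself off-diagonal on six channels, a zero
channel receives $\alpha \times$ (total signal) and even 20% crosstalk
destroys classification, contradicting the known behavior of real
multi-channel optics where small per-pair bleed is the norm. Under the
implemented scale, 0% and 20% give near-identical accuracy (gaps of a few
percentage points at the top of the grid, a deterministic high-occupancy
effect, not Monte Carlo noise), while 80% and 100% collapse onto overlapping,
strongly degraded curves. Accuracy is defined as the fraction of occupied
partitions whose threshold classification equals their true union label;
both the metric and the parameterization are echoed in the result's
`metadata` because neither has a single standardized definition. The default
copies grid ends at 13 copies per target, the upper end of the regime a
728-plex is designed for (its 5% co-presence limit sits at 4).

## Problem sizes and determinism

Test-suite simulations use 26,000 partitions (the canonical plate size) and
replicate counts of a few hundred — sizes chosen so the full suite runs in
under a minute while keeping Monte Carlo error well below the asserted
tolerances. Every stochastic function takes a `seed` argument, restores the
caller's RNG state on exit, and is bit-reproducible given the seed; the CLI
records the seed and input digests in a manifest per run.

## Known limitations

* The hierarchical scheme discards non-signature labels; at high loads this
  inflates variance relative to a joint ML fit (visible as the CV crossover).
* Confidence intervals are not computed; a Poisson-CI hook is a natural
  extension.
* Replicate wells are decoded per well; pooling counts across wells before
  estimation is possible but deliberately not the default, since baseline
  correction is per-well.
* The signature algebra is restricted to two probe classes per channel
  (levels 0–3); `capacity()` alone handles general level counts.
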