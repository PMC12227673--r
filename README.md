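# dpcrcode

Combinatorial fluorescence encoding and hierarchical Poisson deconvolution
for multiplexed digital PCR (dPCR).

## The problem

Digital PCR quantifies nucleic-acid targets by end-point PCR across tens of
thousands of partitions: the fraction of negative partitions inverts to a
concentration through Poisson statistics. Classic multiplexing assigns one
fluorophore per target, so an instrument with C color channels measures C
targets. Universal-signal-encoding assays break that limit by giving every
target a synthetic tag on a primer tail containing one or two *universal*
hydrolysis-probe binding sites, each filled by either a low-concentration
("1i") or a high-concentration ("2i") probe of that channel, mixed at a 2:1
intensity ratio. A target's **signature** is then a digit string over the
channels — `0` no probe site, `1` a 1i site, `2` a 2i site — e.g. `1100`
(1i in channels 1 and 2). With one or two sites over C channels the code
space holds

> sum over k = 1..max_sites of C(C, k) * 2^k

signatures: 32 on 4 channels, 50 on 5, 72 on 6; allowing sites in every
channel gives 3^C − 1 (80 for C = 4, 728 for C = 6).

After calibration (1i cluster at intensity 1), each partition's per-channel
amplitude takes one of four levels — 0 none, 1 only 1i tags, 2 only 2i tags,
3 both — and the concatenated levels form the partition's **label**. Labels
are ambiguous under co-presence: label `1100` can come from tag `1100` alone
or from tags `1000` + `0100` sharing the partition. This package implements
the full computational stack for such assays: codebook algebra, a
ground-truth simulator, signal preprocessing and classification, the
deconvolution estimator, evaluation metrics, and Monte Carlo design studies.

## The estimator

`decode_dpcr()` resolves label ambiguity hierarchically, working upward from
unambiguous labels. With P_0 null partitions and exact-label counts P_L:

* single-site tags: λ̂ = ln(1 + P_L / P_0) (for a one-tag assay this is the
  textbook −ln(1 − P_pos/N));
* multi-site tags, in ascending order of site count: subtract the expected
  co-presence count E_L = P_0 · Σ over subsets S of contained tags with
  union(S) = L of Π (e^{λ̂_t} − 1), giving P′_L = max(P_L − E_L, 0);
  deflate for co-occupancy, P*_L = P′_L · Π e^{−λ̂_t}; then
  λ̂ = ln(1 + P*_L / P_0). Copies = N·λ̂.

Fed exact expected counts, the ladder returns the generating λ exactly (the
test suite verifies machine-precision recovery over random codebooks).
Labels matching no signature — including any level-3 label — are excluded
from estimation and reported with their counts.

## Worked example

A 32-plex rare-variant panel: 31 variants at 8 copies each spiked over a
reference amplicon at 2,000 copies, 26,000 partitions, with a baseline
offset and 8% uniform crosstalk applied and then removed by preprocessing.

```r
library(dpcrcode)

cb     <- enumerate_codebook(4, 2, 2)                  # all 32 signatures
spike  <- setNames(rep(8, 31), setdiff(cb$tags$name, "0010"))
copies <- c(spike, "0010" = 2000)
xt     <- uniform_crosstalk(4, 0.08)

run <- simulate_run(cb, copies, n_partitions = 26000,
                    noise = noise_model(baseline_offset = 1.3),
                    crosstalk = xt, seed = 42)

amp <- compensate_crosstalk(subtract_baseline(run$amplitudes), xt)
cl  <- classify_partitions(amp)
fit <- decode_dpcr(cl$counts, cb)
fit
#> dPCR deconvolution: 32 tags over 4 channels; N = 26,000 partitions, 23,893 null
#> Total estimated copies: 2198.1; 10 partitions in 10 non-signature labels excluded
#> Per-tag copies (head):
#>    0001    0002    0010    0011    0012    0020    0021    0022
#>   13.05   11.97 1965.25    5.10    4.17    2.18    7.61    7.61

vaf(fit, reference_tag = "0010")
#> VAF vs reference '0010' (1965.3 copies): mean VAF 0.003823 over 31 variants
```

The reference recovers 1,965 of 2,000 loaded copies and the mean variant
allele fraction 0.0038 matches the loaded spike ratio 8/2000 = 0.004 within
Poisson sampling error. `summary(fit)` exposes the full per-tag ladder
(P_L, E_L, P′, P*, λ, copies); `euclidean_qc()` scores each assigned
partition's distance to its ideal signature vector (median 0.089 here).

Design studies:

```r
copresence_threshold(728, 26000)   # 4 copies/target reach 5% co-presence
run_cv_study(seed = 1)             # classic 4-plex vs encoded 32-plex CV
run_crosstalk_study(seed = 1)      # accuracy vs uncorrected bleed
```

A thin command-line front end over the same functions lives at
`inst/cli/dpcrcode.R` (subcommands `codebook`, `simulate`, `decode`,
`study`); every run writes a manifest with version, arguments, seed and
input digests.

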