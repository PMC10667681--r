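---
title: "meltplex: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meltplex: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltplex)
```

This vignette is the package's own account of the science it implements:
the calling and quantification model, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator emulates (and
what it deliberately does not), and the design choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A melt-based hairpin probe fluoresces at its full amplitude as long as it is
intact. When its target is present in a partition, the probe is cleaved and
extended into a quencher-bearing hairpin: below the hairpin's melt
temperature the fluorophore is quenched, above it the hairpin opens and
fluorescence returns. Imaging each of 4 optical channels (blue, green,
yellow, red) at 4 temperatures $T_1 < T_2 < T_3 < T_4$ defines three *melt
windows* per channel, and each probe is assigned a unique (channel, window)
pair — 12 slots on the prototype platform.

For partition $p$, channel $c$, window $w$ the **raw melt ratio** is

$$ r_{p,c,w} = \frac{F_{p,c}(T_{w+1})}{F_{p,c}(T_w)} $$

A target-negative partition has stable fluorescence across the window, so
$r \approx 1$; a positive partition has its probe quenched at $T_w$ but not
at $T_{w+1}$, so $r$ is well above 1 (with three equal-amplitude probes per
channel and residual quench $q$, roughly $3/(2+q) \approx 1.46$). The
published per-probe thresholds (1.06–1.12) sit far below this but far above
the noise of negative partitions.

### Rolling normalization

Instrument baselines drift across a well, so raw ratios are normalized per
track: $\tilde r_p = r_p / b_p$, where $b_p$ is a rolling statistic over a
centered window of `window_size` partitions around $p$ *in file order*,
shrinking symmetrically at the edges (half-width $\min(h, p-1, n-p)$). Two
estimators are provided:

* **`rolling_median`** (default): robust to up to ~50% positive partitions
  with no selection step.
* **`rolling_mean_of_preliminary_negatives`**: the mean over partitions
  preliminarily assessed as negative (ratio at or below
  `preliminary_negative_cutoff`, default 1.0). Implemented as a two-pass
  estimator: ratios are first detrended by the rolling median and the
  cutoff is applied to the *detrended* ratio, with
  $b_p = \mathrm{median}_p \times \mathrm{mean}(\text{detrended negatives})$.
  The literal raw-ratio cutoff is undefined whenever a window's ratios all
  sit above 1 — which happens under upward baseline drift, and
  systematically in window $w{+}1$ of a channel whose partitions melt in
  window $w$ (the melt raises the *denominator* temperature's signal).
  Detrending keeps the estimator defined in both situations while
  preserving its negative-selection semantics.

`window_size` defaults to 1,001 partitions (~5% of a 20,480-partition
well): wide enough that ≥600 negatives remain per window at 40% positivity,
narrow enough to track smooth drift. The ordering basis of the instrument
export (spatial vs acquisition) is not public; normalization simply follows
file order, which is what a rolling baseline can defend either way.

### Calling and the saturation guard

Partition $p$ is positive for a probe iff $\tilde r$ in the probe's track is
**strictly** greater than the probe's threshold; ties are negative.
Partitions whose window denominator falls below `denominator_floor`
(10⁻⁹ RFU) are excluded from that track — never imputed — and removed from
the analyzed count.

Rolling normalization has a blind spot: if essentially *every* partition of
a track is positive, the baseline is estimated from positives and the
normalized ratios collapse to ~1, which would silently report zero copies
for a grossly overloaded target. `call_partitions()` therefore checks each
track's preliminary-negative fraction; below `min_negative_fraction`
(default 5%, safely under the ~50% negative fraction of even an 80%-positive
well) the track is called all-positive, which propagates a `saturated` flag
through quantification and signals re-dilution rather than a false zero.

## 2. Poisson quantification

With $N$ analyzed partitions and $m$ negatives, $\hat\lambda = -\ln(m/N)$
copies/partition. The 95% CI uses the delta-method standard error on the
negative fraction, $\mathrm{SE} = \sqrt{(N-m)/(Nm)}$, with a 1.96
multiplier, truncated at 0 — the standard digital-PCR approach. With zero
positives the point estimate is 0 and the upper bound is the one-sided
"rule of three" bound $3/N$. A saturated probe ($m = 0$) is an error at the
estimator level and a flagged row at the pipeline level.

Copies per assay input scale as
$\hat\lambda N / f_{\text{loaded}}$ with $f_{\text{loaded}} = 0.9$ (9 µL of
the 10 µL reaction digitized); concentration divides by the 10 µL reaction
volume. The **hge convention** used throughout: 1 hge = 1 haploid genome =
1 allele copy per locus, so 10,000 hge with opposing homozygotes at a 50%
minor fraction gives 5,000 copies of each allele.

Detection limits follow the blank-replicate construction:
$\mathrm{LoB} = \bar{x}_{fp} + 1.645\, s_{fp}$ and
$\mathrm{LoD} = \mathrm{LoB} + 1.645\, s_{fp}$ partitions, with the $n-1$
sample SD over ≥2 (typically 16) blank replicates; 1.645 is the one-sided
95th percentile of the normal. Frequencies divide by a **caller-supplied**
measured total-copy denominator (×100). Published-style presentation rounds
half-away-from-zero to 2 decimals; full precision is retained. The
denominator is caller-supplied because nominal inputs demonstrably do not
reproduce published frequencies at lower DNA amounts — per-sample measured
totals were evidently used there and are not recoverable.

Replicate precision is mean / $n-1$ SD / CV% with a normal-theory CI;
concordance between runs or sites is Pearson $r$ (both $r$ and $r^2$ are
reported) and an OLS fit on $\log_{10}$ copies.

## 3. The simulator: a stated world

`simulate_well()` layers a phenomenological fluorescence model on exact
Poisson loading:

1. **Loading.** Per probe $k$, partition occupancies are i.i.d.
   $\mathrm{Poisson}(\lambda_k)$ with
   $\lambda_k = \text{copies}_k \cdot f_{\text{loaded}} / N$. The realized
   per-probe digitized copies (and the full occupancy matrix) are returned
   as ground truth, so recovery tests can separate pipeline error from
   loading noise.
2. **Cleavage.** Occupancy ≥ 1 fully cleaves the probe (the endpoint
   plateau of the chemistry); unoccupied partitions cleave spontaneously
   with `false_positive_rate` (default 0). A `cleavage_fraction < 1`
   interpolates toward the uncleaved state for robustness experiments.
3. **Fluorescence.** At temperature $T$, channel $c$ reads
   $F = \sum_{k \in c} A_{p,k}\, m_{p,k}(T) \cdot (1+\varepsilon)$, where a
   cleaved probe's melt state is
   $m(T) = q + (1-q)\,\sigma\!\big((T - T_m)/s\big)$ with logistic
   $\sigma$, residual quench $q$ = `residual_quench`, steepness $s$ =
   `melt_steepness`; an uncleaved probe has $m \equiv 1$. $A_{p,k}$ is the
   probe amplitude perturbed per partition by `amplitude_cv` (negative
   draws resampled), $\varepsilon$ is Gaussian read noise of SD
   `noise_sd_frac` per reading, and everything is scaled to
   `base_fluorescence` RFU. An optional channel crosstalk matrix (identity
   by default) exists for robustness testing only.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `partitions_per_well` | 20,480 | the prototype platform's well size |
| temperatures | 60/72/81/92 °C | the published imaging points |
| `tm_final_hairpin` | window midpoints (66/76.5/86.5 °C) | maximal ratio contrast at both bracketing temperatures; true Tms are not public |
| `loaded_fraction` | 0.9 | 9 µL loaded of a 10 µL reaction |
| `noise_sd_frac` | 0.01 | 1% multiplicative read noise puts negative-ratio scatter (SD ≈ 1.4%) comfortably below the 6–12% thresholds, matching published scatter-around-1 plots qualitatively |
| `amplitude_cv` | 0.05 | partition-to-partition brightness variation; cancels in ratios to first order, so it stresses rather than drives calling |
| `residual_quench` | 0.05 | near-complete quenching below Tm, as the chemistry intends |
| `melt_steepness` | 0.8 °C | sharp transition well inside a ≥9 °C window; exact thermodynamics are out of scope |
| `false_positive_rate` | 0 | blanks are clean unless the experiment under study says otherwise |

True instrument noise magnitudes and the partition volume are not
published; these values are plausibility choices made once and documented,
not dials. Mixture wells derive per-well seeds deterministically from one
master seed, so an entire dilution series is reproducible from a single
integer.

**What a green test establishes — and what it does not.** The simulator
emulates Poisson occupancy exactly and the melt-ratio signature
phenomenologically. It does not model amplification kinetics, partition
volume variation, spatial noise correlation, probe cross-hybridization or
channel bleed (unless enabled). Green recovery tests therefore validate the
*analysis pipeline* — ratio arithmetic, normalization, thresholding and
Poisson inversion — under a faithful partition-statistics model; they do
not certify performance on instrument data, and published results obtained
on real genomic DNA (blank-replicate LoB/LoD tables, inter-site
$r = 0.997$) are not reproducible at desk scale and are not asserted.

## 4. Numerical and design notes

* **Strict thresholds.** Comparisons are `>`, ties negative, as the
  thresholds are published.
* **Rounding.** Reported frequencies round half away from zero (base R's
  `round()` rounds half to even, which would disagree with published
  tables at exact .xx5 boundaries).
* **Zero-positive wells.** The rule-of-three upper bound $3/N$ avoids a
  degenerate zero-width CI at 0 positives.
* **Degenerate inputs.** Zero-denominator partitions are excluded per
  track and surfaced in QC (< 1% tolerated); an all-bad table is an error.
  Saturated probes error at the estimator and flag at the pipeline.
* **Probe→slot mapping.** The true (channel, window) identity of each named
  prototype probe is not public. The default panel uses a deterministic
  round-robin (P1-A→blue/1 … P6-B→red/3), documented as arbitrary and
  fully overridable by config; results depend only on thresholds and
  window membership.
* **LoD formula.** The blank-construction literature sometimes states
  "3× SD" prose; the implemented formula is LoB + 1.645·SD, the displayed
  definition, which the published 10,000-copy tables reproduce exactly.
* **Allele fractions at empty loci** warn and return NA rather than
  aborting, so one dead locus cannot suppress the other five.
* **Determinism.** Simulation restores the caller's RNG state; identical
  config + seed yields byte-identical CSV output, and the CLI's results
  files are byte-stable given a seed.

## 5. Known limitations

* The normalization window, statistic and partition ordering of the
  original instrument software are not public; both implemented modes meet
  the stated goal (negative mean ≈ 1 under drift) but neither is known to
  be the vendor's exact construction.
* LoB/LoD frequencies at inputs other than 10,000 copies require the
  per-sample measured denominators, which are not recoverable from the
  published tables.
* The saturation guard trades a small amount of dynamic range (tracks with
  > 95% positive partitions are declared saturated rather than quantified)
  for never silently reporting zero copies on an overloaded well;
  quantification at $\lambda \gtrsim 3$ is outside the reliable range of
  partition statistics anyway.
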