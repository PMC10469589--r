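---
title: "Read-count pool normalization: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-count pool normalization: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolnorm)
```

## The pooling model

A multiplexed sequencing run distributes its reads among libraries roughly
in proportion to the moles of adaptor-ligated, sequencing-competent DNA each
library contributed to the pool. Fluorometric quantification measures total
dsDNA mass, which overestimates the sequencing-competent fraction by a
library-dependent amount, so a fluorometrically "equimolar" pool sequences
unevenly. A shallow index run measures the thing that actually matters: the
read share each library captures.

`poolnorm` treats the first run as a per-library rate measurement. If
library $i$ contributed $V_i$ nL to the first pool and captured a share
$p_i$ of the run's reads, its effective read yield is $p_i / V_i$ per nL.
Re-pooling at volume $v_i$ moves the expected share to

$$p'_i = \frac{v_i\, p_i / V_i}{\sum_j v_j\, p_j / V_j},$$

so equal representation ($p'_i = 1/N$) requires $v_i \propto V_i / p_i$.
The model's key assumption is that per-volume read yield is stable between
the two runs — same libraries, same chemistry, no re-amplification. It holds
exactly in the package's simulator and approximately in reality, where
flow-cell loading effects and lane-to-lane variation add noise the model
does not capture.

`compute_reads_index()` computes $p_i$ from reads passing filter, or from
*feature counts* (reads on target, e.g. non-ribosomal reads in
metatranscriptomics) to equalize usable data rather than raw depth: the two
modes differ only in which counts enter the numerator and denominator.

## Volume computation and its parameters

`compute_volumes()` applies, in order: scaling, clamping, quantization,
and role policies. The tunable parameters of `normalization_config()`:

* **`v_min_nl` = 10, `v_max_nl` = 1000 (nL)** — the transfer range of the
  workflow. One Echo droplet burst is practical down to a few nL; 1000 nL
  keeps total pool volume and transfer time manageable at 384 libraries.
* **Scaling ("max fill")** — raw volumes $V_i/p_i$ are scaled so the
  *neediest non-blank library* gets exactly `v_max_nl`. This uses the full
  dynamic range of the dispenser: any smaller scale wastes correction
  headroom, any larger one clamps more libraries at the ceiling. Libraries
  whose ideal volume then falls below `v_min_nl` (overrepresented more than
  `v_max/v_min` = 100-fold relative to the neediest) are clamped up and
  flagged `clamped_low`; they remain overrepresented in the re-pool, which
  is the method's known residual ("over-penalized" high-yield libraries end
  up relatively *under*-corrected in depth).
* **`quantum_nl` = 2.5 (nL)** — the droplet increment of the Echo 550.
  Volumes are rounded to the nearest multiple, half up, then pulled back
  inside the bounds if rounding stepped past them. The worst-case share
  distortion is half a droplet relative to the smallest transfer
  ($1.25/10 = 12.5\%$ of one library's volume at the floor), negligible
  against biological dispersion.
* **`blank_policy` = `"fixed_min"`** — extraction blanks have few reads by
  design; a naive $1/p$ rule would hand each of them the maximum volume and
  waste depth on negative controls. They are pinned to `v_min_nl` and
  flagged `blank_fixed`. `"as_sample"` is available when blanks should be
  deeply sequenced (e.g. contamination audits); because scaling anchors on
  non-blank libraries, boosted blanks then typically clamp at the ceiling.
* **`zero_count_policy` = `"max_volume_flagged"`** — a library with zero
  reads has an undefined correction factor. The default gives it the
  maximum volume and a `zero_count` flag: conservative (it may simply have
  been unlucky at shallow depth) and visible in every report.
  `"exclude_flagged"` drops it from the picklist instead.
* **Prior volumes default to equal** when the count table carries none: the
  first pool aimed at equal molarity, and with no per-library record of it,
  a common constant is the only defensible prior (it cancels in the
  scaling).

## Quality metrics

`evenness_stats()` reports the coefficient of variation (sd/mean) of
per-library read proportions. Proportions are shares of the *whole* pool,
blanks included in the denominator, but statistics cover non-blank libraries
by default — the convention used when a study reports its sample read
distribution. The CV uses the sample ($n-1$) standard deviation; at
$n = 352$ the distinction from the population form is below 0.2% and the
sample form behaves correctly in small test fixtures. A reported
"median ± spread" of proportions is interpreted as median and standard
deviation and kept as separate fields.

`retention_curve()` counts the libraries that survive rarefying to each
depth; evenness determines how many libraries a common rarefaction depth
retains, which is the practical payoff of normalization.

## The simulator

`sim_config()` defaults encode the reference study design: 352 samples plus
32 extraction blanks on one 384-well plate, a first run of 5,000,000 read
pairs, and a normalized rerun of 5,700,000 pairs.

* **Fluorometric error model.** Effective molar weights are
  $\mathrm{LogNormal}(0, \sigma)$ with $\sigma = \sqrt{\ln(1 + \mathrm{CV}^2)}$
  (`calibrate_sigma()`), calibrated so the weight CV equals the observed
  first-run proportion CV of 0.72. Log-normal is the standard model for
  multiplicative concentration error; the observed CV is the only published
  constraint, so the distribution's shape beyond its CV is a modeling
  choice.
* **Blanks** draw the same weights scaled by `blank_depletion` = 0.01. The
  real depletion of blanks is not published; 1% puts them far enough below
  samples that blank policies have visible consequences in tests, while
  keeping their counts nonzero at 5 M pairs.
* **Sequencing** draws multinomial counts at the configured depth
  (`overdispersion` = 0). Setting `overdispersion` $> 0$ switches to
  Dirichlet-multinomial with concentration `1/overdispersion`, since real
  flow cells are overdispersed; the default is the pure sampling limit.
* **What passing tests show.** The simulator reproduces the *mechanism* —
  multiplicative mis-quantification corrected by one read-count round — not
  the full error budget of a real laboratory. Its post-normalization CV
  falls to the multinomial floor (about
  $\sqrt{N/\mathrm{depth}} \approx 0.008$, plus first-run estimation noise,
  observed ≈ 0.015), whereas the real study retained CV 0.37 from pipetting
  error, loading effects, and library-specific amplification the simulator
  deliberately omits. Simulation results therefore support the *direction*
  and a *bound* on the improvement, not its exact real-world size.

## Numerical choices and degenerate inputs

* Proportions are validated to sum to 1 within $10^{-9}$; projections
  renormalize explicitly, so conservation holds to floating-point accuracy.
* Quantization rounds half up (`floor(v/q + 0.5) * q`), matching how a
  dispenser work-list is built, and re-clamps afterwards.
* An all-zero count table is a hard error (`degenerate-input`), not a
  silent uniform fallback.
* FASTQ counting streams 4-line records and validates structure, reporting
  the index of the first malformed or truncated record; paired files must
  match in record count. Counts are read *pairs* throughout; single-end
  input counts each record once.
* The loading calculator uses 660 g/mol per base pair for dsDNA and warns
  below a 0.5 µL pipettable pool volume, suggesting an intermediate
  dilution.

## Layout and fixture conventions

`study_plate_map()` places samples in columns 1–22 and blanks in the last
two columns — a common negative-control convention; the true layout of the
reference design is not published. Iteration and output order is row-major
(A1…A24, B1…), and picklists are ordered by source well.

## Problem sizes in the test suite

Unit and property tests run at $n \le 50$ libraries with seeds fixed per
block. End-to-end checks run the full 384-library design: 20 replicates for
the normalization bound and 10 for the first-run calibration, a few seconds
in total since each replicate is two multinomial draws over 384 cells.
Parameter recovery of the log-normal calibration is checked at $n = 10{,}000$
draws within 5%.

## Known limitations

* Single correction round; no iterative re-normalization.
* No fluorometric pooling math — the mass-based baseline exists only as the
  simulator's noise model.
* Feature-count mode takes precomputed on-target counts; the package never
  aligns or classifies reads.
* No dead-volume or source-exhaustion tracking in picklists beyond an
  optional per-transfer cap.
* Projections assume stable per-volume yield between runs; index hopping,
  re-amplification and loading-concentration effects are out of scope.
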