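---
title: "Indel decomposition of Sanger traces and clone triage: methods"
author: "sangerscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indel decomposition of Sanger traces and clone triage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangerscreen)
```

## The problem

When a CRISPR ribonucleoprotein or a zinc-finger nuclease cuts a locus, the
repaired pool carries a mixture of indel alleles. A single bulk Sanger
chromatogram of the PCR amplicon superposes all of them: upstream of the cut
every allele agrees with the wild type, and downstream each allele's trace is
the wild-type trace shifted by its indel size. Decomposing that superposition
recovers the allele-frequency spectrum cheaply enough to drive two workflows
this package implements end to end:

1. **Pool surveillance** — estimating editing efficiency and the indel
   footprint of a nuclease at the bulk level;
2. **Clone triage** — screening limiting-dilution wells so that only
   homozygous or compound-heterozygous knockouts move on to expensive
   single-cell imaging and amplicon sequencing.

Because no public chromatograms accompany this workflow, the package ships a
synthetic-data module that generates traces and read sets with known truth;
every stage is validated against that truth and against an independent
read-count oracle.

## The decomposition model

Let $c(p, b)$ be the control (wild-type) trace intensity at position $p$ and
channel $b \in \{A,C,G,T\}$, after registration and intensity normalization.
For each candidate indel size $d \in \{-D, \dots, D\}$ (default $D = 30$) the
expected contribution of a $d$-allele over the decomposition window is the
shifted control

$$x_d(p, b) = c(p + |d|, b) \;\; (d < 0), \qquad
  x_d(p, b) = c(p - d, b) \;\; (d > 0), \qquad x_0 = c,$$

with the $d$ inserted positions $[\mathrm{cut}, \mathrm{cut}+d)$ of an
insertion masked, since the control carries no information about novel
bases. The sample trace $y$ is modelled as $y \approx \sum_d w_d x_d$ and the
weights are estimated by non-negative least squares,

$$\hat w = \arg\min_{w \ge 0} \Big\| y - \sum_d w_d x_d \Big\|^2,$$

over all decomposition-window cells at or after the cut that no insertion
component masks (masking per component would make the problem nonlinear; the
union $[\mathrm{cut}, \mathrm{cut}+D)$ is excluded for all components
instead, which costs $D$ of the roughly 250 window positions). The convex
problem is solved by the Lawson–Hanson active-set method
(`pracma::lsqnonneg`); any solver reaching the global optimum is equivalent,
and the test suite checks the solution against an exhaustive grid search over
the simplex of candidate proportions on small instances. Reported
frequencies are $100\, \hat w_d / \sum \hat w$.

Defaults follow standard practice for single-cut editing at this amplicon
scale: indel sizes 1–30 bp in both directions, decomposition window
positions [115, 500), a 100 bp upstream alignment window, a per-component
significance cutoff $p < 10^{-4}$, and elimination of fits with
$R^2 < 0.95$.

### Registration and normalization

The sample is registered to the control by the integer shift in
$[-10, 10]$ maximizing the summed channel-wise correlation over the first
100 positions — upstream of the cut, where all alleles agree. A mean
correlation below 0.5 signals a sample/control mismatch:
`align_control()` raises an error there, while `decompose()` proceeds at
offset 0 and lets the $R^2$ filter eliminate the well, so that a plate
screen is never aborted by one bad trace. Both traces are rescaled to unit
mean intensity over the alignment window; frequencies are scale-free
(ratios of weights), so this only conditions the regression.

### Control idealization

A control trace is by definition clonal, so its expected signal has exactly
one peak per position plus crosstalk bleed, riding on a smooth amplitude
envelope. `idealize_control()` (on by default) reconstructs that ideal from
the control's basecalls, a running-mean envelope of the per-position total
intensity (window 21 positions — wide against per-base fluctuation, narrow
against signal decay), and a global median crosstalk estimate. Without it,
control-side noise propagates into every regression component and biases
$R^2$ downward (about 0.94 versus 0.96 on the synthetic defaults). The
idealization flattens genuine sequence-context peak-height variation that
real chromatograms show; with real data and a high-quality control one can
set `idealize_control = FALSE` and accept the noisier design.

### Significance and the $R^2$ gate

Published decomposition workflows name only a cutoff ($p < 10^{-4}$), not
the test behind it.
Per-component two-sided p-values are taken from the coefficient standard
errors of the unconstrained least-squares refit restricted to the active
(non-zero) set — approximate, because the active set is data-chosen, but
consistent with published decomposition practice. Components failing the
cutoff or falling below `min_report_freq` (0.5%, numerical dust) are removed
and the rest renormalized to 100%.

$R^2$ acts as a *trace-quality* gate: results below 0.95 are eliminated. It
is computed over the **full** decomposition window, including the pre-cut
region where the model prediction is $\sum_d w_d \cdot c$ — a region every
genuine sample must reproduce regardless of its allele content. Restricting
$R^2$ to the post-cut cells would make it measure mixture complexity rather
than trace quality: a 5-allele well splits its downstream peaks five ways,
shrinking the signal variance relative to the (fixed) noise floor until even
a perfect fit scores below 0.95. Weights, in contrast, are estimated from
post-cut cells only, because only those carry indel information.

## The synthetic data generator

`simulate_trace()` renders an allele mixture with three noise knobs chosen
to reproduce the qualitative failure modes decomposition must tolerate:

* `base_amplitude` 1000 and exponential `decay_rate` 0.002 /base — 3'-end
  signal degradation (intensity falls to ~37% over a 500 bp read);
* additive truncated-Gaussian `noise_sd` 30 per channel cell — baseline
  noise of roughly 3% of the initial peak height;
* linear `crosstalk` 0.02 — each peak bleeds 2% into each other channel.

These defaults define the study conditions for every simulation-based check
in the package. Reads are single-end, constant-quality, and span the cut
site with at least a 20 bp anchor on either side (`simulate_reads()`,
`span_margin`) — the flank an aligner needs to place an indel; reads
grazing the cut cannot support a call and real amplicon pipelines filter
them. A `low_quality_fraction` knob emits phred-20
reads to exercise the oracle's mean-phred-30 discard rule, which
approximates the per-read filtering of amplicon-sequencing pipelines (the
cited pipelines are ambiguous between per-read discard and end-trimming;
discard is implemented and noted as approximate). What the generator does
*not* emulate: sequence-context peak-height variation, chimeric PCR
artifacts, position-dependent miscall bursts, or paired-end structure — so
passing tests demonstrate correctness of the estimator under a controlled
signal model, not performance on degraded real chromatograms.

`simulate_well()` draws labelled genotype classes: homozygous (one allele
at 100%), compound heterozygous (50:50 with Gaussian jitter, sd 0.05 —
allele-amplification bias), heterozygous-with-wild-type, and nonclonal
(3–5 mutant alleles, symmetric Dirichlet with concentration 5, which keeps
every progenitor's allele visible above the 5% reporting floor — the
operational meaning of "well founded by several edited cells").
`mixing_series()` reproduces the stepwise sensitivity design, Mix-$k$
combining the first $k$ homozygous clones at $1/k$ each; the original
series' exact ratios are figure-internal, so the scheme is a parameter.

## The read-count oracle

`quantify_reads()` is the ground truth the decomposition is validated
against: semi-global affine-gap alignment (read global, reference overhangs
free; match +2, mismatch −3, gap open −8, gap extend −1 — chosen so one
contiguous indel beats scattered gaps, matching single-cut biology), net
indel summed over gap runs overlapping cut ± 10 bp to insulate calls from
read-end errors, frequencies over quality-passing reads. The aligner is
compiled (Rcpp) with a seed-and-band fast path; tests verify it against
exhaustive alignment enumeration on short strings and against
`Biostrings::pairwiseAlignment` under identical scoring.

## Triage rules

`classify_well()` applies, in order: eliminated fit → indeterminate; drop
variants < 5%; wild type ≥ 10% → discard; more than 2 variants → discard
non-clonal; one variant in [85, 100] → retain homozygous; two variants each
in 50 ± 15 → retain compound heterozygous; otherwise discard non-clonal.
The ±15 pp bands are a design choice: comfortably wider than the
decomposition-vs-reads deviation scale (mean |Δ| ≲ 6.7 pp) yet narrow
enough that a 33:33:33 three-way well cannot pass. The variant-count
cutoff defaults to 2 (source texts disagree between 2 and 3; both are a
setting). Retained wells carry a `confirm_by_imaging` flag: frequency
triage cannot exclude a well founded by two cells with identical indels,
and imaging-based clonality confirmation is outside this package's scope.

`aggregate_spectrum()` pools mutant mass across samples into the 1–15 bp
deletion/insertion bins (larger sizes in `other`), renormalized to the
percentage of each allele among all mutant alleles, with a frameshift
fraction (size not divisible by 3). `compare_spectra()` contrasts replicate
spectra bin by bin with Welch t-tests and Benjamini–Hochberg adjustment —
the replicate structure needed for a factorial ANOVA is not part of the
data contract, and the per-bin testing with BH control is verified by
simulation to hold the family-wise null error at or below 7% at level 0.05.
`t7_indel_fraction()` implements the densitometry closed form
$100\,(1 - \sqrt{1 - f_\mathrm{cut}})$.

## Numerical choices and degenerate inputs

* Coordinates are 0-based and half-open everywhere; the cut site is an
  inter-base index. Basecall ties break alphabetically (A<C<G<T).
* The decomposition errors explicitly on all-zero windows and
  under-determined designs rather than fitting silently.
* Perfect fits (zero residual) report p = 0 rather than NaN.
* Insertion alleles' base identities are unmodelled by decomposition; the
  simulator draws them at a recorded seed.
* All generators are bit-reproducible under a fixed seed; pipeline
  experiments derive named sub-seeds so stages can be re-run independently.

## Validation experiments and problem sizes

`run_clone_validation()` is the package's headline check: 13 simulated
compound-heterozygous clones under default noise, each also sequenced as
10,000 error-free spanning reads, decomposition vs read-count frequencies
compared at the true allele sizes (mean absolute deviation, percentage
points). `run_mixing_experiment()` is the sensitivity check: all
constituents of Mix-1..Mix-5 must be detected at $p < 10^{-4}$. The test
suite adds a 200-well triage-recovery experiment (50 wells per genotype
class), a 50-simulation two-allele recovery experiment at 90:10 / 75:25 /
50:50, and a 500-repetition null calibration of `compare_spectra()`. These
sizes give stable pass/fail behaviour at interactive runtimes; all of them
are recomputed from scratch on every run (nothing is cached).

The package exposes no shell entry point: it is an analysis library whose
users compose the exported functions in R, and `scripts/acceptance.R`
demonstrates the full pipeline as a script.

## Known limitations

* The per-component p-values condition on the NNLS-selected active set and
  are therefore approximate.
* Insertion identity (which bases were inserted) is not called.
* Multi-guide / dual-cut decomposition and substitution (base-editing)
  outcomes are out of scope.
* The R² gate, bands and cutoffs are calibrated on the synthetic noise
  model; real chromatograms with strong context effects may need
  `idealize_control = FALSE` and locally recalibrated bands.
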