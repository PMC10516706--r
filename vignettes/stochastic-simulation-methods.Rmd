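---
title: "Methods: stochastic tumour-normal simulation and caller benchmarking"
author: "somaticsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic tumour-normal simulation and caller benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsim)
```

## The problem

Benchmarking a somatic variant caller requires knowing, for every
non-reference base in the sequencing data, where it came from.  Truth sets
built from cell-line mixtures or from read-editing tools are incomplete:
they contain residual true somatic variants, unlabelled sequencing and
alignment errors, and — for read-fraction editing tools — a spike-in model
that removes exactly the sampling noise a caller has to cope with.  If a
locus is assigned frequency $f$ and depth $D$, a read-fraction tool plants
exactly $\mathrm{round}(fD)$ alternate reads on every run, whereas in real
sequencing the alternate-read count is a random variable
$X \sim \mathrm{Binomial}(D, f)$: sometimes more, sometimes fewer, sometimes
zero.

`somaticsim` simulates matched tumour/normal paired-end data in which every
non-reference base is attributable to exactly one of four sources —
germline SNV/indel, somatic spike-in, DNA-damage artefact, sequencing
error — and provides the evaluation machinery to score any caller's VCF
against that comprehensive truth set.

## Simulation model

### Phased genome

A personalized diploid genome is built by applying phased germline SNVs and
indels to a reference, one sequence per haplotype (the left allele of a
`GT` like `1|0` is taken as maternal).  A block-based liftover maps
coordinates in both directions; positions deleted on a haplotype have no
image and are reported as `NA` rather than interpolated, because truth
attribution must never guess.  Overlapping same-haplotype records and
reference-mismatching alleles are hard errors; unphased genotypes are
dropped with a warning — silently "fixing" donor data would corrupt the
truth set.

### Read simulation

Fragments are placed uniformly over the (haplotype-lifted) capture target,
split evenly between haplotypes, with normal insert lengths (default
300 ± 30) and fixed-length reads (default 100 bp).  The expected read-base
depth over interior positions calibrates to `mean_depth`; realized per-site
depth is emergent from random placement, deliberately not exact.  Fragment
orientation (F1R2 vs F2R1) is Bernoulli(1/2).

Sequencing errors are injected per cycle from a configurable rate vector
(default constant $10^{-3}$, Phred-consistent qualities) and **every**
miscalled base is logged with its read id and coordinates.  This error
model is intentionally simple — it is a declared substitute for an
empirical profile of a production read simulator, whose parameters are
external to this package.  GC bias, capture bias, duplicates and adapter
read-through are not modelled; conclusions about those failure modes
cannot be drawn from these simulations.

### Ground-truth frequency spectra

Three spectra are supported by `make_burden()`:

* **neutral**: subclonal frequencies with cumulative count proportional to
  $1/f$ on $[f_\min, f_\max]$ (defaults 0.01–0.25), sampled by inverting
  $F(f) = (1/f_\min - 1/f)/(1/f_\min - 1/f_\max)$, plus an optional clonal
  point mass at 0.5 (a diploid tumour at 100% purity).  The split between
  clonal and subclonal counts is a free parameter (`n_clonal`): it is a
  property of the simulated tumour, not of the method, and no published
  value pins it down.
* **point_mass**: all variants at one frequency (default 0.035), the
  regime where stochastic sampling dominates detection.
* **uniform_bins**: per-bin uniform draws; `semi_centile_bins()` provides
  the canonical partition of $(0, 0.5]$ into 100 half-open bins
  $[(i-1)/200, i/200)$.  Half-open edges are a convention choice;
  any variant exactly at 0.5 belongs to the clonal mass, not a bin.

Purity multiplies all frequencies; 1 throughout the package defaults.

### Somatic spike-in

A variant lives on one haplotype.  In **stochastic** mode every fragment of
that haplotype overlapping the locus carries the alternate allele
independently with probability $\min(2f, 1)$; because each fragment is on
the chosen haplotype with probability 1/2, the marginal alternate fraction
over all fragments is $f$ and alternate *read* counts at fixed depth $D$
are $\mathrm{Binomial}(D, f)$ by thinning.  The editing unit is the
fragment — both mates are edited wherever they cover the locus — since a
fragment is a single DNA molecule.  In **read_fraction** mode (the
BAMSurgeon-style contrast) exactly $\mathrm{round}(fD)$ *reads* are edited
in a fixed reproducible order: reads, not fragments, because that is the
unit read-editing tools operate on, and it reproduces their signature
"exactly 3 alternate reads at $f = 0.1$, $D = 30$, every run" behaviour.
Rounding is half-up; spike loci never collide with germline records, and a
locus falling in a haplotype deletion is skipped and logged.

### Damage artefacts

FFPE fixation deaminates cytosine (C>T); oxidative damage yields
8-oxoguanine (G>T, i.e. C>A in pyrimidine-centred notation).  Both are
strand-asymmetric and appear as a high burden of low-frequency artefacts.
`spike_damage()` draws each artefact site so that its trinucleotide
context matches a channel drawn from a 96-channel SBS signature (estimated
from calls by `estimate_sbs_signature()` or loaded from a COSMIC-format
table), splits the burden exactly in half between the two
fragment-orientation classes, and edits fragments of **one** class per
site with the same Bernoulli-$\min(2v,1)$ rule, $v$ drawn from the
artefact VAF distribution.  The orientation class of a site follows the
damaged-strand chemistry: sites whose pyrimidine lies on the forward
genomic strand feed the F1R2 class.  Because site strata are sampled
half-and-half, this coincides with an even split of the burden.

All pre-error alternate evidence at an artefact site therefore shares one
orientation; opposite-orientation evidence can only arise from a
sequencing error.  That is precisely the escape mechanism by which damage
artefacts defeat orientation-bias filters, and the evaluation layer's
strand-evidence contingency analysis quantifies it.

The default artefact VAF sampler is Beta(1.5, 60) (mean ≈ 0.024, mass
below 0.1): published empirical artefact-fraction sets are not
redistributable, so the sampler is pluggable — pass any `function(n)` to
`damage_plan()` to use measured fractions.

### Truth bookkeeping

`classify_mismatches()` expands every read base, lifts it to reference
space, and attributes each base differing from the reference with
read-level records first (spike edits, then live error-log entries), then
site-level germline state.  When a spike edit overwrites a previously
miscalled base the error-log entry is marked superseded, so sources
partition.  On internally generated data the unattributed count must be 0;
the test suite enforces this on full pipeline runs.  Alignments are
serialized with `XH` (haplotype), `XT` (true reference start) and `XO`
(orientation) tags so that `audit_alignment()` can detect mis-placed reads
after external realignment without re-simulating.

## The naive caller

Reproducing a production caller's internals is out of scope; the built-in
tumour-normal caller is deliberately minimal and fully enumerable: emit a
site when its top alternate allele has ≥ `emit_min` (2) reads; filter with
`min_alt_reads` (< 3 alternate reads), `weak_evidence` (one-sided binomial
test against $\mathrm{Binomial}(D, e)$, $e = 10^{-3}$, not rejected at
$\alpha = 0.01$), `normal_artifact` (≥ 2 alternate reads in the normal) and
`clustered_events` (> 2 emitted candidates within 100 bp; window 0
disables).  `pass_probability()` and `conditional_vaf()` compute the exact
detection probability and $E[X/D \mid \mathrm{PASS}]$ by enumeration, so
simulated detection rates and the conditional VAF bias can be checked
against closed-form expectations rather than against another simulation.

Conditioning on detection inflates inferred frequencies at low $f$: among
loci that pass, high-count binomial fluctuations are over-represented.
The bias shrinks with depth — the package's tests verify both the
enumeration match (within 3 standard errors) and the monotone shrinkage
between 100× and 600×.

## Evaluation layer

`match_calls()` partitions truth into TP and false-negative causes with a
fixed priority: `no_alt_coverage` (no read carries the allele — undetectable
by any pipeline), `misaligned` (all supporting reads mis-placed, when an
alignment audit is supplied), `filtered:<label>`, `not_emitted`.  PASS
calls classify as TP, `FP_artefact`, `FP_germline` or `FP_error`.
Detection matrices over the 100 semi-centile bins, filter attribution,
TMB (PASS calls with inferred frequency ≥ 0.05 per Mb), the
strand-evidence 2×2 table and its one-sided Fisher test
(hypergeometric upper tail via `phyper`; the two-sided value coincides to
one significant figure on realistic tables because the lower tail is
negligible), and the expected-burden false-positive percentage
(`fp_count / round(median_tmb × Mb)`, with `fp/(fp+expected)` reported
separately as a precision-complement) complete the report.

## Numerical and design choices

* Coordinates: VCF 1-based, BED 0-based half-open, 0-based half-open
  internally; conversions only at I/O boundaries.
* Display rounding is half-up (`round_half_up()`), matching printed
  arithmetic conventions; all returned values are unrounded.
* Multi-allelic germline records are split per phased allele index;
  symbolic alleles are rejected.
* One master seed fans out to per-stage child seeds recorded in the run
  manifest; identical config + seed gives byte-identical truth output.
* Ties in the caller's top-alternate choice break by base order (A<C<G<T),
  a documented arbitrary choice that only matters at negligible depths.

## Problem sizes

The package targets desk scale: the bundled tests and examples use 10–50 kb
single-contig genomes, 10×–600× depth, hundreds to a couple of thousand
spiked variants and artefact burdens of a few hundred sites.  These sizes
were chosen so that binomial, goodness-of-fit and enumeration comparisons
have adequate power while a full run remains interactive; nothing in the
implementation is specific to them, and the pipeline scales linearly in
target length × depth.

## Limitations

Somatic indels, SVs and CNVs are not simulated (germline indels are).
Coverage is uniform: capture and GC bias, duplicates and trimming are out
of scope.  The error model is a parametric stand-in, not an empirical
instrument profile.  The naive caller has no local assembly or
orientation-bias filter of its own — it exists to exercise the evaluation
machinery, and numbers produced with it characterize this caller, not any
production caller.  Passing tests on these synthetic genomes demonstrate
the correctness of the simulation and scoring machinery; they do not by
themselves certify caller performance on real tumours.

## A worked miniature

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(
  seed = 11,
  spectrum = list(kind = "point_mass", n_total = 100, f0 = 0.1),
  damage = list(burden = 80, vaf_alpha = 1.5, vaf_beta = 60)))
print(run)
classify_mismatches(run$tumour)$unattributed  # 0: complete truth set
vaf_bias_report(run$matched, 0.1)
```
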