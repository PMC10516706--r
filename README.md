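# somaticsim

Stochastic simulation of matched tumour/normal short-read sequencing data
with a **comprehensive truth set**, plus the evaluation machinery to score
any somatic SNV caller against it.

## Why

Somatic callers are benchmarked against truth sets that are usually
incomplete: cell-line mixtures contain residual true variants and
unlabelled errors, and read-editing spike-in tools plant exactly
`round(f × depth)` alternate reads at every locus — a site assigned
frequency 10% at depth 30 carries exactly 3 alternate reads on every run.
Real sequencing is a sampling process: the alternate-read count is a
random variable `X ~ Binomial(D, f)`, sometimes more than `f·D`, sometimes
fewer, sometimes zero.  That stochasticity is precisely what makes
low-frequency somatic calling hard, and a benchmark that removes it
flatters every caller.

`somaticsim` simulates tumour/normal paired-end data from a personalized
phased diploid genome in which **every non-reference base has a recorded
source**: germline SNV/indel, somatic spike-in, DNA-damage artefact, or
sequencing error.  Nothing in the data is unexplained, so true and false
positives — and the *cause* of every false negative — can be classified
definitively.

## What it does

* **Phased genome** — applies phased germline SNVs/indels per haplotype
  with bidirectional coordinate liftover (`build_phased_genome`,
  `ref_to_hap`/`hap_to_ref`).
* **Read simulation** — uniform paired-end fragments over a padded capture
  target, per-cycle error model with a complete per-base error log,
  SAM/BAM output with truth tags `XH`/`XT`/`XO`
  (`simulate_fragments`, `write_alignments`).
* **Frequency spectra** — neutral-evolution `1/f` spectra (inverse-CDF
  sampling on `[f_min, f_max]`), low-frequency point masses, uniform
  semi-centile bins; ground-truth TMB (`sample_neutral`, `make_burden`,
  `true_tmb`).
* **Stochastic spike-in** — haplotype-aware per-fragment Bernoulli editing
  with probability `min(2f, 1)`, giving binomial alternate-read counts
  (marginally `Binomial(D, f)`); a deterministic read-fraction mode
  emulates BAMSurgeon-style tools for contrast (`plan_variants`,
  `spike_variants`, `apply_stochastic`, `apply_read_fraction`).
* **Damage artefacts** — FFPE C>T and 8-oxoG C>A artefacts drawn
  context-matched from 96-channel SBS signatures (estimated from calls or
  loaded from COSMIC-format TSVs), spiked orientation-pure so that
  both-strand evidence can only arise through sequencing error
  (`estimate_sbs_signature`, `load_cosmic_signature`, `spike_damage`).
* **Truth set & audit** — per-base attribution with a zero-unattributed
  completeness guarantee, truth VCF/TSV serialization, post-realignment
  placement audit (`classify_mismatches`, `write_truth`,
  `audit_alignment`).
* **Naive caller** — a minimal, exactly enumerable tumour-normal binomial
  caller with `min_alt_reads`/`weak_evidence`/`normal_artifact`/
  `clustered_events` filters (`call_somatic`, `pass_probability`,
  `conditional_vaf`).
* **Evaluation** — TP/FP/FN classification with causes, detection matrices
  over 100 semi-centile bins, filter attribution, VAF-bias reports, TMB,
  strand-evidence contingency with a one-sided exact Fisher test
  (`match_calls`, `detection_matrix`, `tmb_estimate`,
  `strand_evidence_contingency`, `fisher_strand_test`).

## Worked example

```r
library(somaticsim)
run <- run_pipeline(pipeline_config(
  seed = 11,
  reference = list(length = 30000, gc = 0.41, contig = "chrS"),
  reads = list(mean_depth = 40, read_len = 100, insert_mean = 300,
               insert_sd = 30, error_rate = 1e-3),
  spectrum = list(kind = "point_mass", n_total = 100, f0 = 0.1),
  damage = list(burden = 80, vaf_alpha = 1.5, vaf_beta = 60)))
print(run)
#> sim_run
#> phased_genome: 1 contig(s), 45 applied germline allele record(s)
#>   chrS: ref 30000 bp | maternal 29997 bp | paternal 30004 bp
#> sim_reads: 5900 fragments (11800 reads) at target depth 40x, read length 100
#>   sequencing errors logged: 1167 | somatic spike-ins: 100 | damage artefact sites: 80
#> matched_calls: 100 truth variant(s): 73 TP (73.0%)
#>   FN causes: filtered=20, no_alt_coverage=1, not_emitted=6
#>   FP classes: FP_artefact=6
```

100 somatic SNVs were spiked at true frequency 0.1 into 40× reads over a
30 kb toy genome, with 80 orientation-pure damage artefacts.  The caller
recovered 73; of the 27 missed, 20 were emitted but filtered, 6 were
dropped without record, and 1 received **no alternate-allele read at
all** — binomial sampling, not caller failure, made it undetectable.  Six
damage artefacts slipped through as false positives.  The truth set
explains every mismatching base:

```r
classify_mismatches(run$tumour)$unattributed
#> [1] 0
vaf_bias_report(run$matched, 0.1)$bias
#> [1] 0.01864907
```

The positive bias (mean inferred frequency 0.119 against truth 0.1)
is the detection-conditioning effect: among loci that pass, upward
binomial fluctuations are over-represented.  `conditional_vaf()` computes
the same quantity by exact enumeration.

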