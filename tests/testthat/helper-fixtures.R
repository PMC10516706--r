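# Shared fixtures, built in code at test time.  All fixtures are
# deterministic under the seeds fixed here.

fix_reference <- function(len = 20000L, seed = 101L, contig = "chrS") {
  generate_toy_reference(len, gc = 0.41, contig = contig, seed = seed)
}

fix_genome <- function(len = 20000L, n_snv = 20L, n_indel = 5L,
                       seed = 101L) {
  ref <- fix_reference(len, seed)
  germ <- generate_toy_germline(ref, n_snv = n_snv, n_indel = n_indel,
                                seed = seed + 1L)
  build_phased_genome(ref, germ)
}

fix_plain_genome <- function(len = 20000L, seed = 101L) {
  ref <- fix_reference(len, seed)
  build_phased_genome(ref, empty_germline())
}

empty_germline <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), gt = character(), stringsAsFactors = FALSE)
}

fix_target <- function(len = 20000L, margin = 500L, contig = "chrS") {
  data.frame(contig = contig, start = margin, end = len - margin)
}

fix_reads <- function(genome, target = fix_target(), depth = 50,
                      error_rate = 1e-3, seed = 202L, ...) {
  simulate_fragments(genome, target, mean_depth = depth,
                     error_rate = error_rate, seed = seed, ...)
}

uniform_signature <- function() {
  load_cosmic_signature(data.frame(Type = sbs_channels(),
                                   weight = rep(1 / 96, 96)))
}

oxo_signature <- function() {
  load_cosmic_signature(system.file("extdata", "sbs45_like_synthetic.tsv",
                                    package = "somaticsim"))
}

# Randomized probability-integral transform of binomial counts: exactly
# Uniform(0,1) under H0 even with per-locus sizes, enabling a calibrated
# pooled chi-square GOF.
binom_pit <- function(k, n, p) {
  stopifnot(length(k) == length(n))
  pbinom(k - 1, n, p) + runif(length(k)) * dbinom(k, n, p)
}

pit_chisq_p <- function(u, n_cells = 10L) {
  obs <- tabulate(pmin(floor(u * n_cells) + 1L, n_cells), n_cells)
  stat <- sum((obs - length(u) / n_cells)^2 / (length(u) / n_cells))
  pchisq(stat, df = n_cells - 1L, lower.tail = FALSE)
}
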