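# Somatic SNV spike-in.  Two editing modes:
#
# * stochastic: the variant lives on one haplotype; every fragment of that
#   haplotype overlapping the locus independently carries the alternate
#   allele with probability min(2 f, 1), so the marginal VAF over all
#   fragments of a pure diploid sample is f and alternate-allele read
#   counts are binomial random variables (some low-frequency loci receive
#   zero alternate reads, as in real sequencing).
# * read_fraction: deterministic BAMSurgeon-style editing of exactly
#   round(f x depth) reads at the locus, giving the same alternate count on
#   every run.
#
# Both mates of an edited fragment are edited consistently wherever they
# cover the locus (a fragment is one DNA molecule); read_fraction mode
# edits individual reads, the unit read-based tools operate on.

#' Plan somatic SNV loci over the target
#'
#' Draws one locus per ground-truth frequency, uniformly without replacement
#' over target positions, excluding positions covered by germline variant
#' records.  The haplotype is chosen uniformly and the alternate base
#' uniformly among the three non-reference bases.
#'
#' @param frequencies vector of true allele frequencies (see
#'   [make_burden()]).
#' @param target target intervals (reference space).
#' @param genome a `phased_genome`.
#' @param mode `"stochastic"` or `"read_fraction"`.
#' @param seed optional RNG seed.
#' @return data.frame of planned variants: `variant_id`, `contig`, `pos`
#'   (1-based), `ref`, `alt`, `hap`, `true_f`, `mode`.
#' @export
plan_variants <- function(frequencies, target,
                          genome, mode = c("stochastic", "read_fraction"),
                          seed = NULL) {
  mode <- match.arg(mode)
  target <- validate_target(target)
  if (!nrow(target)) stopf("target is empty")
  maybe_seed(seed)
  n <- length(frequencies)
  if (n == 0L) {
    p <- empty_somatic_table()
    return(p[, c("variant_id", "contig", "pos", "ref", "alt", "hap",
                 "true_f", "mode")])
  }
  pool <- target_positions(target)
  # exclude any reference position covered by a germline record
  g <- genome$germline
  if (nrow(g)) {
    span <- unlist(lapply(seq_len(nrow(g)), function(i) {
      paste(g$contig[i], seq.int(g$pos[i] - 1L, g$pos[i] + nchar(g$ref[i]) - 2L))
    }))
    pool <- pool[!(paste(pool$contig, pool$pos0) %in% span), , drop = FALSE]
  }
  if (n > nrow(pool))
    stopf("requested %d variants but only %d eligible loci", n, nrow(pool))
  sel <- pool[sample.int(nrow(pool), n), , drop = FALSE]
  refb <- vapply(seq_len(n), function(i)
    substr(genome$ref[[sel$contig[i]]], sel$pos0[i] + 1L, sel$pos0[i] + 1L),
    character(1))
  alt <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L),
                character(1), USE.NAMES = FALSE)
  data.frame(variant_id = sprintf("som%06d", seq_len(n)),
             contig = sel$contig, pos = sel$pos0 + 1L, ref = refb, alt = alt,
             hap = sample(HAPS, n, replace = TRUE),
             true_f = frequencies, mode = mode, stringsAsFactors = FALSE)
}

#' Spike a plan of somatic variants into simulated reads
#'
#' Applies every planned variant in order, in the plan's editing mode,
#' recording one truth entry per edited read base.  Loci falling in a
#' haplotype deletion are skipped with a message and flagged in the
#' per-variant summary.
#'
#' @param sr a `sim_reads` object.
#' @param plan a [plan_variants()] data.frame.
#' @param seed optional RNG seed.
#' @return the edited `sim_reads`; `$somatic` gains one summary row per
#'   variant (`n_overlap`, `n_edited`, `skipped`) and `$spikes` one row per
#'   edited read base.
#' @export
spike_variants <- function(sr, plan, seed = NULL) {
  maybe_seed(seed)
  genome <- sr$genome
  rl <- sr$params$read_len
  seqs <- sr$reads$seq
  err_key <- paste(sr$error_log$read_id, sr$error_log$hap_pos0)
  spikes <- vector("list", nrow(plan))
  summ <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    v <- plan[i, ]
    if (v$mode == "stochastic") {
      hp <- ref_to_hap(genome, v$hap, v$contig, v$pos - 1L)
      rows <- reads_at(sr, v$hap, v$contig, hp)
      if (is.na(hp)) {
        message(sprintf("variant %s at %s:%d falls in a %s deletion; skipped",
                        v$variant_id, v$contig, v$pos, v$hap))
        summ[[i]] <- cbind(v, n_overlap = 0L, n_edited = 0L, skipped = TRUE)
        next
      }
      frag_ids <- unique(sr$reads$frag_id[rows])
      p <- min(2 * v$true_f, 1)
      chosen <- frag_ids[runif(length(frag_ids)) < p]
      edit_rows <- rows[sr$reads$frag_id[rows] %in% chosen]
      n_overlap <- length(frag_ids)
      hp_of <- rep(hp, length(edit_rows))
    } else {                         # read_fraction: deterministic, per read
      per_hap <- lapply(HAPS, function(h) {
        hph <- ref_to_hap(genome, h, v$contig, v$pos - 1L)
        r <- reads_at(sr, h, v$contig, hph)
        if (!length(r)) return(NULL)
        data.frame(row = r, hp = hph)
      })
      cov <- do.call(rbind, per_hap)
      depth <- if (is.null(cov)) 0L else nrow(cov)
      k <- as.integer(round_half_up(v$true_f * depth))
      if (depth == 0L || k == 0L) {
        summ[[i]] <- cbind(v, n_overlap = depth, n_edited = 0L,
                           skipped = FALSE)
        next
      }
      cov <- cov[order(sr$reads$read_id[cov$row]), , drop = FALSE]
      cov <- cov[seq_len(k), , drop = FALSE]
      edit_rows <- cov$row
      hp_of <- cov$hp
      n_overlap <- depth
    }
    if (length(edit_rows)) {
      off <- hp_of - sr$reads$start[edit_rows]
      prev <- substring(seqs[edit_rows], off + 1L, off + 1L)
      for (j in seq_along(edit_rows)) {
        substr(seqs[edit_rows[j]], off[j] + 1L, off[j] + 1L) <- v$alt
      }
      spikes[[i]] <- data.frame(
        read_id = sr$reads$read_id[edit_rows], hap = sr$reads$hap[edit_rows],
        contig = v$contig, hap_pos0 = hp_of, ref_pos0 = v$pos - 1L,
        prev_base = prev, alt = v$alt, source = "somatic_spike_in",
        variant_id = v$variant_id, stringsAsFactors = FALSE)
      hit <- err_key %in% paste(sr$reads$read_id[edit_rows], hp_of)
      if (any(hit)) sr$error_log$superseded[hit] <- TRUE
    }
    n_ed <- if (v$mode == "stochastic") length(unique(chosen)) else
      length(edit_rows)
    summ[[i]] <- cbind(v, n_overlap = n_overlap, n_edited = n_ed,
                       skipped = FALSE)
  }
  sr$reads$seq <- seqs
  new_spikes <- do.call(rbind, spikes[!vapply(spikes, is.null, logical(1))])
  if (!is.null(new_spikes)) sr$spikes <- rbind(sr$spikes, new_spikes)
  sr$somatic <- rbind(sr$somatic, do.call(rbind, summ))
  sr
}

#' Stochastically spike a single somatic variant
#'
#' Per-fragment Bernoulli editing on the variant's haplotype with success
#' probability `min(2 true_f, 1)`; see [spike_variants()].
#'
#' @param sr a `sim_reads` object.
#' @param variant one-row data.frame as produced by [plan_variants()].
#' @param seed optional RNG seed.
#' @return list with the edited `sim_reads` (`$sr`) and a summary
#'   (`$n_overlap` fragments of the chosen haplotype, `$n_edited` fragments
#'   carrying the alternate allele, `$read_ids` of edited reads).
#' @export
apply_stochastic <- function(sr, variant, seed = NULL) {
  variant$mode <- "stochastic"
  if (is.null(variant$variant_id)) variant$variant_id <- "som_manual"
  out <- spike_variants(sr, variant, seed = seed)
  one_spike_result(out, variant)
}

#' Deterministically spike a single variant (read-fraction mode)
#'
#' Edits exactly `round(true_f x depth)` reads at the locus, chosen in a
#' fixed reproducible order (sorted read ids), emulating read-fraction
#' tools such as BAMSurgeon: the alternate-allele count is identical on
#' every run.
#'
#' @inheritParams apply_stochastic
#' @return as [apply_stochastic()]; `$n_overlap` is the read depth at the
#'   locus and `$n_edited` the number of edited reads.
#' @export
apply_read_fraction <- function(sr, variant, seed = NULL) {
  variant$mode <- "read_fraction"
  if (is.null(variant$variant_id)) variant$variant_id <- "som_manual"
  out <- spike_variants(sr, variant, seed = seed)
  one_spike_result(out, variant)
}

one_spike_result <- function(sr, variant) {
  s <- sr$somatic[sr$somatic$variant_id == variant$variant_id, ]
  s <- s[nrow(s), ]
  ed <- sr$spikes[sr$spikes$variant_id == variant$variant_id, ]
  list(sr = sr, variant = variant, n_overlap = s$n_overlap,
       n_edited = s$n_edited, skipped = s$skipped, read_ids = ed$read_id)
}

#' Count alternate-allele reads at a variant locus
#'
#' @param sr a `sim_reads` object.
#' @param variant one-row variant data.frame (`contig`, `pos`, `alt`).
#' @return number of reads whose observed base at the locus equals the
#'   alternate allele.
#' @export
alt_read_count <- function(sr, variant) {
  p <- pileup_at(sr, data.frame(contig = variant$contig, pos = variant$pos))
  as.integer(p[[variant$alt]][1])
}
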