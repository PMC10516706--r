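# Evaluation layer: score any caller's output against the comprehensive
# truth set -- TP/FP/FN classification with causes, detection matrices over
# semi-centile bins, filter attribution, VAF-bias summaries, TMB, and the
# strand-evidence contingency analysis of damage artefacts.

FN_CAUSES <- c("no_alt_coverage", "misaligned", "filtered", "not_emitted")

#' Match caller output against the somatic truth set
#'
#' Every truth somatic variant maps to exactly one of TP or a
#' false-negative cause, in priority order: `no_alt_coverage` (no read
#' supports the alternate allele), `misaligned` (alternate reads exist but
#' all were mis-placed, when a misalignment report is supplied),
#' `filtered:<label>` (an emitted non-PASS record exists) and `not_emitted`
#' (the caller dropped the site without record).  Every PASS call maps to
#' exactly one of TP, `FP_artefact` (damage truth at the site),
#' `FP_germline` or `FP_error`.
#'
#' @param calls a `somatic_calls` data.frame (or [read_calls_vcf()]
#'   output).
#' @param sr the generating `sim_reads` (for truth and alternate-read
#'   counts).
#' @param misalignment optional [audit_alignment()] report.
#' @return object of class `matched_calls`: `truth` (per-variant class and
#'   cause), `calls` (per-PASS-call class), and count summaries.
#' @export
match_calls <- function(calls, sr, misalignment = NULL) {
  truth <- sr$somatic
  if (nrow(truth) &&
      !all(truth$contig %in% unique(c(calls$contig, sr$genome$contigs))))
    stopf("truth and calls disagree on contigs")
  ckey <- paste(calls$contig, calls$pos, calls$alt)
  tkey <- paste(truth$contig, truth$pos, truth$alt)

  cls <- character(nrow(truth)); cause <- rep(NA_character_, nrow(truth))
  infv <- rep(NA_real_, nrow(truth))
  m <- match(tkey, ckey)
  alt_n <- if (nrow(truth))
    vapply(seq_len(nrow(truth)), function(i)
      alt_read_count(sr, truth[i, ]), integer(1)) else integer(0)
  for (i in seq_len(nrow(truth))) {
    if (!is.na(m[i]) && calls$pass[m[i]]) {
      cls[i] <- "TP"; infv[i] <- calls$vaf[m[i]]
      next
    }
    cls[i] <- "FN"
    if (alt_n[i] == 0L) { cause[i] <- "no_alt_coverage"; next }
    if (!is.null(misalignment) && !is.null(misalignment$per_variant)) {
      pv <- misalignment$per_variant
      j <- which(pv$contig == truth$contig[i] & pv$pos == truth$pos[i])
      if (length(j) && pv$n_misplaced[j[1]] >= alt_n[i]) {
        cause[i] <- "misaligned"; next
      }
    }
    if (!is.na(m[i])) {
      cause[i] <- paste0("filtered:", calls$filters[m[i]])
    } else {
      cause[i] <- "not_emitted"
    }
  }
  truth_out <- cbind(truth[, c("variant_id", "contig", "pos", "ref", "alt",
                               "hap", "true_f")],
                     class = cls, cause = cause, alt_reads = alt_n,
                     inferred_vaf = infv)

  pass <- calls[calls$pass, , drop = FALSE]
  pkey <- paste(pass$contig, pass$pos, pass$alt)
  dkey <- if (nrow(sr$damage))
    paste(sr$damage$contig, sr$damage$pos, sr$damage$alt) else character(0)
  g <- sr$genome$germline
  gkey <- if (nrow(g)) paste(g$contig, g$pos) else character(0)
  pclass <- ifelse(pkey %in% tkey, "TP",
                   ifelse(pkey %in% dkey, "FP_artefact",
                          ifelse(paste(pass$contig, pass$pos) %in% gkey,
                                 "FP_germline", "FP_error")))
  pass_out <- cbind(pass, class = pclass)

  structure(list(truth = truth_out, calls = pass_out,
                 n_truth = nrow(truth_out), n_tp = sum(cls == "TP"),
                 fn_causes = table(sub(":.*$", "", cause[cls == "FN"])),
                 fp_classes = table(pclass[pclass != "TP"])),
            class = "matched_calls")
}

#' Detection matrix over true-frequency semi-centile bins
#'
#' Rows are semi-centile bins of the true frequency over `(0, 0.5]`;
#' columns are the semi-centile bin of the inferred frequency of the
#' passing call, plus a `not_detected` column.  Row sums conserve the
#' per-bin ground-truth burden; per-bin detection rate = detected / truth.
#'
#' @param matched a [match_calls()] result.
#' @param n_bins number of equal bins over `(0, 0.5]`; default 100
#'   (semi-centiles).
#' @return list with `matrix` (n_bins x (n_bins + 1) counts), `rate`
#'   (per-bin detection rate, `NA` for empty bins) and `truth_per_bin`.
#' @export
detection_matrix <- function(matched, n_bins = 100L) {
  t <- matched$truth
  edges <- seq(0, 0.5, length.out = n_bins + 1L)
  tb <- pmin(pmax(findInterval(t$true_f, edges, left.open = TRUE,
                               rightmost.closed = TRUE), 1L), n_bins)
  mat <- matrix(0L, n_bins, n_bins + 1L,
                dimnames = list(sprintf("true_bin%03d", 1:n_bins),
                                c(sprintf("inf_bin%03d", 1:n_bins),
                                  "not_detected")))
  det <- t$class == "TP" & !is.na(t$inferred_vaf)
  ib <- rep(n_bins + 1L, nrow(t))
  ib[det] <- pmin(pmax(findInterval(t$inferred_vaf[det], edges,
                                    left.open = TRUE,
                                    rightmost.closed = TRUE), 1L), n_bins)
  for (i in seq_len(nrow(t))) mat[tb[i], ib[i]] <- mat[tb[i], ib[i]] + 1L
  truth_per_bin <- tabulate(tb, n_bins)
  detected_per_bin <- tabulate(tb[t$class == "TP"], n_bins)
  rate <- ifelse(truth_per_bin > 0, detected_per_bin / truth_per_bin,
                 NA_real_)
  list(matrix = mat, rate = rate, truth_per_bin = truth_per_bin)
}

#' TMB estimate from passing calls
#'
#' Number of PASS calls with inferred frequency at or above the threshold,
#' per megabase of target.
#'
#' @param matched a [match_calls()] result or a data.frame of PASS calls
#'   with a `vaf` column.
#' @param threshold inferred-frequency threshold; default 0.05.
#' @param target_mb target size in megabases.
#' @return mutations per megabase.
#' @export
tmb_estimate <- function(matched, threshold = 0.05, target_mb) {
  calls <- if (inherits(matched, "matched_calls")) matched$calls else matched
  if (target_mb <= 0) stopf("target_mb must be positive")
  sum(calls$vaf >= threshold, na.rm = TRUE) / target_mb
}

#' Filter attribution of false negatives
#'
#' Counts, per filter label, how many true somatic variants were emitted by
#' the caller but incorrectly filtered.
#'
#' @param matched a [match_calls()] result.
#' @return named integer vector of filter labels.
#' @export
filter_attribution <- function(matched) {
  f <- matched$truth$cause
  f <- f[!is.na(f) & startsWith(f, "filtered:")]
  lab <- unlist(strsplit(sub("^filtered:", "", f), ";"))
  if (!length(lab)) return(setNames(integer(0), character(0)))
  tb <- table(lab)
  setNames(as.integer(tb), names(tb))
}

#' Strand-evidence contingency table for damage-artefact sites
#'
#' Rows: true negatives (artefact correctly not passed) vs false positives
#' (artefact passed); columns: alternate evidence on a single fragment
#' orientation only vs on both orientations.  Damage is spiked
#' orientation-pure, so both-orientation evidence requires a sequencing
#' error on the opposite strand -- the escape route past orientation-bias
#' filtering.
#'
#' @param sites data.frame with logical columns `fp` (passed) and
#'   `both_strand` (alternate evidence on both orientation classes), e.g.
#'   from [strand_evidence_sites()].
#' @return 2x2 integer matrix (rows `TN`/`FP`, columns
#'   `single_strand`/`both_strand`).
#' @export
strand_evidence_contingency <- function(sites) {
  stopifnot(all(c("fp", "both_strand") %in% names(sites)))
  matrix(c(sum(!sites$fp & !sites$both_strand),
           sum(sites$fp & !sites$both_strand),
           sum(!sites$fp & sites$both_strand),
           sum(sites$fp & sites$both_strand)), 2, 2,
         dimnames = list(c("TN", "FP"), c("single_strand", "both_strand")))
}

#' Per-site strand evidence for analysed damage-artefact sites
#'
#' For every damage site emitted by the caller, determines whether its
#' alternate-allele reads come from one fragment-orientation class or both,
#' and whether the site was (incorrectly) passed.
#'
#' @param sr the `sim_reads` run.
#' @param calls a `somatic_calls` data.frame from the same run.
#' @return data.frame with `site_id`, `fp`, `both_strand`, `n_fwd`,
#'   `n_rev` (alternate reads per orientation class).
#' @export
strand_evidence_sites <- function(sr, calls) {
  d <- sr$damage
  ckey <- paste(calls$contig, calls$pos, calls$alt)
  dkey <- paste(d$contig, d$pos, d$alt)
  m <- match(dkey, ckey)
  analysed <- which(!is.na(m))          # emitted by the caller
  ori <- sr$fragments$orientation[match(sr$reads$frag_id,
                                        sr$fragments$frag_id)]
  names(ori) <- sr$reads$read_id
  out <- lapply(analysed, function(i) {
    nf <- 0L; nr <- 0L
    for (h in HAPS) {
      hp <- ref_to_hap(sr$genome, h, d$contig[i], d$pos[i] - 1L)
      rows <- reads_at(sr, h, d$contig[i], hp)
      if (!length(rows)) next
      b <- substring(sr$reads$seq[rows], hp - sr$reads$start[rows] + 1L,
                     hp - sr$reads$start[rows] + 1L)
      alt_rows <- rows[b == d$alt[i]]
      o <- ori[sr$reads$read_id[alt_rows]]
      nf <- nf + sum(o == "F"); nr <- nr + sum(o == "R")
    }
    data.frame(site_id = d$site_id[i], fp = calls$pass[m[i]],
               both_strand = nf > 0L && nr > 0L, n_fwd = nf, n_rev = nr,
               stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(site_id = character(), fp = logical(),
                      both_strand = logical(), n_fwd = integer(),
                      n_rev = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' One-sided Fisher's exact test for strand-evidence enrichment
#'
#' Tests enrichment of both-orientation alternate evidence among false
#' positives relative to true negatives: the exact hypergeometric upper
#' tail probability of the observed (or larger) both-strand FP cell,
#' computed in log space by `phyper`.  With an all-zero margin the p-value
#' is 1 by convention.
#'
#' @param tab 2x2 matrix as from [strand_evidence_contingency()] (rows
#'   `TN`/`FP`, columns `single_strand`/`both_strand`).
#' @return one-sided p-value.
#' @export
#' @examples
#' fisher_strand_test(matrix(c(4043, 30, 126, 12), 2, 2))  # ~5e-09
fisher_strand_test <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0),
            all(tab == round(tab)))
  m <- tab[1, 2] + tab[2, 2]    # both-strand sites
  n <- tab[1, 1] + tab[2, 1]    # single-strand sites
  k <- tab[2, 1] + tab[2, 2]    # false positives drawn
  if (m + n == 0L || k == 0L || m == 0L) return(1)
  phyper(tab[2, 2] - 1, m = m, n = n, k = k, lower.tail = FALSE)
}

#' False-positive rate relative to an expected somatic burden
#'
#' Scales a median TMB (mut/Mb) to the expected mutation count on the
#' target, and expresses the artefact false-positive count as a rounded
#' percentage of that expectation.
#'
#' @param fp_count number of artefact calls incorrectly passed.
#' @param median_tmb reference median TMB in mut/Mb (2.7 across tumour
#'   types in large cohorts).
#' @param target_mb target size in megabases.
#' @return list with `expected_mutations` and `percentage` (`NA` when the
#'   expectation is zero); `precision_complement` reports
#'   `fp / (fp + expected)` as an alternative denominator convention.
#' @export
#' @examples
#' fp_rate_vs_expected_burden(42, 2.7, 76)  # expected 205, percentage 20
fp_rate_vs_expected_burden <- function(fp_count, median_tmb = 2.7,
                                       target_mb) {
  stopifnot(fp_count >= 0, median_tmb >= 0, target_mb >= 0)
  expected <- as.integer(round_half_up(median_tmb * target_mb))
  pct <- if (expected == 0L) NA_real_ else
    round_half_up(100 * fp_count / expected)
  list(expected_mutations = expected, percentage = pct,
       precision_complement = if (fp_count + expected > 0)
         round_half_up(100 * fp_count / (fp_count + expected)) else
           NA_real_)
}

#' Fraction of a damage burden considered by the caller
#'
#' Of a total spiked artefact burden, the fraction whose sites reached the
#' caller's evidence threshold at all (the rest being ignored or receiving
#' no artefact-carrying reads).
#'
#' @param n_considered artefact sites emitted/considered by the caller.
#' @param total_burden total spiked artefact count.
#' @return fraction rounded to 4 decimals.
#' @export
#' @examples
#' considered_fraction(11283, 7332528)  # 0.0015
considered_fraction <- function(n_considered, total_burden) {
  stopifnot(total_burden > 0, n_considered >= 0)
  round_half_up(n_considered / total_burden, 4)
}

#' Inferred-VAF bias of passing calls at a point-mass truth
#'
#' Summarizes the inferred allele frequencies of PASS calls matching truth
#' variants simulated at a single true frequency `f0`; the conditional bias
#' is `mean - f0` and shrinks with sequencing depth.
#'
#' @param matched a [match_calls()] result.
#' @param f0 the true point-mass frequency.
#' @return list with `n_pass`, `mean`, `median`, `sd`, `bias`; empty
#'   (`n_pass = 0`, `NA` statistics) when nothing passed.
#' @export
vaf_bias_report <- function(matched, f0) {
  v <- matched$truth$inferred_vaf[matched$truth$class == "TP"]
  v <- v[!is.na(v)]
  if (!length(v)) {
    return(list(n_pass = 0L, mean = NA_real_, median = NA_real_,
                sd = NA_real_, bias = NA_real_))
  }
  list(n_pass = length(v), mean = mean(v), median = median(v),
       sd = stats::sd(v), bias = mean(v) - f0)
}

#' @export
print.matched_calls <- function(x, ...) {
  cat(sprintf("matched_calls: %d truth variant(s): %d TP (%.1f%%)\n",
              x$n_truth, x$n_tp,
              if (x$n_truth) 100 * x$n_tp / x$n_truth else 0))
  if (length(x$fn_causes)) {
    cat("  FN causes:", paste(sprintf("%s=%d", names(x$fn_causes),
                                      x$fn_causes), collapse = ", "), "\n")
  }
  if (length(x$fp_classes)) {
    cat("  FP classes:", paste(sprintf("%s=%d", names(x$fp_classes),
                                       x$fp_classes), collapse = ", "),
        "\n")
  }
  invisible(x)
}
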