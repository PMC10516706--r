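# Minimal tumour-normal somatic SNV caller.  It exists as an internal test
# surrogate for production callers: simple enough to enumerate exactly,
# rich enough to exhibit detection-rate curves, filter attribution and the
# conditional low-frequency VAF bias end-to-end.
#
# Emission / filtering rules (all configurable):
#   * a site enters the VCF when its top alternate allele has at least
#     `emit_min` supporting reads (candidates below that are dropped
#     without record, like real callers discarding unconsidered sites);
#   * `min_alt_reads`  : alternate count below `min_alt`;
#   * `weak_evidence`  : one-sided binomial test of the alternate count
#     against Binomial(depth, e) not rejected at `alpha`;
#   * `normal_artifact`: the matched normal shows >= `normal_alt` reads of
#     the same alternate allele;
#   * `clustered_events`: more than 2 emitted candidates within
#     `cluster_window` bases;
#   * PASS iff no filter applies.

#' Default naive-caller parameters
#' @param e assumed per-base error rate of the binomial evidence test.
#' @param alpha significance level of the evidence test.
#' @param min_alt minimum alternate-read count.
#' @param normal_alt alternate reads in the normal at/above which a site is
#'   a `normal_artifact`.
#' @param cluster_window window (bases) of the `clustered_events` filter;
#'   `0` disables it.
#' @param emit_min minimum alternate reads for a site to be emitted at all.
#' @return named list of parameters.
#' @export
caller_params <- function(e = 1e-3, alpha = 0.01, min_alt = 3L,
                          normal_alt = 2L, cluster_window = 100L,
                          emit_min = 2L) {
  list(e = e, alpha = alpha, min_alt = as.integer(min_alt),
       normal_alt = as.integer(normal_alt),
       cluster_window = as.integer(cluster_window),
       emit_min = as.integer(emit_min))
}

#' Call somatic SNVs from tumour and normal pileups
#'
#' @param tumour,normal pileup data.frames from [pileup_at()] over the same
#'   positions (the normal may be `NULL` for tumour-only calling).
#' @param params a [caller_params()] list.
#' @return object of class `somatic_calls`: one row per emitted candidate
#'   with `alt_count`, `depth`, `vaf` (= alt/depth), normal evidence,
#'   `filters` (`;`-separated labels, empty string for PASS) and `pass`.
#' @export
call_somatic <- function(tumour, normal = NULL, params = caller_params()) {
  stopifnot(all(c("contig", "pos", "ref", "depth") %in% names(tumour)))
  if (!is.null(normal) &&
      !identical(paste(tumour$contig, tumour$pos),
                 paste(normal$contig, normal$pos)))
    stopf("tumour and normal pileups cover different sites")
  counts <- as.matrix(tumour[, BASES])
  ref_idx <- match(tumour$ref, BASES)
  counts[cbind(seq_len(nrow(counts)), ref_idx)] <- -1L
  alt_idx <- max.col(counts, ties.method = "first")
  alt_count <- counts[cbind(seq_len(nrow(counts)), alt_idx)]
  keep <- which(tumour$depth > 0L & alt_count >= params$emit_min)

  calls <- data.frame(contig = tumour$contig[keep], pos = tumour$pos[keep],
                      ref = tumour$ref[keep], alt = BASES[alt_idx[keep]],
                      alt_count = as.integer(alt_count[keep]),
                      depth = as.integer(tumour$depth[keep]),
                      stringsAsFactors = FALSE)
  calls$vaf <- ifelse(calls$depth > 0, calls$alt_count / calls$depth, 0)
  if (!is.null(normal)) {
    ncounts <- as.matrix(normal[, BASES])[keep, , drop = FALSE]
    calls$normal_alt <- as.integer(
      ncounts[cbind(seq_len(nrow(calls)), match(calls$alt, BASES))])
    calls$normal_depth <- as.integer(normal$depth[keep])
  } else {
    calls$normal_alt <- 0L
    calls$normal_depth <- 0L
  }

  # filters
  flt <- vector("list", nrow(calls))
  p_err <- pbinom(calls$alt_count - 1L, calls$depth, params$e,
                  lower.tail = FALSE)
  for (i in seq_len(nrow(calls))) {
    f <- character(0)
    if (calls$alt_count[i] < params$min_alt) f <- c(f, "min_alt_reads")
    if (p_err[i] >= params$alpha) f <- c(f, "weak_evidence")
    if (calls$normal_alt[i] >= params$normal_alt)
      f <- c(f, "normal_artifact")
    flt[[i]] <- f
  }
  if (params$cluster_window > 0L && nrow(calls) > 1L) {
    for (i in seq_len(nrow(calls))) {
      near <- calls$contig == calls$contig[i] &
        abs(calls$pos - calls$pos[i]) <= params$cluster_window
      if (sum(near) > 2L) flt[[i]] <- c(flt[[i]], "clustered_events")
    }
  }
  calls$filters <- vapply(flt, paste, character(1), collapse = ";")
  calls$pass <- !nzchar(calls$filters)
  structure(calls, class = c("somatic_calls", "data.frame"),
            params = params)
}

#' Exact detection probability of the naive caller
#'
#' Probability that a variant with true frequency `f` at read depth `depth`
#' is emitted and passes the evidence filters (`min_alt` and
#' `weak_evidence`), computed by exact enumeration over
#' `X ~ Binomial(depth, f)` alternate reads.  Matched-normal and cluster
#' filters are not modelled (no artefact evidence under the enumeration).
#'
#' @param depth read depth at the locus.
#' @param f true allele frequency (marginal alternate-read probability).
#' @param params a [caller_params()] list.
#' @return detection probability in `[0, 1]`.
#' @export
pass_probability <- function(depth, f, params = caller_params()) {
  x <- 0:depth
  ok <- passes_evidence(x, depth, params)
  sum(dbinom(x[ok], depth, f))
}

passes_evidence <- function(x, depth, params) {
  p_err <- pbinom(x - 1L, depth, params$e, lower.tail = FALSE)
  x >= params$min_alt & p_err < params$alpha
}

#' Exact conditional mean inferred VAF of passing calls
#'
#' `E[X / depth | pass]` for `X ~ Binomial(depth, f)`: the expected
#' inferred frequency of a variant *given* that it passed the evidence
#' rules.  Conditioning on detection biases the inferred frequency upward
#' at low `f`, and the bias shrinks with depth.
#'
#' @inheritParams pass_probability
#' @return list with `mean` (conditional mean VAF), `var` (conditional
#'   variance of the VAF) and `p_pass`.
#' @export
conditional_vaf <- function(depth, f, params = caller_params()) {
  x <- 0:depth
  ok <- passes_evidence(x, depth, params)
  w <- dbinom(x, depth, f)[ok]
  if (!sum(w)) return(list(mean = NA_real_, var = NA_real_, p_pass = 0))
  v <- (x[ok] / depth)
  m <- sum(w * v) / sum(w)
  list(mean = m, var = sum(w * (v - m)^2) / sum(w), p_pass = sum(w))
}

#' Write calls as a VCF with FILTER annotations
#' @param calls a `somatic_calls` data.frame.
#' @param genome the `phased_genome` (contig headers).
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=somaticsim naive caller",
           sprintf("##contig=<ID=%s,length=%d>", genome$contigs,
                   nchar(genome$ref[genome$contigs])),
           "##FILTER=<ID=min_alt_reads,Description=\"Too few alternate reads\">",
           "##FILTER=<ID=weak_evidence,Description=\"Binomial evidence test not rejected\">",
           "##FILTER=<ID=normal_artifact,Description=\"Alternate evidence in the matched normal\">",
           "##FILTER=<ID=clustered_events,Description=\"Clustered candidates\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate read count\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Inferred allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  o <- order(calls$contig, calls$pos)
  calls <- calls[o, , drop = FALSE]
  filt <- ifelse(calls$pass, "PASS",
                 gsub(";", ";", calls$filters, fixed = TRUE))
  info <- sprintf("DP=%d;AC=%d;AF=%.6g", calls$depth, calls$alt_count,
                  calls$vaf)
  writeLines(c(hdr, paste(calls$contig, calls$pos, ".", calls$ref,
                          calls$alt, ".", filt, info, sep = "\t")), path)
  invisible(path)
}

#' Read a caller VCF (any caller) into the evaluation call table
#'
#' @param path VCF path with FILTER annotations (`PASS` or `;`-separated
#'   labels).
#' @return data.frame compatible with [match_calls()]: `contig`, `pos`,
#'   `ref`, `alt`, `vaf` (from an `AF` INFO field when present), `filters`,
#'   `pass`.
#' @export
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!nrow(v@fix)) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(), vaf = numeric(),
                      filters = character(), pass = logical(),
                      stringsAsFactors = FALSE))
  }
  info <- as.character(v@fix[, "INFO"])
  af <- suppressWarnings(as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1",
                                        info)))
  af[!grepl("AF=", info)] <- NA_real_
  filt <- as.character(v@fix[, "FILTER"])
  filt[is.na(filt)] <- "PASS"
  data.frame(contig = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             ref = as.character(v@fix[, "REF"]),
             alt = as.character(v@fix[, "ALT"]), vaf = af,
             filters = ifelse(filt %in% c("PASS", "."), "", filt),
             pass = filt %in% c("PASS", "."), stringsAsFactors = FALSE)
}

#' @export
print.somatic_calls <- function(x, ...) {
  cat(sprintf("somatic_calls: %d emitted candidate(s), %d PASS\n",
              nrow(x), sum(x$pass)))
  if (nrow(x)) {
    lab <- unlist(strsplit(x$filters[!x$pass], ";"))
    if (length(lab)) {
      tb <- sort(table(lab), decreasing = TRUE)
      cat("  filters:", paste(sprintf("%s=%d", names(tb), tb),
                              collapse = ", "), "\n")
    }
  }
  invisible(x)
}
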