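# The comprehensive truth set: every non-reference base in the simulated
# data is attributable to exactly one source -- germline SNV/indel, somatic
# spike-in, damage artefact or sequencing error.  Attribution priority is
# read-level first (spike edits, then non-superseded error-log entries),
# then site-level germline state; anything left is "unattributed" and must
# be zero on internally generated data.

TRUTH_SOURCES <- c("germline_snv", "germline_indel", "somatic_spike_in",
                   "damage_artefact", "sequencing_error")

#' Assemble site-level truth records for a run
#'
#' One record per (position, alternate allele, source).  Somatic and damage
#' records with zero supporting reads are flagged `unrepresented` -- ground
#' truth burden that received no coverage of the alternative allele and is
#' therefore undetectable by any caller.
#'
#' @param sr a `sim_reads` object after spiking.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`, `source`,
#'   `true_f`, `channel`, `orientation`, `hap`, `unrepresented`.
#' @export
truth_records <- function(sr) {
  genome <- sr$genome
  recs <- list()
  g <- genome$germline
  if (nrow(g)) {
    type <- ifelse(nchar(g$ref) == 1L & nchar(g$alt) == 1L,
                   "germline_snv", "germline_indel")
    hap <- ifelse(g$gt_maternal == 1L & g$gt_paternal == 1L, "both",
                  ifelse(g$gt_maternal == 1L, "maternal", "paternal"))
    recs$germ <- data.frame(contig = g$contig, pos = g$pos, ref = g$ref,
                            alt = g$alt, source = type, true_f = NA_real_,
                            channel = NA_character_,
                            orientation = NA_character_, hap = hap,
                            unrepresented = FALSE, stringsAsFactors = FALSE)
  }
  s <- sr$somatic
  if (nrow(s)) {
    recs$som <- data.frame(contig = s$contig, pos = s$pos, ref = s$ref,
                           alt = s$alt, source = "somatic_spike_in",
                           true_f = s$true_f, channel = NA_character_,
                           orientation = NA_character_, hap = s$hap,
                           unrepresented = s$n_edited == 0L,
                           stringsAsFactors = FALSE)
  }
  d <- sr$damage
  if (nrow(d)) {
    recs$dmg <- data.frame(contig = d$contig, pos = d$pos, ref = d$ref,
                           alt = d$alt, source = "damage_artefact",
                           true_f = d$vaf, channel = d$channel,
                           orientation = d$orientation, hap = NA_character_,
                           unrepresented = d$n_edited == 0L,
                           stringsAsFactors = FALSE)
  }
  e <- sr$error_log
  e <- e[!e$superseded & !is.na(e$ref_pos0), , drop = FALSE]
  if (nrow(e)) {
    recs$err <- data.frame(contig = e$contig, pos = e$ref_pos0 + 1L,
                           ref = e$true_base, alt = e$obs_base,
                           source = "sequencing_error", true_f = NA_real_,
                           channel = NA_character_,
                           orientation = NA_character_, hap = e$hap,
                           unrepresented = FALSE, stringsAsFactors = FALSE)
    recs$err$read_id <- e$read_id
  }
  for (nm in names(recs))
    if (is.null(recs[[nm]]$read_id)) recs[[nm]]$read_id <- NA_character_
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      source = character(), true_f = numeric(),
                      channel = character(), orientation = character(),
                      hap = character(), unrepresented = logical(),
                      read_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' Attribute every read-base mismatch against the reference
#'
#' Expands all read bases, lifts them to reference coordinates, and assigns
#' every base differing from the reference to exactly one source.  On
#' internally generated data the unattributed count must be zero -- the
#' completeness property of the truth set.
#'
#' @param sr a `sim_reads` object.
#' @return list with `table` (named totals per source), `unattributed`
#'   count, and `details` (one row per mismatching read base).
#' @export
classify_mismatches <- function(sr) {
  genome <- sr$genome
  rl <- sr$params$read_len
  reads <- sr$reads
  n <- nrow(reads)
  row_of <- rep(seq_len(n), each = rl)
  off <- rep(seq_len(rl) - 1L, times = n)
  hp <- reads$start[row_of] + off
  obs <- unlist(strsplit(reads$seq, ""), use.names = FALSE)

  key <- paste(reads$hap, reads$contig)[row_of]
  rp <- integer(length(hp))
  refb <- character(length(hp))
  for (k in unique(key)) {
    i <- which(key == k)
    h <- reads$hap[row_of[i[1]]]; ctg <- reads$contig[row_of[i[1]]]
    rp[i] <- hap_to_ref(genome, h, ctg, hp[i])
    refb[i] <- ifelse(is.na(rp[i]), NA_character_,
                      substring(genome$ref[[ctg]], rp[i] + 1L, rp[i] + 1L))
  }

  mm <- which(is.na(rp) | obs != refb)   # inserted bases count as evidence
  det <- data.frame(read_id = reads$read_id[row_of[mm]],
                    hap = reads$hap[row_of[mm]],
                    contig = reads$contig[row_of[mm]],
                    hap_pos0 = hp[mm], ref_pos0 = rp[mm], obs = obs[mm],
                    stringsAsFactors = FALSE)

  src <- rep(NA_character_, nrow(det))
  bkey <- paste(det$read_id, det$hap_pos0)

  sp <- sr$spikes
  if (nrow(sp)) {
    m <- match(bkey, paste(sp$read_id, sp$hap_pos0))
    hit <- !is.na(m)
    src[hit] <- sp$source[m[hit]]
  }
  e <- sr$error_log[!sr$error_log$superseded, , drop = FALSE]
  if (nrow(e)) {
    m <- match(bkey, paste(e$read_id, e$hap_pos0))
    hit <- is.na(src) & !is.na(m)
    src[hit] <- "sequencing_error"
  }
  # germline: substituted reference positions and inserted haplotype bases
  gs <- genome$gsub
  if (nrow(gs)) {
    m <- match(paste(det$hap, det$contig, det$ref_pos0),
               paste(gs$hap, gs$contig, gs$ref_pos0))
    hit <- is.na(src) & !is.na(m) & det$obs == gs$alt_base[ifelse(is.na(m), 1L, m)]
    src[hit] <- ifelse(gs$type[m[hit]] == "snv", "germline_snv",
                       "germline_indel")
  }
  gi <- genome$gins
  if (nrow(gi)) {
    m <- match(paste(det$hap, det$contig, det$hap_pos0),
               paste(gi$hap, gi$contig, gi$hap_pos0))
    hit <- is.na(src) & !is.na(m)
    src[hit] <- "germline_indel"
  }
  det$source <- src
  tab <- table(factor(src, levels = TRUTH_SOURCES))
  list(table = setNames(as.integer(tab), TRUTH_SOURCES),
       unattributed = sum(is.na(src)), details = det)
}

#' Write the truth set as VCF and TSV
#'
#' The VCF carries the source and its metadata in INFO (keys `SRC`, `TF`,
#' `CH`, `OR`, `HAP`, `RID`, flag `UNREP`); the TSV is a flat mirror.
#' Duplicate (position, alt, source, read) records are an error.
#'
#' @param records a [truth_records()] data.frame.
#' @param genome the generating `phased_genome` (for contig headers).
#' @param vcf_path,tsv_path output paths; either may be `NULL` to skip.
#' @return list of written paths, invisibly.
#' @export
write_truth <- function(records, genome, vcf_path = NULL, tsv_path = NULL) {
  key <- paste(records$contig, records$pos, records$alt, records$source,
               records$read_id)
  if (anyDuplicated(key)) stopf("duplicate truth record(s)")
  records <- records[order(records$contig, records$pos), , drop = FALSE]
  if (!is.null(tsv_path)) {
    write.table(records, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=somaticsim",
             sprintf("##contig=<ID=%s,length=%d>", genome$contigs,
                     nchar(genome$ref[genome$contigs])),
             "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Source of the non-reference allele\">",
             "##INFO=<ID=TF,Number=1,Type=Float,Description=\"True allele frequency\">",
             "##INFO=<ID=CH,Number=1,Type=String,Description=\"SBS channel of a damage artefact\">",
             "##INFO=<ID=OR,Number=1,Type=String,Description=\"Orientation class of a damage artefact\">",
             "##INFO=<ID=HAP,Number=1,Type=String,Description=\"Haplotype carrying the allele\">",
             "##INFO=<ID=RID,Number=1,Type=String,Description=\"Read id of a sequencing error\">",
             "##INFO=<ID=UNREP,Number=0,Type=Flag,Description=\"No read supports the allele\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      f <- c(paste0("SRC=", r$source),
             if (!is.na(r$true_f)) sprintf("TF=%.6g", r$true_f),
             if (!is.na(r$channel)) paste0("CH=", r$channel),
             if (!is.na(r$orientation)) paste0("OR=", r$orientation),
             if (!is.na(r$hap)) paste0("HAP=", r$hap),
             if (!is.na(r$read_id)) paste0("RID=", r$read_id),
             if (isTRUE(r$unrepresented)) "UNREP")
      paste(f, collapse = ";")
    }, character(1))
    body <- if (nrow(records))
      paste(records$contig, records$pos, ".", records$ref,
            records$alt, ".", ".", info, sep = "\t") else character(0)
    writeLines(c(hdr, body), vcf_path)
  }
  invisible(list(vcf = vcf_path, tsv = tsv_path))
}

#' Read a truth TSV back
#' @param tsv_path path written by [write_truth()].
#' @return the truth data.frame.
#' @export
read_truth <- function(tsv_path) {
  read.table(tsv_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA", colClasses = c(pos = "integer"))
}

#' Audit read placement after (external) realignment
#'
#' Compares each read's current alignment start with its `XT` true-position
#' tag and flags moved reads; optionally counts, per variant, how many of
#' its alternate-supporting reads were mis-placed.
#'
#' @param alignments a BAM/SAM path or a [read_alignments()] data.frame
#'   with columns `pos` and `xt` (both 1-based).
#' @param variants optional data.frame (`contig`, `pos`, `alt`) with a
#'   `read_ids` list-column of supporting read ids.
#' @return object of class `misalignment_report`: `n_reads`, `n_flagged`,
#'   `n_missing_tag`, `flagged` (read table subset), and optional
#'   `per_variant` counts.
#' @export
audit_alignment <- function(alignments, variants = NULL) {
  aln <- if (is.character(alignments)) read_alignments(alignments) else
    alignments
  has_tag <- !is.na(aln$xt)
  flagged <- has_tag & aln$pos != aln$xt
  per_variant <- NULL
  if (!is.null(variants) && nrow(variants)) {
    ids <- paste0(aln$qname, "/", aln$mate)
    per_variant <- vapply(seq_len(nrow(variants)), function(i) {
      sup <- variants$read_ids[[i]]
      sum(flagged[ids %in% sup])
    }, integer(1))
    per_variant <- data.frame(contig = variants$contig, pos = variants$pos,
                              n_misplaced = per_variant)
  }
  structure(list(n_reads = nrow(aln), n_flagged = sum(flagged),
                 n_missing_tag = sum(!has_tag),
                 flagged = aln[flagged, , drop = FALSE],
                 per_variant = per_variant),
            class = "misalignment_report")
}

#' @export
print.misalignment_report <- function(x, ...) {
  cat(sprintf("misalignment_report: %d/%d read(s) moved; %d without XT tag\n",
              x$n_flagged, x$n_reads, x$n_missing_tag))
  invisible(x)
}
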