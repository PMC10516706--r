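# SAM/BAM serialization of simulated reads.  Reads are written in
# haplotype-true coordinates against per-haplotype contigs named
# "<contig>#maternal" / "<contig>#paternal".  Custom tags make the truth
# auditable after external realignment:
#   XH:Z haplotype of origin
#   XT:i true reference-lifted 1-based start position
#   XO:Z fragment orientation ("F" = F1R2, "R" = F2R1)

#' Write simulated alignments as SAM (optionally BAM)
#'
#' Emits a coordinate-sorted SAM file with properly-paired FLAG bits and the
#' XH/XT/XO truth tags. With `bam = TRUE` the SAM is converted, sorted and
#' indexed via Rsamtools.
#'
#' @param sr a `sim_reads` object.
#' @param path output path (`.sam`; with `bam = TRUE` the `.bam` path is
#'   derived from it).
#' @param bam also produce a coordinate-sorted, indexed BAM.
#' @return the path of the written SAM (or BAM when `bam = TRUE`),
#'   invisibly.
#' @export
write_alignments <- function(sr, path, bam = FALSE) {
  genome <- sr$genome
  rl <- sr$params$read_len
  reads <- sr$reads
  frag <- sr$fragments[match(reads$frag_id, sr$fragments$frag_id), ]

  rname <- paste0(reads$contig, "#", reads$hap)
  flag <- 1L + 2L +
    ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$strand == "+", 32L, 0L) +   # mate is the opposite strand
    ifelse(reads$mate == 1L, 64L, 128L)
  pos <- reads$start + 1L
  mate_start <- ifelse(reads$strand == "+",
                       frag$start + frag$insert - rl, frag$start)
  tlen <- ifelse(reads$strand == "+", frag$insert, -frag$insert)
  xt <- integer(nrow(reads))
  key <- paste(reads$hap, reads$contig)
  for (k in unique(key)) {
    i <- which(key == k)
    xt[i] <- hap_to_ref(genome, reads$hap[i[1]], reads$contig[i[1]],
                        reads$start[i])
  }
  xt_field <- ifelse(is.na(xt), "XT:i:-1", paste0("XT:i:", xt + 1L))

  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           unlist(lapply(genome$contigs, function(ctg) {
             vapply(HAPS, function(h) {
               sprintf("@SQ\tSN:%s#%s\tLN:%d", ctg, h,
                       nchar(genome$hap[[h]][[ctg]]))
             }, character(1))
           })),
           "@PG\tID:somaticsim\tPN:somaticsim")
  body <- paste(reads$frag_id, flag, rname, pos, 60L, paste0(rl, "M"), "=",
                mate_start + 1L, tlen, reads$seq, reads$qual,
                paste0("XH:Z:", reads$hap), xt_field,
                paste0("XO:Z:", frag$orientation), sep = "\t")
  body <- body[order(rname, pos)]
  writeLines(c(hdr, body), path)
  if (bam) {
    bam_path <- Rsamtools::asBam(path, sub("\\.sam$", "", path),
                                 overwrite = TRUE, indexDestination = TRUE)
    return(invisible(bam_path))
  }
  invisible(path)
}

#' Read alignments back from SAM/BAM
#'
#' Reads a BAM (or converts a SAM first) and returns one row per record with
#' the XH/XT/XO tags; used for round-trip checks and misalignment audits.
#'
#' @param path a `.sam` or `.bam` path.
#' @return data.frame with qname, flag, contig, pos (1-based), strand, mate,
#'   seq, qual, and tags `xh`, `xt` (1-based reference start; `NA` when the
#'   tag is absent or was unmapped), `xo`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "seq", "qual"),
    tag = c("XH", "XT", "XO"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  xt <- b$tag$XT %||% rep(NA_integer_, n)
  xt[!is.na(xt) & xt < 0] <- NA_integer_
  data.frame(qname = b$qname, flag = b$flag, contig = as.character(b$rname),
             pos = b$pos, strand = as.character(b$strand),
             mate = ifelse(bitwAnd(b$flag, 64L) > 0L, 1L, 2L),
             seq = as.character(b$seq), qual = as.character(b$qual),
             xh = b$tag$XH %||% rep(NA_character_, n), xt = xt,
             xo = b$tag$XO %||% rep(NA_character_, n),
             stringsAsFactors = FALSE)
}
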