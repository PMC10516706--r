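# Personalized phased diploid genome: reference + phased germline variants
# applied per haplotype, with bidirectional coordinate liftover.  The left
# allele of a phased genotype is the maternal haplotype by convention.

HAPS <- c("maternal", "paternal")

#' Build a personalized phased diploid genome
#'
#' Applies phased germline SNVs and indels to a reference, producing one
#' sequence per haplotype together with a monotone coordinate liftover
#' between haplotype and reference space.  Positions deleted on a haplotype
#' have no image ("deleted" rather than interpolated); inserted haplotype
#' bases map to `NA` in reference space.
#'
#' @param reference named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param germline phased germline variants: a data.frame with columns
#'   `contig`, `pos` (1-based), `ref`, `alt`, `gt` (e.g. `"0|1"`), or a VCF
#'   path.  Multi-allelic records are split; symbolic alleles are rejected;
#'   unphased genotypes are dropped with a warning; a REF allele that does
#'   not match the reference, or two retained records overlapping on the
#'   same haplotype, is an error.
#' @return an object of class `phased_genome` with elements `contigs`,
#'   `ref`, `hap` (per-haplotype sequences), `lift` (per-haplotype block
#'   maps), `germline` (retained records with `gt_maternal`/`gt_paternal`),
#'   and internal substitution/insertion indices used for truth attribution.
#' @export
#' @examples
#' ref <- c(chr = "ACGTACGT")
#' g <- data.frame(contig = "chr", pos = 3, ref = "G", alt = "C", gt = "1|0")
#' pg <- build_phased_genome(ref, g)
#' pg$hap$maternal[["chr"]]
build_phased_genome <- function(reference, germline) {
  ref <- as_seq_vector(reference)
  germ <- normalize_germline(germline, ref)

  lift <- list(); hapseq <- list()
  gsub_list <- list(); gins_list <- list()
  for (h in HAPS) {
    lift[[h]] <- list(); hapseq[[h]] <- character(0)
    for (ctg in names(ref)) {
      vars <- germ[germ$contig == ctg & germ[[paste0("gt_", h)]] == 1L, ,
                   drop = FALSE]
      vars <- vars[order(vars$pos), , drop = FALSE]
      built <- apply_haplotype(ref[[ctg]], vars, ctg, h)
      hapseq[[h]][ctg] <- built$seq
      lift[[h]][[ctg]] <- built$blocks
      gsub_list[[length(gsub_list) + 1L]] <- built$gsub
      gins_list[[length(gins_list) + 1L]] <- built$gins
    }
  }
  empty_gsub <- data.frame(hap = character(), contig = character(),
                           ref_pos0 = integer(), alt_base = character(),
                           type = character(), stringsAsFactors = FALSE)
  empty_gins <- data.frame(hap = character(), contig = character(),
                           hap_pos0 = integer(), base = character(),
                           stringsAsFactors = FALSE)
  gsub <- if (length(gsub_list)) do.call(rbind, gsub_list) else empty_gsub
  gins <- if (length(gins_list)) do.call(rbind, gins_list) else empty_gins
  structure(list(contigs = names(ref), ref = ref, hap = hapseq, lift = lift,
                 germline = germ, gsub = gsub, gins = gins),
            class = "phased_genome")
}

# Apply sorted variants of one haplotype/contig.  Returns the haplotype
# sequence, liftover blocks (hs = hap start, rs = ref start or NA for
# insertions, len), substituted reference positions and inserted hap bases.
apply_haplotype <- function(refseq, vars, ctg, hap) {
  pieces <- character(0)
  hs <- integer(0); rs <- integer(0); len <- integer(0)
  gsub <- list(); gins <- list()
  cursor <- 0L     # next unconsumed reference position (0-based)
  hcur <- 0L       # next haplotype position
  nref <- nchar(refseq)
  add_block <- function(h, r, l) {
    if (l > 0L) { hs <<- c(hs, h); rs <<- c(rs, r); len <<- c(len, l) }
  }
  for (i in seq_len(nrow(vars))) {
    p0 <- vars$pos[i] - 1L
    ra <- vars$ref[i]; aa <- vars$alt[i]
    nr <- nchar(ra); na <- nchar(aa)
    if (p0 < cursor)
      stopf("overlapping germline records on %s haplotype at %s:%d",
            hap, ctg, vars$pos[i])
    if (p0 + nr > nref)
      stopf("germline record at %s:%d extends past contig end", ctg, vars$pos[i])
    if (substr(refseq, p0 + 1L, p0 + nr) != ra)
      stopf("REF allele mismatch at %s:%d: VCF '%s' vs reference '%s'",
            ctg, vars$pos[i], ra, substr(refseq, p0 + 1L, p0 + nr))
    pre <- p0 - cursor
    if (pre > 0L) {
      pieces <- c(pieces, substr(refseq, cursor + 1L, p0))
      add_block(hcur, cursor, pre)
      hcur <- hcur + pre
    }
    m <- min(nr, na)
    if (m > 0L) {
      sub_piece <- substr(aa, 1L, m)
      pieces <- c(pieces, sub_piece)
      add_block(hcur, p0, m)
      # record substituted reference positions (differing bases only)
      rch <- strsplit(substr(ra, 1L, m), "")[[1]]
      ach <- strsplit(sub_piece, "")[[1]]
      d <- which(rch != ach)
      if (length(d)) {
        gsub[[length(gsub) + 1L]] <- data.frame(
          hap = hap, contig = ctg, ref_pos0 = p0 + d - 1L, alt_base = ach[d],
          type = if (nr == 1L && na == 1L) "snv" else "indel",
          stringsAsFactors = FALSE)
      }
      hcur <- hcur + m
    }
    if (na > nr) {          # insertion: hap-only block
      ins <- substr(aa, m + 1L, na)
      pieces <- c(pieces, ins)
      add_block(hcur, NA_integer_, na - m)
      gins[[length(gins) + 1L]] <- data.frame(
        hap = hap, contig = ctg, hap_pos0 = hcur + seq_len(na - m) - 1L,
        base = strsplit(ins, "")[[1]], stringsAsFactors = FALSE)
      hcur <- hcur + (na - m)
    }
    cursor <- p0 + nr       # nr > na: deleted ref bases simply skipped
  }
  if (cursor < nref) {
    pieces <- c(pieces, substr(refseq, cursor + 1L, nref))
    add_block(hcur, cursor, nref - cursor)
  }
  list(seq = paste(pieces, collapse = ""),
       blocks = data.frame(hs = hs, rs = rs, len = len),
       gsub = if (length(gsub)) do.call(rbind, gsub) else NULL,
       gins = if (length(gins)) do.call(rbind, gins) else NULL)
}

# Germline input normalization: VCF path or data.frame -> one row per
# (biallelic) applied allele with integer gt per haplotype.
normalize_germline <- function(germline, ref) {
  if (is.character(germline) && length(germline) == 1L) {
    germline <- read_germline_vcf(germline)
  }
  need <- c("contig", "pos", "ref", "alt", "gt")
  if (!nrow(germline)) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), gt_maternal = integer(),
                      gt_paternal = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(all(need %in% names(germline)))
  out <- list()
  for (i in seq_len(nrow(germline))) {
    gt <- germline$gt[i]
    if (!grepl("|", gt, fixed = TRUE)) {
      warnf("dropping unphased genotype '%s' at %s:%d", gt,
            germline$contig[i], germline$pos[i])
      next
    }
    al <- as.integer(strsplit(gt, "|", fixed = TRUE)[[1]][1:2])
    alts <- strsplit(germline$alt[i], ",", fixed = TRUE)[[1]]
    if (any(grepl("^<", alts)))
      stopf("symbolic allele not supported at %s:%d",
            germline$contig[i], germline$pos[i])
    for (a in seq_along(alts)) {
      gm <- as.integer(al[1] == a); gp <- as.integer(al[2] == a)
      if (gm == 0L && gp == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        contig = as.character(germline$contig[i]),
        pos = as.integer(germline$pos[i]),
        ref = toupper(germline$ref[i]), alt = toupper(alts[a]),
        gt_maternal = gm, gt_paternal = gp, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(normalize_germline(
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), gt = character()), ref))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$pos), , drop = FALSE]
}

read_germline_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!nrow(v@fix)) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), gt = character()))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  data.frame(contig = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             ref = as.character(v@fix[, "REF"]),
             alt = as.character(v@fix[, "ALT"]),
             gt = as.character(gt), stringsAsFactors = FALSE)
}

#' Lift haplotype coordinates to reference coordinates
#'
#' @param genome a `phased_genome`.
#' @param hap `"maternal"` or `"paternal"`.
#' @param contig contig name.
#' @param pos0 integer vector of 0-based haplotype positions.
#' @return integer vector of 0-based reference positions; `NA` for inserted
#'   haplotype bases (no reference image) or out-of-range input.
#' @export
hap_to_ref <- function(genome, hap, contig, pos0) {
  b <- genome$lift[[hap]][[contig]]
  if (is.null(b) || !nrow(b)) return(rep(NA_integer_, length(pos0)))
  i <- findInterval(pos0, b$hs)
  ok <- i >= 1L & !is.na(pos0)
  ok[ok] <- pos0[ok] < b$hs[i[ok]] + b$len[i[ok]]
  out <- rep(NA_integer_, length(pos0))
  out[ok] <- b$rs[i[ok]] + (pos0[ok] - b$hs[i[ok]])
  out
}

#' Lift reference coordinates to haplotype coordinates
#'
#' @inheritParams hap_to_ref
#' @param pos0 integer vector of 0-based reference positions.
#' @return integer vector of 0-based haplotype positions; `NA` where the
#'   position is deleted on that haplotype.
#' @export
ref_to_hap <- function(genome, hap, contig, pos0) {
  b <- genome$lift[[hap]][[contig]]
  if (is.null(b) || !nrow(b)) return(rep(NA_integer_, length(pos0)))
  m <- b[!is.na(b$rs), , drop = FALSE]
  i <- findInterval(pos0, m$rs)
  ok <- i >= 1L & !is.na(pos0)
  ok[ok] <- pos0[ok] < m$rs[i[ok]] + m$len[i[ok]]
  out <- rep(NA_integer_, length(pos0))
  out[ok] <- m$hs[i[ok]] + (pos0[ok] - m$rs[i[ok]])
  out
}

#' @export
print.phased_genome <- function(x, ...) {
  cat("phased_genome:", length(x$contigs), "contig(s),",
      nrow(x$germline), "applied germline allele record(s)\n")
  for (ctg in x$contigs) {
    cat(sprintf("  %s: ref %d bp | maternal %d bp | paternal %d bp\n", ctg,
                nchar(x$ref[[ctg]]), nchar(x$hap$maternal[[ctg]]),
                nchar(x$hap$paternal[[ctg]])))
  }
  invisible(x)
}

#' Write the two haplotype sequences as FASTA
#'
#' Contigs are named `<contig>#maternal` / `<contig>#paternal`.
#' @param genome a `phased_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_phased_fasta <- function(genome, path) {
  seqs <- c(genome$hap$maternal, genome$hap$paternal)
  names(seqs) <- c(paste0(genome$contigs, "#maternal"),
                   paste0(genome$contigs, "#paternal"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
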