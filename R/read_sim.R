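# Minimal paired-end read simulator over the phased genome.  Fragments are
# placed uniformly over the (haplotype-lifted) target; every miscalled base
# is logged, so the simulator's output carries a complete per-base error
# record.  Reads are stored in aligned (genomic forward-strand) orientation
# in haplotype-true coordinates.
#
# Fragment orientation: "F" means the first-in-pair read aligns to the
# forward genomic strand (F1R2); "R" means F2R1.

#' Simulate paired-end fragments over a phased genome
#'
#' Fragments are drawn uniformly over the target, split evenly between the
#' two haplotypes, so that the expected read-base depth over interior
#' positions approximates `mean_depth`.  Sequencing errors are injected
#' per cycle at the configured rates and every miscalled base is logged
#' (read id, haplotype and reference coordinates, true and observed base).
#'
#' @param genome a [build_phased_genome()] result.
#' @param target target intervals (reference coordinates, 0-based
#'   half-open).
#' @param mean_depth target mean read-base depth (e.g. 100 for 100x).
#' @param read_len read length in bases (default 100).
#' @param insert_mean,insert_sd fragment-length distribution (normal,
#'   rounded, clamped to at least `read_len`). Defaults 300 / 30.
#' @param error_rate per-base miscall probability: a scalar or a
#'   per-cycle vector of length `read_len`, each in `[0, 1)`. Default 1e-3.
#' @param seed optional RNG seed.
#' @return object of class `sim_reads`: `fragments` (one row per fragment:
#'   haplotype, contig, start, insert length, orientation), `reads` (two
#'   rows per fragment: mate, strand, haplotype start, sequence, quality),
#'   `error_log`, empty spike/damage truth tables, and the generating
#'   `genome`/`params`.
#' @export
simulate_fragments <- function(genome, target, mean_depth, read_len = 100L,
                               insert_mean = 300L, insert_sd = 30L,
                               error_rate = 1e-3, seed = NULL) {
  stopifnot(inherits(genome, "phased_genome"), mean_depth > 0, read_len > 0)
  target <- validate_target(target)
  if (!nrow(target)) stopf("target is empty")
  if (length(error_rate) == 1L) error_rate <- rep(error_rate, read_len)
  stopifnot(length(error_rate) == read_len, all(error_rate >= 0),
            all(error_rate < 1))
  maybe_seed(seed)

  frag_rows <- list()
  for (h in HAPS) {
    iv <- lift_target_to_hap(genome, h, target)
    too_short <- iv$len < read_len
    if (any(too_short)) {
      warnf("%d target interval(s) shorter than the read length skipped",
            sum(too_short))
      iv <- iv[!too_short, , drop = FALSE]
    }
    if (!nrow(iv)) next
    # effective length discounts fragment-edge loss so interior depth
    # calibrates to mean_depth
    iv$eff <- pmax(iv$len - insert_mean, read_len)
    n_h <- round(mean_depth * sum(iv$eff) / (4 * read_len))
    if (n_h == 0L) next
    pick <- sample.int(nrow(iv), n_h, replace = TRUE, prob = iv$eff)
    ins <- pmax(read_len, round(rnorm(n_h, insert_mean, insert_sd)))
    ins <- pmin(ins, iv$len[pick])
    start <- iv$hs[pick] +
      floor(runif(n_h) * (iv$len[pick] - ins + 1))
    frag_rows[[h]] <- data.frame(
      hap = h, contig = iv$contig[pick], start = as.integer(start),
      insert = as.integer(ins),
      orientation = ifelse(runif(n_h) < 0.5, "F", "R"),
      stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frag_rows)
  if (is.null(frags) || !nrow(frags)) stopf("no fragments simulated")
  rownames(frags) <- NULL
  frags$frag_id <- sprintf("frag%07d", seq_len(nrow(frags)))

  # two reads per fragment: left mate on "+", right mate on "-"
  left_mate <- ifelse(frags$orientation == "F", 1L, 2L)
  reads <- data.frame(
    frag_id = rep(frags$frag_id, each = 2L),
    hap = rep(frags$hap, each = 2L),
    contig = rep(frags$contig, each = 2L),
    mate = as.integer(rbind(left_mate, 3L - left_mate)),
    strand = rep(c("+", "-"), nrow(frags)),
    start = as.integer(rbind(frags$start,
                             frags$start + frags$insert - read_len)),
    stringsAsFactors = FALSE)
  reads$read_id <- paste0(reads$frag_id, "/", reads$mate)

  # true sequences from the haplotype
  key <- paste(reads$hap, reads$contig)
  seqs <- character(nrow(reads))
  for (k in unique(key)) {
    idx <- which(key == k)
    hs <- genome$hap[[reads$hap[idx[1]]]][[reads$contig[idx[1]]]]
    seqs[idx] <- substring(hs, reads$start[idx] + 1L,
                           reads$start[idx] + read_len)
  }
  reads$seq <- seqs

  # per-cycle qualities; '-' reads store the aligned (reversed) cycle order
  qual_fwd <- phred_chars(error_rate)
  qual_rev <- paste(rev(strsplit(qual_fwd, "")[[1]]), collapse = "")
  reads$qual <- ifelse(reads$strand == "+", qual_fwd, qual_rev)

  # inject sequencing errors; cycle i of a '-' read is aligned offset
  # read_len - i
  if (all(error_rate == 0)) {
    hit <- integer(0)
  } else {
    nb <- nrow(reads) * read_len
    offset <- rep(seq_len(read_len) - 1L, times = nrow(reads))
    row_of <- rep(seq_len(nrow(reads)), each = read_len)
    cyc <- ifelse(reads$strand[row_of] == "+", offset + 1L,
                  read_len - offset)
    hit <- which(runif(nb) < error_rate[cyc])
  }
  err <- NULL
  if (length(hit)) {
    r <- row_of[hit]; off <- offset[hit]
    true_b <- substring(reads$seq[r], off + 1L, off + 1L)
    obs_b <- vapply(true_b, function(b)
      sample(setdiff(BASES, b), 1L), character(1), USE.NAMES = FALSE)
    for (j in seq_along(hit)) {
      substr(reads$seq[r[j]], off[j] + 1L, off[j] + 1L) <- obs_b[j]
    }
    hp <- reads$start[r] + off
    rp <- integer(length(hit))
    kk <- paste(reads$hap[r], reads$contig[r])
    for (k in unique(kk)) {
      i2 <- which(kk == k)
      rp[i2] <- hap_to_ref(genome, reads$hap[r[i2[1]]],
                           reads$contig[r[i2[1]]], hp[i2])
    }
    err <- data.frame(read_id = reads$read_id[r], hap = reads$hap[r],
                      contig = reads$contig[r], hap_pos0 = hp, ref_pos0 = rp,
                      true_base = true_b, obs_base = obs_b,
                      qual = cyc[hit], superseded = FALSE,
                      stringsAsFactors = FALSE)
  }
  if (is.null(err)) {
    err <- data.frame(read_id = character(), hap = character(),
                      contig = character(), hap_pos0 = integer(),
                      ref_pos0 = integer(), true_base = character(),
                      obs_base = character(), qual = integer(),
                      superseded = logical(), stringsAsFactors = FALSE)
  }

  sr <- structure(list(
    genome = genome, target = target,
    params = list(mean_depth = mean_depth, read_len = as.integer(read_len),
                  insert_mean = insert_mean, insert_sd = insert_sd,
                  error_rate = error_rate),
    fragments = frags, reads = reads, error_log = err,
    spikes = empty_spike_log(), somatic = empty_somatic_table(),
    damage = empty_damage_table()), class = "sim_reads")
  index_reads(sr)
}

empty_spike_log <- function() {
  data.frame(read_id = character(), hap = character(), contig = character(),
             hap_pos0 = integer(), ref_pos0 = integer(),
             prev_base = character(), alt = character(), source = character(),
             variant_id = character(), stringsAsFactors = FALSE)
}
empty_somatic_table <- function() {
  data.frame(variant_id = character(), contig = character(), pos = integer(),
             ref = character(), alt = character(), hap = character(),
             true_f = numeric(), mode = character(), n_overlap = integer(),
             n_edited = integer(), skipped = logical(),
             stringsAsFactors = FALSE)
}
empty_damage_table <- function() {
  data.frame(site_id = character(), contig = character(), pos = integer(),
             ref = character(), alt = character(), channel = character(),
             orientation = character(), vaf = numeric(),
             n_overlap = integer(), n_edited = integer(),
             stringsAsFactors = FALSE)
}

# Sort reads by (hap, contig, start) and build a per-group start index for
# O(log n) coverage queries; called whenever read positions change (never
# after simulation, edits only change bases).
index_reads <- function(sr) {
  o <- order(sr$reads$hap, sr$reads$contig, sr$reads$start)
  sr$reads <- sr$reads[o, , drop = FALSE]
  rownames(sr$reads) <- NULL
  key <- paste(sr$reads$hap, sr$reads$contig, sep = "\r")
  idx <- lapply(split(seq_len(nrow(sr$reads)), key), function(rows) {
    list(rows = rows, starts = sr$reads$start[rows])
  })
  attr(sr, "read_index") <- idx
  sr
}

#' Reads of one haplotype covering a reference position
#'
#' @param sr a `sim_reads` object.
#' @param hap `"maternal"` or `"paternal"`.
#' @param contig contig name.
#' @param ref_pos0 0-based reference position (lifted internally).
#' @return read ids of the covering reads of that haplotype.
#' @export
reads_covering <- function(sr, hap, contig, ref_pos0) {
  hp <- ref_to_hap(sr$genome, hap, contig, ref_pos0)
  sr$reads$read_id[reads_at(sr, hap, contig, hp)]
}

# Row indices of reads covering 0-based haplotype position hp0.
reads_at <- function(sr, hap, contig, hp0) {
  g <- attr(sr, "read_index")[[paste(hap, contig, sep = "\r")]]
  if (is.null(g) || is.na(hp0)) return(integer(0))
  rl <- sr$params$read_len
  lo <- findInterval(hp0 - rl, g$starts) + 1L
  hi <- findInterval(hp0, g$starts)
  if (hi < lo) return(integer(0))
  g$rows[lo:hi]
}

# Lift a reference-space target to haplotype coordinates; interval ends are
# nudged inwards past deleted bases.
lift_target_to_hap <- function(genome, hap, target) {
  out <- lapply(seq_len(nrow(target)), function(i) {
    s <- target$start[i]; e <- target$end[i]; ctg <- target$contig[i]
    span <- seq.int(s, e - 1L)
    hp <- ref_to_hap(genome, hap, ctg, span)
    ok <- which(!is.na(hp))
    if (!length(ok)) return(NULL)
    data.frame(contig = ctg, hs = hp[ok[1]],
               len = hp[ok[length(ok)]] - hp[ok[1]] + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(contig = character(), hs = integer(),
                               len = integer())
  else out
}

#' Pileup base counts at reference positions
#'
#' Counts observed bases over both haplotypes at the requested reference
#' positions (1-based), lifting each haplotype's reads through the phased
#' genome's coordinate map.
#'
#' @param sr a `sim_reads` object.
#' @param positions data.frame with columns `contig` and `pos` (1-based
#'   reference positions).
#' @return data.frame with `contig`, `pos`, `ref`, `depth` and one count
#'   column per base `A`/`C`/`G`/`T`.
#' @export
pileup_at <- function(sr, positions) {
  genome <- sr$genome
  n <- nrow(positions)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  depth <- integer(n)
  refb <- character(n)
  for (i in seq_len(n)) {
    ctg <- positions$contig[i]; p0 <- positions$pos[i] - 1L
    refb[i] <- substr(genome$ref[[ctg]], p0 + 1L, p0 + 1L)
    for (h in HAPS) {
      hp <- ref_to_hap(genome, h, ctg, p0)
      rows <- reads_at(sr, h, ctg, hp)
      if (!length(rows)) next
      b <- substring(sr$reads$seq[rows], hp - sr$reads$start[rows] + 1L,
                     hp - sr$reads$start[rows] + 1L)
      tb <- table(factor(b, levels = BASES))
      counts[i, ] <- counts[i, ] + as.integer(tb)
      depth[i] <- depth[i] + length(rows)
    }
  }
  data.frame(contig = positions$contig, pos = positions$pos, ref = refb,
             depth = depth, counts, stringsAsFactors = FALSE)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(paste0("sim_reads: %d fragments (%d reads) at target depth ",
                     "%gx, read length %d\n"),
              nrow(x$fragments), nrow(x$reads), x$params$mean_depth,
              x$params$read_len))
  cat(sprintf("  sequencing errors logged: %d | somatic spike-ins: %d | ",
              nrow(x$error_log), nrow(x$somatic)))
  cat(sprintf("damage artefact sites: %d\n", nrow(x$damage)))
  invisible(x)
}
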