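# FFPE / 8-oxoG DNA-damage artefacts.
#
# Damage chemistry is strand-asymmetric: formalin fixation deaminates
# cytosine (C>T on the damaged strand), oxidative damage produces
# 8-oxoguanine (G>T, i.e. C>A in the pyrimidine-centred signature
# convention).  Artefact sites are drawn context-matched from a 96-channel
# single-base-substitution (SBS) signature and spiked so that all
# alternate-allele evidence at a site comes from fragments of ONE
# orientation class (F1R2 or F2R1); evidence on the opposite orientation
# can then arise only through sequencing error, which is exactly the escape
# route that defeats orientation-bias filters.

SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 pyrimidine-centred trinucleotide substitution channels
#'
#' COSMIC-style labels `"A[C>A]A"`, ordered by substitution, then 5' base,
#' then 3' base.
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  out <- character(0)
  for (s in SBS_SUBS) for (p5 in BASES) for (p3 in BASES)
    out <- c(out, sprintf("%s[%s]%s", p5, s, p3))
  out
}

# Normalize (ref triplet, ref, alt) to the pyrimidine-centred channel.
channel_of <- function(triplet, ref, alt) {
  pur <- ref %in% c("A", "G")
  t2 <- ifelse(pur, revcomp(triplet), triplet)
  r2 <- ifelse(pur, comp_base(ref), ref)
  a2 <- ifelse(pur, comp_base(alt), alt)
  sprintf("%s[%s>%s]%s", substr(t2, 1, 1), r2, a2, substr(t2, 3, 3))
}

new_sbs_signature <- function(w) {
  ch <- sbs_channels()
  stopifnot(all(names(w) %in% ch))
  full <- setNames(numeric(96), ch)
  full[names(w)] <- w
  if (any(full < 0)) stopf("negative signature weight")
  s <- sum(full)
  if (s <= 0) stopf("signature has zero total weight")
  structure(full / s, class = "sbs_signature")
}

#' Estimate a 96-channel SBS signature from SNV calls
#'
#' Counts each variant's trinucleotide context (reverse-complemented to the
#' pyrimidine-centred convention when the reference base is a purine) and
#' normalizes to channel probabilities.  This is how a damage signature is
#' estimated from variants private to an FFPE sample relative to its
#' fresh-frozen pair.
#'
#' @param variants data.frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`; non-SNV rows are skipped with a warning.
#' @param reference named character vector of contig sequences (or
#'   `DNAStringSet` / FASTA path).
#' @return an `sbs_signature` (named numeric vector over the 96 channels,
#'   summing to 1).
#' @export
estimate_sbs_signature <- function(variants, reference) {
  ref <- as_seq_vector(reference)
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% BASES & variants$alt %in% BASES
  if (any(!snv)) warnf("skipping %d non-SNV record(s)", sum(!snv))
  variants <- variants[snv, , drop = FALSE]
  if (!nrow(variants)) stopf("no SNVs to estimate a signature from")
  trip <- vapply(seq_len(nrow(variants)), function(i) {
    s <- ref[[variants$contig[i]]]
    p <- variants$pos[i]
    if (p < 2L || p > nchar(s) - 1L) return(NA_character_)
    substr(s, p - 1L, p + 1L)
  }, character(1))
  keep <- !is.na(trip)
  ch <- channel_of(trip[keep], variants$ref[keep], variants$alt[keep])
  new_sbs_signature(table(factor(ch, levels = sbs_channels())))
}

#' Load a COSMIC-format SBS signature table
#'
#' Accepts a TSV with a channel column in COSMIC `"A[C>A]A"` style plus one
#' numeric weight column; rows may be in any order.  Weights are validated
#' (96 unique channels) and renormalized to sum to 1.
#'
#' @param path TSV path (or a data.frame already read).
#' @param column name or index of the weight column; default: the first
#'   numeric column.
#' @return an `sbs_signature`.
#' @export
load_cosmic_signature <- function(path, column = NULL) {
  tab <- if (is.data.frame(path)) path else
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE)
  lab_col <- which(vapply(tab, function(x)
    any(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", as.character(x))),
    logical(1)))[1]
  if (is.na(lab_col)) stopf("no channel-label column found")
  labels <- as.character(tab[[lab_col]])
  if (is.null(column)) {
    column <- which(vapply(tab, is.numeric, logical(1)))[1]
    if (is.na(column)) stopf("no numeric weight column found")
  }
  w <- tab[[column]]
  bad <- setdiff(labels, sbs_channels())
  if (length(bad)) stopf("unknown channel label(s): %s",
                         paste(head(bad, 3), collapse = ", "))
  if (anyDuplicated(labels)) stopf("duplicate channel label(s)")
  if (length(labels) != 96L) stopf("expected 96 channels, got %d",
                                   length(labels))
  new_sbs_signature(setNames(w, labels))
}

#' Partition reads by fragment orientation
#'
#' Every read is assigned to exactly one class by its fragment's
#' orientation: F1R2 fragments (first-in-pair read aligned to the forward
#' genomic strand) to `forward`, F2R1 to `reverse`.
#'
#' @param sr a `sim_reads` object, or a data.frame of alignment records
#'   with `flag` and `qname` columns (unpaired reads are assigned by their
#'   own strand, with a message).
#' @return list with `forward` and `reverse` character vectors of read ids;
#'   the union is the input.
#' @export
partition_by_orientation <- function(sr) {
  if (inherits(sr, "sim_reads")) {
    ori <- sr$fragments$orientation[match(sr$reads$frag_id,
                                          sr$fragments$frag_id)]
    return(list(forward = sr$reads$read_id[ori == "F"],
                reverse = sr$reads$read_id[ori == "R"]))
  }
  stopifnot(is.data.frame(sr), all(c("flag", "qname") %in% names(sr)))
  paired <- bitwAnd(sr$flag, 1L) > 0L
  if (any(!paired)) message(sum(!paired), " unpaired read(s) assigned by own strand")
  first <- bitwAnd(sr$flag, 64L) > 0L
  self_rev <- bitwAnd(sr$flag, 16L) > 0L
  mate_rev <- bitwAnd(sr$flag, 32L) > 0L
  # F1R2: the first-in-pair read maps forward (for the second-in-pair
  # record that information sits in the mate-reverse bit)
  first_fwd <- ifelse(first, !self_rev, !mate_rev)
  cls <- ifelse(!paired, ifelse(self_rev, "reverse", "forward"),
                ifelse(first_fwd, "forward", "reverse"))
  id <- paste0(sr$qname, "/", ifelse(first, 1L, 2L))
  split(id, factor(cls, levels = c("forward", "reverse")))
}

#' Plan a DNA-damage artefact burden
#'
#' @param total_burden number of artefact sites to spike.
#' @param signature an `sbs_signature` giving the trinucleotide channel
#'   distribution of the damage process.
#' @param vaf_dist sampler for per-site artefact allele fractions: a
#'   function `n -> numeric`, default `Beta(1.5, 60)` (low-frequency
#'   artefacts, mean ~0.024); supply an empirical sampler to use measured
#'   artefact fractions.
#' @param target target intervals.
#' @return object of class `damage_plan`.
#' @export
damage_plan <- function(total_burden, signature,
                        vaf_dist = function(n) rbeta(n, 1.5, 60),
                        target = NULL) {
  stopifnot(inherits(signature, "sbs_signature"), total_burden >= 0)
  structure(list(total_burden = as.integer(total_burden),
                 signature = signature, vaf_dist = vaf_dist,
                 target = target), class = "damage_plan")
}

#' Spike DNA-damage artefacts into simulated reads
#'
#' Sites are drawn so that each artefact's trinucleotide context matches
#' its signature channel; the burden is split exactly in half between the
#' two fragment-orientation classes, with the class of each site chosen by
#' the damaged-strand chemistry (sites whose pyrimidine lies on the forward
#' genomic strand feed the forward/F1R2 class).  At each site an allele
#' fraction is drawn from the plan's `vaf_dist` and fragments of that ONE
#' orientation class are edited per-fragment Bernoulli with probability
#' `min(2 vaf, 1)`, so the marginal alternate fraction over all fragments
#' matches the drawn fraction and all pre-error alternate evidence shares
#' one orientation.  Artefact sites avoid germline and somatic loci.
#'
#' @param sr a `sim_reads` object.
#' @param plan a [damage_plan()]; its `target` defaults to `sr$target`.
#' @param seed optional RNG seed.
#' @param max_tries rejection-sampling cap per site before the channel is
#'   resampled (with a message).
#' @return the edited `sim_reads`; `$damage` gains one row per artefact
#'   site and `$spikes` one row per edited read base (source
#'   `damage_artefact`).
#' @export
spike_damage <- function(sr, plan, seed = NULL, max_tries = 50L) {
  stopifnot(inherits(plan, "damage_plan"))
  maybe_seed(seed)
  if (plan$total_burden == 0L) return(sr)
  genome <- sr$genome
  target <- plan$target %||% sr$target

  # context index over target positions, stratified by pyrimidine strand
  pool <- target_positions(target)
  ctx <- context_table(genome$ref, pool)
  used <- character(0)
  if (nrow(genome$germline))
    used <- c(used, paste(genome$germline$contig, genome$germline$pos))
  if (nrow(sr$somatic))
    used <- c(used, paste(sr$somatic$contig, sr$somatic$pos))
  ctx <- ctx[!(paste(ctx$contig, ctx$pos0 + 1L) %in% used), , drop = FALSE]

  n_fwd <- ceiling(plan$total_burden / 2)
  n_rev <- plan$total_burden - n_fwd
  site_list <- list()
  for (cls in c("forward", "reverse")) {
    n_cls <- if (cls == "forward") n_fwd else n_rev
    if (n_cls == 0L) next
    sub <- ctx[ctx$pyr_strand == (if (cls == "forward") "+" else "-"), ,
               drop = FALSE]
    # index positions by pyrimidine-centred context (16 x 2 centres)
    by_ctx <- split(seq_len(nrow(sub)), sub$pyr_context)
    taken <- rep(FALSE, nrow(sub))
    drawn <- 0L
    while (drawn < n_cls) {
      chan <- sample(sbs_channels(), 1L, prob = plan$signature)
      key <- paste0(substr(chan, 1, 1), substr(chan, 3, 3), substr(chan, 7, 7))
      cand <- by_ctx[[key]]
      cand <- if (is.null(cand)) integer(0) else cand[!taken[cand]]
      tries <- 0L
      while (!length(cand) && tries < max_tries) {
        message("no untaken locus for channel ", chan, "; resampling channel")
        chan <- sample(sbs_channels(), 1L, prob = plan$signature)
        key <- paste0(substr(chan, 1, 1), substr(chan, 3, 3),
                      substr(chan, 7, 7))
        cand <- by_ctx[[key]]
        cand <- if (is.null(cand)) integer(0) else cand[!taken[cand]]
        tries <- tries + 1L
      }
      if (!length(cand)) stopf("cannot place channel %s in target", chan)
      pick <- cand[sample.int(length(cand), 1L)]
      taken[pick] <- TRUE
      drawn <- drawn + 1L
      # alternate base on the reference strand
      alt_pyr <- substr(chan, 5, 5)
      alt_ref <- if (sub$pyr_strand[pick] == "+") alt_pyr else
        comp_base(alt_pyr)
      site_list[[length(site_list) + 1L]] <- data.frame(
        contig = sub$contig[pick], pos = sub$pos0[pick] + 1L,
        ref = sub$ref_base[pick], alt = alt_ref, channel = chan,
        orientation = cls, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_list)
  sites$vaf <- plan$vaf_dist(nrow(sites))
  sites$site_id <- sprintf("dmg%07d", seq_len(nrow(sites)) +
                             nrow(sr$damage))

  # edit fragments of the site's orientation class only
  ori_cls <- ifelse(sr$fragments$orientation == "F", "forward", "reverse")
  names(ori_cls) <- sr$fragments$frag_id
  seqs <- sr$reads$seq
  err_key <- paste(sr$error_log$read_id, sr$error_log$hap_pos0)
  spikes <- vector("list", nrow(sites))
  n_overlap <- integer(nrow(sites)); n_edited <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    rows <- integer(0); hps <- integer(0)
    for (h in HAPS) {
      hp <- ref_to_hap(genome, h, s$contig, s$pos - 1L)
      r <- reads_at(sr, h, s$contig, hp)
      rows <- c(rows, r); hps <- c(hps, rep(hp, length(r)))
    }
    in_cls <- ori_cls[sr$reads$frag_id[rows]] == s$orientation
    rows_cls <- rows[in_cls]; hps_cls <- hps[in_cls]
    frag_ids <- unique(sr$reads$frag_id[rows_cls])
    n_overlap[i] <- length(frag_ids)
    p <- min(2 * s$vaf, 1)
    chosen <- frag_ids[runif(length(frag_ids)) < p]
    n_edited[i] <- length(chosen)
    keep <- sr$reads$frag_id[rows_cls] %in% chosen
    er <- rows_cls[keep]; eh <- hps_cls[keep]
    if (!length(er)) next
    off <- eh - sr$reads$start[er]
    prev <- substring(seqs[er], off + 1L, off + 1L)
    for (j in seq_along(er)) {
      substr(seqs[er[j]], off[j] + 1L, off[j] + 1L) <- s$alt
    }
    spikes[[i]] <- data.frame(
      read_id = sr$reads$read_id[er], hap = sr$reads$hap[er],
      contig = s$contig, hap_pos0 = eh, ref_pos0 = s$pos - 1L,
      prev_base = prev, alt = s$alt, source = "damage_artefact",
      variant_id = s$site_id, stringsAsFactors = FALSE)
    hit <- err_key %in% paste(sr$reads$read_id[er], eh)
    if (any(hit)) sr$error_log$superseded[hit] <- TRUE
  }
  sr$reads$seq <- seqs
  new_spikes <- do.call(rbind, spikes[!vapply(spikes, is.null, logical(1))])
  if (!is.null(new_spikes)) sr$spikes <- rbind(sr$spikes, new_spikes)
  sites$n_overlap <- n_overlap; sites$n_edited <- n_edited
  sr$damage <- rbind(sr$damage,
                     sites[, c("site_id", "contig", "pos", "ref", "alt",
                               "channel", "orientation", "vaf", "n_overlap",
                               "n_edited")])
  sr
}

# Per-position pyrimidine-normalized context over a position pool.
context_table <- function(ref, pool) {
  out <- lapply(split(pool, pool$contig), function(p) {
    s <- ref[[p$contig[1]]]
    ok <- p$pos0 >= 1L & p$pos0 <= nchar(s) - 2L
    p <- p[ok, , drop = FALSE]
    trip <- substring(s, p$pos0, p$pos0 + 2L)
    centre <- substr(trip, 2, 2)
    pyr <- centre %in% c("C", "T")
    data.frame(contig = p$contig, pos0 = p$pos0, ref_base = centre,
               pyr_strand = ifelse(pyr, "+", "-"),
               pyr_context = pcontext(trip, pyr), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Pyrimidine-strand triplet key, e.g. "ACG" for A[C]G on the forward strand
# and for its reverse complement C[G]T.
pcontext <- function(trip, pyr) {
  t2 <- trip
  t2[!pyr] <- revcomp(trip[!pyr])
  t2
}

#' Simulate SNVs drawn from a known SBS signature
#'
#' Generative counterpart of [estimate_sbs_signature()]: draws channels from
#' the signature and places each variant at a uniformly chosen
#' context-matching position of the reference.  Used to validate signature
#' recovery.
#'
#' @param reference named character vector of contig sequences.
#' @param signature an `sbs_signature`.
#' @param n number of variants.
#' @param seed optional RNG seed.
#' @return data.frame with `contig`, `pos`, `ref`, `alt`, `channel`.
#' @export
simulate_signature_variants <- function(reference, signature, n,
                                        seed = NULL) {
  maybe_seed(seed)
  ref <- as_seq_vector(reference)
  pool <- do.call(rbind, lapply(names(ref), function(ctg)
    data.frame(contig = ctg, pos0 = seq.int(1L, nchar(ref[[ctg]]) - 2L),
               stringsAsFactors = FALSE)))
  ctx <- context_table(ref, pool)
  by_key <- split(seq_len(nrow(ctx)), paste(ctx$pyr_context, ctx$pyr_strand))
  chans <- sample(sbs_channels(), n, replace = TRUE, prob = signature)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    chan <- chans[i]
    key3 <- paste0(substr(chan, 1, 1), substr(chan, 3, 3),
                   substr(chan, 7, 7))
    cand <- c(by_key[[paste(key3, "+")]], by_key[[paste(key3, "-")]])
    if (!length(cand)) stopf("context %s absent from reference", key3)
    pick <- cand[sample.int(length(cand), 1L)]
    alt_pyr <- substr(chan, 5, 5)
    alt_ref <- if (ctx$pyr_strand[pick] == "+") alt_pyr else comp_base(alt_pyr)
    out[[i]] <- data.frame(contig = ctx$contig[pick], pos = ctx$pos0[pick] + 1L,
                           ref = ctx$ref_base[pick], alt = alt_ref,
                           channel = chan, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cosine similarity between two SBS signatures
#' @param a,b `sbs_signature` objects or numeric vectors over the channels.
#' @return cosine similarity in `[0, 1]`.
#' @export
signature_cosine <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' @export
print.sbs_signature <- function(x, ...) {
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("sbs_signature (96 channels); top channels:\n")
  for (i in seq_along(top))
    cat(sprintf("  %s  %.3f\n", names(top)[i], top[i]))
  invisible(x)
}

#' @export
plot.sbs_signature <- function(x, main = "SBS signature", ...) {
  cols <- rep(c("deepskyblue", "black", "red", "grey", "darkolivegreen3",
                "pink"), each = 16)
  barplot(unclass(x), col = cols, border = NA, names.arg = rep("", 96),
          main = main, ylab = "channel probability", ...)
  invisible(x)
}
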