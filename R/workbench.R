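# Desk-scale fixtures and pipeline orchestration.  Toy references and
# phased germline VCFs stand in for a real 1000 Genomes donor and an exome
# capture; everything is reproducible from a single master seed fanned out
# to per-stage child seeds.

#' Generate a toy reference sequence
#'
#' @param length contig length in bases (>= 1000).
#' @param gc GC fraction in `[0, 1]`; default 0.41, roughly genomic.
#' @param contig contig name.
#' @param seed optional RNG seed.
#' @param path optional FASTA output path.
#' @return named character vector of length 1 (invisible FASTA written
#'   when `path` is given).
#' @export
generate_toy_reference <- function(length = 50000L, gc = 0.41,
                                   contig = "chrS", seed = NULL,
                                   path = NULL) {
  if (is.na(gc) || gc < 0 || gc > 1) stopf("invalid GC fraction %s", gc)
  if (length < 1000L) stopf("reference shorter than 1 kb")
  maybe_seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(BASES, length, replace = TRUE, prob = p),
               collapse = "")
  out <- setNames(seq, contig)
  if (!is.null(path))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out), path)
  out
}

#' Generate a phased toy germline call set
#'
#' Random phased heterozygous/homozygous SNVs and short indels (1-5 bp) at
#' non-overlapping positions, valid as input to [build_phased_genome()].
#'
#' @param reference named character vector of contig sequences.
#' @param n_snv,n_indel variant counts.
#' @param het_frac fraction of heterozygous genotypes; default 2/3, the
#'   usual het/hom ratio of a human call set.
#' @param seed optional RNG seed.
#' @param path optional phased VCF output path.
#' @return germline data.frame (`contig`, `pos`, `ref`, `alt`, `gt`).
#' @export
generate_toy_germline <- function(reference, n_snv = 50L, n_indel = 5L,
                                  het_frac = 2 / 3, seed = NULL,
                                  path = NULL) {
  maybe_seed(seed)
  ref <- as_seq_vector(reference)
  n <- n_snv + n_indel
  if (n == 0L) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(), gt = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(path)) write_germline_vcf_file(out, ref, path)
    return(out)
  }
  ctg <- sample(names(ref), n, replace = TRUE,
                prob = nchar(ref) / sum(nchar(ref)))
  # keep a 10-bp exclusion zone between variants so records never overlap
  pos <- integer(n); guard <- 10L
  taken <- new.env()
  for (i in seq_len(n)) {
    L <- nchar(ref[[ctg[i]]])
    for (try in 1:200) {
      p <- sample.int(L - guard - 2L, 1L) + 1L
      cells <- paste(ctg[i], (p - guard):(p + guard))
      if (!any(vapply(cells, exists, logical(1), envir = taken))) break
      if (try == 200L) stopf("germline density infeasible")
    }
    for (c2 in cells) assign(c2, TRUE, envir = taken)
    pos[i] <- p
  }
  is_indel <- c(rep(FALSE, n_snv), rep(TRUE, n_indel))
  refa <- character(n); alta <- character(n)
  for (i in seq_len(n)) {
    s <- ref[[ctg[i]]]
    b <- substr(s, pos[i], pos[i])
    if (!is_indel[i]) {
      refa[i] <- b
      alta[i] <- sample(setdiff(BASES, b), 1L)
    } else if (runif(1) < 0.5) {      # deletion of 1-5 bp after the anchor
      dl <- sample.int(5L, 1L)
      refa[i] <- substr(s, pos[i], pos[i] + dl)
      alta[i] <- b
    } else {                          # insertion of 1-5 bp after the anchor
      il <- sample.int(5L, 1L)
      refa[i] <- b
      alta[i] <- paste0(b, paste(sample(BASES, il, replace = TRUE),
                                 collapse = ""))
    }
  }
  het <- runif(n) < het_frac
  gt <- ifelse(het, ifelse(runif(n) < 0.5, "1|0", "0|1"), "1|1")
  out <- data.frame(contig = ctg, pos = pos, ref = refa, alt = alta,
                    gt = gt, stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) write_germline_vcf_file(out, ref, path)
  out
}

#' Write a germline data.frame as a phased VCF
#' @param germline data.frame with `contig`, `pos`, `ref`, `alt`, `gt`.
#' @param reference named character vector (contig header lengths).
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_germline_vcf_file <- function(germline, reference, path) {
  ref <- as_seq_vector(reference)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(ref), nchar(ref)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tDONOR")
  body <- if (nrow(germline))
    paste(germline$contig, germline$pos, ".", germline$ref, germline$alt,
          ".", "PASS", ".", "GT", germline$gt, sep = "\t") else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default desk-scale pipeline configuration
#'
#' @param ... overrides of any default entry.
#' @return named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    reference = list(length = 50000L, gc = 0.41, contig = "chrS"),
    germline = list(n_snv = 40L, n_indel = 5L, het_frac = 2 / 3),
    target = list(n = 4L, length = 8000L, pad = 100L),
    reads = list(mean_depth = 60, read_len = 100L, insert_mean = 300L,
                 insert_sd = 30L, error_rate = 1e-3),
    spectrum = list(kind = "point_mass", n_total = 150L, f0 = 0.1,
                    f_min = 0.01, f_max = 0.25, clonal_f = 0.5,
                    n_clonal = 0L, purity = 1),
    spike = list(mode = "stochastic"),
    damage = list(burden = 0L, vaf_alpha = 1.5, vaf_beta = 60),
    caller = list(run = TRUE, e = 1e-3, alpha = 0.01, min_alt = 3L,
                  normal_alt = 2L, cluster_window = 100L, emit_min = 2L),
    output = list(write_sam = FALSE, write_vcf = TRUE))
  mod <- list(...)
  for (nm in names(mod)) {
    if (is.list(mod[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(mod[[nm]])] <- mod[[nm]]
    else cfg[[nm]] <- mod[[nm]]
  }
  cfg
}

#' Run the full simulation-to-evaluation pipeline
#'
#' Executes genome construction, normal and pre-tumour read simulation,
#' spectrum sampling, somatic spike-in, optional damage spike-in (into the
#' tumour, and optionally the same plan into the normal), the naive caller
#' and the evaluation layer.  All randomness flows from one master seed
#' fanned out to per-stage child seeds recorded in the run manifest; the
#' same config and seed give identical outputs.
#'
#' @param config a [pipeline_config()] list or a YAML path.
#' @param run_dir output directory (created); `NULL` for no file output.
#' @return object of class `sim_run` with the genome, target, tumour and
#'   normal `sim_reads`, truth records, calls, matched evaluation and
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = NULL) {
  if (is.character(config)) config <- modify_config(yaml::read_yaml(config))
  seeds <- child_seeds(config$seed, 8L)
  names(seeds) <- c("reference", "germline", "normal_reads", "tumour_reads",
                    "spectrum", "plan", "spike", "damage")

  stage <- "reference"
  res <- try({
    ref <- generate_toy_reference(config$reference$length,
                                  config$reference$gc,
                                  config$reference$contig,
                                  seed = seeds["reference"])
    stage <- "germline"
    germ <- generate_toy_germline(ref, config$germline$n_snv,
                                  config$germline$n_indel,
                                  config$germline$het_frac,
                                  seed = seeds["germline"])
    genome <- build_phased_genome(ref, germ)
    stage <- "target"
    target <- make_tiling_target(ref, config$target$n, config$target$length)
    target <- pad_target(target, config$target$pad,
                         setNames(nchar(ref), names(ref)))
    stage <- "reads"
    rd <- config$reads
    normal <- simulate_fragments(genome, target, rd$mean_depth, rd$read_len,
                                 rd$insert_mean, rd$insert_sd,
                                 rd$error_rate, seed = seeds["normal_reads"])
    tumour <- simulate_fragments(genome, target, rd$mean_depth, rd$read_len,
                                 rd$insert_mean, rd$insert_sd,
                                 rd$error_rate, seed = seeds["tumour_reads"])
    stage <- "spectrum"
    sp <- config$spectrum
    spec <- spectrum_spec(sp$kind, n_total = sp$n_total %||% 0L,
                          f_min = sp$f_min %||% 0.01,
                          f_max = sp$f_max %||% 0.25,
                          clonal_f = sp$clonal_f %||% 0.5,
                          n_clonal = sp$n_clonal %||% 0L,
                          f0 = sp$f0 %||% 0.035, bins = sp$bins,
                          purity = sp$purity %||% 1)
    freqs <- make_burden(spec, seed = seeds["spectrum"])
    stage <- "spike"
    plan <- plan_variants(freqs, target, genome, mode = config$spike$mode,
                          seed = seeds["plan"])
    tumour <- spike_variants(tumour, plan, seed = seeds["spike"])
    stage <- "damage"
    dmg_tab <- NULL
    if ((config$damage$burden %||% 0L) > 0L) {
      sig <- config$damage$signature %||% default_damage_signature()
      dp <- damage_plan(config$damage$burden, sig,
                        vaf_dist = function(n)
                          rbeta(n, config$damage$vaf_alpha,
                                config$damage$vaf_beta),
                        target = target)
      tumour <- spike_damage(tumour, dp, seed = seeds["damage"])
      if (isTRUE(config$damage$also_normal))
        normal <- spike_damage(normal, dp, seed = seeds["damage"] + 1L)
      dmg_tab <- tumour$damage
    }
    stage <- "truth"
    truth <- truth_records(tumour)
    stage <- "caller"
    calls <- NULL; matched <- NULL
    if (isTRUE(config$caller$run)) {
      sites <- data.frame(contig = c(tumour$somatic$contig,
                                     tumour$damage$contig),
                          pos = c(tumour$somatic$pos, tumour$damage$pos))
      cp <- caller_params(config$caller$e, config$caller$alpha,
                          config$caller$min_alt, config$caller$normal_alt,
                          config$caller$cluster_window,
                          config$caller$emit_min)
      calls <- call_somatic(pileup_at(tumour, sites),
                            pileup_at(normal, sites), cp)
      stage <- "evaluate"
      matched <- match_calls(calls, tumour)
    }
    list(genome = genome, target = target, normal = normal,
         tumour = tumour, plan = plan, truth = truth, calls = calls,
         matched = matched, damage = dmg_tab)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stopf("pipeline stage '%s' failed: %s", stage,
          attr(res, "condition")$message %||% as.character(res))

  manifest <- list(package = "somaticsim",
                   version = as.character(utils::packageVersion("somaticsim")),
                   config = config[setdiff(names(config), "damage_signature")],
                   seeds = as.list(seeds))
  out <- structure(c(res, list(manifest = manifest)), class = "sim_run")
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    write_truth(res$truth, res$genome,
                vcf_path = file.path(run_dir, "truth.vcf"),
                tsv_path = file.path(run_dir, "truth.tsv"))
    if (isTRUE(config$output$write_sam)) {
      write_alignments(res$tumour, file.path(run_dir, "tumour.sam"))
      write_alignments(res$normal, file.path(run_dir, "normal.sam"))
    }
    if (!is.null(res$calls) && isTRUE(config$output$write_vcf))
      write_calls_vcf(res$calls, res$genome,
                      file.path(run_dir, "calls.vcf"))
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# Evenly spaced capture-like intervals across each contig.
make_tiling_target <- function(ref, n, length_each) {
  ref <- as_seq_vector(ref)
  do.call(rbind, lapply(names(ref), function(ctg) {
    L <- nchar(ref[[ctg]])
    starts <- round(seq(200, L - length_each - 200, length.out = n))
    new_target(ctg, starts, starts + length_each)
  }))
}

# A C>T / C>A concentrated signature standing in for combined FFPE +
# oxidative damage when no signature table is supplied.
default_damage_signature <- function() {
  ch <- sbs_channels()
  w <- setNames(rep(0.001, 96), ch)
  w[grepl("\\[C>T\\]", ch)] <- w[grepl("\\[C>T\\]", ch)] + 0.6 / 16
  w[grepl("\\[C>A\\]", ch)] <- w[grepl("\\[C>A\\]", ch)] + 0.4 / 16
  new_sbs_signature(w)
}

modify_config <- function(x) do.call(pipeline_config, x)

#' @export
print.sim_run <- function(x, ...) {
  cat("sim_run\n")
  print(x$genome)
  print(x$tumour)
  if (!is.null(x$matched)) print(x$matched)
  invisible(x)
}
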