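test_that("plan_variants places unique in-target loci away from germline records", {
  pg <- fix_genome(10000L, n_snv = 15L, n_indel = 3L, seed = 91L)
  tg <- fix_target(10000L)
  expect_identical(nrow(plan_variants(numeric(0), tg, pg)), 0L)
  plan <- plan_variants(rep(0.1, 1000), tg, pg, seed = 92L)
  expect_identical(anyDuplicated(plan$pos), 0L)
  expect_true(all(plan$pos > tg$start & plan$pos <= tg$end))
  expect_true(all(plan$alt != plan$ref))
  expect_false(any(plan$pos %in% pg$germline$pos))
  # haplotype assignment is Binomial(n, 1/2)
  k <- sum(plan$hap == "maternal")
  expect_gt(2 * pbinom(min(k, 1000 - k), 1000, 0.5), 0.01)
  expect_error(plan_variants(rep(0.1, 1e6), tg, pg), "eligible loci")
})

test_that("stochastic spiking edits nothing at f = 0 and everything at f = 0.5", {
  pg <- fix_plain_genome(8000L, seed = 95L)
  sr <- fix_reads(pg, fix_target(8000L), depth = 40, error_rate = 0,
                  seed = 96L)
  v0 <- data.frame(variant_id = "v0", contig = "chrS", pos = 4000L,
                   ref = substr(pg$ref[["chrS"]], 4000, 4000), alt = "N",
                   hap = "maternal", true_f = 0, mode = "stochastic")
  v0$alt <- setdiff(c("A", "C", "G", "T"), v0$ref)[1]
  r0 <- apply_stochastic(sr, v0, seed = 1)
  expect_identical(r0$n_edited, 0L)

  v5 <- v0; v5$true_f <- 0.5; v5$variant_id <- "v5"
  r5 <- apply_stochastic(sr, v5, seed = 2)
  expect_identical(r5$n_edited, r5$n_overlap)  # p = min(2f, 1) = 1
  # marginal VAF ~ 0.5: the chosen haplotype carries all alternate reads
  ac <- alt_read_count(r5$sr, v5)
  dp <- pileup_at(r5$sr, data.frame(contig = "chrS", pos = 4000L))$depth
  expect_gt(ac / dp, 0.35); expect_lt(ac / dp, 0.65)
})

test_that("both mates of an edited fragment carry the variant where they overlap it", {
  pg <- fix_plain_genome(6000L, seed = 97L)
  # short inserts force mate overlap at the locus
  sr <- simulate_fragments(pg, fix_target(6000L), mean_depth = 40,
                           insert_mean = 150L, insert_sd = 5L,
                           error_rate = 0, seed = 98L)
  v <- data.frame(variant_id = "v", contig = "chrS", pos = 3000L,
                  ref = substr(pg$ref[["chrS"]], 3000, 3000), alt = "A",
                  hap = "paternal", true_f = 0.5, mode = "stochastic")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  r <- apply_stochastic(sr, v, seed = 3)
  ed <- r$sr$spikes
  # fragments contributing two covering reads were edited on both
  frag_of <- sub("/.*$", "", ed$read_id)
  cov_ids <- reads_covering(r$sr, "paternal", "chrS", 2999L)
  cov_frags <- table(sub("/.*$", "", cov_ids))
  dbl <- names(cov_frags)[cov_frags == 2L]
  dbl_edited <- dbl[dbl %in% frag_of]
  expect_gt(length(dbl_edited), 0L)
  for (f in dbl_edited) expect_identical(sum(frag_of == f), 2L)
})

test_that("stochastic alt-fragment counts are Binomial(n_fragments, 2f)", {
  pg <- fix_plain_genome(20000L, seed = 111L)
  sr <- fix_reads(pg, fix_target(20000L), depth = 50, error_rate = 0,
                  seed = 112L)
  plan <- plan_variants(rep(0.05, 300), fix_target(20000L), pg, seed = 113L)
  sr <- spike_variants(sr, plan, seed = 114L)
  s <- sr$somatic
  set.seed(115)
  u <- binom_pit(s$n_edited, s$n_overlap, 0.1)
  expect_gt(pit_chisq_p(u), 0.01)
})

test_that("read-fraction mode edits exactly round(f x depth) reads, reproducibly", {
  pg <- fix_plain_genome(8000L, seed = 121L)
  sr <- fix_reads(pg, fix_target(8000L), depth = 30, error_rate = 0,
                  seed = 122L)
  plan <- plan_variants(c(0.1, 0.2, 0), fix_target(8000L), pg,
                        mode = "read_fraction", seed = 123L)
  counts <- sapply(1:3, function(rep) {
    out <- spike_variants(sr, plan, seed = 1000L + rep)
    out$somatic$n_edited
  })
  # identical across runs regardless of seed
  expect_identical(counts[, 1], counts[, 2])
  expect_identical(counts[, 1], counts[, 3])
  out <- spike_variants(sr, plan, seed = 9L)
  expect_identical(out$somatic$n_edited,
                   as.integer(round_half_up(plan$true_f *
                                              out$somatic$n_overlap)))
  expect_identical(out$somatic$n_edited[plan$true_f == 0], 0L)
  # alternate reads observed equal the edit count (f = 0.2, depth ~30)
  i <- 2L
  expect_identical(alt_read_count(out, plan[i, ]), out$somatic$n_edited[i])
})

test_that("truth conservation: alt-base gain equals emitted truth entries", {
  pg <- fix_plain_genome(10000L, seed = 131L)
  sr <- fix_reads(pg, fix_target(10000L), depth = 30, error_rate = 0,
                  seed = 132L)
  plan <- plan_variants(rep(c(0.1, 0.3), 25), fix_target(10000L), pg,
                        seed = 133L)
  sr2 <- spike_variants(sr, plan, seed = 134L)
  gained <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                            strsplit(b, "")[[1]]),
                       sr2$reads$seq, sr$reads$seq))
  expect_identical(as.integer(gained), nrow(sr2$spikes))
  expect_identical(sum(sr2$somatic$n_edited > 0) +
                     sum(sr2$somatic$n_edited == 0), nrow(plan))
})

test_that("a locus deleted on the chosen haplotype is skipped and flagged", {
  ref <- c(chrS = paste(rep("ACGT", 2500), collapse = ""))
  g <- data.frame(contig = "chrS", pos = 5000, ref = "TACGTACGTA",
                  alt = "T", gt = "1|0")
  pg <- build_phased_genome(ref, g)
  sr <- fix_reads(pg, fix_target(10000L), depth = 20, error_rate = 0,
                  seed = 141L)
  v <- data.frame(variant_id = "vdel", contig = "chrS", pos = 5004L,
                  ref = substr(ref[["chrS"]], 5004, 5004), alt = "A",
                  hap = "maternal", true_f = 0.4, mode = "stochastic")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_message(r <- apply_stochastic(sr, v, seed = 1), "deletion")
  expect_true(r$skipped)
  expect_identical(r$n_edited, 0L)
})
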