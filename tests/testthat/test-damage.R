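test_that("channel normalization reverse-complements purine-reference SNVs", {
  # G>A seen in 5'-TGC-3' is C>T in G[C>T]A on the pyrimidine strand
  expect_identical(somaticsim:::channel_of("TGC", "G", "A"), "G[C>T]A")
  expect_identical(somaticsim:::channel_of("ACA", "C", "T"), "A[C>T]A")
  expect_identical(sort(sbs_channels()), sort(unique(sbs_channels())))
  expect_length(sbs_channels(), 96L)
})

test_that("signature estimation handles point masses and strand normalization", {
  ref <- c(c1 = "GACAGACAGACAG")
  v <- data.frame(contig = "c1", pos = rep(3L, 10), ref = "C", alt = "T")
  sig <- estimate_sbs_signature(v, ref)
  expect_equal(unname(sig["A[C>T]A"]), 1)
  expect_equal(sum(sig), 1)
  expect_error(estimate_sbs_signature(v[0, ], ref), "no SNVs")
  v2 <- rbind(v, data.frame(contig = "c1", pos = 3L, ref = "CA", alt = "C"))
  expect_warning(estimate_sbs_signature(v2, ref), "non-SNV")
})

test_that("COSMIC-format tables load normalized and label-keyed", {
  u <- data.frame(Type = sbs_channels(), w = rep(1, 96))
  sig <- load_cosmic_signature(u)
  expect_equal(unname(unclass(sig)), rep(1 / 96, 96))
  # un-normalized and shuffled rows give the identical signature
  set.seed(6); perm <- sample(96)
  w <- runif(96)
  s1 <- load_cosmic_signature(data.frame(Type = sbs_channels(), w = w))
  s2 <- load_cosmic_signature(data.frame(Type = sbs_channels()[perm],
                                         w = w[perm]))
  expect_equal(unclass(s1), unclass(s2))
  expect_equal(sum(s1), 1)
  expect_error(load_cosmic_signature(
    data.frame(Type = sbs_channels()[c(1, 1:95)], w = rep(1, 96))),
    "duplicate")
  expect_error(load_cosmic_signature(
    data.frame(Type = sbs_channels()[1:95], w = rep(1, 95))), "96")
})

test_that("orientation partition is exhaustive and class sizes are binomial", {
  pg <- fix_plain_genome(10000L, seed = 151L)
  sr <- fix_reads(pg, fix_target(10000L), depth = 30, seed = 152L)
  cls <- partition_by_orientation(sr)
  expect_identical(length(cls$forward) + length(cls$reverse),
                   nrow(sr$reads))
  expect_identical(length(intersect(cls$forward, cls$reverse)), 0L)
  n_frag <- nrow(sr$fragments)
  k <- length(cls$forward) / 2          # reads -> fragments
  expect_gt(2 * pbinom(min(k, n_frag - k), n_frag, 0.5), 0.01)
  # flag-based classification agrees on serialized alignments
  p <- withr::local_tempfile(fileext = ".sam")
  write_alignments(sr, p)
  a <- read_alignments(p)
  cls2 <- partition_by_orientation(a)
  expect_setequal(cls2$forward, cls$forward)
})

test_that("damage spiking is context-matched, orientation-pure and half-split", {
  pg <- fix_plain_genome(30000L, seed = 161L)
  sr <- fix_reads(pg, fix_target(30000L), depth = 40, error_rate = 0,
                  seed = 162L)
  sr0 <- spike_damage(sr, damage_plan(0, uniform_signature()), seed = 1)
  expect_identical(nrow(sr0$spikes), 0L)

  plan <- damage_plan(401, uniform_signature(), target = fix_target(30000L))
  sr2 <- spike_damage(sr, plan, seed = 163L)
  d <- sr2$damage
  expect_identical(nrow(d), 401L)
  expect_lte(abs(sum(d$orientation == "forward") -
                   sum(d$orientation == "reverse")), 1L)
  # every site's reference context matches its drawn channel
  ref <- pg$ref[["chrS"]]
  chan <- vapply(seq_len(nrow(d)), function(i)
    somaticsim:::channel_of(substr(ref, d$pos[i] - 1L, d$pos[i] + 1L),
                            d$ref[i], d$alt[i]), character(1))
  expect_identical(chan, d$channel)
  # orientation purity: all edited fragments share the site's class
  ori <- sr2$fragments$orientation[match(sub("/.*$", "", sr2$spikes$read_id),
                                         sr2$fragments$frag_id)]
  cls <- d$orientation[match(sr2$spikes$variant_id, d$site_id)]
  expect_true(all(ifelse(ori == "F", "forward", "reverse") == cls))
})

test_that("spiked channel distribution follows the plan signature", {
  pg <- fix_plain_genome(50000L, seed = 171L)
  sr <- fix_reads(pg, fix_target(50000L), depth = 10, error_rate = 0,
                  seed = 172L)
  sig <- oxo_signature()
  sr2 <- spike_damage(sr, damage_plan(1500, sig,
                                      target = fix_target(50000L)),
                      seed = 173L)
  obs <- table(factor(sr2$damage$channel, levels = sbs_channels()))
  # pool rare channels so expected cell counts support the chi-square
  expd <- as.numeric(sig) * 1500
  big <- expd >= 5
  o <- c(obs[big], sum(obs[!big])); e <- c(expd[big], sum(expd[!big]))
  stat <- sum((o - e)^2 / e)
  expect_gt(pchisq(stat, length(o) - 1, lower.tail = FALSE), 0.01)
})

test_that("signatures are recovered from generated variants", {
  ref <- fix_reference(50000L, seed = 181L)
  sig <- oxo_signature()
  v <- simulate_signature_variants(ref, sig, 4000, seed = 182L)
  est <- estimate_sbs_signature(v, ref)
  expect_gte(signature_cosine(est, sig), 0.99)
  # C>A channels dominate the oxidative-damage signature estimate
  ca <- grepl("\\[C>A\\]", sbs_channels())
  expect_gt(sum(est[ca]), 0.8)
})
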