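test_that("variant-free genome reproduces the reference with identity liftover", {
  ref <- c(chrA = "ACGTACGT")
  pg <- build_phased_genome(ref, empty_germline())
  expect_identical(pg$hap$maternal[["chrA"]], "ACGTACGT")
  expect_identical(pg$hap$paternal[["chrA"]], "ACGTACGT")
  expect_identical(hap_to_ref(pg, "maternal", "chrA", 0:7), 0:7)
  expect_identical(ref_to_hap(pg, "paternal", "chrA", 0:7), 0:7)
})

test_that("a phased het SNV is applied to the carrying haplotype only", {
  ref <- c(chrA = "ACGTACGT")
  g <- data.frame(contig = "chrA", pos = 3, ref = "G", alt = "C",
                  gt = "1|0")
  pg <- build_phased_genome(ref, g)
  expect_identical(pg$hap$maternal[["chrA"]], "ACCTACGT")
  expect_identical(pg$hap$paternal[["chrA"]], "ACGTACGT")
  # hom-alt hits both
  g$gt <- "1|1"
  pg2 <- build_phased_genome(ref, g)
  expect_identical(pg2$hap$paternal[["chrA"]], "ACCTACGT")
})

test_that("a deletion shifts the liftover as brute-force string alignment predicts", {
  ref <- c(chrA = "ACGTACGTAC")
  # deletion of the 2 bases after pos 3 on the maternal haplotype
  g <- data.frame(contig = "chrA", pos = 3, ref = "GTA", alt = "G",
                  gt = "1|0")
  pg <- build_phased_genome(ref, g)
  expect_identical(pg$hap$maternal[["chrA"]], "ACGCGTAC")
  # brute-force oracle: walk the two strings with the known edit
  hap <- pg$hap$maternal[["chrA"]]
  expect_map <- c(0:2, 5:9)  # hap index i aligns to these ref indices
  expect_identical(hap_to_ref(pg, "maternal", "chrA",
                              seq_len(nchar(hap)) - 1L), expect_map)
  # deleted reference positions have no haplotype image
  expect_true(all(is.na(ref_to_hap(pg, "maternal", "chrA", 3:4))))
  # round trip wherever defined
  rp <- hap_to_ref(pg, "maternal", "chrA", 0:7)
  expect_identical(ref_to_hap(pg, "maternal", "chrA", rp), 0:7)
})

test_that("insertions map inserted bases to NA and round-trip elsewhere", {
  ref <- c(chrA = "ACGTACGT")
  g <- data.frame(contig = "chrA", pos = 4, ref = "T", alt = "TGG",
                  gt = "0|1")
  pg <- build_phased_genome(ref, g)
  expect_identical(pg$hap$paternal[["chrA"]], "ACGTGGACGT")
  rp <- hap_to_ref(pg, "paternal", "chrA", 0:9)
  expect_identical(rp, c(0:3, NA, NA, 4:7))
  ok <- !is.na(rp)
  expect_identical(ref_to_hap(pg, "paternal", "chrA", rp[ok]),
                   (0:9)[ok])
})

test_that("malformed germline input is rejected as specified", {
  ref <- c(chrA = "ACGTACGT")
  expect_warning(
    pg <- build_phased_genome(ref, data.frame(
      contig = "chrA", pos = 3, ref = "G", alt = "C", gt = "0/1")),
    "unphased")
  expect_identical(pg$hap$maternal[["chrA"]], "ACGTACGT")
  expect_error(build_phased_genome(ref, data.frame(
    contig = "chrA", pos = 3, ref = "T", alt = "C", gt = "1|0")),
    "REF allele mismatch")
  expect_error(build_phased_genome(ref, data.frame(
    contig = "chrA", pos = c(3, 4), ref = c("GTA", "T"), alt = c("G", "A"),
    gt = c("1|0", "1|0"))), "overlapping")
  expect_error(build_phased_genome(ref, data.frame(
    contig = "chrA", pos = 3, ref = "G", alt = "<DEL>", gt = "1|0")),
    "symbolic")
})

test_that("multi-allelic records are split by phased allele index", {
  ref <- c(chrA = "ACGTACGT")
  g <- data.frame(contig = "chrA", pos = 3, ref = "G", alt = "C,T",
                  gt = "1|2")
  pg <- build_phased_genome(ref, g)
  expect_identical(pg$hap$maternal[["chrA"]], "ACCTACGT")
  expect_identical(pg$hap$paternal[["chrA"]], "ACTTACGT")
  expect_identical(nrow(pg$germline), 2L)
})

test_that("liftover round-trips on a random fixture with many indels", {
  pg <- fix_genome(n_snv = 30L, n_indel = 12L, seed = 303L)
  for (h in c("maternal", "paternal")) {
    L <- nchar(pg$hap[[h]][["chrS"]])
    set.seed(7)
    hp <- sample.int(L, 1000L) - 1L
    rp <- hap_to_ref(pg, h, "chrS", hp)
    ok <- !is.na(rp)
    expect_gt(sum(ok), 900)
    expect_identical(ref_to_hap(pg, h, "chrS", rp[ok]), hp[ok])
    expect_true(all(diff(rp[ok][order(hp[ok])]) > 0))  # strict monotonicity
  }
})

test_that("haplotype mismatch count equals applied SNVs on an indel-free fixture", {
  ref <- fix_reference(5000L, seed = 11L)
  germ <- generate_toy_germline(ref, n_snv = 25L, n_indel = 0L, seed = 12L)
  pg <- build_phased_genome(ref, germ)
  for (h in c("maternal", "paternal")) {
    n_applied <- sum(pg$germline[[paste0("gt_", h)]] == 1L)
    mism <- sum(strsplit(pg$hap[[h]][["chrS"]], "")[[1]] !=
                  strsplit(ref[["chrS"]], "")[[1]])
    expect_identical(mism, n_applied)
  }
})

test_that("pad_target pads, clips, merges, and matches a per-base union oracle", {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer())
  expect_identical(nrow(pad_target(empty)), 0L)
  out <- pad_target(data.frame(contig = "c", start = 100, end = 200),
                    pad = 100, contig_lengths = c(c = 1000))
  expect_identical(out$start, 0L)
  expect_identical(out$end, 300L)
  # random interval sets vs brute-force per-base union
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(2:8, 1)
    s <- sample.int(900, n)
    tg <- data.frame(contig = "c", start = s, end = s + sample.int(80, n))
    pad <- sample(0:60, 1)
    out <- pad_target(tg, pad, c(c = 1000))
    covered <- rep(FALSE, 1000)
    for (i in seq_len(n)) {
      lo <- max(0, tg$start[i] - pad); hi <- min(1000, tg$end[i] + pad)
      covered[(lo + 1):hi] <- TRUE
    }
    got <- rep(FALSE, 1000)
    for (i in seq_len(nrow(out))) got[(out$start[i] + 1):out$end[i]] <- TRUE
    expect_identical(got, covered)
    expect_identical(attr(out, "total_length"), sum(covered))
    expect_true(all(diff(out$start) > 0))
  }
})

test_that("read_targets reports malformed BED lines with their line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c\t0\t100", "c\tnot_a_number\t200"), p)
  expect_error(read_targets(p), "line 2")
  writeLines(c("# comment", "c\t10\t20"), p)
  expect_identical(read_targets(p)$start, 10L)
})
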