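# Small end-to-end fixture shared by the evaluation tests.
eval_fixture <- function() {
  pg <- fix_plain_genome(15000L, seed = 251L)
  tg <- fix_target(15000L)
  sr <- fix_reads(pg, tg, depth = 50, error_rate = 1e-3, seed = 252L)
  nr <- fix_reads(pg, tg, depth = 50, error_rate = 1e-3, seed = 253L)
  plan <- plan_variants(rep(c(0.02, 0.1, 0.3), 30), tg, pg, seed = 254L)
  sr <- spike_variants(sr, plan, seed = 255L)
  sr <- spike_damage(sr, damage_plan(120, uniform_signature(), target = tg),
                     seed = 256L)
  sites <- data.frame(contig = c(sr$somatic$contig, sr$damage$contig),
                      pos = c(sr$somatic$pos, sr$damage$pos))
  calls <- call_somatic(pileup_at(sr, sites), pileup_at(nr, sites),
                        caller_params(cluster_window = 0L))
  list(pg = pg, sr = sr, nr = nr, calls = calls,
       matched = match_calls(calls, sr))
}

FIX <- eval_fixture()

test_that("classification partitions truth and PASS calls exactly", {
  m <- FIX$matched
  expect_identical(m$n_truth, nrow(FIX$sr$somatic))
  expect_identical(m$n_tp + sum(m$fn_causes), m$n_truth)
  expect_identical(m$n_tp + sum(m$fp_classes), nrow(m$calls))
  expect_true(all(m$truth$class %in% c("TP", "FN")))
  # per-cause totals equal a brute-force reclassification
  t <- m$truth
  ck <- paste(FIX$calls$contig, FIX$calls$pos, FIX$calls$alt)
  for (i in sample(nrow(t), 40)) {
    key <- paste(t$contig[i], t$pos[i], t$alt[i])
    j <- match(key, ck)
    expected <- if (!is.na(j) && FIX$calls$pass[j]) "TP"
      else if (t$alt_reads[i] == 0L) "FN:no_alt_coverage"
      else if (!is.na(j)) paste0("FN:filtered:", FIX$calls$filters[j])
      else "FN:not_emitted"
    got <- if (t$class[i] == "TP") "TP" else paste0("FN:", t$cause[i])
    expect_identical(got, expected)
  }
})

test_that("PASS calls at artefact sites classify as FP_artefact", {
  m <- FIX$matched
  fp <- m$calls[m$calls$class == "FP_artefact", ]
  dkey <- paste(FIX$sr$damage$contig, FIX$sr$damage$pos, FIX$sr$damage$alt)
  if (nrow(fp)) {
    expect_true(all(paste(fp$contig, fp$pos, fp$alt) %in% dkey))
  }
  # an empty VCF leaves every truth variant an FN with a coverage-aware cause
  m0 <- match_calls(FIX$calls[0, ], FIX$sr)
  expect_identical(m0$n_tp, 0L)
  expect_true(all(m0$truth$cause %in% c("no_alt_coverage", "not_emitted")))
  expect_identical(sum(m0$truth$cause == "no_alt_coverage"),
                   sum(m0$truth$alt_reads == 0L))
})

test_that("detection matrix conserves burden and degenerates correctly", {
  m <- FIX$matched
  dm <- detection_matrix(m)
  expect_identical(sum(dm$matrix), m$n_truth)
  expect_identical(as.integer(rowSums(dm$matrix)), dm$truth_per_bin)
  expect_true(all(dm$rate >= 0 & dm$rate <= 1, na.rm = TRUE))
  # all-detected-in-bin fixture: identity-concentrated matrix, rates 1
  m1 <- m
  m1$truth <- data.frame(contig = "c", pos = 1:10, ref = "A", alt = "C",
                         variant_id = paste0("v", 1:10), hap = "maternal",
                         true_f = seq(0.05, 0.45, length.out = 10),
                         class = "TP", cause = NA, alt_reads = 5L,
                         inferred_vaf = seq(0.05, 0.45, length.out = 10))
  dm1 <- detection_matrix(m1)
  expect_true(all(dm1$rate[dm1$truth_per_bin > 0] == 1))
  m2 <- m1; m2$truth$class <- "FN"; m2$truth$inferred_vaf <- NA
  dm2 <- detection_matrix(m2)
  expect_true(all(dm2$rate[dm2$truth_per_bin > 0] == 0))
})

test_that("TMB estimate equals the brute-force count per megabase", {
  calls <- data.frame(vaf = c(0.04, 0.05, 0.2, 0.6, NA))
  expect_equal(tmb_estimate(calls, 0.05, 2), 3 / 2)
  expect_equal(tmb_estimate(data.frame(vaf = numeric(0)), 0.05, 10), 0)
  expect_equal(round_half_up(tmb_estimate(data.frame(vaf = rep(0.1, 645)),
                                          0.05, 76), 1), 8.5)
})

test_that("strand contingency reconstructs printed totals and recounts", {
  # 4169 true negatives (126 both-strand), 42 false positives (12 both)
  sites <- data.frame(
    fp = rep(c(FALSE, TRUE), c(4169, 42)),
    both_strand = c(rep(c(FALSE, TRUE), c(4043, 126)),
                    rep(c(FALSE, TRUE), c(30, 12))))
  tab <- strand_evidence_contingency(sites)
  expect_identical(unname(tab),
                   matrix(c(4043L, 30L, 126L, 12L), 2, 2))
  # all single-strand: second column zero
  s2 <- data.frame(fp = c(TRUE, FALSE), both_strand = FALSE)
  expect_identical(unname(strand_evidence_contingency(s2)[, 2]), c(0L, 0L))
  # simulation recount: table equals a per-site brute-force recount
  se <- strand_evidence_sites(FIX$sr, FIX$calls)
  tab3 <- strand_evidence_contingency(se)
  expect_identical(sum(tab3), nrow(se))
  expect_identical(unname(tab3["FP", "single_strand"] +
                            tab3["FP", "both_strand"]), sum(se$fp))
  # artefacts are spiked orientation-pure: both-strand evidence requires a
  # sequencing error, so it must be rare
  expect_lt(mean(se$both_strand), 0.5)
})

test_that("one-sided Fisher test matches enumeration and printed precision", {
  tab <- matrix(c(4043, 30, 126, 12), 2, 2)
  p <- fisher_strand_test(tab)
  expect_equal(signif(p, 1), 5e-09)
  # cross-check against the standard implementation
  expect_equal(p, fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-10)
  # brute-force hypergeometric enumeration on random small tables
  set.seed(90)
  for (rep in 1:20) {
    t2 <- matrix(sample(0:12, 4, replace = TRUE), 2, 2)
    m <- t2[1, 2] + t2[2, 2]; n <- t2[1, 1] + t2[2, 1]
    k <- t2[2, 1] + t2[2, 2]
    brute <- if (m + n == 0 || k == 0 || m == 0) 1 else {
      xs <- max(0, k - n):min(k, m)
      probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
      sum(probs[xs >= t2[2, 2]])
    }
    expect_equal(fisher_strand_test(t2), brute, tolerance = 1e-12)
  }
  # a perfectly balanced table shows no enrichment
  expect_gt(fisher_strand_test(matrix(c(10, 10, 10, 10), 2, 2)), 0.5)
  expect_equal(fisher_strand_test(matrix(c(5, 7, 0, 0), 2, 2)), 1)
})

test_that("expected-burden arithmetic reproduces the printed percentages", {
  r <- fp_rate_vs_expected_burden(42, 2.7, 76)
  expect_identical(r$expected_mutations, 205L)
  expect_equal(r$percentage, 20)
  expect_equal(r$precision_complement, 17)
  expect_equal(fp_rate_vs_expected_burden(0, 2.7, 76)$percentage, 0)
  expect_true(is.na(fp_rate_vs_expected_burden(5, 0, 76)$percentage))
  set.seed(17)
  for (rep in 1:10) {
    fp <- sample(0:100, 1); tmb <- runif(1, 0, 10); mb <- runif(1, 1, 100)
    r2 <- fp_rate_vs_expected_burden(fp, tmb, mb)
    expect_equal(r2$expected_mutations, as.integer(round_half_up(tmb * mb)))
  }
  expect_equal(considered_fraction(11283, 7332528), 0.0015)
})

test_that("VAF bias reporting summarizes PASS calls against the point mass", {
  m <- FIX$matched
  vb <- vaf_bias_report(m, 0.1)
  expect_identical(vb$n_pass,
                   sum(m$truth$class == "TP" & !is.na(m$truth$inferred_vaf)))
  em <- m; em$truth$class <- "FN"; em$truth$inferred_vaf <- NA
  expect_identical(vaf_bias_report(em, 0.1)$n_pass, 0L)
})
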