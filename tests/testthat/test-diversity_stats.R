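test_that("diversity metrics match closed forms on constructed data", {
  # biallelic locus, all heterozygotes, p = 0.5
  g <- matrix(c(100L, 102L), 10, 2, byrow = TRUE,
              dimnames = list(NULL, c("A.1", "A.2")))
  div <- diversity_table(g)
  expect_equal(div$Ho, 1.0)
  expect_equal(div$He, 0.5)
  expect_equal(div$Na, 2)
  expect_equal(div$AR, 2)          # AR at full gene count equals Na
  expect_equal(div$Fis, -1)        # complete heterozygote excess
})

test_that("rarefied allelic richness interpolates correctly", {
  # locus with counts (6, 2) in 8 genes, rarefied to g = 2:
  # AR = sum_a 1 - C(8 - n_a, 2)/C(8, 2)
  g <- matrix(NA_integer_, 4, 4,
              dimnames = list(NULL, c("A.1", "A.2", "B.1", "B.2")))
  g[, 1] <- c(100L, 100L, 100L, 102L); g[, 2] <- c(100L, 100L, 100L, 102L)
  g[, 3] <- c(100L, 102L, 104L, 106L); g[, 4] <- c(100L, 102L, 104L, 106L)
  div <- diversity_table(g, rarefy_g = 2)
  exp_a <- (1 - choose(2, 2) / choose(8, 2)) + (1 - choose(6, 2) / choose(8, 2))
  expect_equal(div$AR[div$locus == "A"], exp_a)
  # He invariant under allele relabeling
  g2 <- g; g2[g2 == 100L] <- 990L
  expect_equal(diversity_table(g2, rarefy_g = 2)$He, div$He)
})

test_that("summary row reproduces mean and SE exactly", {
  tbl <- data.frame(Na = c(3, 2, 3, 4, 5, 2, 3, 4))
  s <- summarize_diversity(tbl, "Na")
  expect_equal(s["mean", "Na"], 3.25)
  expect_equal(round(s["se", "Na"], 2), 0.37)
})

test_that("HWE exact test behaves at its boundaries", {
  expect_error(hwe_exact_test(geno_from_hw(make_eq_freqs(1, 2), 10), "L01",
                              n_perm = 0), "n_perm")
  mono <- matrix(100L, 10, 2, dimnames = list(NULL, c("A.1", "A.2")))
  expect_equal(hwe_exact_test(mono, "A"), 1.0)
  # all homozygotes at p = q = 0.5, n = 20: extreme deficit
  g <- matrix(rep(c(100L, 100L, 102L, 102L), each = 10), 20, 2,
              dimnames = list(NULL, c("A.1", "A.2")))
  expect_lt(hwe_exact_test(g, "A", n_perm = 2000, seed = 1), 0.01)
  # exact Hardy-Weinberg counts (25, 50, 25) are modal: large p
  g2 <- matrix(c(rep(c(100L, 100L), 25), rep(c(100L, 102L), 50),
                 rep(c(102L, 102L), 25)), 100, 2, byrow = TRUE,
               dimnames = list(NULL, c("A.1", "A.2")))
  expect_gt(hwe_exact_test(g2, "A", n_perm = 500, seed = 1), 0.5)
})

test_that("HWE permutation p-values are uniform under the null", {
  set.seed(7)
  fr <- make_eq_freqs(1, 3)
  ps <- vapply(1:200, function(i) {
    g <- geno_from_hw(fr, 25, seed = 7000 + i)
    hwe_exact_test(g, "L01", n_perm = 99, seed = i)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("LD test flags duplicated loci and stays calibrated under the null", {
  fr <- make_eq_freqs(2, 3)
  g <- geno_from_hw(fr, 30, seed = 2)
  dup <- cbind(g, g[, 1:2])
  colnames(dup) <- c("L01.1", "L01.2", "L02.1", "L02.2", "L03.1", "L03.2")
  res <- ld_pairwise_test(dup, n_perm = 199, seed = 3)
  p_dup <- res$p[res$locus1 == "L01" & res$locus2 == "L03"]
  expect_lte(p_dup, 1 / 200 + 1e-12)
  # single polymorphic locus: empty result
  mono <- g; mono[, 3:4] <- 100L
  expect_equal(nrow(ld_pairwise_test(mono)), 0)
  # null calibration across independent replicates
  ps <- vapply(1:200, function(i) {
    gg <- geno_from_hw(fr, 30, seed = 4000 + i)
    ld_pairwise_test(gg, n_perm = 99, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.5)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("Friedman comparison: exact small-sample p and df shape", {
  he <- matrix(0.6, 4, 3)
  he <- he + matrix(rnorm(12, 0, 1e-12), 4, 3) * 0  # identical columns
  res <- friedman_locality_comparison(he)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  # one locality strictly dominating across 4 blocks, k = 2
  he2 <- cbind(a = c(.5, .6, .7, .8), b = c(.6, .7, .8, .9))
  res2 <- friedman_locality_comparison(he2)
  expect_equal(res2$p, 0.125)            # exact binomial 2 * 2^-4
  expect_equal(res2$df, 1)
  # df shape of the regional comparison: 9 localities, 4 loci
  he9 <- matrix(runif(36), 4, 9)
  res9 <- friedman_locality_comparison(he9)
  expect_equal(res9$df, 8)
  expect_error(friedman_locality_comparison(matrix(c(1, NA, 2, 3), 2, 2)),
               "missing cells")
})

test_that("Friedman statistic agrees with the stats oracle", {
  set.seed(5)
  he <- matrix(runif(45), 9, 5)
  ours <- friedman_locality_comparison(he)
  oracle <- stats::friedman.test(he)
  expect_equal(ours$chi2, unname(oracle$statistic))
  expect_equal(ours$df, unname(oracle$parameter))
})
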