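test_that("dyad likelihood factorizes and excludes correctly", {
  fr <- make_eq_freqs(3, 4)
  g1 <- c(100L, 102L, 100L, 100L, 102L, 104L)
  g2 <- c(100L, 104L, 102L, 104L, 102L, 104L)
  # unrelated: product of genotype probabilities
  ll_u <- dyad_log_likelihood(g1, g2, fr, c(1, 0, 0))
  manual <- sum(log(vapply(1:3, function(i) {
    p <- fr[[i]]$freq
    pg <- function(g) if (g[1] == g[2]) p[1]^2 else 2 * p[1] * p[2]
    a <- g1[c(2 * i - 1, 2 * i)]; b <- g2[c(2 * i - 1, 2 * i)]
    pa <- if (a[1] == a[2]) 0.25^2 else 2 * 0.25^2
    pb <- if (b[1] == b[2]) 0.25^2 else 2 * 0.25^2
    pa * pb
  }, numeric(1))))
  expect_equal(ll_u, manual)
  # no shared allele at a locus: PO impossible
  g3 <- c(104L, 106L, 102L, 104L, 102L, 104L)
  expect_equal(dyad_log_likelihood(g1, g3, fr, c(0, 1, 0)), -Inf)
  expect_error(dyad_log_likelihood(c(999L, 999L, g1[3:6]), g2, fr, c(1, 0, 0)),
               "absent")
  expect_error(dyad_log_likelihood(g1, g2, fr, c(0.6, 0.6, -0.2)), "simplex")
})

test_that("likelihood is symmetric in the two genotypes", {
  fr <- make_eq_freqs(6, 4)
  set.seed(3)
  for (cat in names(scatpop:::KIN_CATEGORIES)) {
    k <- scatpop:::KIN_CATEGORIES[[cat]]
    g <- simulate_dyad(fr, k)
    expect_equal(dyad_log_likelihood(g$g1, g$g2, fr, k),
                 dyad_log_likelihood(g$g2, g$g1, fr, k))
  }
})

test_that("identical rare homozygotes favour FS over U", {
  k <- 10
  fr <- make_eq_freqs(6, k)     # each allele at 0.1
  rare_hom <- rep(c(100L, 100L), 6)
  expect_gt(dyad_log_likelihood(rare_hom, rare_hom, fr, c(0.25, 0.5, 0.25)),
            dyad_log_likelihood(rare_hom, rare_hom, fr, c(1, 0, 0)))
})

test_that("category likelihoods never exceed the continuous optimum", {
  fr <- make_eq_freqs(8, 4)
  set.seed(11)
  for (i in 1:10) {
    g <- simulate_dyad(fr, c(0.25, 0.5, 0.25))
    cl <- classify_dyad(g$g1, g$g2, fr)
    comp <- scatpop:::dyad_components(g$g1, g$g2, fr)
    ll_opt <- sum(log(comp %*% cl$k_ml))
    expect_gte(ll_opt + 1e-9, max(cl$loglik))
    expect_gte(cl$r_ml, 0); expect_lte(cl$r_ml, 1)
  }
})

test_that("simulated dyads are recovered with expected accuracy", {
  fr <- make_eq_freqs(8, 4)
  set.seed(21)
  po_r <- vapply(1:300, function(i) {
    g <- simulate_dyad(fr, c(0, 1, 0))
    classify_dyad(g$g1, g$g2, fr)$r_ml
  }, numeric(1))
  expect_lt(abs(mean(po_r) - 0.5), 0.05)
  u_r <- vapply(1:300, function(i) {
    g <- simulate_dyad(fr, c(1, 0, 0))
    classify_dyad(g$g1, g$g2, fr)$r_ml
  }, numeric(1))
  expect_lte(median(u_r), 0.05)
  # exclusionary locus: PO never selected
  g1 <- rep(c(100L, 100L), 8); g2 <- rep(c(102L, 104L), 8)
  expect_false(classify_dyad(g1, g2, fr)$category == "PO")
})

test_that("classification accuracy improves with locus count", {
  set.seed(31)
  acc <- vapply(c(4, 8, 16), function(L) {
    fr <- make_eq_freqs(L, 4)
    mean(vapply(1:150, function(i) {
      g <- simulate_dyad(fr, c(0, 1, 0))
      classify_dyad(g$g1, g$g2, fr)$category %in% c("PO", "FS")
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("Wang-type estimator is consistent for FS, U and self", {
  fr <- make_eq_freqs(8, 4)
  set.seed(41)
  fs <- vapply(1:500, function(i) {
    g <- simulate_dyad(fr, c(0.25, 0.5, 0.25))
    wang_relatedness(g$g1, g$g2, fr)
  }, numeric(1))
  expect_lt(abs(mean(fs) - 0.5), 0.05)
  u <- vapply(1:500, function(i) {
    g <- simulate_dyad(fr, c(1, 0, 0))
    wang_relatedness(g$g1, g$g2, fr)
  }, numeric(1))
  expect_lt(abs(mean(u)), 0.05)
  selfs <- vapply(1:200, function(i) {
    g <- simulate_dyad(fr, c(1, 0, 0))
    wang_relatedness(g$g1, g$g1, fr)
  }, numeric(1))
  expect_lt(abs(mean(selfs) - 1), 0.1)
  # monomorphic-only overlap undefined
  mono <- structure(list(L01 = list(freq = c(`100` = 1), n_genes = Inf)),
                    class = "allele_freqs")
  expect_true(is.na(wang_relatedness(c(100L, 100L), c(100L, 100L), mono)))
})

test_that("kin_matrix enumerates dyads and recovers pedigree structure", {
  fr <- make_eq_freqs(8, 4)
  g <- geno_from_hw(fr, 9, seed = 51)
  km <- kin_matrix(g, fr)
  expect_equal(nrow(km), 36)          # 9 choose 2
  counts <- attr(km, "category_counts")
  expect_equal(names(which.max(counts)), "U")   # all-founder population
  # pedigree world: >= 80% of first-order dyads called FS or PO
  cfg <- sim_config(seed = 61, n_loci = 8, alleles_per_locus = c(4, 4))
  pop <- simulate_population(cfg)
  first <- pop$dyads[pop$dyads$category %in% c("FS", "PO"), ]
  freqs <- pop$founder_freqs
  hit <- vapply(seq_len(nrow(first)), function(i) {
    classify_dyad(pop$genotypes[first$id1[i], ],
                  pop$genotypes[first$id2[i], ], freqs)$category %in%
      c("FS", "PO")
  }, logical(1))
  expect_gte(mean(hit), 0.8 - 1e-9)
  # fewer than 4 shared loci: unresolved
  g1 <- g[1, ]; g1[7:16] <- NA
  expect_equal(classify_dyad(g1, g[2, ], fr)$category, "unresolved")
})
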