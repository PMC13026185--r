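test_that("the 40% amplification screen applies the ceiling rule", {
  loci <- sprintf("L%02d", 1:11)
  mk <- function(sample, n_amp) {
    lapply(seq_along(loci), function(i) {
      a <- if (i <= n_amp) c(150L, 150L) else c(0L, 0L)
      list(sample = sample, locus = loci[i], reps = list(a, a))
    })
  }
  tab <- make_replicate_table(c(mk("s4", 4), mk("s5", 5), mk("s11", 11)))
  kept <- screen_samples(tab, loci)
  expect_false("s4" %in% kept)   # 4/11 = 0.36 < 0.40
  expect_true("s5" %in% kept)    # 5/11 = 0.45
  expect_true("s11" %in% kept)
  expect_error(screen_samples(tab, loci[1:5]), "unknown locus")
})

test_that("consensus confirmation rules match the multitube protocol", {
  tab <- make_replicate_table(list(
    list(sample = "s1", locus = "L01",
         reps = list(c(150, 154), c(150, 154))),
    list(sample = "s1", locus = "L02",
         reps = list(c(150, 150), c(150, 150), c(150, 150))),
    list(sample = "s1", locus = "L03",
         reps = list(c(150, 150), c(150, 154))),
    # three alleles each confirmed twice: conflict
    list(sample = "s1", locus = "L04",
         reps = list(c(150, 154), c(150, 158), c(154, 158))),
    # hom with a single discordant observation: tolerated but flagged
    list(sample = "s1", locus = "L05",
         reps = list(c(150, 150), c(150, 150), c(150, 150), c(150, 154)))
  ))
  cons <- call_consensus(tab)
  get <- function(l) cons[cons$locus == l, ]
  expect_equal(get("L01")$call, "het")
  expect_equal(c(get("L01")$allele1, get("L01")$allele2), c(150, 154))
  expect_equal(get("L02")$call, "hom")
  expect_equal(get("L02")$allele1, 150)
  expect_equal(get("L03")$call, "missing")
  expect_equal(get("L04")$call, "missing")
  expect_match(get("L04")$flag, "conflict")
  expect_equal(get("L05")$call, "hom")
  expect_match(get("L05")$flag, "discordant")
})

test_that("consensus is idempotent and exact on clean data", {
  cfg <- sim_config(seed = 8, ado_rate = 0, fa_rate = 0,
                    locus_failure_rate = 0)
  pop <- simulate_population(cfg)
  tab <- simulate_replicate_table(pop)
  tr <- attr(tab, "truth")
  cons <- call_consensus(tab, samples = tr$sample_id[tr$good][1:10])
  cons2 <- call_consensus(tab[paste(tab$sample_id, tab$locus) %in%
                                paste(cons$sample_id, cons$locus), ],
                          samples = unique(cons$sample_id))
  expect_equal(cons$call, cons2$call)
  expect_equal(cons$allele1, cons2$allele1)
  # every cell with >= 3 successful replicates equals the truth
  msat <- cons[cons$locus != "ZF" & cons$n_success >= 3, ]
  loci <- pop$loci$locus
  for (i in seq_len(nrow(msat))) {
    ind <- tr$individual_id[tr$sample_id == msat$sample_id[i]]
    li <- match(msat$locus[i], loci)
    expect_equal(c(msat$allele1[i], msat$allele2[i]),
                 unname(pop$genotypes[ind, c(2 * li - 1, 2 * li)]))
  }
})

test_that("error-rate estimators count dropout and false alleles correctly", {
  tab <- make_replicate_table(list(
    list(sample = "s1", locus = "L01",
         reps = list(c(150, 154), c(150, 154), c(150, 150), c(150, 154)))
  ))
  cons <- call_consensus(tab)
  er <- estimate_error_rates(tab, cons)
  expect_equal(er$per_locus$ado, 1 / 4)   # one dropout replicate of four
  expect_equal(er$per_locus$fa, 0)
  # all replicates equal to consensus: both rates zero
  tab0 <- make_replicate_table(list(
    list(sample = "s1", locus = "L01",
         reps = list(c(150, 154), c(150, 154)))))
  er0 <- estimate_error_rates(tab0, call_consensus(tab0))
  expect_equal(er0$cumulative, c(ado = 0, fa = 0))
})

test_that("error-rate estimators are consistent at the generator's rates", {
  cfg <- sim_config(seed = 31)
  pop <- simulate_population(cfg)
  tab <- simulate_replicate_table(pop)
  tr <- attr(tab, "truth")
  cons <- call_consensus(tab, samples = tr$sample_id[tr$good])
  er <- estimate_error_rates(tab[tab$locus != "ZF", ],
                             cons[cons$locus != "ZF", ])
  n_het <- sum(er$per_locus$n_het_reps)
  expect_gt(n_het, 1000)
  expect_lt(abs(er$cumulative["ado"] - cfg$ado_rate),
            3 * sqrt(0.21 * 0.79 / n_het) + 0.02)
  expect_lt(abs(er$cumulative["fa"] - cfg$fa_rate), 0.005)
})

test_that("Brookfield estimator follows its closed form", {
  expect_equal(null_allele_frequency(0.5, 0.5), 0)
  expect_equal(null_allele_frequency(0.5, 0.25), 0.25 / 1.5)
  # strong heterozygote deficit gives a large positive estimate
  expect_gt(null_allele_frequency(0.66, 0.13), 0.3)
  expect_lt(null_allele_frequency(0.2, 0.4), 0)
})
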