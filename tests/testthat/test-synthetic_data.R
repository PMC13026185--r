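test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(ado_rate = 1.2), "probabilities")
  expect_error(sim_config(diet_profile = c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(sim_config(scats_per_individual = 0), ">= 1")
})

test_that("degenerate pedigrees give the forced structures", {
  one <- data.frame(id = "A", sex = "male", father = NA, mother = NA,
                    sampled = TRUE, stringsAsFactors = FALSE)
  cfg <- sim_config(pedigree_spec = one, n_loci = 1,
                    alleles_per_locus = c(2, 2),
                    scats_per_individual = 2, seed = 3)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$individuals), 1)
  expect_equal(nrow(pop$dyads), 0)

  trio <- data.frame(id = c("A", "B", "C"),
                     sex = c("male", "female", "male"),
                     father = c(NA, NA, "A"), mother = c(NA, NA, "B"),
                     sampled = TRUE, stringsAsFactors = FALSE)
  dy <- pedigree_dyads(trio, trio$id)
  expect_equal(sum(dy$category == "PO"), 2)
  expect_equal(sum(dy$category == "U"), 1)
})

test_that("cyclic pedigrees are rejected naming the cycle", {
  cyc <- data.frame(id = c("A", "B"), sex = c("male", "female"),
                    father = c("B", "A"), mother = c(NA, NA),
                    sampled = TRUE, stringsAsFactors = FALSE)
  expect_error(simulate_population(sim_config(pedigree_spec = cyc)), "cycle")
})

test_that("default pedigree carries the emulated kin structure", {
  pop <- simulate_population(sim_config(seed = 1))
  counts <- table(pop$dyads$category)
  expect_equal(unname(counts["PO"]), 5)
  expect_equal(unname(counts["FS"]), 4)
  expect_equal(sum(pop$individuals$sex == "male"), 6)
  expect_equal(sum(pop$individuals$sex == "female"), 3)
})

test_that("PO dyads always share an allele identical-by-state", {
  # Mendelian transmission forces one shared allele in every PO pair
  set.seed(42)
  fr <- make_eq_freqs(1, 4)
  shares <- vapply(1:10000, function(i) {
    g <- simulate_dyad(fr, c(0, 1, 0))
    length(intersect(g$g1, g$g2)) >= 1
  }, logical(1))
  expect_equal(mean(shares), 1.0)
})

test_that("replicate tables are deterministic and truth-consistent", {
  cfg <- sim_config(seed = 11)
  pop <- simulate_population(cfg)
  t1 <- simulate_replicate_table(pop)
  t2 <- simulate_replicate_table(pop)
  expect_identical(t1, t2)
  tr <- attr(t1, "truth")
  expect_setequal(unique(tr$individual_id), pop$individuals$id)
  # fixed capture mode realises the configured good-scat counts exactly
  good <- tr[tr$good, ]
  expect_equal(sort(as.integer(table(good$individual_id))),
               sort(cfg$scats_per_individual))
})

test_that("zero-noise replicates equal the true genotype", {
  cfg <- sim_config(seed = 5, ado_rate = 0, fa_rate = 0,
                    locus_failure_rate = 0, sample_success_rate = 1)
  pop <- simulate_population(cfg)
  tab <- simulate_replicate_table(pop)
  tr <- attr(tab, "truth")
  loci <- pop$loci$locus
  for (s in sample(tr$sample_id, 5)) {
    ind <- tr$individual_id[tr$sample_id == s]
    for (l in sample(loci, 3)) {
      li <- match(l, loci)
      reps <- tab[tab$sample_id == s & tab$locus == l, ]
      truthg <- pop$genotypes[ind, c(2 * li - 1, 2 * li)]
      expect_true(all(reps$allele1 == truthg[1] & reps$allele2 == truthg[2]))
    }
  }
})

test_that("configured error rates are recovered empirically", {
  # binomial 3-SD bands at n >= 10^4 heterozygous replicates
  cfg <- sim_config(seed = 21)
  set.seed(99)
  fr <- c(a = 150L, b = 154L)
  alleles <- c(150L, 152L, 154L, 156L)
  n <- 20000
  obs <- t(vapply(seq_len(n), function(i)
    scatpop:::simulate_one_replicate(fr, alleles, 0, 0.21, 0.005), integer(2)))
  drop_frac <- mean(obs[, 1] == obs[, 2])
  expect_lt(abs(drop_frac - 0.21), 3 * sqrt(0.21 * 0.79 / n) + 0.005)
  # ado_rate = 1: every successful replicate shows exactly one allele
  obs1 <- t(vapply(seq_len(200), function(i)
    scatpop:::simulate_one_replicate(fr, alleles, 0, 1, 0), integer(2)))
  expect_true(all(obs1[, 1] == obs1[, 2]))
})

test_that("diet generator honours degenerate configurations", {
  cfg <- sim_config(seed = 2, diet_profile = c(Aegialomys_xanthaeolus = 1),
                    contam_rate = 0, diet_success_rate = 1,
                    meal_size_probs = c(1, 0, 0))
  pop <- simulate_population(cfg)
  dt <- simulate_diet_table(pop, cfg, n_scats = 30)
  expect_true(all(dt$taxon == "Aegialomys_xanthaeolus"))
  det <- filter_reads(dt)
  expect_equal(unname(foo(det)), 1.0)
  expect_equal(unname(wpoo(det)), 1.0)
  expect_error(simulate_diet_table(pop, sim_config(diet_profile = numeric(0))),
               "sum to 1|non-empty")
})

test_that("wPOO of the generator's own profile is recovered at N = 200", {
  cfg <- sim_config(seed = 1, diet_success_rate = 1)
  pop <- simulate_population(cfg)
  dt <- simulate_diet_table(pop, cfg, n_scats = 200)
  det <- filter_reads(dt)
  w <- wpoo(det)
  expect_true(all(abs(w - cfg$diet_profile[names(w)]) < 0.05))
})
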