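# shared fixtures, built in code

# equifrequent allele-frequency object: L loci x k alleles on a 2-bp ladder
make_eq_freqs <- function(L = 8L, k = 4L) {
  fr <- lapply(seq_len(L), function(i)
    list(freq = stats::setNames(rep(1 / k, k), 100 + 2 * (0:(k - 1))),
         n_genes = Inf))
  names(fr) <- sprintf("L%02d", seq_len(L))
  structure(fr, class = "allele_freqs")
}

# genotype matrix drawn in Hardy-Weinberg proportions from an allele_freqs
geno_from_hw <- function(freqs, n, seed = 1L) {
  L <- length(freqs)
  m <- matrix(NA_integer_, n, 2 * L,
              dimnames = list(sprintf("I%02d", seq_len(n)),
                              paste0(rep(names(freqs), each = 2), c(".1", ".2"))))
  set.seed(seed)
  for (l in seq_len(L)) {
    fr <- freqs[[l]]$freq
    sizes <- as.integer(names(fr))
    a <- sizes[sample.int(length(sizes), 2 * n, replace = TRUE, prob = fr)]
    m[, 2 * l - 1] <- pmin(a[seq_len(n)], a[n + seq_len(n)])
    m[, 2 * l] <- pmax(a[seq_len(n)], a[n + seq_len(n)])
  }
  m
}

# tiny replicate table from a list of cells:
# list(list(sample, locus, reps = list(c(a, b), ...)), ...)
make_replicate_table <- function(cells) {
  rows <- list()
  for (cell in cells) {
    for (r in seq_along(cell$reps)) {
      p <- sort(cell$reps[[r]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cell$sample, locus = cell$locus, replicate = r,
        allele1 = p[1], allele2 = p[2], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("replicate_table", "data.frame")
  tab
}

# run the identification chain of the pipeline on one generator seed and
# return the number of individuals recovered
recovered_individuals <- function(seed, cfg_args = list()) {
  cfg <- do.call(sim_config, c(list(seed = seed), cfg_args))
  pop <- simulate_population(cfg)
  tab <- simulate_replicate_table(pop)
  loci <- sort(setdiff(unique(tab$locus), "ZF"))
  ret <- screen_samples(tab, loci)
  cons <- call_consensus(tab, samples = ret)
  inds <- match_individuals(cons)
  nrow(inds$individuals)
}
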