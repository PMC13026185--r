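#' Per-locus diversity table
#'
#' Computes, for each locus with at least two typed individuals: allele count
#' (Na), rarefied allelic richness (AR), observed heterozygosity (Ho),
#' expected heterozygosity (He = 1 - sum(p^2), or Nei's unbiased variant),
#' and Weir & Cockerham's f (F_IS). Loci with all-missing data are excluded
#' and reported in the `excluded` attribute.
#'
#' @param geno Genotype matrix (one row per individual; see
#'   [consensus_to_matrix()]).
#' @param rarefy_g Gene count to rarefy AR to; default is the smallest
#'   non-missing gene count across included loci.
#' @param unbiased_he Use Nei's unbiased He (`2n/(2n-1) * (1 - sum p^2)`).
#' @return A `diversity_table` data.frame (`locus`, `N`, `Na`, `AR`, `Ho`,
#'   `He`, `Fis`) with a `summary` attribute holding across-loci mean and SE,
#'   plus `rarefy_g` and `excluded` attributes.
#' @export
diversity_table <- function(geno, rarefy_g = NULL, unbiased_he = FALSE) {
  loci <- unique(sub("\\.[12]$", "", colnames(geno)))
  per <- list(); excluded <- character(0)
  gene_counts <- integer(0)
  for (l in loci) {
    a1 <- geno[, paste0(l, ".1")]; a2 <- geno[, paste0(l, ".2")]
    ok <- !is.na(a1) & !is.na(a2)
    if (sum(ok) < 2) { excluded <- c(excluded, l); next }
    gene_counts[l] <- 2L * sum(ok)
  }
  stop_if(length(gene_counts) == 0, "no usable loci")
  g <- rarefy_g %||% min(gene_counts)

  wc_b <- wc_c <- 0
  for (l in names(gene_counts)) {
    a1 <- geno[, paste0(l, ".1")]; a2 <- geno[, paste0(l, ".2")]
    ok <- !is.na(a1) & !is.na(a2)
    a1 <- a1[ok]; a2 <- a2[ok]
    n <- length(a1); N <- 2L * n
    tb <- table(c(a1, a2))
    p <- as.numeric(tb) / N
    na <- length(tb)
    ho <- mean(a1 != a2)
    he <- 1 - sum(p^2)
    if (unbiased_he) he <- N / (N - 1) * he
    counts <- as.numeric(tb)
    ar <- sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
    # Weir & Cockerham (1984) f, single population: variance components per
    # allele; h_i = proportion of individuals heterozygous for allele i
    h <- vapply(names(tb), function(al) {
      al <- as.numeric(al)
      mean((a1 == al) != (a2 == al))
    }, numeric(1))
    b_i <- n / (n - 1) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
    c_i <- h / 2
    fis <- if (sum(b_i + c_i) > 0) 1 - sum(c_i) / sum(b_i + c_i) else NA_real_
    wc_b <- wc_b + sum(b_i); wc_c <- wc_c + sum(c_i)
    per[[l]] <- data.frame(locus = l, N = n, Na = na, AR = ar, Ho = ho,
                           He = he, Fis = fis, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  summ <- summarize_diversity(out, cols = c("N", "Na", "AR", "Ho", "He", "Fis"))
  attr(out, "summary") <- summ
  attr(out, "fis_multilocus") <- if ((wc_b + wc_c) > 0)
    1 - wc_c / (wc_b + wc_c) else NA_real_
  attr(out, "rarefy_g") <- g
  attr(out, "excluded") <- excluded
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Across-loci mean and standard error of diversity columns
#'
#' Reproduces the "Overall / SE" rows of a per-locus summary table:
#' mean and `sd/sqrt(L)` over loci for each requested column.
#'
#' @param tbl A per-locus data.frame.
#' @param cols Columns to summarize.
#' @return data.frame with rows `mean` and `se`.
#' @export
summarize_diversity <- function(tbl, cols = c("Na", "AR", "Ho", "He")) {
  cols <- intersect(cols, names(tbl))
  res <- vapply(cols, function(cn) mean_se(tbl[[cn]]), numeric(2))
  out <- as.data.frame(res)
  rownames(out) <- c("mean", "se")
  out
}

#' Monte Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The test statistic is the conditional probability of the genotype array
#' given the allele counts (Levene / Guo-Thompson); the null is generated by
#' reshuffling the 2n alleles into n genotypes. `p` is the fraction of
#' permuted arrays at most as probable as the observed one, with the +1/+1
#' Monte Carlo correction.
#'
#' @param geno Genotype matrix.
#' @param locus Locus name.
#' @param n_perm Number of permutations (must be >= 1).
#' @param seed Seed.
#' @return p-value (1.0 for a monomorphic locus).
#' @export
hwe_exact_test <- function(geno, locus, n_perm = 2000L, seed = 1L) {
  stop_if(n_perm < 1, "n_perm must be >= 1")
  a1 <- geno[, paste0(locus, ".1")]; a2 <- geno[, paste0(locus, ".2")]
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  alleles <- unique(c(a1, a2))
  if (length(alleles) < 2) return(1.0)
  n <- length(a1)
  # log conditional probability terms that vary under permutation:
  # h*log(2) - sum(lfactorial(genotype counts))
  arr_stat <- function(x1, x2) {
    g <- paste(pmin(x1, x2), pmax(x1, x2))
    h <- sum(x1 != x2)
    h * log(2) - sum(lfactorial(table(g)))
  }
  obs <- arr_stat(a1, a2)
  pool <- c(a1, a2)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample(pool)
      s <- arr_stat(perm[seq_len(n)], perm[seq_len(n) + n])
      if (s <= obs + 1e-9) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

#' Pairwise genotypic linkage-disequilibrium tests
#'
#' For every pair of polymorphic loci, a log-likelihood-ratio (G) statistic
#' for association between the genotype classifications, with the null
#' distribution obtained by permuting one locus's genotypes across
#' individuals. Pairs with fewer than 5 complete observations are reported
#' with a missing p-value.
#'
#' @param geno Genotype matrix.
#' @param n_perm Permutations per pair.
#' @param seed Seed.
#' @return data.frame `locus1`, `locus2`, `n`, `p`.
#' @export
ld_pairwise_test <- function(geno, n_perm = 2000L, seed = 1L) {
  stop_if(n_perm < 1, "n_perm must be >= 1")
  loci <- unique(sub("\\.[12]$", "", colnames(geno)))
  poly <- loci[vapply(loci, function(l) {
    a <- c(geno[, paste0(l, ".1")], geno[, paste0(l, ".2")])
    length(unique(a[!is.na(a)])) >= 2
  }, logical(1))]
  if (length(poly) < 2) {
    return(data.frame(locus1 = character(0), locus2 = character(0),
                      n = integer(0), p = numeric(0)))
  }
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sel <- tab > 0
    2 * sum(tab[sel] * log(tab[sel] / e[sel]))
  }
  prs <- utils::combn(poly, 2)
  out <- vector("list", ncol(prs))
  with_seed(seed, {
    for (k in seq_len(ncol(prs))) {
      l1 <- prs[1, k]; l2 <- prs[2, k]
      g1 <- paste(geno[, paste0(l1, ".1")], geno[, paste0(l1, ".2")])
      g2 <- paste(geno[, paste0(l2, ".1")], geno[, paste0(l2, ".2")])
      ok <- !is.na(geno[, paste0(l1, ".1")]) & !is.na(geno[, paste0(l2, ".1")])
      g1 <- g1[ok]; g2 <- g2[ok]
      if (sum(ok) < 5) {
        out[[k]] <- data.frame(locus1 = l1, locus2 = l2, n = sum(ok),
                               p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      obs <- gstat(g1, g2)
      hits <- 0L
      for (i in seq_len(n_perm)) {
        if (gstat(g1, sample(g2)) >= obs - 1e-9) hits <- hits + 1L
      }
      out[[k]] <- data.frame(locus1 = l1, locus2 = l2, n = sum(ok),
                             p = (hits + 1) / (n_perm + 1),
                             stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p Vector of p-values in \[0, 1\] (NAs passed through).
#' @return Adjusted p-values (monotone step-up; always >= raw).
#' @export
bh_fdr <- function(p) {
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Friedman comparison of expected heterozygosity across localities
#'
#' Loci are treated as repeated measures (blocks) and localities as
#' treatments. The Friedman chi-square uses average ranks; the p-value is an
#' exact within-block permutation enumeration when `(k!)^n` is small enough,
#' otherwise the chi-square approximation with `df = k - 1`. When the overall
#' test is significant at `alpha`, all pairwise two-sided Wilcoxon
#' signed-rank tests are run with BH adjustment.
#'
#' @param he Numeric matrix, loci x localities; no missing cells allowed.
#' @param alpha Significance gate for the post hoc tests.
#' @param exact_limit Maximum number of permutation states for exact
#'   enumeration.
#' @return List `chi2`, `df`, `p`, `p_method`, `pairwise` (data.frame or NULL).
#' @export
friedman_locality_comparison <- function(he, alpha = 0.05,
                                         exact_limit = 1e5) {
  he <- as.matrix(he)
  stop_if(ncol(he) < 2 || nrow(he) < 2,
          "need >= 2 localities and >= 2 loci")
  if (anyNA(he)) {
    bad <- which(is.na(he), arr.ind = TRUE)
    stop_if(TRUE, "missing cells: %s",
            paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  }
  n <- nrow(he); k <- ncol(he)
  fr_stat <- function(m) {
    r <- t(apply(m, 1, rank))
    rj <- colSums(r)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  chi2 <- fr_stat(he)
  n_states <- factorial(k)^n
  if (n_states <= exact_limit) {
    perms <- asplit(permutations_of(k), 1)
    idx <- rep(1L, n)
    total <- 0L; hits <- 0L
    repeat {
      m <- t(vapply(seq_len(n), function(i) he[i, perms[[idx[i]]]],
                    numeric(k)))
      total <- total + 1L
      if (fr_stat(m) >= chi2 - 1e-9) hits <- hits + 1L
      j <- 1L
      repeat {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(perms)) break
        idx[j] <- 1L; j <- j + 1L
        if (j > n) break
      }
      if (j > n) break
    }
    p <- hits / total
    p_method <- "exact"
  } else {
    p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
    p_method <- "chisq"
  }
  pairwise <- NULL
  if (!is.na(p) && p <= alpha && k > 2) {
    prs <- utils::combn(k, 2)
    pw <- apply(prs, 2, function(ij) {
      suppressWarnings(stats::wilcox.test(he[, ij[1]], he[, ij[2]],
                                          paired = TRUE)$p.value)
    })
    pairwise <- data.frame(
      locality1 = colnames(he)[prs[1, ]] %||% prs[1, ],
      locality2 = colnames(he)[prs[2, ]] %||% prs[2, ],
      p = pw, p_adj = bh_fdr(pw))
  }
  list(chi2 = chi2, df = k - 1, p = p, p_method = p_method,
       pairwise = pairwise)
}

# all permutations of 1..k as a matrix (k! x k)
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}
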