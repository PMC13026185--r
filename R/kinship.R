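# Cotterman coefficients of the four pedigree relationship categories:
# probabilities of sharing 0/1/2 alleles identical by descent.
KIN_CATEGORIES <- list(
  U  = c(1, 0, 0),
  HS = c(0.5, 0.5, 0),
  FS = c(0.25, 0.5, 0.25),
  PO = c(0, 1, 0)
)

# P(genotype) under Hardy-Weinberg for an unordered pair c(a, b)
p_geno <- function(g, fr) {
  pa <- fr[as.character(g[1])]; pb <- fr[as.character(g[2])]
  if (g[1] == g[2]) unname(pa^2) else unname(2 * pa * pb)
}

# transition probability P(G2 | G1 shares exactly one IBD allele)
trans1 <- function(g1, g2, fr) {
  p <- function(a) unname(fr[as.character(a)])
  if (g1[1] == g1[2]) {                 # G1 homozygous (a,a)
    a <- g1[1]
    if (!(a %in% g2)) return(0)
    if (g2[1] == g2[2]) return(if (g2[1] == a) p(a) else 0)
    other <- if (g2[1] == a) g2[2] else g2[1]
    return(p(other))
  }
  a <- g1[1]; b <- g1[2]                # G1 heterozygous (a,b)
  if (g2[1] == g2[2]) {
    if (g2[1] == a) return(p(a) / 2)
    if (g2[1] == b) return(p(b) / 2)
    return(0)
  }
  s <- intersect(g1, g2)
  if (length(s) == 0) return(0)
  if (length(s) == 2) return((p(a) + p(b)) / 2)
  other <- setdiff(g2, s)
  p(other) / 2
}

# per-locus likelihood components P0, P1, P2 for a dyad; loci with missing
# data in either genotype are skipped. Returns an L x 3 matrix.
dyad_components <- function(g1, g2, freqs) {
  loci <- names(freqs)
  comp <- matrix(NA_real_, 0, 3, dimnames = list(NULL, c("P0", "P1", "P2")))
  for (i in seq_along(loci)) {
    a <- g1[c(2 * i - 1, 2 * i)]; b <- g2[c(2 * i - 1, 2 * i)]
    if (anyNA(a) || anyNA(b)) next
    fr <- freqs[[i]]$freq
    missing_alleles <- setdiff(as.character(c(a, b)), names(fr))
    stop_if(length(missing_alleles) > 0,
            "allele(s) %s absent from frequencies at locus %s",
            paste(missing_alleles, collapse = ", "), loci[i])
    pg1 <- p_geno(a, fr)
    p0 <- pg1 * p_geno(b, fr)
    p1 <- pg1 * trans1(a, b, fr)
    p2 <- pg1 * as.numeric(all(sort(a) == sort(b)))
    comp <- rbind(comp, c(p0, p1, p2))
  }
  comp
}

#' Log-likelihood of a dyad under Cotterman coefficients k
#'
#' `P(G1, G2 | k) = k0 P0 + k1 P1 + k2 P2` per locus, multiplied across loci;
#' P0 is the product of genotype probabilities, P2 requires identity, and P1
#' uses the standard unordered-genotype one-IBD transition table.
#'
#' @param g1,g2 Genotype vectors (two entries per locus, order matching
#'   `freqs`; `NA` = missing, the locus is skipped).
#' @param freqs An [allele_freqs()] object.
#' @param k Numeric `c(k0, k1, k2)` on the simplex.
#' @return Log-likelihood (may be `-Inf` under exclusion).
#' @export
dyad_log_likelihood <- function(g1, g2, freqs, k) {
  stop_if(abs(sum(k) - 1) > 1e-9 || any(k < -1e-12),
          "k must lie on the probability simplex")
  comp <- dyad_components(g1, g2, freqs)
  sum(log(comp %*% k))
}

# simplex grid with given step; rows (k0, k1, k2)
k_simplex_grid <- function(step) {
  k2 <- seq(0, 1, by = step)
  out <- list()
  for (z in k2) {
    k1 <- seq(0, 1 - z, by = step)
    out[[length(out) + 1L]] <- cbind(1 - z - k1, k1, z)
  }
  g <- do.call(rbind, out)
  colnames(g) <- c("k0", "k1", "k2")
  g
}

# maximum-likelihood k over the simplex: coarse grid then local refinement;
# deterministic tie-break toward larger k0.
ml_k <- function(comp, step = 0.01) {
  best_of <- function(grid) {
    ll <- colSums(log(comp %*% t(grid)))
    ll[is.nan(ll)] <- -Inf
    top <- which(ll == max(ll))
    top <- top[order(-grid[top, 1])][1]
    list(k = grid[top, ], ll = ll[top])
  }
  coarse <- best_of(k_simplex_grid(step))
  lo <- pmax(coarse$k - step, 0)
  fine_k1 <- seq(lo[2], min(coarse$k[2] + step, 1), by = step / 10)
  fine_k2 <- seq(lo[3], min(coarse$k[3] + step, 1), by = step / 10)
  grid <- as.matrix(expand.grid(k1 = fine_k1, k2 = fine_k2))
  grid <- grid[grid[, 1] + grid[, 2] <= 1 + 1e-12, , drop = FALSE]
  grid <- cbind(k0 = pmax(1 - grid[, 1] - grid[, 2], 0), grid)
  fine <- best_of(grid)
  if (fine$ll > coarse$ll) fine else coarse
}

#' Classify a dyad into U / HS / FS / PO
#'
#' Evaluates the four fixed Cotterman vectors, picks the maximum-likelihood
#' category (ties resolved toward larger k0), computes the continuous ML
#' relatedness `r = k1/2 + k2` over the simplex (0.01 grid plus refinement),
#' and the log-likelihood margin to the runner-up. With `n_sim > 0`, a
#' parametric simulation support value is added: the fraction of dyads
#' simulated under the runner-up category whose margin exceeds the observed.
#'
#' @param g1,g2 Genotype vectors.
#' @param freqs [allele_freqs()].
#' @param n_sim Simulated dyads for the support value (0 = skip).
#' @param seed Seed for the simulation support.
#' @return List `category`, `r_ml`, `k_ml`, `delta_lnl`, `loglik` (per
#'   category), `n_loci`, `sim_support`. Category is `"unresolved"` with
#'   fewer than 4 shared informative loci.
#' @export
classify_dyad <- function(g1, g2, freqs, n_sim = 0L, seed = 1L) {
  comp <- dyad_components(g1, g2, freqs)
  if (nrow(comp) < 4) {
    return(list(category = "unresolved", r_ml = NA_real_, k_ml = rep(NA_real_, 3),
                delta_lnl = NA_real_, loglik = NULL, n_loci = nrow(comp),
                sim_support = NA_real_))
  }
  ll <- vapply(KIN_CATEGORIES, function(k) sum(log(comp %*% k)), numeric(1))
  ord <- order(ll, decreasing = TRUE)
  category <- names(ll)[ord[1]]
  delta <- ll[ord[1]] - ll[ord[2]]
  opt <- ml_k(comp)
  r_ml <- unname(opt$k[2] / 2 + opt$k[3])
  sim_support <- NA_real_
  if (n_sim > 0) {
    runner <- names(ll)[ord[2]]
    sim_support <- with_seed(seed, {
      margins <- vapply(seq_len(n_sim), function(i) {
        gg <- simulate_dyad(freqs, KIN_CATEGORIES[[runner]])
        cs <- dyad_components(gg$g1, gg$g2, freqs)
        lls <- vapply(KIN_CATEGORIES, function(k) sum(log(cs %*% k)), numeric(1))
        o <- order(lls, decreasing = TRUE)
        lls[o[1]] - lls[o[2]]
      }, numeric(1))
      mean(margins > delta)
    })
  }
  list(category = category, r_ml = r_ml, k_ml = opt$k,
       delta_lnl = unname(delta), loglik = ll, n_loci = nrow(comp),
       sim_support = sim_support)
}

#' Simulate a dyad with given Cotterman coefficients
#'
#' Per locus the IBD state (0/1/2 shared alleles) is drawn from `k`; shared
#' alleles are copied, the rest drawn independently from the allele
#' frequencies. Used for classification support values and recovery tests.
#'
#' @param freqs [allele_freqs()].
#' @param k `c(k0, k1, k2)`.
#' @return List `g1`, `g2` genotype vectors (2 entries per locus).
#' @export
simulate_dyad <- function(freqs, k) {
  L <- length(freqs)
  g1 <- integer(2 * L); g2 <- integer(2 * L)
  for (i in seq_len(L)) {
    fr <- freqs[[i]]$freq
    sizes <- as.integer(names(fr))
    draw <- function(n) sizes[sample.int(length(sizes), n, replace = TRUE, prob = fr)]
    a <- draw(2)
    ibd <- sample.int(3, 1, prob = k) - 1L
    b <- switch(as.character(ibd),
                "0" = draw(2),
                "1" = c(a[sample.int(2, 1)], draw(1)),
                "2" = a)
    g1[c(2 * i - 1, 2 * i)] <- sort(a)
    g2[c(2 * i - 1, 2 * i)] <- sort(b)
  }
  list(g1 = g1, g2 = g2)
}

# unbiased estimators of sum(p^m) from allele counts (falling factorials)
power_sums <- function(fr, n_genes) {
  p <- unname(fr)
  if (!is.finite(n_genes)) {
    return(c(a2 = sum(p^2), a3 = sum(p^3), a4 = sum(p^4)))
  }
  x <- p * n_genes
  n <- n_genes
  a2 <- sum(x * (x - 1)) / (n * (n - 1))
  a3 <- sum(x * (x - 1) * (x - 2)) / (n * (n - 1) * (n - 2))
  a4 <- sum(x * (x - 1) * (x - 2) * (x - 3)) / (n * (n - 1) * (n - 2) * (n - 3))
  c(a2 = max(a2, 0), a3 = max(a3, 0), a4 = max(a4, 0))
}

#' Wang-type moment estimator of pairwise relatedness
#'
#' Moment estimator in the spirit of Wang (2002): the observed genotype-pair
#' similarity class at each locus (identical; one homozygote/one heterozygote
#' sharing an allele; two heterozygotes sharing exactly one allele; no
#' sharing) is matched to its expectation, which is linear in the two-gene
#' and four-gene IBD coefficients (phi, Delta). The system is solved by
#' weighted least squares across loci with Wang's locus weights
#' `1/(2*a2 - a3)`, using unbiased small-sample estimates of the allele
#' frequency power sums. `r = phi/2 + Delta`; unbounded below.
#'
#' @param g1,g2 Genotype vectors.
#' @param freqs [allele_freqs()] (its `n_genes` drives the bias correction).
#' @return Relatedness estimate, or `NA` if no polymorphic locus is shared.
#' @export
wang_relatedness <- function(g1, g2, freqs) {
  loci <- names(freqs)
  X <- NULL; y <- NULL; w <- NULL
  for (i in seq_along(loci)) {
    a <- g1[c(2 * i - 1, 2 * i)]; b <- g2[c(2 * i - 1, 2 * i)]
    if (anyNA(a) || anyNA(b)) next
    fr <- freqs[[i]]$freq
    if (length(fr) < 2) next
    ps <- power_sums(fr, freqs[[i]]$n_genes)
    a2 <- ps["a2"]; a3 <- ps["a3"]; a4 <- ps["a4"]
    # class probabilities under 0/1/2 IBD alleles (columns: c0, c1, c2)
    cmat <- rbind(
      s1 = c(2 * a2^2 - a4,                 a2,               1),
      s2 = c(4 * (a3 - a4),                 2 * (a2 - a3),    0),
      s3 = c(4 * (a2 - a2^2 - 2 * a3 + 2 * a4), 1 - 3 * a2 + 2 * a3, 0)
    )
    ident <- all(sort(a) == sort(b))
    shared <- length(intersect(a, b))
    hom1 <- a[1] == a[2]; hom2 <- b[1] == b[2]
    s <- c(
      s1 = as.numeric(ident),
      s2 = as.numeric(!ident & xor(hom1, hom2) & shared >= 1),
      s3 = as.numeric(!ident & !hom1 & !hom2 & shared == 1)
    )
    u <- 2 * a2 - a3
    if (u <= 0) next
    X <- rbind(X, cbind(cmat[, 2] - cmat[, 1], cmat[, 3] - cmat[, 1]))
    y <- c(y, s - cmat[, 1])
    w <- c(w, rep(1 / u, 3))
  }
  if (is.null(X)) return(NA_real_)
  fit <- stats::lm.wfit(x = X, y = y, w = w)
  phi <- fit$coefficients[1]; delta <- fit$coefficients[2]
  if (anyNA(c(phi, delta))) return(NA_real_)
  unname(phi / 2 + delta)
}

#' All-pairs kinship matrix
#'
#' @param geno Genotype matrix (one row per individual).
#' @param freqs [allele_freqs()].
#' @param n_sim Simulation-support draws per dyad (0 = skip).
#' @param seed Seed.
#' @return data.frame `id1`, `id2`, `category`, `r_ml`, `r_wang`,
#'   `delta_lnl`, `n_loci`, with a `category_counts` attribute.
#' @export
kin_matrix <- function(geno, freqs, n_sim = 0L, seed = 1L) {
  ids <- rownames(geno)
  stop_if(length(ids) < 2, "need >= 2 individuals")
  prs <- utils::combn(ids, 2)
  out <- vector("list", ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    cl <- classify_dyad(geno[i, ], geno[j, ], freqs, n_sim = n_sim,
                        seed = child_seed(seed, k))
    out[[k]] <- data.frame(
      id1 = i, id2 = j, category = cl$category, r_ml = cl$r_ml,
      r_wang = wang_relatedness(geno[i, ], geno[j, ], freqs),
      delta_lnl = cl$delta_lnl, n_loci = cl$n_loci,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "category_counts") <- table(factor(res$category,
    levels = c("U", "HS", "FS", "PO", "unresolved")))
  res
}
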