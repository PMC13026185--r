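#' Filter a taxon-assigned metabarcoding read table into detections
#'
#' Quality control in the order: (0) predator and human reads removed;
#' (i) within each PCR replicate, taxa at or below `min_prop` of the
#' replicate's total reads dropped; (ii) a taxon is retained for a sample
#' iff it survives step (i) in at least `min_reps` replicates. Samples with
#' no retained prey taxon are excluded from the sample count N.
#'
#' @param table A `diet_read_table` (columns `sample_id`, `pcr_replicate`,
#'   `taxon`, `reads`).
#' @param predator_taxa Taxa removed before proportional filtering.
#' @param min_prop Within-replicate read-proportion threshold (inclusive
#'   drop; default 0.005).
#' @param min_reps Minimum replicates a taxon must appear in (default 2).
#' @return A `diet_detections` list: `detections` (sample -> character vector
#'   of prey taxa), `taxa_per_sample` (T_s), `n_samples` (N),
#'   `taxon_counts` (n_i), `excluded` (sample ids), `sample_owner`
#'   (carried through if present on `table`).
#' @export
filter_reads <- function(table,
                         predator_taxa = c("Leopardus_garleppi", "Homo_sapiens"),
                         min_prop = 0.005, min_reps = 2L) {
  stopifnot(all(c("sample_id", "pcr_replicate", "taxon", "reads") %in%
                  names(table)))
  stop_if(any(table$reads < 0), "read counts must be non-negative")
  all_samples <- unique(table$sample_id)
  totals <- tapply(table$reads, table$sample_id, sum)
  zero <- names(totals)[totals == 0]
  tab <- table[!(table$taxon %in% predator_taxa) & table$reads > 0 &
                 !(table$sample_id %in% zero), ]

  detections <- list(); excluded <- zero
  for (s in setdiff(all_samples, zero)) {
    sub <- tab[tab$sample_id == s, ]
    kept <- character(0)
    if (nrow(sub) > 0) {
      reps_of <- split(sub, sub$pcr_replicate)
      per_rep <- lapply(reps_of, function(r) {
        tot <- sum(r$reads)
        r$taxon[r$reads > min_prop * tot]
      })
      cnt <- table(unlist(per_rep))
      kept <- names(cnt)[cnt >= min_reps]
    }
    if (length(kept) > 0) detections[[s]] <- sort(kept)
    else excluded <- c(excluded, s)
  }
  taxa <- sort(unique(unlist(detections)))
  structure(list(
    detections = detections,
    taxa_per_sample = vapply(detections, length, integer(1)),
    n_samples = length(detections),
    taxon_counts = vapply(taxa, function(t)
      sum(vapply(detections, function(d) t %in% d, logical(1))), integer(1)),
    excluded = excluded,
    sample_owner = attr(table, "sample_owner")
  ), class = "diet_detections")
}

#' Frequency of occurrence
#'
#' `FOO_i = n_i / N`: the fraction of retained samples containing taxon i.
#'
#' @param x A `diet_detections`, or a named vector of per-taxon detection
#'   counts (then `n_samples` is required).
#' @param n_samples Total retained samples N (only with count input).
#' @return Named numeric vector of FOO values.
#' @export
foo <- function(x, n_samples = NULL) {
  if (inherits(x, "diet_detections")) {
    stop_if(x$n_samples < 1, "no retained samples")
    return(x$taxon_counts / x$n_samples)
  }
  stop_if(is.null(n_samples) || n_samples < 1, "n_samples required")
  x / n_samples
}

#' Weighted percent of occurrence
#'
#' `wPOO_i = (1/N) * sum_s 1[i in s] / T_s`: each detection is weighted by
#' the number of prey taxa in its sample, so samples contribute equally and
#' the values sum to 1 over taxa.
#'
#' @param detections A `diet_detections`.
#' @return Named numeric vector summing to 1.
#' @export
wpoo <- function(detections) {
  stopifnot(inherits(detections, "diet_detections"))
  stop_if(detections$n_samples < 1, "no retained samples")
  taxa <- names(detections$taxon_counts)
  out <- stats::setNames(numeric(length(taxa)), taxa)
  for (s in names(detections$detections)) {
    d <- detections$detections[[s]]
    out[d] <- out[d] + 1 / length(d)
  }
  out / detections$n_samples
}

#' Per-individual mean diet profiles
#'
#' Averages each sample's equal-share composition (1/T_s per detected taxon)
#' over the samples of each individual; these unit-level profiles feed the
#' Bray-Curtis / PERMANOVA comparison without pseudoreplicating scats.
#'
#' @param detections A `diet_detections` whose `sample_owner` maps samples to
#'   individuals (or supply `owners`).
#' @param owners Optional named vector sample_id -> individual.
#' @return Matrix: individuals x taxa, rows summing to 1.
#' @export
individual_diet_profiles <- function(detections, owners = NULL) {
  owners <- owners %||% detections$sample_owner
  stop_if(is.null(owners), "no sample -> individual mapping available")
  taxa <- names(detections$taxon_counts)
  samp <- names(detections$detections)
  inds <- sort(unique(unname(owners[samp])))
  m <- matrix(0, length(inds), length(taxa), dimnames = list(inds, taxa))
  cnt <- stats::setNames(numeric(length(inds)), inds)
  for (s in samp) {
    d <- detections$detections[[s]]
    ind <- unname(owners[s])
    m[ind, d] <- m[ind, d] + 1 / length(d)
    cnt[ind] <- cnt[ind] + 1
  }
  sweep(m, 1, cnt, "/")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; symmetric with zero
#' diagonal, in \[0, 1\] for non-negative profiles.
#'
#' @param profiles Non-negative matrix, one composition per row (each row
#'   must have a positive sum).
#' @return Symmetric dissimilarity matrix.
#' @export
bray_curtis <- function(profiles) {
  profiles <- as.matrix(profiles)
  stop_if(any(profiles < 0), "profiles must be non-negative")
  stop_if(any(rowSums(profiles) == 0), "all-zero profile row")
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(abs(profiles[i, ] - profiles[j, ])) /
        sum(profiles[i, ] + profiles[j, ])
    }
  }
  d
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the squared dissimilarities (Gower) into between- and
#' within-group sums of squares; the pseudo-F is referenced to its
#' permutation distribution under random relabelling of units, with the
#' +1/+1 correction.
#'
#' @param d Dissimilarity matrix (square, symmetric).
#' @param groups Factor of group labels, one per unit.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Seed.
#' @return List `R2`, `F`, `p`, `df` (between, within).
#' @export
permanova <- function(d, groups, n_perm = 9999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  stop_if(length(groups) != n, "groups length must match units")
  stop_if(nlevels(groups) < 2, "need >= 2 groups")
  stop_if(any(table(groups) == 0), "empty group")
  stop_if(n - nlevels(groups) < 1, "no within-group degrees of freedom")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        s <- s + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    s
  }
  a <- nlevels(groups)
  f_of <- function(g) {
    ssw <- ss_within(g)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  ssw_obs <- ss_within(groups)
  r2 <- (ss_total - ssw_obs) / ss_total
  p <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (f_of(groups[sample.int(n)]) >= f_obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  list(R2 = r2, F = f_obs, p = p, df = c(between = a - 1, within = n - a))
}
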