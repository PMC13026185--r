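#' Screen samples by initial amplification success
#'
#' Applies the first step of the two-step multitube protocol: a sample is
#' retained iff the number of loci with at least one successful initial
#' replicate reaches `ceil(min_fraction * n_loci)` (the "40% rule").
#'
#' @param table A `replicate_table`.
#' @param loci Character vector of the microsatellite loci the screen is
#'   evaluated over (the sex marker is not part of the screen). Loci present
#'   in `table` but absent from `loci` (other than `"ZF"`) are an error.
#' @param min_fraction Minimum fraction of amplifying loci (default 0.40).
#' @param initial_replicates Number of initial duplicate PCRs (default 2).
#' @return Character vector of retained sample ids.
#' @export
screen_samples <- function(table, loci, min_fraction = 0.40,
                           initial_replicates = 2L) {
  stopifnot(is.data.frame(table))
  unknown <- setdiff(unique(table$locus), c(loci, "ZF"))
  stop_if(length(unknown) > 0, "unknown locus names in table: %s",
          paste(unknown, collapse = ", "))
  n_loci <- length(loci)
  need <- ceiling(min_fraction * n_loci)
  t0 <- table[table$locus %in% loci & table$replicate <= initial_replicates &
                table$allele1 > 0, c("sample_id", "locus")]
  amp <- unique(t0)
  cnt <- table(amp$sample_id)
  all_samples <- unique(table$sample_id)
  ok <- names(cnt)[cnt >= need]
  sort(intersect(all_samples, ok))
}

# Consensus kernel for one sample x locus cell.
# reps: 2-column matrix of successful replicate allele pairs (allele1 <= allele2).
consensus_cell <- function(reps) {
  n_success <- nrow(reps)
  if (n_success == 0) {
    return(list(call = "missing", a = 0L, b = 0L, support = c(0L, 0L),
                n_success = 0L, flag = ""))
  }
  sets <- lapply(seq_len(n_success), function(i) unique(reps[i, ]))
  alleles <- sort(unique(unlist(sets)))
  support <- vapply(alleles, function(a)
    sum(vapply(sets, function(s) a %in% s, logical(1))), integer(1))
  names(support) <- alleles
  confirmed <- alleles[support >= 2L]

  if (length(confirmed) > 2L) {
    return(list(call = "missing", a = 0L, b = 0L, support = c(0L, 0L),
                n_success = n_success, flag = "multi-allele conflict"))
  }
  if (length(confirmed) == 2L) {
    ab <- sort(confirmed)
    sup <- support[as.character(ab)]
    # a heterozygote whose weaker allele was seen only twice among >=5
    # successful replicates is consistent with a twice-repeated false allele
    flag <- if (min(sup) == 2L && n_success >= 5L) "low-confidence" else ""
    return(list(call = "het", a = ab[1], b = ab[2], support = as.integer(sup),
                n_success = n_success, flag = flag))
  }
  if (length(confirmed) == 1L) {
    a <- confirmed[1]
    only_a <- sum(vapply(sets, function(s) length(s) == 1L && s == a, logical(1)))
    if (only_a >= 3L) {
      # discordant alleles seen once do not void the call, but flag it
      flag <- if (n_success > only_a) "discordant-single" else ""
      return(list(call = "hom", a = a, b = a,
                  support = c(as.integer(only_a), as.integer(only_a)),
                  n_success = n_success, flag = flag))
    }
  }
  list(call = "missing", a = 0L, b = 0L, support = c(0L, 0L),
       n_success = n_success, flag = "")
}

#' Call consensus genotypes from replicate PCRs
#'
#' Multitube confirmation rules: a heterozygote requires each allele observed
#' in at least two replicates; a homozygote requires at least three successful
#' replicates showing only that allele (single discordant observations are
#' tolerated as presumed false alleles but flagged). Three or more alleles
#' each confirmed twice give a multi-allele conflict (missing). A confirmed
#' heterozygote takes precedence over a homozygote interpretation.
#'
#' @param table A `replicate_table` (all replicates of each cell are used).
#' @param samples Optional subset of sample ids (e.g. the screened set).
#' @return A `consensus_table` data.frame: `sample_id`, `locus`, `call`
#'   ("het", "hom", "missing"), `allele1`, `allele2` (0 when missing),
#'   `support1`, `support2`, `n_success`, `n_replicates`, `flag`.
#' @export
call_consensus <- function(table, samples = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(samples)) table <- table[table$sample_id %in% samples, ]
  key <- paste(table$sample_id, table$locus, sep = "\r")
  cells <- split(seq_len(nrow(table)), key)
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    idx <- cells[[i]]
    sid <- table$sample_id[idx[1]]
    loc <- table$locus[idx[1]]
    ok <- table$allele1[idx] > 0
    reps <- cbind(table$allele1[idx][ok], table$allele2[idx][ok])
    cc <- consensus_cell(reps)
    out[[i]] <- data.frame(sample_id = sid, locus = loc, call = cc$call,
                           allele1 = cc$a, allele2 = cc$b,
                           support1 = cc$support[1], support2 = cc$support[2],
                           n_success = cc$n_success,
                           n_replicates = length(idx), flag = cc$flag,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$locus), ]
  rownames(res) <- NULL
  class(res) <- c("consensus_table", "data.frame")
  res
}

#' Estimate allelic-dropout and false-allele rates
#'
#' ADO per locus is the fraction of successful replicates, at cells with a
#' heterozygous consensus, that show exactly one of the two consensus alleles.
#' FA per locus is the fraction of successful replicates, at cells with any
#' non-missing consensus, containing at least one allele absent from the
#' consensus call. Cumulative rates pool the counts across loci (replicate-
#' weighted means). Loci without heterozygous consensus have undefined ADO.
#'
#' @param table The `replicate_table` the consensus was called from.
#' @param consensus The matching `consensus_table`.
#' @return An `error_rates` list: `per_locus` data.frame (`locus`, `ado`,
#'   `fa`, `n_het_reps`, `n_reps`) and `cumulative` (named vector `ado`, `fa`).
#' @export
estimate_error_rates <- function(table, consensus) {
  loci <- sort(unique(consensus$locus))
  per <- data.frame(locus = loci, ado = NA_real_, fa = NA_real_,
                    n_het_reps = 0L, n_reps = 0L, stringsAsFactors = FALSE)
  ado_num <- ado_den <- fa_num <- fa_den <- stats::setNames(numeric(length(loci)), loci)

  cons_key <- paste(consensus$sample_id, consensus$locus, sep = "\r")
  tab_key <- paste(table$sample_id, table$locus, sep = "\r")
  m <- match(tab_key, cons_key)
  ok <- !is.na(m) & table$allele1 > 0
  tt <- table[ok, ]
  cc <- consensus[m[ok], ]

  for (l in loci) {
    sel <- tt$locus == l & cc$call != "missing"
    if (!any(sel)) next
    t_l <- tt[sel, ]; c_l <- cc[sel, ]
    # FA: replicate carries an allele outside the consensus pair
    outside <- (t_l$allele1 != c_l$allele1 & t_l$allele1 != c_l$allele2) |
               (t_l$allele2 != c_l$allele1 & t_l$allele2 != c_l$allele2)
    fa_num[l] <- sum(outside)
    fa_den[l] <- nrow(t_l)
    het <- c_l$call == "het"
    if (any(het)) {
      th <- t_l[het, ]; ch <- c_l[het, ]
      has_a <- th$allele1 == ch$allele1 | th$allele2 == ch$allele1
      has_b <- th$allele1 == ch$allele2 | th$allele2 == ch$allele2
      ado_num[l] <- sum(xor(has_a, has_b))
      ado_den[l] <- nrow(th)
    }
  }
  per$ado <- ifelse(ado_den > 0, ado_num / ado_den, NA_real_)
  per$fa <- ifelse(fa_den > 0, fa_num / fa_den, NA_real_)
  per$n_het_reps <- as.integer(ado_den)
  per$n_reps <- as.integer(fa_den)
  cumulative <- c(
    ado = if (sum(ado_den) > 0) sum(ado_num) / sum(ado_den) else NA_real_,
    fa = if (sum(fa_den) > 0) sum(fa_num) / sum(fa_den) else NA_real_
  )
  structure(list(per_locus = per, cumulative = cumulative),
            class = "error_rates")
}

#' Brookfield (1) null-allele frequency estimator
#'
#' @param He Expected heterozygosity at the locus.
#' @param Ho Observed heterozygosity.
#' @return `(He - Ho) / (1 + He)`; negative values are reported as-is and
#'   indicate no null-allele signal.
#' @export
null_allele_frequency <- function(He, Ho) {
  stop_if(!is_prob(He) || !is_prob(Ho), "He and Ho must be in [0, 1]")
  (He - Ho) / (1 + He)
}
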