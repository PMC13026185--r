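#' Convert a consensus table to a wide genotype matrix
#'
#' @param consensus A `consensus_table`.
#' @param loci Loci to include (default: all except the sex marker `ZF`).
#' @param drop_flagged Treat flagged (low-confidence) calls as missing. Used
#'   by the matcher so that single discordant observations cannot split a true
#'   recapture into a spurious new individual.
#' @return Integer matrix, one row per sample, two columns per locus
#'   (`<locus>.1`, `<locus>.2`), `NA` = missing.
#' @export
consensus_to_matrix <- function(consensus, loci = NULL, drop_flagged = FALSE) {
  if (is.null(loci)) loci <- sort(setdiff(unique(consensus$locus), "ZF"))
  samples <- sort(unique(consensus$sample_id))
  m <- matrix(NA_integer_, length(samples), 2L * length(loci),
              dimnames = list(samples,
                              paste0(rep(loci, each = 2), c(".1", ".2"))))
  cc <- consensus[consensus$locus %in% loci & consensus$call != "missing", ]
  if (drop_flagged) cc <- cc[cc$flag == "", ]
  li <- match(cc$locus, loci)
  ri <- match(cc$sample_id, samples)
  m[cbind(ri, 2L * li - 1L)] <- cc$allele1
  m[cbind(ri, 2L * li)] <- cc$allele2
  m
}

#' Allele frequencies from a genotype matrix
#'
#' @param geno Genotype matrix (two columns per locus, `NA` missing).
#' @return An `allele_freqs` object: per locus a list with `freq` (named
#'   numeric, sums to 1) and `n_genes` (non-missing gene count).
#' @export
allele_freqs <- function(geno) {
  loci <- unique(sub("\\.[12]$", "", colnames(geno)))
  out <- lapply(loci, function(l) {
    a <- c(geno[, paste0(l, ".1")], geno[, paste0(l, ".2")])
    a <- a[!is.na(a)]
    if (length(a) == 0) return(list(freq = numeric(0), n_genes = 0L))
    tb <- table(a)
    list(freq = stats::setNames(as.numeric(tb) / length(a), names(tb)),
         n_genes = length(a))
  })
  names(out) <- loci
  structure(out, class = "allele_freqs")
}

#' Per-locus probability of identity
#'
#' `pid_unrelated = sum(p^4) + sum_{i<j} (2 p_i p_j)^2`;
#' `pid_sibs = 0.25 + 0.5*sum(p^2) + 0.5*(sum(p^2))^2 - 0.25*sum(p^4)`.
#' A monomorphic locus returns (1, 1).
#'
#' @param freq Named numeric allele-frequency vector for one locus (or an
#'   element of [allele_freqs()]).
#' @return Named vector `c(pid_unrelated, pid_sibs)`.
#' @export
pid_per_locus <- function(freq) {
  if (is.list(freq)) freq <- freq$freq
  stop_if(abs(sum(freq) - 1) > 1e-9, "allele frequencies must sum to 1")
  s2 <- sum(freq^2); s4 <- sum(freq^4)
  # sum_{i<j} (2 p_i p_j)^2 = 2 * ((sum p^2)^2 - sum p^4)
  pid_u <- s4 + 2 * (s2^2 - s4)
  pid_s <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  c(pid_unrelated = pid_u, pid_sibs = pid_s)
}

#' Cumulative probability of identity across loci
#'
#' @param per_locus_values Numeric vector of per-locus P(ID) values, in the
#'   locus order used for accumulation.
#' @param threshold Discrimination threshold (default 0.01).
#' @return List with `cumulative` (non-increasing products) and
#'   `min_loci` (smallest prefix length with product < threshold, or `NA`
#'   when the threshold is not reached).
#' @export
cumulative_pid <- function(per_locus_values, threshold = 0.01) {
  stop_if(length(per_locus_values) < 1, "need at least one locus")
  cp <- cumprod(per_locus_values)
  hit <- which(cp < threshold)
  list(cumulative = cp,
       min_loci = if (length(hit)) hit[1] else NA_integer_)
}

# mismatches and overlap between two genotype rows
pair_compare <- function(g1, g2, n_loci) {
  l1 <- matrix(g1, ncol = 2, byrow = TRUE)
  l2 <- matrix(g2, ncol = 2, byrow = TRUE)
  both <- !is.na(l1[, 1]) & !is.na(l2[, 1])
  mism <- sum(both & (l1[, 1] != l2[, 1] | l1[, 2] != l2[, 2]))
  c(overlap = sum(both), mismatches = mism)
}

#' Match consensus genotypes into individuals
#'
#' Samples are grouped by exact genotype agreement on all overlapping loci,
#' requiring at least `min_overlap` overlapping loci per merge, with transitive
#' closure and a consistency check. Near-matches (1-2 mismatching loci) are
#' reported for manual review and never merged automatically. Low-confidence
#' (flagged) consensus calls are excluded from the comparisons.
#'
#' @param consensus A `consensus_table`.
#' @param min_overlap Minimum overlapping typed loci for a merge (default 6).
#' @param sample_info Optional data.frame `sample_id`, `year` used to build
#'   capture events.
#' @param sex Optional named vector sample_id -> sex (see [assign_sex_all()]).
#' @return An `individual_set`: `individuals` data.frame (`individual_id`,
#'   `sex`, `n_samples`), `genotypes` matrix (one row per individual),
#'   `members` list, `captures` data.frame (`individual_id`, `sample_id`,
#'   `year`), `near_matches` data.frame and `conflicts` character vector.
#' @export
match_individuals <- function(consensus, min_overlap = 6L, sample_info = NULL,
                              sex = NULL) {
  geno <- consensus_to_matrix(consensus, drop_flagged = TRUE)
  n_loci <- ncol(geno) / 2L
  typed <- apply(!is.na(geno[, seq(1, 2 * n_loci, by = 2), drop = FALSE]), 1, sum)
  usable <- rownames(geno)[typed >= min_overlap]
  dropped <- setdiff(rownames(geno), usable)
  geno <- geno[usable, , drop = FALSE]
  n <- nrow(geno)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  near <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        pc <- pair_compare(geno[i, ], geno[j, ], n_loci)
        if (pc["overlap"] < min_overlap) next
        if (pc["mismatches"] == 0) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        } else if (pc["mismatches"] <= 2) {
          near[[length(near) + 1L]] <- data.frame(
            sample1 = usable[i], sample2 = usable[j],
            overlap = pc["overlap"], mismatches = pc["mismatches"],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  # consistency check: within a component, every overlapping pair must agree
  conflicts <- character(0)
  groups <- split(seq_len(n), comp)
  final <- list()
  for (g in groups) {
    ok <- TRUE
    if (length(g) > 1) {
      prs <- utils::combn(g, 2)
      for (c_i in seq_len(ncol(prs))) {
        pc <- pair_compare(geno[prs[1, c_i], ], geno[prs[2, c_i], ], n_loci)
        if (pc["mismatches"] > 0) { ok <- FALSE; break }
      }
    }
    if (ok) {
      final[[length(final) + 1L]] <- g
    } else {
      # greedy re-grouping in deterministic id order; conflicting members
      # stay split rather than being silently merged
      conflicts <- c(conflicts, paste("transitive-closure conflict among:",
                                      paste(usable[g], collapse = ", ")))
      sub <- list()
      for (i in g[order(usable[g])]) {
        placed <- FALSE
        for (s_i in seq_along(sub)) {
          cand <- sub[[s_i]]
          cons_ok <- all(vapply(cand, function(j)
            pair_compare(geno[i, ], geno[j, ], n_loci)["mismatches"] == 0,
            logical(1)))
          link_ok <- any(vapply(cand, function(j)
            pair_compare(geno[i, ], geno[j, ], n_loci)["overlap"] >= min_overlap,
            logical(1)))
          if (cons_ok && link_ok) { sub[[s_i]] <- c(cand, i); placed <- TRUE; break }
        }
        if (!placed) sub[[length(sub) + 1L]] <- i
      }
      final <- c(final, sub)
    }
  }

  # deterministic individual ids, ordered by first member sample id
  first_member <- vapply(final, function(g) min(usable[g]), character(1))
  final <- final[order(first_member)]
  ids <- sprintf("IND%02d", seq_along(final))

  # merged genotype: per locus, the modal non-missing call among members
  gm <- matrix(NA_integer_, length(final), ncol(geno),
               dimnames = list(ids, colnames(geno)))
  for (k in seq_along(final)) {
    rows <- geno[final[[k]], , drop = FALSE]
    for (l in seq_len(n_loci)) {
      cols <- c(2 * l - 1, 2 * l)
      sub <- rows[!is.na(rows[, cols[1]]), cols, drop = FALSE]
      if (nrow(sub) > 0) {
        keys <- paste(sub[, 1], sub[, 2])
        best <- names(sort(table(keys), decreasing = TRUE))[1]
        gm[k, cols] <- sub[which(keys == best)[1], ]
      }
    }
  }

  members <- lapply(final, function(g) usable[g])
  names(members) <- ids
  sex_of <- function(samps) {
    if (is.null(sex)) return("unknown")
    s <- sex[samps]; s <- s[!is.na(s) & s != "unknown"]
    if (length(s) == 0) return("unknown")
    u <- unique(s)
    if (length(u) == 1) u else "unknown"
  }
  ind_df <- data.frame(
    individual_id = ids,
    sex = vapply(members, sex_of, character(1)),
    n_samples = lengths(members),
    stringsAsFactors = FALSE
  )
  caps <- do.call(rbind, lapply(ids, function(id) {
    data.frame(individual_id = id, sample_id = members[[id]],
               stringsAsFactors = FALSE)
  }))
  caps$year <- if (!is.null(sample_info)) {
    sample_info$year[match(caps$sample_id, sample_info$sample_id)]
  } else NA_integer_
  near_df <- if (length(near)) do.call(rbind, near) else
    data.frame(sample1 = character(0), sample2 = character(0),
               overlap = integer(0), mismatches = integer(0))
  structure(list(individuals = ind_df, genotypes = gm, members = members,
                 captures = caps, near_matches = near_df,
                 conflicts = conflicts, dropped_samples = dropped),
            class = "individual_set")
}

#' Assign sex from sex-marker replicates
#'
#' Male iff X and Y are each confirmed in at least two replicates; female iff
#' at least three successful replicates are X-only; otherwise unknown.
#'
#' @param table A `replicate_table` containing the sex-marker locus.
#' @param sex_locus Name of the sex pseudo-locus (default `"ZF"`).
#' @param x_allele,y_allele Allele-size codes of the X and Y copies.
#' @return Named character vector sample_id -> "male"/"female"/"unknown".
#' @export
assign_sex_all <- function(table, sex_locus = "ZF",
                           x_allele = SEX_X_ALLELE, y_allele = SEX_Y_ALLELE) {
  tt <- table[table$locus == sex_locus, ]
  samples <- sort(unique(table$sample_id))
  out <- stats::setNames(rep("unknown", length(samples)), samples)
  for (s in unique(tt$sample_id)) {
    sub <- tt[tt$sample_id == s & tt$allele1 > 0, ]
    reps <- cbind(sub$allele1, sub$allele2)
    cc <- consensus_cell(reps)
    out[s] <- if (cc$call == "het" && all(sort(c(cc$a, cc$b)) ==
                                          sort(c(x_allele, y_allele)))) {
      "male"
    } else if (cc$call == "hom" && cc$a == x_allele) {
      "female"
    } else "unknown"
  }
  out
}

#' Demographic summary of matched individuals
#'
#' @param individuals An `individual_set` (or a data.frame with `sex`).
#' @param area_ha Surveyed area in hectares (density is per km^2).
#' @param sessions Optional vector of session labels (years); defaults to the
#'   sorted years present in the capture events.
#' @return List with counts by sex, `sex_ratio` (males per female, plus a
#'   label such as "2:1"), per-session minimum counts, interannual recapture
#'   rates `|t intersect t+1| / |t|`, and `density_km2`.
#' @export
demography_summary <- function(individuals, area_ha = NULL, sessions = NULL) {
  if (inherits(individuals, "individual_set")) {
    df <- individuals$individuals
    caps <- individuals$captures
  } else {
    df <- individuals
    caps <- attr(individuals, "captures")
  }
  males <- sum(df$sex == "male"); females <- sum(df$sex == "female")
  ratio <- if (females > 0) males / females else NA_real_
  ratio_label <- if (females > 0) {
    d <- gcd2(males, females)
    sprintf("%d:%d", males %/% d, females %/% d)
  } else sprintf("%d:0", males)

  session_counts <- NULL; recapture <- NULL
  if (!is.null(caps) && any(!is.na(caps$year))) {
    if (is.null(sessions)) sessions <- sort(unique(caps$year[!is.na(caps$year)]))
    rosters <- lapply(sessions, function(y)
      unique(caps$individual_id[!is.na(caps$year) & caps$year == y]))
    names(rosters) <- sessions
    session_counts <- vapply(rosters, length, integer(1))
    if (length(sessions) > 1) {
      recapture <- vapply(seq_len(length(sessions) - 1), function(i) {
        a <- rosters[[i]]; b <- rosters[[i + 1]]
        if (length(a) == 0) NA_real_ else length(intersect(a, b)) / length(a)
      }, numeric(1))
      names(recapture) <- paste(sessions[-length(sessions)], sessions[-1],
                                sep = "->")
    }
  }
  list(n_individuals = nrow(df), males = males, females = females,
       sex_ratio = ratio, sex_ratio_label = ratio_label,
       session_counts = session_counts, recapture_rates = recapture,
       density_km2 = if (!is.null(area_ha)) nrow(df) / (area_ha / 100) else NA_real_)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
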