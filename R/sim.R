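#' Default pedigree for the simulated felid population
#'
#' Nine sampled individuals (six males, three females) connected through five
#' parent-offspring and four full-sib dyads, plus three unsampled founders that
#' carry the sib-ship structure. This mirrors the kin structure of a small,
#' closed wetland population in which every resident is tied to another by a
#' first-order relationship.
#'
#' @return A data.frame with columns `id`, `sex` ("male"/"female"), `father`,
#'   `mother` (NA for founders) and `sampled` (logical).
#' @export
default_pedigree <- function() {
  data.frame(
    id      = c("M1", "F1", "H1", "H2", "H3", "M3", "M4", "M2", "M5", "F2", "M6", "F3"),
    sex     = c("male", "female", "male", "female", "female", "male", "male",
                "male", "male", "female", "male", "female"),
    father  = c(NA, NA, NA, NA, NA, "M1", "M1", "H1", "H1", "H1", "M2", NA),
    mother  = c(NA, NA, NA, NA, NA, "F1", "F1", "H2", "H2", "H2", "H3", NA),
    sampled = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default scat-level diet profile
#'
#' Multinomial prey-taxon probabilities for the generator, set to the weighted
#' percent-of-occurrence of the eight vertebrate prey taxa reported for the
#' study population (rodent-dominated, with wetland birds as secondary prey).
#'
#' @return Named numeric vector summing to 1.
#' @export
default_diet_profile <- function() {
  p <- c(
    Spatula_cyanoptera   = 0.05,
    Aramides_axillaris   = 0.08,
    Gallinula_chloropus  = 0.10,
    Rallus_longirostris  = 0.12,
    Platalea_ajaja       = 0.02,
    Tachuris_rubrigastra = 0.07,
    Aegialomys_xanthaeolus = 0.53,
    Mus_musculus         = 0.02
  )
  p / sum(p)
}

#' Build a validated simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults are the
#' conditions of the emulated study: 11 dinucleotide microsatellites with 2-5
#' alleles, per-replicate allelic dropout 0.21, false-allele rate 0.005, ~48%
#' sample-level genotyping success, per-individual scat counts 2-10, and a
#' rodent-dominated 8-taxon diet amplified in triplicate.
#'
#' @param pedigree_spec Pedigree data.frame (see [default_pedigree()]).
#' @param n_loci Number of autosomal microsatellite loci.
#' @param alleles_per_locus Integer range (length-2) of allele counts per locus.
#' @param repeat_unit_bp Per-locus repeat unit in bp (recycled to `n_loci`).
#' @param ado_rate Probability that a PCR replicate of a heterozygous locus
#'   drops one allele (apparent homozygote).
#' @param fa_rate Probability that a replicate carries a false allele.
#' @param locus_failure_rate Probability that a replicate PCR fails outright
#'   for a good-quality scat.
#' @param bad_failure_rate Replicate failure probability for degraded scats
#'   (the ones that the 40% amplification screen removes).
#' @param sample_success_rate Target fraction of field scats that pass
#'   screening and yield genotypes.
#' @param scats_per_individual Integer vector of genotyped-scat counts per
#'   sampled individual (capture heterogeneity). Recycled/truncated to the
#'   number of sampled individuals.
#' @param capture_mode `"fixed"` realises `scats_per_individual` exactly
#'   (ground truth for capture counts is then controlled); `"multinomial"`
#'   assigns each scat an owner with probability proportional to the weights.
#' @param max_replicates Maximum PCR replicates per sample x locus.
#' @param diet_profile Named prey-taxon probability vector (sums to 1).
#' @param meal_size_probs Probabilities that a scat's true meal was built from
#'   1, 2 or 3 prey draws.
#' @param reads_per_replicate Sequencing reads per diet PCR replicate.
#' @param contam_rate Fraction of reads from non-prey sources (predator/human).
#' @param diet_success_rate Fraction of diet samples expected to amplify and
#'   pass quality control.
#' @param seed Integer seed for the single global random stream.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(pedigree_spec = default_pedigree(),
                       n_loci = 11L,
                       alleles_per_locus = c(2L, 5L),
                       repeat_unit_bp = 2L,
                       ado_rate = 0.21,
                       fa_rate = 0.005,
                       locus_failure_rate = 0.05,
                       bad_failure_rate = 0.90,
                       sample_success_rate = 0.48,
                       scats_per_individual = c(10L, 8L, 2L, 7L, 2L, 5L, 7L, 10L, 2L),
                       capture_mode = c("fixed", "multinomial"),
                       max_replicates = 6L,
                       diet_profile = default_diet_profile(),
                       meal_size_probs = c(0.80, 0.18, 0.02),
                       reads_per_replicate = 5000L,
                       contam_rate = 0.02,
                       diet_success_rate = 0.77,
                       seed = 1L) {
  capture_mode <- match.arg(capture_mode)
  stopifnot(is.data.frame(pedigree_spec),
            all(c("id", "sex", "father", "mother", "sampled") %in% names(pedigree_spec)))
  stop_if(anyDuplicated(pedigree_spec$id) > 0, "duplicate ids in pedigree_spec")
  n_ind <- sum(pedigree_spec$sampled)
  stop_if(n_ind < 1, "n_individuals must be >= 1")
  stop_if(!is_prob(c(ado_rate, fa_rate, locus_failure_rate, bad_failure_rate,
                     sample_success_rate, diet_success_rate, contam_rate)),
          "all rates must be probabilities in [0, 1]")
  stop_if(length(alleles_per_locus) != 2 || alleles_per_locus[1] < 1 ||
            alleles_per_locus[2] < alleles_per_locus[1],
          "alleles_per_locus must be an increasing length-2 range")
  stop_if(abs(sum(diet_profile) - 1) > 1e-9, "diet_profile must sum to 1")
  stop_if(any(diet_profile < 0), "diet_profile entries must be non-negative")
  stop_if(abs(sum(meal_size_probs) - 1) > 1e-9, "meal_size_probs must sum to 1")
  stop_if(sample_success_rate <= 0, "sample_success_rate must be positive")
  repeat_unit_bp <- rep_len(as.integer(repeat_unit_bp), n_loci)
  stop_if(any(repeat_unit_bp < 1), "repeat_unit_bp must be positive integers")
  scats_per_individual <- rep_len(as.integer(scats_per_individual), n_ind)
  stop_if(any(scats_per_individual < 1), "scats_per_individual must be >= 1")

  structure(list(
    pedigree_spec = pedigree_spec,
    n_individuals = n_ind,
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    repeat_unit_bp = repeat_unit_bp,
    ado_rate = ado_rate,
    fa_rate = fa_rate,
    locus_failure_rate = locus_failure_rate,
    bad_failure_rate = bad_failure_rate,
    sample_success_rate = sample_success_rate,
    scats_per_individual = scats_per_individual,
    capture_mode = capture_mode,
    max_replicates = as.integer(max_replicates),
    diet_profile = diet_profile,
    meal_size_probs = meal_size_probs,
    reads_per_replicate = as.integer(reads_per_replicate),
    contam_rate = contam_rate,
    diet_success_rate = diet_success_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Topological order of a pedigree; errors on cycles naming one offending id.
pedigree_order <- function(ped) {
  ids <- ped$id
  placed <- character(0)
  remaining <- ids
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      ok_f <- is.na(r$father) || r$father %in% placed || !(r$father %in% ids)
      ok_m <- is.na(r$mother) || r$mother %in% placed || !(r$mother %in% ids)
      ok_f && ok_m
    }, logical(1))]
    if (length(ready) == 0) {
      stop_if(length(remaining) > 0,
              "pedigree_spec contains a cycle involving '%s'", remaining[1])
      break
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
    if (length(remaining) == 0) break
  }
  placed
}

#' Classify all dyads of a pedigree into U/HS/FS/PO
#'
#' A dyad is PO if one member is a recorded parent of the other, FS if both
#' parents are recorded and shared, HS if exactly one recorded parent is
#' shared, and U otherwise. Grandparental and avuncular ties fall into U,
#' matching the four-category classification used downstream.
#'
#' @param pedigree Pedigree data.frame.
#' @param ids Individuals to form dyads over (default: sampled ones).
#' @return data.frame with `id1`, `id2`, `category`.
#' @export
pedigree_dyads <- function(pedigree, ids = pedigree$id[pedigree$sampled]) {
  if (length(ids) < 2) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  prs <- utils::combn(sort(ids), 2)
  category <- apply(prs, 2, function(p) {
    r1 <- pedigree[pedigree$id == p[1], ]
    r2 <- pedigree[pedigree$id == p[2], ]
    if (identical(r1$id, r2$father) || identical(r1$id, r2$mother) ||
        identical(r2$id, r1$father) || identical(r2$id, r1$mother)) return("PO")
    sf <- !is.na(r1$father) && !is.na(r2$father) && r1$father == r2$father
    sm <- !is.na(r1$mother) && !is.na(r2$mother) && r1$mother == r2$mother
    if (sf && sm) return("FS")
    if (xor(sf, sm)) return("HS")
    "U"
  })
  data.frame(id1 = prs[1, ], id2 = prs[2, ], category = category,
             stringsAsFactors = FALSE)
}

#' Simulate a true population from a pedigree
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions from per-locus
#' founder frequencies (symmetric Dirichlet over a microsatellite size ladder);
#' descendants receive one Mendelian allele from each parent. A Zinc-Finger
#' style sex marker is added (males X/Y, females X/X).
#'
#' @param config A [sim_config()] object.
#' @return A `true_population` list with elements `individuals` (id, sex,
#'   sampled), `genotypes` (n x 2L allele-size matrix, sampled individuals),
#'   `sex_marker` (per-individual X/Y pair), `loci` (locus metadata),
#'   `founder_freqs`, `pedigree`, `dyads` (true categories among sampled
#'   individuals) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- config$pedigree_spec
  ord <- pedigree_order(ped)

  with_seed(config$seed, {
    L <- config$n_loci
    loci <- data.frame(
      locus = sprintf("L%02d", seq_len(L)),
      repeat_unit = config$repeat_unit_bp,
      stringsAsFactors = FALSE
    )
    # Allele ladders: k alleles on a repeat-unit grid, gaps allowed so that
    # M-ratio inputs are realistic.
    founder_freqs <- list()
    for (l in seq_len(L)) {
      k <- sample(seq(config$alleles_per_locus[1], config$alleles_per_locus[2]), 1)
      base <- 100L + (l - 1L) * 20L
      steps <- sort(sample.int(2L * k, k) - 1L)
      sizes <- base + steps * loci$repeat_unit[l]
      fr <- stats::rgamma(k, 1)
      fr <- fr / sum(fr)
      founder_freqs[[loci$locus[l]]] <- list(freq = stats::setNames(fr, sizes),
                                             n_genes = Inf)
    }

    geno <- list()  # id -> 2 x L matrix of allele sizes (rows = two copies)
    for (id in ord) {
      r <- ped[ped$id == id, ]
      g <- matrix(NA_integer_, 2, L)
      for (l in seq_len(L)) {
        fr <- founder_freqs[[l]]$freq
        sizes <- as.integer(names(fr))
        from_parent <- function(pid) {
          if (is.na(pid) || !(pid %in% names(geno))) {
            sizes[sample.int(length(sizes), 1, prob = fr)]
          } else {
            geno[[pid]][sample.int(2, 1), l]
          }
        }
        g[1, l] <- from_parent(r$father)
        g[2, l] <- from_parent(r$mother)
      }
      geno[[id]] <- g
    }

    samp_ids <- ped$id[ped$sampled]
    gm <- matrix(NA_integer_, length(samp_ids), 2L * L,
                 dimnames = list(samp_ids,
                                 paste0(rep(loci$locus, each = 2), c(".1", ".2"))))
    for (i in seq_along(samp_ids)) {
      g <- geno[[samp_ids[i]]]
      for (l in seq_len(L)) gm[i, c(2 * l - 1, 2 * l)] <- sort(g[, l])
    }

    sex <- stats::setNames(ped$sex[match(samp_ids, ped$id)], samp_ids)
    sexm <- t(vapply(sex, function(s) {
      if (s == "male") c(SEX_X_ALLELE, SEX_Y_ALLELE) else c(SEX_X_ALLELE, SEX_X_ALLELE)
    }, integer(2)))
    colnames(sexm) <- c("ZF.1", "ZF.2")

    structure(list(
      individuals = data.frame(id = samp_ids, sex = unname(sex),
                               sampled = TRUE, stringsAsFactors = FALSE),
      genotypes = gm,
      sex_marker = sexm,
      loci = loci,
      founder_freqs = structure(founder_freqs, class = "allele_freqs"),
      pedigree = ped,
      dyads = pedigree_dyads(ped, samp_ids),
      config = config
    ), class = "true_population")
  })
}

# Allele-size codes of the sex pseudo-locus ("ZF"): X and Y chromosome copies.
SEX_X_ALLELE <- 163L
SEX_Y_ALLELE <- 147L

# One simulated PCR replicate of a true genotype c(a, b): returns c(0, 0) on
# failure, otherwise the observed (possibly erroneous) sorted allele pair.
simulate_one_replicate <- function(true_pair, locus_alleles, fail_rate,
                                   ado_rate, fa_rate) {
  if (stats::runif(1) < fail_rate) return(c(0L, 0L))
  obs <- true_pair
  if (obs[1] != obs[2] && stats::runif(1) < ado_rate) {
    keep <- sample.int(2, 1)            # dropped het looks homozygous
    obs <- rep(obs[keep], 2)
  }
  if (stats::runif(1) < fa_rate) {
    wrong <- setdiff(locus_alleles, obs)
    if (length(wrong) > 0) {
      obs[sample.int(2, 1)] <- wrong[sample.int(length(wrong), 1)]
    }
  }
  sort(obs)
}

#' Simulate a replicate-PCR genotype table
#'
#' Generates the field + laboratory layer: scats are deposited by individuals
#' according to the capture-heterogeneity weights, degraded scats (the
#' complement of the sample success rate) amplify at `bad_failure_rate`, and
#' every scat x locus cell receives `max_replicates` independent PCR
#' replicates subject to allelic dropout, false alleles and amplification
#' failure. A sex-marker pseudo-locus `ZF` is included.
#'
#' @param pop A `true_population`.
#' @param config The same [sim_config()] used to build `pop`.
#' @param seed Optional seed override (defaults to `config$seed + 1`).
#' @return A `replicate_table` data.frame with columns `sample_id`, `locus`,
#'   `replicate`, `allele1`, `allele2` (0 = failed/missing), carrying a
#'   `truth` attribute (sample_id, individual_id, good).
#' @export
simulate_replicate_table <- function(pop, config = pop$config, seed = NULL) {
  stopifnot(inherits(pop, "true_population"))
  seed <- seed %||% child_seed(config$seed, 1L)
  with_seed(seed, {
    ids <- pop$individuals$id
    w <- config$scats_per_individual
    n_good <- sum(w)
    n_total <- max(n_good, round(n_good / config$sample_success_rate))
    n_bad <- n_total - n_good

    if (config$capture_mode == "fixed") {
      owners_good <- rep(ids, times = w)
    } else {
      owners_good <- ids[sample.int(length(ids), n_good, replace = TRUE,
                                    prob = w / sum(w))]
    }
    owners_bad <- ids[sample.int(length(ids), n_bad, replace = TRUE,
                                 prob = w / sum(w))]
    owners <- c(owners_good, owners_bad)
    good <- rep(c(TRUE, FALSE), c(n_good, n_bad))
    perm <- sample.int(n_total)           # shuffle field order
    owners <- owners[perm]; good <- good[perm]
    sample_ids <- sprintf("S%03d", seq_len(n_total))
    # field seasons with effort proportional to the emulated survey
    years <- sample(c(2019L, 2020L, 2021L), n_total, replace = TRUE,
                    prob = c(46, 78, 18) / 142)

    loci <- c(pop$loci$locus, "ZF")
    locus_alleles <- c(lapply(pop$founder_freqs,
                              function(x) as.integer(names(x$freq))),
                       list(ZF = c(SEX_Y_ALLELE, SEX_X_ALLELE)))
    names(locus_alleles) <- loci
    R <- config$max_replicates

    n_rows <- n_total * length(loci) * R
    out_s <- character(n_rows); out_l <- character(n_rows)
    out_r <- integer(n_rows); out_a <- integer(n_rows); out_b <- integer(n_rows)
    row <- 0L
    for (s in seq_len(n_total)) {
      ind <- owners[s]
      fail <- if (good[s]) config$locus_failure_rate else config$bad_failure_rate
      for (l in seq_along(loci)) {
        tg <- if (loci[l] == "ZF") {
          pop$sex_marker[ind, ]
        } else {
          pop$genotypes[ind, c(2 * l - 1, 2 * l)]
        }
        for (r in seq_len(R)) {
          obs <- simulate_one_replicate(tg, locus_alleles[[l]], fail,
                                        config$ado_rate, config$fa_rate)
          row <- row + 1L
          out_s[row] <- sample_ids[s]; out_l[row] <- loci[l]
          out_r[row] <- r; out_a[row] <- obs[1]; out_b[row] <- obs[2]
        }
      }
    }
    tab <- data.frame(sample_id = out_s, locus = out_l, replicate = out_r,
                      allele1 = out_a, allele2 = out_b, stringsAsFactors = FALSE)
    class(tab) <- c("replicate_table", "data.frame")
    attr(tab, "truth") <- data.frame(sample_id = sample_ids,
                                     individual_id = owners, good = good,
                                     year = years, stringsAsFactors = FALSE)
    tab
  })
}

#' Simulate a taxon-assigned diet read table
#'
#' Each scat receives a true meal built from 1-3 prey draws (with replacement,
#' duplicates collapsed) from the diet profile, then three PCR replicates of
#' multinomial read counts over the meal plus a low-rate contaminant component
#' (predator and human reads). A fraction of samples fails quality control and
#' yields only trace contaminant reads.
#'
#' @param pop A `true_population`.
#' @param config The matching [sim_config()].
#' @param n_scats Number of diet samples (default: one per genotyped scat).
#' @param seed Optional seed override.
#' @return A `diet_read_table` data.frame with columns `sample_id`,
#'   `pcr_replicate`, `taxon`, `reads`, plus attributes `sample_owner`
#'   (sample_id -> individual) and `truth` (the per-sample true meal).
#' @export
simulate_diet_table <- function(pop, config = pop$config, n_scats = NULL,
                                seed = NULL) {
  stopifnot(inherits(pop, "true_population"))
  stop_if(length(config$diet_profile) == 0, "diet_profile must be non-empty")
  stop_if(config$reads_per_replicate <= 0, "reads_per_replicate must be > 0")
  seed <- seed %||% child_seed(config$seed, 2L)
  with_seed(seed, {
    ids <- pop$individuals$id
    w <- config$scats_per_individual
    if (is.null(n_scats)) {
      owners <- rep(ids, times = w)
    } else {
      owners <- ids[sample.int(length(ids), n_scats, replace = TRUE,
                               prob = w / sum(w))]
    }
    n <- length(owners)
    sample_ids <- sprintf("D%03d", seq_len(n))
    taxa <- names(config$diet_profile)
    contam_taxa <- c("Leopardus_garleppi", "Homo_sapiens")
    contam_p <- c(0.9, 0.1)

    rows <- list(); meals <- vector("list", n)
    for (s in seq_len(n)) {
      t_draws <- sample.int(3L, 1, prob = config$meal_size_probs)
      draws <- sample(taxa, t_draws, replace = TRUE, prob = config$diet_profile)
      tab <- table(draws)
      meal <- names(tab)
      share <- as.numeric(tab) / t_draws
      meals[[s]] <- stats::setNames(share, meal)
      ok <- stats::runif(1) < config$diet_success_rate
      for (r in 1:3) {
        if (ok) {
          p <- c(share * (1 - config$contam_rate), config$contam_rate * contam_p)
          nm <- c(meal, contam_taxa)
          reads <- stats::rmultinom(1, config$reads_per_replicate, p)[, 1]
        } else {
          nm <- contam_taxa      # failed amplification: trace contamination only
          reads <- stats::rmultinom(1, 50L, contam_p)[, 1]
        }
        keep <- reads > 0
        if (any(keep)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_ids[s], pcr_replicate = r,
            taxon = nm[keep], reads = as.integer(reads[keep]),
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("diet_read_table", "data.frame")
    attr(tab, "sample_owner") <- stats::setNames(owners, sample_ids)
    attr(tab, "truth") <- meals
    tab
  })
}
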