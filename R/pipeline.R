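#' Pipeline configuration with study-default thresholds
#'
#' Every default equals the study's stated analysis setting: 40% screening
#' threshold, P(ID)sibs discrimination threshold 0.01, six overlapping loci
#' for matching, minimum allele frequency 0.02 for the LD-Ne estimator, diet
#' read-proportion threshold 0.5%, census-size search capped at 25, 100 LRT
#' and 1000 CI bootstrap replicates, 1000 bottleneck iterations, and the
#' 3013-ha survey area.
#'
#' @param min_fraction Amplification screen fraction.
#' @param pid_sibs_threshold Cumulative P(ID)sibs threshold.
#' @param min_overlap Minimum overlapping loci for matching.
#' @param maf Minimum allele frequency for LD-Ne.
#' @param min_prop Diet within-replicate proportion threshold.
#' @param max_n Census-size search cap.
#' @param n_boot_lrt,n_boot_ci Bootstrap replicates.
#' @param bottleneck_iter Coalescent iterations per locus.
#' @param n_perm HWE/LD permutations.
#' @param permanova_perm PERMANOVA permutations.
#' @param area_ha Survey area in hectares.
#' @param seed Global seed (fans out to per-stage child seeds).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_fraction = 0.40, pid_sibs_threshold = 0.01,
                            min_overlap = 6L, maf = 0.02, min_prop = 0.005,
                            max_n = 25L, n_boot_lrt = 100L, n_boot_ci = 1000L,
                            bottleneck_iter = 1000L, n_perm = 2000L,
                            permanova_perm = 9999L, area_ha = 3013,
                            seed = 1L) {
  stop_if(!is_prob(c(min_fraction, pid_sibs_threshold, maf, min_prop)),
          "fractional thresholds must be in [0, 1]")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: sample screening, consensus genotyping and error rates, sex
#' assignment and individual matching, P(ID) and diversity statistics with
#' HWE/LD tests, kinship classification, census and effective population
#' size, bottleneck battery, and (when a diet table is supplied) diet
#' metrics. Per-stage filter counts are collected in `log`; headline numbers
#' in `report`.
#'
#' @param replicates A `replicate_table`.
#' @param locus_metadata data.frame `locus`, `repeat_unit` for the M-ratio.
#' @param diet A `diet_read_table` or NULL.
#' @param config A [pipeline_config()].
#' @param sample_info Optional data.frame `sample_id`, `year` (defaults to
#'   the generator's truth attribute when present).
#' @param diet_sex Optional named vector mapping the diet table's owner ids
#'   to sexes, for the sex-based diet comparison.
#' @return A `pipeline_result` list with per-stage objects, `report`, `log`.
#' @export
run_pipeline <- function(replicates, locus_metadata = NULL, diet = NULL,
                         config = pipeline_config(), sample_info = NULL,
                         diet_sex = NULL) {
  log <- list(); report <- list()
  truth <- attr(replicates, "truth")
  if (is.null(sample_info) && !is.null(truth)) {
    sample_info <- truth[, c("sample_id", "year")]
  }
  loci <- sort(setdiff(unique(replicates$locus), "ZF"))
  log$n_samples_collected <- length(unique(replicates$sample_id))

  ## 1. screening
  retained <- screen_samples(replicates, loci, config$min_fraction)
  log$n_samples_screened <- length(retained)
  report$genotyping_success <- length(retained) / log$n_samples_collected

  ## 2. consensus + error rates
  consensus <- call_consensus(replicates, samples = retained)
  errors <- estimate_error_rates(
    replicates[replicates$locus != "ZF", ],
    consensus[consensus$locus != "ZF", ])
  report$ado <- unname(errors$cumulative["ado"])
  report$fa <- unname(errors$cumulative["fa"])

  ## 3. sex + matching
  sex <- assign_sex_all(replicates[replicates$sample_id %in% retained, ])
  inds <- match_individuals(consensus, min_overlap = config$min_overlap,
                            sample_info = sample_info, sex = sex)
  log$n_samples_matched <- sum(inds$individuals$n_samples)
  log$n_samples_dropped_few_loci <- length(inds$dropped_samples)
  report$n_individuals <- nrow(inds$individuals)

  ## 4. diversity + P(ID)
  geno <- inds$genotypes
  freqs <- allele_freqs(geno)
  pid <- t(vapply(freqs, pid_per_locus, numeric(2)))
  ord <- order(pid[, "pid_sibs"])
  cum <- cumulative_pid(pid[ord, "pid_sibs"], config$pid_sibs_threshold)
  div <- diversity_table(geno)
  div$FNA <- null_allele_frequency(div$He, div$Ho)
  hwe_p <- vapply(div$locus, function(l)
    hwe_exact_test(geno, l, n_perm = config$n_perm,
                   seed = child_seed(config$seed, 41L)), numeric(1))
  ld <- ld_pairwise_test(geno, n_perm = config$n_perm,
                         seed = child_seed(config$seed, 42L))
  # worst (largest) adjusted LD p per locus, for the summary table
  ld_adj <- bh_fdr(ld$p)
  ld_by_locus <- vapply(div$locus, function(l) {
    sel <- ld$locus1 == l | ld$locus2 == l
    if (any(sel)) max(ld_adj[sel], na.rm = TRUE) else NA_real_
  }, numeric(1))
  table1 <- data.frame(
    locus = div$locus,
    pid_sibs = pid[div$locus, "pid_sibs"],
    N = div$N, Na = div$Na, AR = div$AR, Ho = div$Ho, He = div$He,
    FNA = div$FNA, Fis = div$Fis,
    ld_p = ld_by_locus, hwe_p = bh_fdr(hwe_p))
  diversity <- list(table = div, table1 = table1, pid = pid,
                    cumulative_pid = cum,
                    hwe = data.frame(locus = div$locus, p = hwe_p,
                                     p_adj = bh_fdr(hwe_p)),
                    ld = transform(ld, p_adj = bh_fdr(p)))
  report$mean_He <- attr(div, "summary")["mean", "He"]
  report$mean_Ho <- attr(div, "summary")["mean", "Ho"]

  ## 5. kinship
  kin <- kin_matrix(geno, freqs, seed = child_seed(config$seed, 51L))

  ## 6. population size
  counts <- inds$individuals$n_samples
  lrt <- model_select_lrt(counts, max_n = config$max_n,
                          n_boot = config$n_boot_lrt,
                          seed = child_seed(config$seed, 61L))
  ci <- bootstrap_ci(counts, model = lrt$model, max_n = config$max_n,
                     n_boot = config$n_boot_ci,
                     seed = child_seed(config$seed, 62L))
  ne <- tryCatch(ld_ne(geno, maf = config$maf), error = function(e) NULL)
  popsize <- list(lrt = lrt, ci = ci, ne = ne, counts = counts)
  report$Nc <- ci$N_hat
  report$Ne <- if (!is.null(ne)) ne$Ne_hat else NA_real_
  report$Ne_over_Nc <- if (!is.null(ne)) ne$Ne_hat / ci$N_hat else NA_real_

  ## 7. bottleneck battery
  bots <- lapply(c(IAM = "IAM", TPM = "TPM", SMM = "SMM"), function(m)
    het_excess_test(geno, model = m, n_iter = config$bottleneck_iter,
                    seed = child_seed(config$seed, 71L)))
  ms <- mode_shift(freqs)
  mr <- NULL
  if (!is.null(locus_metadata)) {
    sizes <- lapply(freqs, function(x) as.integer(names(x$freq)))
    ru <- locus_metadata$repeat_unit[match(names(sizes), locus_metadata$locus)]
    keep <- !is.na(ru) & lengths(sizes) >= 2
    if (any(keep)) mr <- m_ratio(sizes[keep], ru[keep])
  }
  table2 <- data.frame(
    model = names(bots),
    expected_excess = vapply(bots, function(b) b$expected_excess, numeric(1)),
    observed_excess = vapply(bots, function(b) b$n_excess, numeric(1)),
    wilcoxon_p = vapply(bots, function(b) b$wilcoxon_p, numeric(1)),
    mode_shift = ms$verdict, row.names = NULL)
  bottleneck <- list(het_excess = bots, table2 = table2, mode_shift = ms,
                     m_ratio = mr)
  report$bottleneck_p <- vapply(bots, function(b) b$wilcoxon_p, numeric(1))
  report$mode_shift <- ms$verdict
  if (!is.null(mr)) report$mean_M <- mr$mean_M

  ## 8. demography
  demo <- demography_summary(inds, area_ha = config$area_ha)
  report$sex_ratio <- demo$sex_ratio_label
  report$density_km2 <- demo$density_km2

  ## 9. diet
  diet_res <- NULL
  if (!is.null(diet)) {
    det <- filter_reads(diet, min_prop = config$min_prop)
    log$n_diet_samples <- length(unique(diet$sample_id))
    log$n_diet_retained <- det$n_samples
    diet_res <- list(detections = det, foo = foo(det), wpoo = wpoo(det))
    owners <- det$sample_owner
    if (!is.null(owners) && !is.null(diet_sex)) {
      prof <- individual_diet_profiles(det)
      grp <- diet_sex[rownames(prof)]
      if (length(unique(grp)) >= 2 && nrow(prof) - length(unique(grp)) >= 1) {
        d <- bray_curtis(prof)
        diet_res$permanova <- permanova(d, grp,
                                        n_perm = config$permanova_perm,
                                        seed = child_seed(config$seed, 91L))
        report$diet_sex_p <- diet_res$permanova$p
      }
    }
    report$foo <- diet_res$foo
    report$wpoo <- diet_res$wpoo
  }

  structure(list(
    screened = retained, consensus = consensus, errors = errors,
    individuals = inds, diversity = diversity, kinship = kin,
    popsize = popsize, bottleneck = bottleneck, demography = demo,
    diet = diet_res, report = report, log = log, config = config
  ), class = "pipeline_result")
}
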