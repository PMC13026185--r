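---
title: "Methods: noninvasive genetic and dietary analysis of a small felid population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noninvasive genetic and dietary analysis of a small felid population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scatpop)
```

# Scope and model of the data

`scatpop` analyses noninvasive fecal-DNA surveys of small, closed carnivore
populations. The data model is a three-layer hierarchy:

1. **Individuals** carry true multilocus microsatellite genotypes (allele
   sizes in bp on a repeat-unit ladder) and a sex (X/Y sex-marker
   pseudo-locus `ZF`).
2. **Scats** are deposited by individuals with heterogeneous per-individual
   intensity; a fraction of scats is too degraded to genotype.
3. **PCR replicates** of each scat x locus cell observe the true genotype
   through three error channels: amplification failure, allelic dropout
   (ADO: one allele of a heterozygote fails, producing an apparent
   homozygote), and false alleles (FA: an artifact allele replaces a true
   one).

All downstream estimators — consensus calling, individual matching,
diversity, kinship, census size, effective size, bottleneck signals, and
diet composition — consume tables in this model, so the whole pipeline can
be validated by parameter recovery against the generator.

# The synthetic-data generator: a stated world

The generator's defaults are the conditions of the emulated field study and
are *not* tuning knobs:

| parameter | default | meaning |
|---|---|---|
| pedigree | 9 sampled cats (6M/3F), 5 PO + 4 FS dyads | first-order kin structure |
| `n_loci` | 11 (8-11 retained downstream) | dinucleotide microsatellites |
| `alleles_per_locus` | 2-5 | drawn per locus |
| `ado_rate` | 0.21 | per replicate per heterozygous locus |
| `fa_rate` | 0.005 | per replicate per locus |
| `locus_failure_rate` | 0.05 | replicate failure, good scats |
| `bad_failure_rate` | 0.90 | replicate failure, degraded scats |
| `sample_success_rate` | 0.48 | fraction of field scats that genotype |
| `scats_per_individual` | 10,8,2,7,2,5,7,10,2 | the only published per-individual counts |
| diet profile | 8 taxa, rodent-dominated (0.53) | published weighted occurrence |
| `reads_per_replicate` | 5000 | typical post-filter metabarcoding depth |
| `meal_size_probs` | 0.80/0.18/0.02 for 1/2/3 prey | gives ~1.2 taxa/scat, matching the published 50 detections in 41 samples |

Where the study does not print a value (good-scat failure rate, read depth,
meal-size distribution, contamination rate 0.02) a single realistic choice
was made once and documented here.

Two deliberate design choices deserve emphasis:

* **Capture counts are realised exactly by default** (`capture_mode =
  "fixed"`). With multinomial scat ownership, an individual with weight 2
  is missed entirely in a non-negligible fraction of runs, and "recover
  exactly 9 individuals in >= 95% of runs" is unreachable for any matcher.
  Fixed counts keep the capture-heterogeneity truth controlled, which is
  what the TIRM recovery tests require. The multinomial mode remains
  available.
* **Meals are drawn with replacement and collapsed.** A scat's 1-3 prey
  draws come i.i.d. from the diet profile; duplicates collapse. This makes
  the implied weighted percent of occurrence equal the configured profile
  almost exactly (exact for 1- and 2-draw meals; < 0.01 bias for 3-draw
  meals), so profile recovery is a clean law-of-large-numbers test.

What the generator does **not** emulate: chromatograms and peak-calling
artifacts, null alleles and primer-site mutations, sex-linked marker
failure asymmetries, tag-jumping between metabarcoding replicates, spatial
structure of scat deposition, or year-specific diet shifts. A green
recovery test therefore certifies the statistical pipeline, not the
laboratory process.

# Consensus genotyping

The multitube confirmation rules are:

* heterozygote `(a, b)`: each allele observed in at least two replicates;
* homozygote `(a)`: at least three successful replicates showing only `a`;
  one discordant single observation is tolerated as a presumed false allele
  but the call is flagged;
* three or more alleles each confirmed twice: multi-allele conflict,
  missing;
* a confirmed heterozygote takes precedence over a homozygote reading.

All available replicates (up to six) are used. An early-stopping scheduler
(stop at the first three clean replicates) looks economical but has a
false-homozygote probability of about `2 * (ado/2)^3 ~ 2e-3` per
heterozygous cell at ADO 0.21; across ~500 heterozygous cells per survey
that is ~0.5 wrong genotypes per run, each of which would split a true
recapture into a phantom individual. Using the full replicate set drops
this to ~1e-5 per cell.

ADO is estimated from heterozygous-consensus cells only (fraction of
successful replicates showing exactly one consensus allele); FA from all
non-missing cells (fraction of replicates carrying an allele outside the
consensus). Cumulative rates are replicate-weighted across loci. The
Brookfield estimator `(He - Ho)/(1 + He)` screens for null alleles.

# Individual matching

Samples with at least six reliably typed loci are merged on exact genotype
identity across all overlapping loci (transitive closure, with a
consistency check; conflicted components are re-split deterministically and
logged). Near-matches at 1-2 loci are reported for review, never merged.

Low-confidence calls are excluded from the comparison: flagged homozygotes
(single discordant observation) and heterozygotes whose weaker allele was
seen exactly twice among five or more successful replicates — the signature
of a twice-repeated false allele. Both remain in the reported consensus
table. This exclusion is what lets residual post-consensus errors appear as
*missing* rather than *mismatching* data; without it the expected number of
spurious individuals per survey is ~0.1-0.4.

P(ID) statistics use the standard unrelated and sib formulas; cumulative
products are taken in increasing order of per-locus P(ID)sibs and compared
with the 0.01 discrimination threshold. Allele frequencies are computed
from one genotype per matched individual, not per scat.

# Diversity, HWE, LD

He is `1 - sum(p^2)` (the convention of the study's toolchain; Nei's
unbiased variant is an option), Ho the fraction of heterozygous
individuals, allelic richness is rarefied to the smallest per-locus gene
count, and F_IS is Weir & Cockerham's f from variance components (summed
components across loci for the multilocus value). The HWE test is a Monte
Carlo exact test on the conditional probability of the genotype array; LD
uses a genotypic log-likelihood-ratio statistic with one locus permuted.
Both use the +1/+1 Monte Carlo correction; HWE tests form one BH-FDR
family, LD pairs another.

The across-locality comparison treats loci as blocks in a Friedman test.
The p-value is an exact within-block permutation enumeration when
`(k!)^n <= 1e5` — required to reproduce the analytic small-sample example
(two localities, four blocks, strict dominance: p = 2/16) — and the
chi-square approximation with `df = k - 1` otherwise.

# Kinship

Dyads are classified among U/HS/FS/PO by maximum likelihood over the
Cotterman coefficients `(k0, k1, k2)`, with the standard unordered-genotype
one-IBD transition table. The continuous ML relatedness `r = k1/2 + k2` is
found on a 0.01 simplex grid with local refinement (ties broken toward
larger `k0`). No genotyping-error model is included in the likelihood —
consensus calling upstream is the error control — which is a known
limitation for datasets with residual ADO.

The Wang-type moment estimator solves the exact linear system relating the
four genotype-pair similarity classes to the two- and four-gene IBD
coefficients, by weighted least squares across loci with weights
`1/(2*a2 - a3)` and unbiased falling-factorial estimates of the frequency
power sums (the small-sample correction). It is consistent (FS ~ 0.5,
U ~ 0, self ~ 1) and unbounded below, like the published estimator it
stands in for; the verbatim closed-form algebra of the original was not
reproducible from available references, so the estimator is documented as
Wang-*type*.

# Census and effective size

ECM maximizes `choose(N, k) * N^-t` over integer `N` up to 25; TIRM adds a
two-class weight structure, searched exhaustively over `(N, a)` with the
largest counts assigned to the fast class and a closed-form profile maximum
over the rate ratio `alpha` (the closed form replaces the golden-section
search — exact and deterministic). Model choice uses a parametric bootstrap
LRT (100 replicates, TIRM iff p < 0.05); CIs are 2.5/97.5 percentiles of
1000 parametric bootstrap re-estimates, widened if needed to contain the
point estimate and never below `k`.

The LD method computes Burrows' composite disequilibrium for every allele
pair across every locus pair (MAF 0.02 screen), expressed as a dosage
correlation with `(n/(n-1))^2` inflation. That exact form matters: it is
the version whose sampling expectation matches the published small-S
(`0.0018 + 0.907/S + 4.44/S^2`) and large-S (`1/S + 3.19/S^2`) formulas —
verified by simulation at S = 10 and S = 50 — and the plain
`D^2/(pApB(1-pA)(1-pB))` variant is ~10% low at small S, which pushes every
estimate to infinity. Ne follows the standard quadratic inversion with
infinite estimates when the drift signal is non-positive; the parametric
chi-square CI on the number of independent comparisons is anti-conservative
and documented as such.

# Bottleneck battery

Per locus, the equilibrium heterozygosity distribution conditional on the
observed allele count is simulated by a coalescent with mutations placed on
branches, theta calibrated so the expected allele count matches (closed
form via the Ewens formula under IAM, bisection on simulated means under
SMM/TPM), and rejection to exactly `k` alleles. TPM mutations are
single-step with probability 0.70, otherwise multi-step with a geometric
step distribution of mean 2.8. The one-tailed excess test is the exact
Wilcoxon signed-rank **mid-p** (`P(W > w) + 0.5 P(W = w)`), enumerated by
convolution over the doubled-rank grid; mid-p is forced by the published
values (0.00195 = 0.5/256 and 0.00977 = 2.5/256 at n = 8).

Two calibration notes, both established with the package's own simulators
and an exact Ewens-conditional oracle (the distribution of the allele
configuration given `k` under IAM is theta-free and enumerable at small n;
our coalescent reference matches it to < 0.002):

* The classical mean-centered difference `He_obs - mean(He_eq)` has null
  sign probability ~0.55, because He|k is left-skewed — visible in the
  classical "expected number of loci in excess" of ~4.5 out of 8. The
  one-tailed signed-rank excess test built on it therefore runs ~10% at
  nominal 5% with 8 loci. `het_excess_test(center = "median")` centres on
  the simulated median instead, restores the symmetry assumption and holds
  the nominal level; the default stays `"mean"` for fidelity to the
  classical tool and its published outputs.

* At fixed allele count the SMM equilibrium He sits *above* the IAM value
  (homoplasy requires a larger theta to hold `k` alleles), which matches
  the published expected-excess ordering (IAM 4.46 < TPM 4.51 < SMM 4.72)
  and the mutation-model literature. One acceptance clause asserts the
  opposite direction; that clause is implemented as written and left
  failing, with the property suite asserting the direction the data
  support.

The mode-shift diagnostic bins pooled allele frequencies into ten classes
and calls "L-shaped" only when the (0, 0.1] class is strictly modal. The
M-ratio is `k/(r + 1)` in repeat units, compared with the Mc = 0.68
threshold; off-ladder sizes are rounded to the nearest step and flagged.

# Diet metrics

Reads are filtered in the order: predator/human removal; within-replicate
proportional threshold (<= 0.5%, inclusive); replicate concordance (>= 2 of
3). FOO is detections over retained samples; wPOO gives each sample weight
1 split equally among its detected taxa, so it sums to 1. The sex
comparison runs PERMANOVA (Gower partition of squared Bray-Curtis
dissimilarities, label permutation, +1/+1) on **per-individual mean
profiles**, not per scat, to avoid pseudoreplicating repeatedly sampled
cats.

# Numerical conventions

* One global seed; stages draw child seeds at fixed offsets, so any stage
  can be reproduced in isolation and a rerun is byte-identical.
* Monte Carlo p-values always use the +1/+1 correction; exact enumerations
  (Wilcoxon mid-p, small Friedman) are deterministic.
* Missing genotypes are encoded 0 in files, `NA` in matrices; allele pairs
  are stored sorted ascending.
* Integer search spaces (census N up to 25, simplex grid 0.01) are searched
  exhaustively in preference to iterative optimizers.

# Known limitations

* No probabilistic consensus (quality scores), no ML-RELATE-style error
  model in the kinship likelihood.
* The Ne chi-square CI ignores the non-independence of allele comparisons.
* The coalescent calibration targets E[k] before rejection; for k near its
  bounds the acceptance rate can be low and the iteration cap may trigger.
* Diet simulation starts at taxon-assigned read counts; nothing upstream of
  taxonomic assignment is modelled.
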