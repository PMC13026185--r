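# scatpop

Noninvasive genetic and dietary analysis of small, kin-structured carnivore
populations, from replicate fecal-PCR genotype tables to census size,
bottleneck signals and diet composition — in one tested R pipeline.

## Who this is for

Conservation geneticists running scat-based microsatellite surveys of
elusive carnivores: a handful of individuals, repeated noninvasive captures,
high genotyping error (allelic dropout ~0.2 per replicate), and a companion
metabarcoding diet dataset. Every stage that such a study normally spreads
across GenAlEx, ML-RELATE, CAPWIRE, NeEstimator, BOTTLENECK and ad-hoc
scripts is implemented here behind one seedable interface, together with a
synthetic-data generator so each estimator can be checked by parameter
recovery.

## What it computes

- **Consensus genotyping** (multitube rules: heterozygote alleles confirmed
  in ≥2 PCRs, homozygotes in ≥3 clean replicates; up to 6 replicates), with
  ADO/FA error rates and the Brookfield null-allele estimator
  `F_N = (He − Ho)/(1 + He)`.
- **Individual identification**: probability of identity,
  `P_ID = Σp_i⁴ + Σ_{i<j}(2p_ip_j)²` and its sib analogue
  `P_IDsibs = 0.25 + 0.5Σp² + 0.5(Σp²)² − 0.25Σp⁴`, exact genotype matching
  with ≥6 overlapping loci, Zinc-Finger-style sex assignment, sex ratio,
  density and interannual recaptures.
- **Diversity**: Na, rarefied allelic richness, Ho, `He = 1 − Σp²`,
  Weir–Cockerham F_IS, Monte-Carlo-exact HWE tests, genotypic LD tests,
  Benjamini–Hochberg FDR, Friedman across-locality comparison (exact
  small-sample p).
- **Kinship**: ML classification of dyads over Cotterman coefficients
  `(k0, k1, k2)` into U/HS/FS/PO, continuous ML relatedness
  `r = k1/2 + k2`, and a Wang-type moment estimator cross-check.
- **Population size**: capture-with-replacement likelihoods — ECM
  `L(N) ∝ C(N,k)·N^(−t)` and the two-rate TIRM — with parametric-bootstrap
  model selection and CIs; effective size by the linkage-disequilibrium
  method (Burrows composite r², Waples sampling expectations).
- **Bottlenecks**: coalescent heterozygosity-excess tests under IAM/TPM/SMM
  with the exact mid-p Wilcoxon signed-rank test, mode-shift diagnostic, and
  the M-ratio `M = k/(r+1)` against Mc = 0.68.
- **Diet**: replicate-concordance read filtering, FOO, wPOO (sums to 1),
  Bray–Curtis dissimilarities and PERMANOVA by sex on per-individual
  profiles.

## Worked example

Simulate a study-scale survey (9 cats in a first-order pedigree, 11 loci,
ADO 0.21, FA 0.005, ~48% genotyping success) and run the full pipeline:

```r
library(scatpop)
cfg <- sim_config(seed = 4)
pop <- simulate_population(cfg)
res <- run_pipeline(simulate_replicate_table(pop),
                    locus_metadata = pop$loci,
                    diet = simulate_diet_table(pop),
                    config = pipeline_config(seed = 4, bottleneck_iter = 100))
str(res$report[c("genotyping_success", "ado", "fa", "n_individuals",
                 "Nc", "sex_ratio", "density_km2")])
```

```
List of 7
 $ genotyping_success: num 0.491
 $ ado               : num 0.21
 $ fa                : num 0.0045
 $ n_individuals     : int 9
 $ Nc                : int 9
 $ sex_ratio         : chr "2:1"
 $ density_km2       : num 0.299
```

All nine true individuals are recovered from 110 field scats; the estimated
error rates match the generator's configured ADO/FA; the census-size MLE on
the per-individual capture counts returns the true 9; and with 9 cats on
3013 ha the density is ~0.30 /km². The same run also fills
`res$diversity`, `res$kinship`, `res$bottleneck` and `res$diet`.

The same stages are scriptable:

```sh
Rscript exec/scatpop simulate --seed 4 --out-dir sim/
Rscript exec/scatpop all --replicates sim/replicates.csv \
        --loci sim/loci.csv --diet sim/diet.csv --seed 4 --out-dir results/
```

## Notes

Two acceptance clauses in the test suite are intentionally left failing
with analysis (the SMM-vs-IAM equilibrium-heterozygosity ordering and the
type-I level of the mean-centered excess test); see
`vignettes/scatpop-methods.Rmd` for the package's account of its methods,
calibration experiments and limitations.
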