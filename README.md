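# beetqtl

Comparing QTL detection between an (elite × exotic) sugar-beet progeny and
a structured elite panel, for root-impurity traits.

Sodium, potassium and α-amino nitrogen are the main melassigenic impurities
of the sugar-beet root: they keep sucrose in solution and reduce the white
sugar that can be crystallised, so breeders want alleles that *lower* them.
Exotic, unselected beet accessions are a candidate source of such alleles.
`beetqtl` implements the full analysis needed to ask whether an exotic
parent contributes favorable impurity alleles that the elite germplasm does
not already carry:

* a **synthetic-data generator** for biparental crossing schemes (F1,
  backcross, selfing, with or without a pedigree bottleneck), structured
  multi-family panels, planted QTLs, and lattice field trials with row,
  column, spatial and replicate effects at a target generalized
  heritability;
* **per-environment mixed-model adjustment** of plot data (fixed checks,
  replicates and a polynomial spatial surface; random rows, columns and
  genotypes) with Cullis generalized heritability, multi-environment mean
  phenotypes and environment correlations;
* **marker quality control**: missingness, chi-square segregation
  distortion, inverted-allele detection, flanking-marker imputation,
  redundancy, MAF and three-genotype-class filters;
* **linkage tools**: two-point recombination estimates (recombinant
  counting for backcross data, EM for three-class data), transitive linkage
  grouping, Haldane conversions, consensus inter-marker distances;
* **multi-locus mixed-model GWAS (MLMM)**: additive (A) and
  additive+dominance (AD) models with unscaled VanRaden / NOIA kinships,
  P3D Wald scans, forward selection, BIC/eBIC model choice, joint AD effect
  estimation and Tukey comparison of genotype classes;
* **kinship- and structure-corrected LD** with a resampled
  inter-chromosome significance threshold, **QTL merging** (≤ 5 cM between
  consecutive SNPs in LD above the threshold), favorable-exotic-allele
  labelling and cross-population **colocation**.

## The models

Phenotypes are testcross values adjusted per environment with

y = f(row, col) + Z_r c_r + Z_c c_c + Z_g c_g + X_t β_t + X_n β_n + ε,

and averaged over environments. The additive association model at locus
*l* is

y_i = μ (+ c_i) + x_il θ_a + u_i + e_i,  u ~ N(0, σ²_u K_a),  K_a = XX′,

with x the centered genotype codes (0/1/2 = elite homozygote /
heterozygote / exotic homozygote in the progeny) and c_i an optional
cluster (structure) term. The AD model adds a dominance regressor w_il and
a second polygenic term with K_d = WW′, where W is the unscaled NOIA
dominance design: for genotypic frequencies (p0, p1, p2) at a locus the
entries are (−p1p2, 2p0p2, −p0p1) for codes (0, 1, 2), the coding that is
exactly orthogonal to the centered additive column at the sample
frequencies. Forward selection adds the smallest-Wald-p SNP as a fixed
cofactor per step (variance components re-estimated once per step); the
reported step minimises BIC = −2·loglik + k·log n or
eBIC = BIC + 2γ·log C(m, s).

## Worked example

```r
library(beetqtl)
library(dplyr)

map     <- make_map(n_chrom = 9, markers_per_chrom = 30, length_cm = 90,
                    spacing = "random", seed = 11)
scheme  <- cross_scheme(c("F1", "BC", "self"), n_individuals = 187)
progeny <- simulate_cross(map, scheme, seed = 12)

# two favorable exotic QTLs for sodium content on chr1 and chr5
qtls  <- qtl_spec(marker = map$marker[c(15, 130)],
                  theta_a = c(-0.9, -0.6), trait = "Na")
specs <- lapply(sprintf("ENV%d", 1:3), field_trial_spec,
                n_rows = 20, n_cols = 20, n_reps = 2, n_checks = 4,
                env_mean = 10, sigma_row = 0.3, sigma_col = 0.3,
                sigma_spatial = 0.5, target_h2 = 0.75)
trials   <- simulate_trials(progeny, qtls, specs, polygenic_var = 0.4, seed = 13)
adjusted <- adjust_trials(trials, trait = "Na")
purrr::map_dfr(adjusted, glance)
#>   env   trait    h2 sigma_g2 sigma_row2 sigma_col2 sigma_e2 n_genotypes
#> 1 ENV1  Na    0.725    0.768     0.0502      0.136    0.521         187
#> 2 ENV2  Na    0.713    0.756     0.114       0.153    0.535         187
#> 3 ENV3  Na    0.776    0.836     0.0578      0.161    0.423         187

pheno <- mean_phenotype(adjusted)
trace <- forward_select(pheno, progeny, model = "A", map = map, max_steps = 5)
best  <- select_best_model(trace, criterion = "eBIC")
(effects <- estimate_effects(best, pheno, progeny))
#>   marker    theta_a theta_d pct_var mean_class0 mean_class1 mean_class2 favorable_exotic
#> 1 c01_m0015  -0.668 -0.0842   0.403        10.4        9.81        9.16 TRUE
#> 2 c05_m0010  -0.331 -0.156    0.139        10.3        9.91        9.57 TRUE

thr <- ld_threshold(progeny, map, correction = "kinship",
                    n_pairs = 5000, seed = 14)
merge_into_qtls(effects, map, ld = ld_provider(progeny, "kinship"),
                threshold = thr) |>
  label_favorable() |>
  select(-members)
#>   qtl_id  chrom start_cm end_cm n_members favorable
#> 1 QTL_001 chr1      31.5   31.5         1 yes
#> 2 QTL_002 chr5      26.0   26.0         1 yes
```

Both planted QTLs are recovered (the eBIC step keeps the two markers at
the planted positions), their additive effects are negative — the exotic
allele lowers sodium content, so both QTLs are labelled favorable — and
each SNP's share of the mean-phenotype variance (`pct_var`) is reported
from the joint AD fit. `run_pipeline(default_config())` chains the same
stages end to end for a progeny and a panel and writes all stage tables
plus a run manifest.

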