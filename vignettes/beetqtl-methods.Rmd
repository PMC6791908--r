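---
title: "Models and methods behind beetqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beetqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetqtl)
```

`beetqtl` compares QTL detection between two kinds of sugar-beet breeding
populations — a biparental (elite × exotic) progeny and a large, weakly
structured elite panel — for root impurity traits (potassium, sodium,
α-amino nitrogen, meq/100 g; lower is better, because these solutes impede
sucrose crystallisation). This vignette explains the models the package
implements, the choices made where several defensible options existed, and
what the synthetic-data generator does and does not emulate.

## The synthetic populations

**Meiosis.** Gametes are generated under the Haldane model: the crossover
count on a chromosome of length $L$ cM is Poisson($L/100$), breakpoints
are uniform, and there is no interference. This is the exactly consistent
counterpart of the Haldane map function used everywhere else in the
package ($d = -50\,\ln(1-2r)$, $r = (1 - e^{-2d/100})/2$), so estimated
recombination fractions converge to $r(d)$ by construction.

**Crossing schemes.** A scheme starts from an F1 of two fully homozygous
founders and applies any sequence of backcrosses to the elite parent and
selfings. Genotype codes are exotic-allele dosages (0 = elite homozygote,
2 = exotic homozygote). By default every individual descends through its
own lineage, which makes single-locus class frequencies exactly the
Mendelian chain expectations (`mendelian_expectation()`: 1:1 for BC1,
1:2:1 for F2, 5:2:1 for BC1S1). A real backcross progeny, however,
descends from a handful of BC plants; `cross_scheme(..., n_parents = k)`
reproduces that bottleneck with balanced families. The bottleneck leaves
single-locus marginals unchanged but makes class counts overdispersed
(the chi-square segregation filter is therefore only valid for
independent-lineage schemes) and creates genuine family structure, which
inflates raw inter-chromosome linkage disequilibrium — useful for studying
the LD-threshold machinery, and the reason the end-to-end demo pipeline
uses it, while the statistical acceptance experiments use independent
lineages.

**Panels.** A panel is a set of clusters, each a pool of homozygous
founder lines drawn from cluster-specific allele frequencies
($p_c = (1-\delta)p_{base} + \delta u_c$, so $\delta = 0$ gives
exchangeable clusters), from which many small biparental families are
produced as selfed F1s of random founder pairs. This mirrors breeding
panels that are unions of small crosses with mild global structure; the
cluster label is the structure covariate downstream.

**Field trials.** Each environment is a row × column grid holding complete
replicates of all entries plus fixed check entries repeated in every
replicate. A plot value is the sum of the environment mean, the genotype's
genetic value, random row and column effects, a smooth degree-2 polynomial
surface in the scaled coordinates (a deliberately simple stand-in for
spline-based spatial trend), a replicate effect, and iid residual noise.
The genetic value is $g_i = \sum_l x_{il}\theta_a^l + w_{il}\theta_d^l +
u_i$ with $x$ centered codes, $w$ the NOIA dominance codes of the
simulated population, and $u \sim N(0, \sigma^2_{poly} K_a/\overline{diag
K_a})$. Given `target_h2`, the residual SD is set from the realized
genetic variance as $\sigma_e^2 = r\,V_g(1-h^2)/h^2$ for $r$ replicates,
which calibrates the *entry-mean* (generalized) heritability the
adjustment recovers. Checks receive fixed genetic values (normal scores
scaled to the entry genetic SD).

What is *not* emulated: genotyping error and array-calling classes,
selection during population development, genotype × environment
interaction of QTL effects, multi-allelic markers, and sequence-level
processes. Green tests therefore certify the statistical machinery under
clean Mendelian sampling, not robustness to assay artefacts.

## Trial adjustment and heritability

Each environment is adjusted with a REML mixed model: fixed intercept,
replicate effects, one fixed level per check, and a polynomial surface
(default degree 2) in scaled row/column; random row, random column and
random genotype intercepts; iid residual. Checks share a single dummy
random-genotype level so they inform the nuisance terms without entering
the genetic variance. The adjusted phenotype is defined as intercept +
genotype BLUP — the standard single-trial genotype prediction — and the
multi-environment phenotype is the arithmetic mean over the environments
where a genotype is present.

The generalized heritability uses the Cullis prediction-error-variance
form, $h^2 = 1 - \overline{v}^{\Delta}_{BLUP} / (2\sigma^2_g)$, computed
from the conditional variances of the genotype BLUPs (the mean variance of
a BLUP difference is approximated by twice the mean PEV; off-diagonal
prediction covariances are negligible in these designs), clamped to
$[0,1]$. A classical entry-mean variant,
$\sigma^2_g/(\sigma^2_g+\sigma^2_e/r)$, is available via
`heritability = "entry_mean"`. On pure-noise traits the Cullis form
concentrates near zero (18/20 replicates below 0.1 at $n = 187$), and on
noise-free trials it saturates at 1.

White sugar is computed as $WS = S - (0.14(K+Na) + 0.25N + 0.5)$ — the
parenthesisation that matches standard extractable-sugar loss formulas,
with the fixed 0.5% processing loss outside the impurity terms — and
white sugar yield as $WSY = RY \cdot WS/100$.

## Marker quality control

Filters run in the order missingness (> 5% missing) → segregation
distortion (chi-square against the scheme's Mendelian expectation, raw
$p < 0.05$, degrees of freedom = non-null classes − 1, no continuity
correction) → inverted-allele detection → flanking imputation → redundancy
→ MAF (0.03 progeny / 0.05 panel) → three-genotype-class. MAF and
redundancy are computed after imputation, on complete data, so the chain
is deterministic; re-running any stage on its own output is a no-op.

Inverted markers (elite/exotic allele labels swapped) behave as $2-g$
relative to their neighbourhood. For each marker we collect map neighbours
within 20 cM whose phase-agnostic two-point LOD (a Gaussian-likelihood
score $-\tfrac{n}{2}\log_{10}(1-\rho^2)$ on genotype codes, so that a
swapped marker still *qualifies* as linked) reaches 3, and flag the marker
when most such neighbours correlate negatively with it. Markers without a
qualifying neighbour are left alone with a warning.

Imputation replaces a missing code by the nearest informative flanking
marker's code, preferring the flank with the larger no-recombination
probability $(1-r)^2$ under the Haldane map (agreeing flanks win
immediately; terminal gaps copy the nearest marker). At ~1 cM marker
density this recovers ≥ 95% of masked codes; it is a deliberately simple,
deterministic local rule, not a haplotype-phasing imputer.

## Linkage estimation and consensus maps

Two-class (backcross) pairs are estimated by recombinant counting;
three-class pairs by EM on the standard F2/S1 coupling likelihood
(initialised at $r = 0.25$, stopped at $|\Delta r| < 10^{-8}$ or 200
iterations; both are exact for the population types used in map building).
LOD is $\log_{10} L(\hat r) - \log_{10} L(0.5)$ with $\hat r$ truncated to
$[0, 0.5]$. Linkage groups are connected components of the graph with
edges $\hat r < 0.35$ and LOD $> 6$; components under 5 markers are set
aside, and groups are attributed to chromosomes by majority vote against a
reference map when one exists. Within-group marker *ordering* is out of
scope — consensus distances assume a shared order, as produced by external
ordering software or the simulation truth.

Consensus distances across populations: for each consecutive marker pair
in the global order, the consensus interval is the mean of that interval
over the maps containing both endpoints; a marker present in a single map
therefore splits its neighbourhood using that map's distances only, and
intervals defined in no map (endpoints that never co-occur) fall back to
linear interpolation on the marker index. Conflicting orders abort with
the chromosome and the offending pair named.

## Kinship, corrected LD and the significance threshold

The additive kinship is the unscaled VanRaden cross-product
$K_a = XX'$ of centered codes; the dominance kinship is $K_d = WW'$ with
the unscaled NOIA dominance design
$$w = \begin{cases} -p_1 p_2 & \text{code } 0\\ \;\;2 p_0 p_2 &
\text{code } 1\\ -p_0 p_1 & \text{code } 2,\end{cases}$$
each class weighted by the product of the other two genotypic-class
frequencies. This is the coding for which $\sum_i x_i w_i = 0$ holds
*exactly at arbitrary sample frequencies* (a frequently printed variant
that pairs each class with its own frequency loses this orthogonality
except at 1:2:1); orthogonality keeps the additive and dominance variance
components separable.

Corrected LD follows the whitening approach: kinship correction computes
the squared correlation of $V^{-1/2}$-transformed centered genotype
vectors with $V = K_a/\overline{diag K_a} + \delta I$,
$\delta = 10^{-6}\,tr(V)/n$ (the floor exists only for invertibility);
structure correction correlates residuals after regression on cluster
indicators. The significance threshold is the type-7 empirical 99%
quantile of corrected $r^2$ over 10,000 inter-chromosome marker pairs
sampled with replacement (undefined pairs are resampled and counted), with
every draw governed by an explicit seed.

A consequence worth knowing: when the kinship is estimated from the same
few hundred markers being tested, $V^{-1/2}$ whitening removes essentially
*all* relatedness-driven covariance, and the corrected progeny threshold
can fall below the iid null quantile — and below a structure-corrected
panel threshold, since cluster-mean regression leaves family-level LD in
place. Analyses that want only a partial correction need a
better-conditioned external kinship; with a marker-derived $V$ and a
near-zero ridge the correction is complete by construction. The package
reports both corrected and uncorrected thresholds so this behaviour is
visible.

## The multi-locus mixed model

REML variance components: with one kinship the restricted likelihood
(Harville form, profiled over $\sigma^2_e$) is maximised over the variance
ratio on the spectral decomposition of $K_a$ by 1-D optimisation; with two
kinships, by Nelder-Mead over both log ratios from a coarse log-grid
screen plus fixed starts, with a refinement pass (convergence checked
against brute-force grids in the tests). A positivity floor of
$10^{-8}\,var(y)$ on $\sigma^2_e$ guards exactly-representable phenotypes,
with a warning.

Scans are P3D: components are estimated once per forward step under the
current cofactor model and held fixed while every candidate is tested by a
generalized-least-squares Wald test — 1 df on the centered-code
coefficient under A, a joint 2-df test on the additive and dominance
coefficients under AD (a single ranking p-value per SNP is required by the
forward rule; an additive-only ranking inside the AD model is possible but
the joint test is the default). Candidates collinear with the current
fixed design are reported undefined, and a candidate whose columns would
make the design rank-deficient is skipped in favour of the next-best
p-value. Ties resolve to the lowest (chromosome, position, marker id).
With several hundred markers and fewer individuals the estimated-vc scan
is mildly conservative (the marker being tested also sits inside $K_a$,
which absorbs part of its signal); calibration given the true components
is exact, which is how the type-I-error property is tested.

Forward selection stops when the genetic variance share
$(\sigma^2_a \overline{k}_a + \sigma^2_d \overline{k}_d)/(\cdot +
\sigma^2_e)$ drops below `var_stop` ($10^{-3}$ operationalises "close to
zero"), at `max_steps` (20), or when no candidate is defined. Per step the
package records BIC $= -2\,\ell_{ML} + k\log n$ — the full-data Gaussian
log-likelihood at the step's REML variance estimates and GLS fixed
effects, with $k$ counting *all* fixed coefficients including intercept
and structure — and eBIC $= BIC + 2\gamma\log\binom{m}{s}$ with $\gamma =
1$ and $m$ the number of scanned candidates. eBIC is the intended
criterion for small-$n$/large-$m$ progenies; BIC for large panels.

Effects of the selected SNPs are estimated jointly in the AD model (the
most complete model) at the chosen step: GLS coefficients
$(\hat\theta_a, \hat\theta_d)$ per SNP, the share of phenotypic variance
$var(x\hat\theta_a + w\hat\theta_d)/var(y)$ (one defensible reading of a
multi-SNP "%var"; alternatives that partial out co-selected SNPs would
shrink it), the empirical class means, a Tukey HSD comparison of the three
genotype classes with a compact letter display, and the favorable-exotic
flag: for an impurity, the exotic allele is favorable iff the fitted
exotic-homozygote class value lies below the elite-homozygote one.

## QTL merging and colocation

Detected SNPs merge into a QTL when, on one chromosome in position order,
consecutive members are ≤ 5 cM apart *and* their corrected $r^2$ exceeds
the population's LD threshold; the LD condition is applied between
consecutive members during chain extension (matching the "consecutive
SNPs" reading; `mode = "all_pairs"` enforces it between all members).
Unmergeable and unmapped SNPs are singleton QTLs, so merging is a
partition — verified exhaustively against a connected-component oracle on
small cases. An optional post-pass (`split_qtls()`) cuts intervals longer
than 5 cM into 5 cM bins, for genomes where residual long-range LD would
otherwise produce implausibly long QTLs. Colocation annotates each QTL of
one population with the nearest same-chromosome (and same-trait) QTL of
the other; intervals at gap ≤ 5 cM (0 when overlapping) are colocated,
others novel.

## Problem sizes, determinism and limitations

The test suite and the acceptance script use a 9-chromosome, 90 cM map
with ~630 markers, a progeny of 187, panels of 400–2,000, six simulated
environments on 20 × 20 lattices, 10,000 (threshold) or 2,000
(replicated-threshold) LD pairs, and 10–20 replicates per Monte-Carlo
claim — sizes at which every stochastic assertion has comfortable margin
while a full run stays in the minutes range. Every random step is a pure
function of an explicit seed (`withr::with_seed`; derived stream seeds
stay below $2^{31}$), so identical configurations reproduce identical
tables byte for byte.

Known limitations: single-trait models only (no G×E or multi-trait
decomposition); no haplotype-based LD measures; no marker ordering; the
spatial surface is polynomial, not spline-based; the imputation is local
and deterministic rather than probabilistic; detection power for QTLs
explaining ≲ 10% of a 187-individual progeny's phenotype under a strong
polygenic background is intrinsically low for a forward-selected
mixed-model scan with an eBIC penalty — the kinship absorbs small signals
(proximal contamination), and the package deliberately does not exclude
the tested marker from the kinship.
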