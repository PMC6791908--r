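# Study-condition fixtures: canned synthetic populations matching the
# analysis conditions (BC1S1 progeny of 187 on 9 chromosomes with ~630
# three-class SNPs; structured two-cluster elite panel), used by the
# examples, the acceptance experiments and the vignette.

#' Study-scale genetic map
#'
#' Nine chromosomes of 90 cM with `markers_per_chrom` markers at random
#' positions.
#'
#' @param seed Integer seed.
#' @param markers_per_chrom Markers per chromosome (default 70, ~630 total).
#' @return A map tibble.
#' @export
study_map <- function(seed = 101L, markers_per_chrom = 70L) {
  make_map(9L, markers_per_chrom, 90, "random", seed = seed)
}

#' Simulate the study progeny with planted QTLs and field trials
#'
#' Generates a BC1S1 (elite x exotic) progeny, plants additive QTLs on
#' distinct chromosomes, simulates lattice trials in `n_env` environments
#' at a target per-environment generalized heritability, adjusts each
#' environment and returns the multi-environment mean phenotype.
#'
#' QTL effect sizes are chosen so each QTL's variance share of the mean
#' phenotype equals `qtl_shares[l]`; the remaining genetic variance needed
#' to reach `h2_env` is polygenic (`N(0, sigma2 K_a)`). QTL markers are the
#' highest-variance markers in the 30-60 cM window of chromosomes 1, 4 and
#' 7 (deterministic given the genotypes).
#'
#' @param seed Integer seed driving all randomness.
#' @param n Progeny size (default 187).
#' @param markers_per_chrom Markers per chromosome (default 70).
#' @param qtl_shares Per-QTL variance shares of the mean phenotype
#'   (default `c(0.10, 0.05, 0.05)`).
#' @param h2_env Target per-environment generalized heritability
#'   (default 0.7).
#' @param n_env Number of environments (default 6).
#' @param n_parents Optional pedigree bottleneck (see [cross_scheme()]).
#' @return List with `map`, `scheme`, `geno`, `qtls` (tibble with `marker`,
#'   `chrom`, `pos_cm`, `theta_a`), `trials`, `adjusted` (list of
#'   `beet_adjusted`), `pheno` (mean-phenotype tibble), `h2` (per-env
#'   vector).
#' @export
simulate_progeny_study <- function(seed, n = 187L, markers_per_chrom = 70L,
                                   qtl_shares = c(0.10, 0.05, 0.05),
                                   h2_env = 0.7, n_env = 6L, n_parents = NULL) {
  map <- study_map(markers_per_chrom = markers_per_chrom)
  scheme <- cross_scheme(c("F1", "BC", "self"), n, n_parents = n_parents)
  geno <- simulate_cross(map, scheme, seed = child_seed(seed, 11L))
  cg <- center_genotypes(geno)
  vx <- apply(cg$X, 2, var)
  qtl_chroms <- c("chr1", "chr4", "chr7")[seq_along(qtl_shares)]
  qi <- vapply(qtl_chroms, function(ch) {
    i <- which(map$chrom == ch & map$pos_cm > 30 & map$pos_cm < 60)
    i[which.max(vx[i])]
  }, integer(1))
  # variance bookkeeping on the entry-mean scale (Vm = 1):
  # Vg = h2_env, mean-phenotype variance = Vg + (1 - h2_env) / n_env
  v_mean <- h2_env + (1 - h2_env) / n_env
  f_abs <- qtl_shares * v_mean
  if (sum(f_abs) >= h2_env) {
    rlang::abort("QTL shares exceed the genetic variance implied by `h2_env`.")
  }
  theta <- -sqrt(f_abs / vx[qi])
  polygenic_var <- h2_env - sum(f_abs)
  qtls <- qtl_spec(map$marker[qi], theta, 0, "K")
  specs <- lapply(seq_len(n_env), function(i) {
    field_trial_spec(sprintf("ENV%d", i), 20L, 20L, 2L, 4L, env_mean = 40,
                     sigma_row = 0.3, sigma_col = 0.3, sigma_spatial = 0.5,
                     target_h2 = h2_env)
  })
  trials <- simulate_trials(geno, qtls, specs, polygenic_var = polygenic_var,
                            seed = child_seed(seed, 12L))
  adjusted <- adjust_trials(trials, "K")
  pheno <- suppressWarnings(mean_phenotype(adjusted))
  list(map = map, scheme = scheme, geno = geno,
       qtls = dplyr::mutate(qtls,
                            chrom = map$chrom[qi], pos_cm = map$pos_cm[qi]),
       trials = trials, adjusted = adjusted, pheno = pheno,
       h2 = vapply(adjusted, function(a) a$h2, numeric(1)))
}

#' Simulate the study elite panel
#'
#' Two clusters of many small biparental families (cluster sizes roughly
#' 1:2, as in the study's hierarchical clustering), on the study map.
#'
#' @param seed Integer seed.
#' @param n Approximate panel size (default 2000).
#' @param family_size Individuals per family (default 10).
#' @param markers_per_chrom Markers per chromosome (default 70).
#' @param founder_divergence Cluster divergence (default 0.4).
#' @return A [beet_geno()] with cluster labels.
#' @export
simulate_panel_study <- function(seed, n = 2000L, family_size = 10L,
                                 markers_per_chrom = 70L,
                                 founder_divergence = 0.4) {
  map <- study_map(markers_per_chrom = markers_per_chrom)
  fams <- max(2L, round(n / family_size / 2))
  simulate_panel(map, n_clusters = 2L, families_per_cluster = fams,
                 family_size = family_size,
                 founder_divergence = founder_divergence,
                 seed = child_seed(seed, 13L))
}

#' Score detected SNPs against planted QTLs
#'
#' A planted QTL counts as recovered when some selected SNP lies within
#' `window_cm` of it on its chromosome; a selected SNP matching no planted
#' QTL within the window counts as a false QTL.
#'
#' @param selected Marker ids selected by the model.
#' @param truth Tibble with `chrom`, `pos_cm` of the planted QTLs.
#' @param map Map tibble.
#' @param window_cm Match window (default 5).
#' @return List with `n_hit`, `n_false`, `n_selected`.
#' @export
score_qtl_recovery <- function(selected, truth, map, window_cm = 5) {
  if (length(selected) == 0L) {
    return(list(n_hit = 0L, n_false = 0L, n_selected = 0L))
  }
  sc <- map$chrom[match(selected, map$marker)]
  sp <- map$pos_cm[match(selected, map$marker)]
  hit <- vapply(seq_len(nrow(truth)), function(j) {
    any(sc == truth$chrom[j] & abs(sp - truth$pos_cm[j]) <= window_cm,
        na.rm = TRUE)
  }, logical(1))
  false <- vapply(seq_along(selected), function(s) {
    !any(sc[s] == truth$chrom & abs(sp[s] - truth$pos_cm) <= window_cm,
         na.rm = TRUE)
  }, logical(1))
  list(n_hit = sum(hit), n_false = sum(false), n_selected = length(selected))
}
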