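#' Simulate a structured elite panel
#'
#' Emulates a breeding panel composed of many small biparental families
#' organised in clusters. Per cluster, a pool of fully homozygous founder
#' lines is drawn from cluster-specific allele frequencies; each family is
#' the selfed progeny (with recombination) of the F1 of a random founder
#' pair within its cluster.
#'
#' Cluster allele frequencies are
#' `p_c = (1 - divergence) * p_base + divergence * u_c`, with `p_base ~
#' U(0.1, 0.9)` shared across clusters and `u_c ~ U(0, 1)` per cluster, so
#' `divergence = 0` gives identical founder pools and larger values give
#' separable cluster structure.
#'
#' @param map Map tibble (see [make_map()]).
#' @param n_clusters Number of clusters (>= 1).
#' @param families_per_cluster Families per cluster (>= 1).
#' @param family_size Individuals per family (>= 1).
#' @param founder_divergence Cluster allele-frequency divergence in `[0, 1]`.
#' @param founders_per_cluster Size of each cluster's founder pool.
#' @param seed Integer seed.
#' @return A [beet_geno()] with `population = "panel"` and cluster labels.
#' @export
#' @examples
#' map <- make_map(3, 20, 90, "uniform", seed = 1)
#' p <- simulate_panel(map, 2, 10, 20, founder_divergence = 0.4, seed = 3)
#' table(p$cluster)
simulate_panel <- function(map, n_clusters, families_per_cluster, family_size,
                           founder_divergence = 0.3,
                           founders_per_cluster = max(4L, families_per_cluster),
                           seed = 1L) {
  map <- validate_map(map)
  if (family_size < 1) rlang::abort("`family_size` must be >= 1.")
  if (n_clusters < 1) rlang::abort("`n_clusters` must be >= 1.")
  if (families_per_cluster < 1) rlang::abort("`families_per_cluster` must be >= 1.")
  assert_scalar_number(founder_divergence, "founder_divergence", 0, 1)
  founders_per_cluster <- max(2L, as.integer(founders_per_cluster))
  chroms <- split(map, map$chrom)
  m <- nrow(map)
  with_seed(seed, {
    p_base <- runif(m, 0.1, 0.9)
    names(p_base) <- map$marker
    rows <- list()
    cluster_lab <- character(0)
    ids <- character(0)
    for (cl in seq_len(n_clusters)) {
      u_c <- runif(m)
      p_c <- (1 - founder_divergence) * p_base + founder_divergence * u_c
      founders <- matrix(rbinom(founders_per_cluster * m, 1L, rep(p_c, each = founders_per_cluster)),
                         nrow = founders_per_cluster, ncol = m)
      for (fam in seq_len(families_per_cluster)) {
        pair <- sample.int(founders_per_cluster, 2L)
        fa <- founders[pair[1], ]
        fb <- founders[pair[2], ]
        fam_codes <- matrix(0L, family_size, m)
        for (i in seq_len(family_size)) {
          off <- 0L
          geno_i <- integer(m)
          for (cm in chroms) {
            idx <- off + seq_along(cm$pos_cm)
            len <- max(cm$pos_cm)
            ga <- gamete_one_chrom(fa[idx], fb[idx], cm$pos_cm, len)
            gb <- gamete_one_chrom(fa[idx], fb[idx], cm$pos_cm, len)
            geno_i[idx] <- ga + gb
            off <- off + length(idx)
          }
          fam_codes[i, ] <- geno_i
        }
        rows[[length(rows) + 1L]] <- fam_codes
        lab <- LETTERS[(cl - 1L) %% 26L + 1L]
        cluster_lab <- c(cluster_lab, rep(lab, family_size))
        ids <- c(ids, sprintf("cl%s_f%03d_i%03d", lab, fam, seq_len(family_size)))
      }
    }
    codes <- do.call(rbind, rows)
    # chromosomes were walked in split() order; markers follow sorted map order
    ord_map <- dplyr::bind_rows(chroms)
    colnames(codes) <- ord_map$marker
    rownames(codes) <- ids
    codes <- codes[, map$marker, drop = FALSE]
    beet_geno(codes, population = "panel", cluster = cluster_lab)
  })
}
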