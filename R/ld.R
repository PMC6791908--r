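# Kinship/structure-corrected linkage disequilibrium.

# Symmetric inverse square root of V = K/mean(diag(K)) + delta*I, the
# whitening operator used for kinship-corrected r2.
ld_whitener <- function(K) {
  if (inherits(K, "beet_kinship")) K <- K$K
  n <- nrow(K)
  V <- K / mean(diag(K))
  delta <- 1e-6 * sum(diag(V)) / n
  V <- V + diag(delta, n)
  ev <- eigen(V, symmetric = TRUE)
  lam <- pmax(ev$values, delta)
  ev$vectors %*% (t(ev$vectors) / sqrt(lam))
}

#' Corrected squared correlation between two markers
#'
#' Squared Pearson correlation of two genotype-code vectors, optionally
#' corrected for genetic relatedness or for population structure.
#' `correction = "kinship"` whitens the centered vectors by the symmetric
#' inverse square root of `V = K / mean(diag(K)) + delta * I`
#' (`delta = 1e-6 * trace(V)/n`); `correction = "structure"` correlates the
#' residuals of each vector after regression on cluster indicators.
#'
#' @param x,y Numeric genotype-code vectors (complete).
#' @param correction `"none"`, `"kinship"` or `"structure"`.
#' @param kinship A [kinship()] object or square matrix (for
#'   `correction = "kinship"`).
#' @param cluster Cluster labels (for `correction = "structure"`).
#' @param whitener Optional precomputed [ld_whitener()] matrix; overrides
#'   `kinship` and saves the eigendecomposition when scoring many pairs.
#' @return Squared correlation in `[0, 1]`, or `NA` when a vector has zero
#'   variance after correction.
#' @export
corrected_r2 <- function(x, y, correction = c("none", "kinship", "structure"),
                         kinship = NULL, cluster = NULL, whitener = NULL) {
  correction <- match.arg(correction)
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  if (anyNA(x) || anyNA(y)) rlang::abort("Complete codes required.")
  if (correction == "none") {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    return(cor(x, y)^2)
  }
  if (correction == "kinship") {
    Wm <- whitener %||% ld_whitener(kinship %||%
      rlang::abort("`kinship` (or `whitener`) required for kinship correction."))
    xr <- as.vector(Wm %*% (x - mean(x)))
    yr <- as.vector(Wm %*% (y - mean(y)))
  } else {
    if (is.null(cluster)) rlang::abort("`cluster` required for structure correction.")
    f <- factor(cluster)
    xr <- x - stats::ave(x, f)
    yr <- y - stats::ave(y, f)
  }
  if (sd(xr) == 0 || sd(yr) == 0) return(NA_real_)
  cor(xr, yr)^2
}

#' Resampled inter-chromosome LD significance threshold
#'
#' Samples `n_pairs` marker pairs (with replacement) from different
#' chromosomes, computes the corrected squared correlation of each pair,
#' and returns the empirical `q`-quantile (type-7) of the distribution as
#' the LD significance threshold. Pairs undefined after correction
#' (monomorphic or zero within-cluster variance) are resampled and the
#' resample count recorded.
#'
#' @param geno A [beet_geno()] with complete codes.
#' @param map Map tibble with at least 2 chromosomes covering the markers.
#' @param correction `"none"`, `"kinship"` or `"structure"`.
#' @param kinship A [kinship()] object (computed from `geno` when `NULL` and
#'   `correction = "kinship"`).
#' @param cluster Cluster labels; defaults to `geno$cluster`.
#' @param n_pairs Number of sampled pairs (default 10000).
#' @param q Quantile (default 0.99).
#' @param seed Integer seed.
#' @return A `beet_ld_threshold` object: list with `value`, `n_pairs`, `q`,
#'   `correction`, `seed`, `n_resampled` and the sampled `r2` values.
#' @export
ld_threshold <- function(geno, map, correction = c("none", "kinship", "structure"),
                         kinship = NULL, cluster = NULL,
                         n_pairs = 10000L, q = 0.99, seed = 1L) {
  correction <- match.arg(correction)
  map <- validate_map(map)
  mk <- intersect(marker_ids(geno), map$marker)
  if (length(mk) < 2L) rlang::abort("Map does not cover the genotyped markers.")
  chrom <- map$chrom[match(mk, map$marker)]
  if (length(unique(chrom)) < 2L) {
    rlang::abort("LD thresholding needs markers on at least 2 chromosomes.")
  }
  codes <- geno$codes[, mk, drop = FALSE]
  if (anyNA(codes)) rlang::abort("Complete codes required; impute first.")
  cluster <- cluster %||% geno$cluster
  whitener <- NULL
  if (correction == "kinship") {
    K <- kinship %||% kinship(center_genotypes(geno))
    whitener <- ld_whitener(K)
  }
  # pre-transform all marker columns once
  Xc <- scale(codes, center = TRUE, scale = FALSE)
  if (correction == "kinship") {
    Xt <- whitener %*% Xc
  } else if (correction == "structure") {
    if (is.null(cluster)) rlang::abort("`cluster` required for structure correction.")
    f <- factor(cluster)
    Xt <- apply(codes, 2, function(x) x - stats::ave(x, f))
  } else {
    Xt <- Xc
  }
  sds <- apply(Xt, 2, sd)
  m <- length(mk)
  with_seed(seed, {
    r2 <- numeric(n_pairs)
    n_resampled <- 0L
    filled <- 0L
    while (filled < n_pairs) {
      todo <- n_pairs - filled
      i <- sample.int(m, todo, replace = TRUE)
      j <- sample.int(m, todo, replace = TRUE)
      ok <- chrom[i] != chrom[j] & sds[i] > 0 & sds[j] > 0
      n_resampled <- n_resampled + sum(!ok & chrom[i] != chrom[j])
      i <- i[ok]; j <- j[ok]
      if (length(i) == 0L) next
      vals <- vapply(seq_along(i), function(k) {
        cor(Xt[, i[k]], Xt[, j[k]])^2
      }, numeric(1))
      r2[filled + seq_along(vals)] <- vals
      filled <- filled + length(vals)
    }
    structure(list(value = unname(quantile(r2, q, type = 7)),
                   n_pairs = as.integer(n_pairs), q = q,
                   correction = correction, seed = as.integer(seed),
                   n_resampled = n_resampled, r2 = r2),
              class = "beet_ld_threshold")
  })
}

#' @export
print.beet_ld_threshold <- function(x, ...) {
  cat(sprintf("<beet_ld_threshold> %.4f (%s-corrected, %d pairs, q = %.2f)\n",
              x$value, x$correction, x$n_pairs, x$q))
  invisible(x)
}
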