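#' Center genotype codes
#'
#' Subtracts the per-marker mean code, giving the additive design matrix `X`
#' used both for the additive kinship `K_a = X X'` and as the fixed additive
#' regressor of each tested SNP. Per-marker genotypic frequencies
#' `(p0, p1, p2)` are recorded for the dominance design.
#'
#' @param geno A [beet_geno()] with no missing codes.
#' @return A `beet_centered` object: list with `X` (individuals x markers,
#'   column means zero) and `freqs` (tibble `marker`, `p0`, `p1`, `p2`).
#' @export
center_genotypes <- function(geno) {
  codes <- geno$codes
  if (anyNA(codes)) {
    rlang::abort("Genotypes must be complete before centering; impute first.")
  }
  X <- scale(codes, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  freqs <- tibble::tibble(
    marker = colnames(codes),
    p0 = unname(colMeans(codes == 0L)),
    p1 = unname(colMeans(codes == 1L)),
    p2 = unname(colMeans(codes == 2L))
  )
  structure(list(X = X, freqs = freqs), class = "beet_centered")
}

#' NOIA dominance design matrix
#'
#' Builds the unscaled NOIA dominance predictor: with genotypic frequencies
#' `(p0, p1, p2)` at a locus, the entry for an individual is `-p1*p2` for
#' the 0 homozygote, `2*p0*p2` for the heterozygote, and `-p0*p1` for the 2
#' homozygote (each class weighted by the product of the other two class
#' frequencies). This is the coding that makes every dominance column
#' exactly orthogonal to the same marker's centered additive column at the
#' sample genotypic frequencies; at symmetric (1:2:1) frequencies it equals
#' `(-0.125, 0.125, -0.125)` for codes (0, 1, 2).
#'
#' @param geno A [beet_geno()] with no missing codes.
#' @return A `beet_dominance` object: list with `W` (individuals x markers)
#'   and `freqs` as in [center_genotypes()].
#' @export
dominance_design <- function(geno) {
  codes <- geno$codes
  if (anyNA(codes)) {
    rlang::abort("Genotypes must be complete before building the dominance design.")
  }
  p0 <- colMeans(codes == 0L)
  p1 <- colMeans(codes == 1L)
  p2 <- colMeans(codes == 2L)
  v0 <- -p1 * p2
  v1 <- 2 * p0 * p2
  v2 <- -p0 * p1
  W <- matrix(0, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  for (k in seq_len(ncol(codes))) {
    W[, k] <- c(v0[k], v1[k], v2[k])[codes[, k] + 1L]
  }
  freqs <- tibble::tibble(marker = colnames(codes), p0 = unname(p0),
                          p1 = unname(p1), p2 = unname(p2))
  structure(list(W = W, freqs = freqs), class = "beet_dominance")
}

#' Unscaled kinship matrix
#'
#' Computes `K = M M'` for a centered additive design (`K_a`, the unscaled
#' VanRaden relationship) or a NOIA dominance design (`K_d`). No scaling is
#' applied.
#'
#' @param design A `beet_centered` or `beet_dominance` object.
#' @return A `beet_kinship` object: list with symmetric PSD matrix `K` and
#'   `kind` (`"additive"` or `"dominance"`).
#' @export
kinship <- function(design) {
  if (inherits(design, "beet_centered")) {
    M <- design$X
    kind <- "additive"
  } else if (inherits(design, "beet_dominance")) {
    M <- design$W
    kind <- "dominance"
  } else {
    rlang::abort("`design` must come from center_genotypes() or dominance_design().")
  }
  K <- tcrossprod(M)
  K <- (K + t(K)) / 2
  structure(list(K = K, kind = kind), class = "beet_kinship")
}

#' @export
print.beet_kinship <- function(x, ...) {
  cat(sprintf("<beet_kinship> %s, %d individuals, mean diagonal %.3f\n",
              x$kind, nrow(x$K), mean(diag(x$K))))
  invisible(x)
}
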