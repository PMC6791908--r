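#' Genotype matrix container
#'
#' A `beet_geno` object holds an individuals-by-markers matrix of genotype
#' codes together with population metadata. Codes are 0, 1, 2 or `NA`.
#' In a biparental progeny, 0 is the elite homozygote, 1 the heterozygote and
#' 2 the exotic homozygote; in a panel the orientation of each marker is
#' arbitrary.
#'
#' @param codes Integer or numeric matrix (individuals x markers) with values
#'   in `{0, 1, 2, NA}`. Must carry row names (individual ids) and column
#'   names (marker ids).
#' @param population Either `"progeny"` or `"panel"`.
#' @param cluster Optional character/factor vector of cluster labels, one per
#'   individual (panel structure). Recycled names are taken from `codes`.
#' @param scheme Optional [cross_scheme()] that produced a progeny.
#'
#' @return A `beet_geno` object: a list with elements `codes`, `population`,
#'   `cluster` and `scheme`.
#' @export
#' @examples
#' g <- beet_geno(matrix(c(0, 1, 2, 1), 2, 2,
#'                       dimnames = list(c("i1", "i2"), c("m1", "m2"))),
#'                population = "progeny")
#' dim(g)
beet_geno <- function(codes, population = c("progeny", "panel"),
                      cluster = NULL, scheme = NULL) {
  population <- match.arg(population)
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    rlang::abort("`codes` must have individual row names and marker column names.")
  }
  bad <- !(codes %in% c(0, 1, 2) | is.na(codes))
  if (any(bad)) {
    rlang::abort("Genotype codes must be 0, 1, 2 or NA.")
  }
  storage.mode(codes) <- "integer"
  if (anyDuplicated(colnames(codes))) rlang::abort("Marker ids must be unique.")
  if (anyDuplicated(rownames(codes))) rlang::abort("Individual ids must be unique.")
  if (!is.null(cluster)) {
    cluster <- as.character(cluster)
    if (length(cluster) != nrow(codes)) {
      rlang::abort("`cluster` must have one label per individual.")
    }
    names(cluster) <- rownames(codes)
  }
  structure(list(codes = codes, population = population,
                 cluster = cluster, scheme = scheme),
            class = "beet_geno")
}

#' @export
dim.beet_geno <- function(x) dim(x$codes)

#' @export
print.beet_geno <- function(x, ...) {
  cat(sprintf("<beet_geno> %d individuals x %d markers (%s)\n",
              nrow(x$codes), ncol(x$codes), x$population))
  if (!is.null(x$cluster)) {
    tab <- table(x$cluster)
    cat("clusters:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  nm <- sum(is.na(x$codes))
  cat(sprintf("missing codes: %d (%.2f%%)\n", nm, 100 * nm / length(x$codes)))
  invisible(x)
}

marker_ids <- function(geno) colnames(geno$codes)
individual_ids <- function(geno) rownames(geno$codes)

# Replace the code matrix, keeping metadata.
set_codes <- function(geno, codes) {
  geno$codes <- codes
  geno
}

#' Convert a genotype matrix to a long tibble
#'
#' @param x A `beet_geno` object.
#' @param ... Unused.
#' @return A tibble with columns `individual`, `marker`, `code`.
#' @export
as_tibble.beet_geno <- function(x, ...) {
  tibble::tibble(
    individual = rep(rownames(x$codes), times = ncol(x$codes)),
    marker = rep(colnames(x$codes), each = nrow(x$codes)),
    code = as.integer(x$codes)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
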