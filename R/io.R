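# Plain-TSV input/output with validation. Every table written by the
# pipeline starts with a comment line recording the producing stage and a
# config hash; readers skip '#' lines.

config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

write_tsv_stamped <- function(df, path, stage, hash = "none") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beetqtl stage=%s config=%s", stage, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA")
}

#' Read and write genotype tables
#'
#' Genotype TSV: an `individual` id column, an optional `cluster` column,
#' then one column per marker; missing codes are `NA`. Codes other than
#' 0/1/2/NA are rejected with the offending line number.
#'
#' @param geno A [beet_geno()].
#' @param path File path.
#' @param stage,hash Stamp for the header comment line.
#' @param population Population kind for [read_genotype_tsv()].
#' @return `read_genotype_tsv()` returns a [beet_geno()].
#' @export
write_genotype_tsv <- function(geno, path, stage = "genotype", hash = "none") {
  df <- data.frame(individual = rownames(geno$codes))
  if (!is.null(geno$cluster)) df$cluster <- unname(geno$cluster)
  df <- cbind(df, as.data.frame(geno$codes, check.names = FALSE))
  write_tsv_stamped(df, path, stage, hash)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path, population = c("progeny", "panel")) {
  population <- match.arg(population)
  df <- read_tsv_plain(path)
  if (names(df)[1] != "individual") {
    rlang::abort("Genotype TSV must start with an `individual` column.")
  }
  cluster <- NULL
  first_mk <- 2L
  if (ncol(df) >= 2L && names(df)[2] == "cluster") {
    cluster <- df$cluster
    first_mk <- 3L
  }
  codes <- as.matrix(df[, first_mk:ncol(df), drop = FALSE])
  bad <- which(!(codes %in% c(0, 1, 2)) & !is.na(codes), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf("Invalid genotype code at line %d (marker %s).",
                         bad[1, 1] + 2L, colnames(codes)[bad[1, 2]]))
  }
  if (anyDuplicated(df$individual)) {
    rlang::abort(sprintf("Duplicate individual id at line %d.",
                         anyDuplicated(df$individual) + 2L))
  }
  rownames(codes) <- df$individual
  beet_geno(codes, population = population, cluster = cluster)
}

#' Read and write genetic-map tables
#'
#' Map TSV columns: `marker`, `chrom`, `pos_cm`. Reading validates the map
#' invariants (unique markers, strictly increasing positions within each
#' chromosome).
#'
#' @param map Map tibble.
#' @param path File path.
#' @param stage,hash Stamp for the header comment line.
#' @return `read_map_tsv()` returns a validated map tibble.
#' @export
write_map_tsv <- function(map, path, stage = "map", hash = "none") {
  write_tsv_stamped(as.data.frame(map), path, stage, hash)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  df <- tibble::as_tibble(read_tsv_plain(path))
  validate_map(df)
  dplyr::arrange(df, .data$chrom, .data$pos_cm)
}

#' Read and write field-trial plot tables
#'
#' Trial TSV columns: `env`, `genotype`, `row`, `col`, `rep`, `is_check`,
#' then one numeric column per trait.
#'
#' @param trials Plot tibble (see [simulate_trials()]).
#' @param path File path.
#' @param stage,hash Stamp for the header comment line.
#' @return `read_trials_tsv()` returns the plot tibble.
#' @export
write_trials_tsv <- function(trials, path, stage = "trials", hash = "none") {
  write_tsv_stamped(as.data.frame(trials), path, stage, hash)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  df <- tibble::as_tibble(read_tsv_plain(path))
  need <- c("env", "genotype", "row", "col", "rep", "is_check")
  if (!all(need %in% names(df))) {
    rlang::abort(paste0("Trial TSV must have columns ", paste(need, collapse = ", "), "."))
  }
  traits <- setdiff(names(df), need)
  for (tr in traits) {
    if (!is.numeric(df[[tr]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[tr]]))) & !is.na(df[[tr]]))[1]
      rlang::abort(sprintf("Non-numeric trait value in column %s at line %d.",
                           tr, bad + 2L))
    }
  }
  df$is_check <- as.logical(df$is_check)
  df
}

#' Read and write kinship matrices
#'
#' Square TSV with individual ids as first column and as column names.
#'
#' @param k A [kinship()] object or square matrix.
#' @param path File path.
#' @param stage,hash Stamp for the header comment line.
#' @param kind Kinship kind for `read_kinship_tsv()`.
#' @return `read_kinship_tsv()` returns a `beet_kinship`.
#' @export
write_kinship_tsv <- function(k, path, stage = "kinship", hash = "none") {
  K <- if (inherits(k, "beet_kinship")) k$K else k
  df <- data.frame(individual = rownames(K), K, check.names = FALSE)
  write_tsv_stamped(df, path, stage, hash)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path, kind = c("additive", "dominance")) {
  kind <- match.arg(kind)
  df <- read_tsv_plain(path)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  if (nrow(K) != ncol(K)) rlang::abort("Kinship TSV must be square.")
  structure(list(K = K, kind = kind), class = "beet_kinship")
}
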