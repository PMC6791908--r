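# Shared small fixtures built in code.

tiny_map <- function(n_chrom = 2, m = 10, len = 90) {
  make_map(n_chrom, m, len, "uniform", seed = 1)
}

# A genotype object from an explicit code matrix.
geno_from <- function(codes, population = "progeny", cluster = NULL) {
  if (is.null(rownames(codes))) rownames(codes) <- sprintf("i%02d", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("m%02d", seq_len(ncol(codes)))
  beet_geno(codes, population = population, cluster = cluster)
}

# Independent HWE markers (no LD, no structure), allele freqs in [0.2, 0.8].
iid_panel <- function(n, m, seed) {
  withr::with_seed(seed, {
    p <- runif(m, 0.2, 0.8)
    codes <- sapply(p, function(pp) rbinom(n, 2L, pp))
    colnames(codes) <- sprintf("m%03d", seq_len(m))
    rownames(codes) <- sprintf("i%04d", seq_len(n))
    beet_geno(codes, population = "panel")
  })
}

# Map placing iid markers on alternating chromosomes.
iid_map <- function(m, n_chrom = 2) {
  tibble::tibble(marker = sprintf("m%03d", seq_len(m)),
                 chrom = sprintf("chr%d", rep_len(seq_len(n_chrom), m)),
                 pos_cm = as.numeric(seq_len(m))) |>
    dplyr::group_by(chrom) |>
    dplyr::mutate(pos_cm = dplyr::row_number() * 5) |>
    dplyr::ungroup() |>
    dplyr::arrange(chrom, pos_cm)
}
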