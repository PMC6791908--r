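# Genotype quality-control filters. Each filter returns list(geno, report)
# where report is a tibble with one row per *input* marker:
#   marker, kept (logical), reason (NA when kept), plus filter-specific columns.

filter_report <- function(markers, kept, reason, ...) {
  extra <- lapply(list(...), unname)
  dplyr::bind_cols(
    tibble::tibble(marker = unname(markers), kept = unname(kept),
                   reason = ifelse(kept, NA_character_, reason)),
    tibble::as_tibble(extra))
}

drop_markers <- function(geno, drop) {
  set_codes(geno, geno$codes[, setdiff(colnames(geno$codes), drop), drop = FALSE])
}

#' Filter markers by missingness
#'
#' Removes markers whose fraction of missing codes exceeds `max_missing`.
#'
#' @param geno A [beet_geno()].
#' @param max_missing Maximum tolerated missing fraction (default 0.05).
#' @return `list(geno, report)`; the report has one row per input marker.
#' @export
filter_missingness <- function(geno, max_missing = 0.05) {
  frac <- colMeans(is.na(geno$codes))
  kept <- frac <= max_missing
  rep <- filter_report(marker_ids(geno), kept, "missingness", missing_frac = frac)
  list(geno = drop_markers(geno, marker_ids(geno)[!kept]), report = rep)
}

#' Test markers for segregation distortion
#'
#' Chi-square goodness-of-fit test of each marker's genotype-class counts
#' (missing codes excluded) against the Mendelian expectation of the
#' crossing scheme ([mendelian_expectation()]); markers with `p < alpha` are
#' removed. Degrees of freedom are the number of classes with non-zero
#' expectation minus one; observations in zero-expectation classes give
#' `p = 0`.
#'
#' @param geno A [beet_geno()].
#' @param scheme The [cross_scheme()] that produced the population.
#' @param alpha Removal threshold on the p-value (default 0.05).
#' @return `list(geno, report)` with per-marker `chisq` and `p_value`.
#' @export
test_segregation <- function(geno, scheme, alpha = 0.05) {
  p_exp <- mendelian_expectation(scheme)
  live <- p_exp > 0
  if (sum(live) < 2L) rlang::abort("Scheme leaves fewer than two genotype classes.")
  codes <- geno$codes
  stats_p <- vapply(seq_len(ncol(codes)), function(k) {
    x <- codes[, k]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, 0))
    obs <- c(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    if (any(obs[!live] > 0)) return(c(Inf, 0))
    o <- obs[live]
    e <- length(x) * p_exp[live] / sum(p_exp[live])
    stat <- sum((o - e)^2 / e)
    c(stat, pchisq(stat, df = sum(live) - 1L, lower.tail = FALSE))
  }, numeric(2))
  pv <- stats_p[2, ]
  kept <- pv >= alpha
  rep <- filter_report(marker_ids(geno), kept, "distortion",
                       chisq = stats_p[1, ], p_value = pv)
  list(geno = drop_markers(geno, marker_ids(geno)[!kept]), report = rep)
}

# Gaussian-likelihood two-point LOD used for neighbour qualification in swap
# detection: LOD = -n/2 * log10(1 - cor^2), phase-agnostic by construction.
cor_lod <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(c(cor = NA, lod = 0))
  r <- cor(x[ok], y[ok])
  c(cor = r, lod = -n / 2 * log10(max(1 - r^2, 1e-12)))
}

#' Detect markers with swapped allele coding
#'
#' A marker whose elite/exotic alleles were inverted behaves as `2 - g`
#' relative to its neighbourhood. For each marker, map neighbours within
#' `window_cm` whose phase-agnostic two-point LOD reaches `lod_min` are
#' collected; the marker is flagged when the majority of those neighbours
#' are negatively correlated with it. Markers with no qualifying neighbour
#' are left unflagged with a warning.
#'
#' @param geno A [beet_geno()].
#' @param map Map tibble covering the markers.
#' @param lod_min Minimum linkage LOD for a neighbour to qualify (default 3).
#' @param window_cm Neighbourhood half-width in cM (default 20).
#' @return A report tibble with `marker`, `kept` (`FALSE` = flagged as
#'   swapped), `reason`, `n_neighbors`, `n_negative`.
#' @export
detect_swapped_alleles <- function(geno, map, lod_min = 3, window_cm = 20) {
  map <- validate_map(map)
  mk <- marker_ids(geno)
  miss <- setdiff(mk, map$marker)
  if (length(miss) > 0) {
    rlang::abort(paste0("Marker(s) absent from map: ", paste(miss, collapse = ", ")))
  }
  map <- map[match(mk, map$marker), ]
  codes <- geno$codes
  n_mk <- length(mk)
  n_nb <- integer(n_mk)
  n_neg <- integer(n_mk)
  for (k in seq_len(n_mk)) {
    nb <- which(map$chrom == map$chrom[k] &
                  abs(map$pos_cm - map$pos_cm[k]) <= window_cm &
                  seq_len(n_mk) != k)
    negs <- 0L
    quals <- 0L
    for (j in nb) {
      cl <- cor_lod(codes[, k], codes[, j])
      if (!is.na(cl[["cor"]]) && cl[["lod"]] >= lod_min) {
        quals <- quals + 1L
        if (cl[["cor"]] < 0) negs <- negs + 1L
      }
    }
    n_nb[k] <- quals
    n_neg[k] <- negs
  }
  if (any(n_nb == 0L)) {
    rlang::warn(sprintf("%d marker(s) had no linked neighbour and were left unflagged.",
                        sum(n_nb == 0L)))
  }
  flagged <- n_nb > 0L & n_neg > n_nb / 2
  filter_report(mk, !flagged, "swapped", n_neighbors = n_nb, n_negative = n_neg)
}

#' Impute missing codes from flanking markers
#'
#' Replaces each missing code with the code of the most informative flanking
#' marker on the same chromosome: when both flanks carry the same code that
#' code is used; otherwise the flank with the higher no-recombination
#' probability `(1 - r)^2` under the Haldane map function wins (the nearer
#' flank; ties go left). Terminal gaps copy the nearest informative marker.
#'
#' @param geno A [beet_geno()].
#' @param map Map tibble covering all markers.
#' @return A [beet_geno()] with no missing codes.
#' @export
impute_flanking <- function(geno, map) {
  map <- validate_map(map)
  mk <- marker_ids(geno)
  miss <- setdiff(mk, map$marker)
  if (length(miss) > 0) {
    rlang::abort(paste0("Map does not cover marker(s): ", paste(miss, collapse = ", ")))
  }
  codes <- geno$codes
  map <- map[match(mk, map$marker), ]
  by_chr <- split(seq_along(mk), map$chrom)
  for (idx in by_chr) {
    idx <- idx[order(map$pos_cm[idx])]
    pos <- map$pos_cm[idx]
    sub <- codes[, idx, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      x <- sub[i, ]
      nas <- which(is.na(x))
      if (length(nas) == 0L) next
      inf <- which(!is.na(x))
      if (length(inf) == 0L) {
        rlang::abort(sprintf(
          "Individual %s has no informative marker on chromosome %s.",
          rownames(codes)[i], map$chrom[idx[1]]))
      }
      for (j in nas) {
        left <- inf[inf < j]
        right <- inf[inf > j]
        if (length(left) == 0L) {
          x[j] <- x[right[1]]
        } else if (length(right) == 0L) {
          x[j] <- x[left[length(left)]]
        } else {
          l <- left[length(left)]
          r <- right[1]
          if (x[l] == x[r]) {
            x[j] <- x[l]
          } else {
            pl <- (1 - haldane_cm_to_r(pos[j] - pos[l]))^2
            pr <- (1 - haldane_cm_to_r(pos[r] - pos[j]))^2
            x[j] <- if (pl >= pr) x[l] else x[r]
          }
        }
      }
      sub[i, ] <- x
    }
    codes[, idx] <- sub
  }
  set_codes(geno, codes)
}

#' Drop redundant markers
#'
#' Among sets of identical marker columns (run on complete genotypes), the
#' first in column (map) order is kept and the rest removed; the report
#' records each dropped marker's representative.
#'
#' @param geno A [beet_geno()] with no missing codes.
#' @return `list(geno, report)` with a `representative` column.
#' @export
drop_redundant <- function(geno) {
  codes <- geno$codes
  if (anyNA(codes)) rlang::abort("Run drop_redundant() on complete genotypes.")
  key <- apply(codes, 2, paste, collapse = ",")
  first <- !duplicated(key)
  rep_of <- marker_ids(geno)[first][match(key, key[first])]
  kept <- first
  rep <- filter_report(marker_ids(geno), kept, "redundant",
                       representative = ifelse(kept, NA_character_, rep_of))
  list(geno = drop_markers(geno, marker_ids(geno)[!kept]), report = rep)
}

#' Filter markers by minor allele frequency
#'
#' Allele frequency is `(n1 + 2 * n2) / (2 * n_nonmissing)`; markers with
#' `min(p, 1 - p) < min_maf` are removed.
#'
#' @param geno A [beet_geno()].
#' @param min_maf Minimum minor allele frequency (e.g. 0.03 for a progeny,
#'   0.05 for a panel).
#' @return `list(geno, report)` with a `maf` column.
#' @export
filter_maf <- function(geno, min_maf) {
  codes <- geno$codes
  p <- vapply(seq_len(ncol(codes)), function(k) {
    x <- codes[, k]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(0)
    (sum(x == 1L) + 2 * sum(x == 2L)) / (2 * length(x))
  }, numeric(1))
  maf <- pmin(p, 1 - p)
  kept <- maf >= min_maf
  rep <- filter_report(marker_ids(geno), kept, "maf", maf = maf)
  list(geno = drop_markers(geno, marker_ids(geno)[!kept]), report = rep)
}

#' Keep only markers showing all three genotype classes
#'
#' @param geno A [beet_geno()].
#' @return `list(geno, report)` with an `n_classes` column.
#' @export
filter_three_classes <- function(geno) {
  codes <- geno$codes
  ncl <- vapply(seq_len(ncol(codes)), function(k) {
    length(unique(codes[!is.na(codes[, k]), k]))
  }, integer(1))
  has_all <- vapply(seq_len(ncol(codes)), function(k) {
    all(c(0L, 1L, 2L) %in% codes[, k])
  }, logical(1))
  rep <- filter_report(marker_ids(geno), has_all, "classes", n_classes = ncl)
  list(geno = drop_markers(geno, marker_ids(geno)[!has_all]), report = rep)
}

#' Run the full marker quality-control chain
#'
#' Applies, in order: missingness filter, segregation-distortion test, swap
#' detection, flanking imputation, redundancy removal, MAF filter and the
#' three-class filter. Stages can be skipped by name.
#'
#' @param geno A [beet_geno()].
#' @param map Map tibble (needed for swap detection and imputation).
#' @param scheme [cross_scheme()] for the segregation test (progeny only;
#'   `NULL` skips the stage).
#' @param max_missing,seg_alpha,min_maf,lod_min Stage parameters.
#' @param skip Character vector of stage names to skip, among
#'   `c("missingness", "distortion", "swap", "impute", "redundancy", "maf",
#'   "classes")`.
#' @return `list(geno, report)`; the report stacks per-stage reports with a
#'   `stage` column.
#' @export
filter_chain <- function(geno, map, scheme = NULL, max_missing = 0.05,
                         seg_alpha = 0.05, min_maf = 0.03, lod_min = 3,
                         skip = character(0)) {
  reports <- list()
  add <- function(stage, rep) {
    reports[[length(reports) + 1L]] <<- dplyr::mutate(rep, stage = stage, .before = 1)
  }
  if (!"missingness" %in% skip) {
    st <- filter_missingness(geno, max_missing); geno <- st$geno; add("missingness", st$report)
  }
  if (!"distortion" %in% skip && !is.null(scheme)) {
    st <- test_segregation(geno, scheme, seg_alpha); geno <- st$geno; add("distortion", st$report)
  }
  if (!"swap" %in% skip) {
    rep <- detect_swapped_alleles(geno, map, lod_min = lod_min)
    geno <- drop_markers(geno, rep$marker[!rep$kept])
    add("swap", rep)
  }
  if (!"impute" %in% skip) geno <- impute_flanking(geno, map)
  if (!"redundancy" %in% skip) {
    st <- drop_redundant(geno); geno <- st$geno; add("redundancy", st$report)
  }
  if (!"maf" %in% skip) {
    st <- filter_maf(geno, min_maf); geno <- st$geno; add("maf", st$report)
  }
  if (!"classes" %in% skip) {
    st <- filter_three_classes(geno); geno <- st$geno; add("classes", st$report)
  }
  list(geno = geno, report = dplyr::bind_rows(reports))
}
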