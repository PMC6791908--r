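# Merging detected SNPs into QTLs and cross-population comparison.

#' LD provider for QTL merging
#'
#' Returns a function `f(marker1, marker2)` computing the corrected squared
#' correlation between two markers of `geno`, with the whitening or cluster
#' residualisation precomputed once.
#'
#' @inheritParams ld_threshold
#' @return A function of two marker ids returning r-squared.
#' @export
ld_provider <- function(geno, correction = c("none", "kinship", "structure"),
                        kinship = NULL, cluster = NULL) {
  correction <- match.arg(correction)
  codes <- geno$codes
  if (anyNA(codes)) rlang::abort("Complete codes required.")
  cluster <- cluster %||% geno$cluster
  Xt <- scale(codes, center = TRUE, scale = FALSE)
  if (correction == "kinship") {
    K <- kinship %||% kinship(center_genotypes(geno))
    Xt <- ld_whitener(K) %*% Xt
  } else if (correction == "structure") {
    if (is.null(cluster)) rlang::abort("`cluster` required for structure correction.")
    f <- factor(cluster)
    Xt <- apply(codes, 2, function(x) x - stats::ave(x, f))
    colnames(Xt) <- colnames(codes)
  }
  function(m1, m2) {
    x <- Xt[, m1]
    y <- Xt[, m2]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }
}

#' Merge detected SNPs into QTLs
#'
#' Per chromosome, detected SNPs are sorted by map position and chained into
#' a QTL while the gap to the previous member is at most `max_gap_cm` AND
#' the corrected r-squared exceeds the LD threshold (between consecutive
#' members by default, or between all members with
#' `mode = "all_pairs"`). SNPs that cannot be merged, and unmapped SNPs,
#' form singleton QTLs.
#'
#' @param effects Tibble of detected SNPs with a `marker` column (typically
#'   from [estimate_effects()]); extra columns are carried into the members.
#' @param map Map tibble; markers absent from it are treated as unmapped.
#' @param ld A function of two marker ids returning r-squared (see
#'   [ld_provider()]), or `NULL` to skip the LD condition.
#' @param threshold A `beet_ld_threshold` or a number.
#' @param max_gap_cm Maximum gap between consecutive members (default 5).
#' @param mode `"consecutive"` (default) or `"all_pairs"`.
#' @return A `beet_qtls` tibble: `qtl_id`, `chrom`, `start_cm`, `end_cm`,
#'   `n_members`, `members` (list column of member tibbles).
#' @export
merge_into_qtls <- function(effects, map, ld = NULL, threshold = 0,
                            max_gap_cm = 5, mode = c("consecutive", "all_pairs")) {
  mode <- match.arg(mode)
  thr <- if (inherits(threshold, "beet_ld_threshold")) threshold$value else threshold
  effects <- tibble::as_tibble(effects)
  if (nrow(effects) == 0) {
    out <- tibble::tibble(qtl_id = character(0), chrom = character(0),
                          start_cm = numeric(0), end_cm = numeric(0),
                          n_members = integer(0), members = list())
    class(out) <- c("beet_qtls", class(out))
    return(out)
  }
  effects$chrom <- map$chrom[match(effects$marker, map$marker)]
  effects$pos_cm <- map$pos_cm[match(effects$marker, map$marker)]
  effects <- dplyr::arrange(effects, is.na(.data$chrom), .data$chrom,
                            .data$pos_cm, .data$marker)
  linked <- function(a, b) {
    if (is.null(ld)) TRUE else {
      r2 <- ld(a, b)
      !is.na(r2) && r2 > thr
    }
  }
  groups <- list()
  for (part in split(effects, ifelse(is.na(effects$chrom), "(unmapped)", effects$chrom))) {
    if (all(is.na(part$chrom))) {
      for (i in seq_len(nrow(part))) groups[[length(groups) + 1L]] <- part[i, ]
      next
    }
    cur <- part[1, ]
    for (i in seq_len(nrow(part))[-1]) {
      gap <- part$pos_cm[i] - cur$pos_cm[nrow(cur)]
      others <- if (mode == "consecutive") cur$marker[nrow(cur)] else cur$marker
      ok <- gap <= max_gap_cm &&
        all(vapply(others, function(o) linked(o, part$marker[i]), logical(1)))
      if (ok) {
        cur <- dplyr::bind_rows(cur, part[i, ])
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- part[i, ]
      }
    }
    groups[[length(groups) + 1L]] <- cur
  }
  out <- purrr::imap_dfr(groups, function(g, i) {
    tibble::tibble(
      qtl_id = sprintf("QTL_%03d", i),
      chrom = if (all(is.na(g$chrom))) NA_character_ else g$chrom[1],
      start_cm = if (all(is.na(g$pos_cm))) NA_real_ else min(g$pos_cm),
      end_cm = if (all(is.na(g$pos_cm))) NA_real_ else max(g$pos_cm),
      n_members = nrow(g),
      members = list(g))
  })
  class(out) <- c("beet_qtls", class(out))
  out
}

#' Split long QTLs into fixed-width intervals
#'
#' Optional post-pass cutting any QTL whose interval exceeds `interval_cm`
#' into consecutive `interval_cm`-wide bins from its start; members falling
#' in the same bin stay together.
#'
#' @param qtls A `beet_qtls` tibble.
#' @param interval_cm Bin width in cM (default 5).
#' @return A re-numbered `beet_qtls` tibble.
#' @export
split_qtls <- function(qtls, interval_cm = 5) {
  pieces <- list()
  for (i in seq_len(nrow(qtls))) {
    g <- qtls$members[[i]]
    if (is.na(qtls$chrom[i]) || qtls$end_cm[i] - qtls$start_cm[i] <= interval_cm) {
      pieces[[length(pieces) + 1L]] <- g
    } else {
      bin <- floor((g$pos_cm - min(g$pos_cm)) / interval_cm)
      for (b in split(g, bin)) pieces[[length(pieces) + 1L]] <- b
    }
  }
  out <- purrr::imap_dfr(pieces, function(g, i) {
    tibble::tibble(
      qtl_id = sprintf("QTL_%03d", i),
      chrom = if (all(is.na(g$chrom))) NA_character_ else g$chrom[1],
      start_cm = if (all(is.na(g$pos_cm))) NA_real_ else min(g$pos_cm),
      end_cm = if (all(is.na(g$pos_cm))) NA_real_ else max(g$pos_cm),
      n_members = nrow(g),
      members = list(g))
  })
  class(out) <- c("beet_qtls", class(out))
  out
}

#' Label QTLs by the direction of the exotic-allele effect
#'
#' A QTL is favorable when the exotic allele shifts the trait in the
#' favorable direction for all of its members (`favorable_exotic` flags on
#' the member records, as produced by [estimate_effects()]); QTLs whose
#' members disagree are labelled `"mixed"`.
#'
#' @param qtls A `beet_qtls` tibble whose members carry `favorable_exotic`.
#' @return The tibble with a `favorable` column (`"yes"`, `"no"`,
#'   `"mixed"`).
#' @export
label_favorable <- function(qtls) {
  fav <- vapply(qtls$members, function(g) {
    if (!"favorable_exotic" %in% names(g)) {
      rlang::abort("Members lack `favorable_exotic`; run estimate_effects() first.")
    }
    f <- g$favorable_exotic
    if (all(f)) "yes" else if (all(!f)) "no" else "mixed"
  }, character(1))
  dplyr::mutate(qtls, favorable = fav)
}

#' Colocate two QTL sets on a shared map
#'
#' Annotates each QTL of set A as colocated when some QTL of set B lies on
#' the same chromosome with interval distance at most `window_cm` (0 when
#' the intervals overlap, else the nearest-endpoint gap), and as novel
#' otherwise. When both sets carry a `trait` column, only same-trait pairs
#' are compared.
#'
#' @param qtls_a,qtls_b `beet_qtls` tibbles (B is the reference set).
#' @param window_cm Colocation window in cM (default 5).
#' @return `qtls_a` with columns `status` (`"colocated"`/`"novel"`),
#'   `nearest_b` and `distance_cm`; a count summary (by `favorable` if
#'   present) is attached as attribute `"summary"`.
#' @export
colocate <- function(qtls_a, qtls_b, window_cm = 5) {
  by_trait <- "trait" %in% names(qtls_a) && "trait" %in% names(qtls_b)
  interval_dist <- function(s1, e1, s2, e2) {
    if (e1 < s2) s2 - e1 else if (e2 < s1) s1 - e2 else 0
  }
  res <- purrr::map_dfr(seq_len(nrow(qtls_a)), function(i) {
    a <- qtls_a[i, ]
    cand <- qtls_b
    if (by_trait) cand <- cand[cand$trait == a$trait, , drop = FALSE]
    cand <- cand[!is.na(cand$chrom) & !is.na(a$chrom) & cand$chrom == a$chrom, ,
                 drop = FALSE]
    if (nrow(cand) == 0) {
      return(tibble::tibble(status = "novel", nearest_b = NA_character_,
                            distance_cm = NA_real_))
    }
    d <- vapply(seq_len(nrow(cand)), function(j) {
      interval_dist(a$start_cm, a$end_cm, cand$start_cm[j], cand$end_cm[j])
    }, numeric(1))
    jmin <- which.min(d)
    tibble::tibble(
      status = if (d[jmin] <= window_cm) "colocated" else "novel",
      nearest_b = cand$qtl_id[jmin], distance_cm = d[jmin])
  })
  out <- dplyr::bind_cols(qtls_a, res)
  summ <- if ("favorable" %in% names(out)) {
    dplyr::count(tibble::as_tibble(out), .data$status, .data$favorable)
  } else {
    dplyr::count(tibble::as_tibble(out), .data$status)
  }
  attr(out, "summary") <- summ
  out
}
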