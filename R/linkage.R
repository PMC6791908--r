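#' Two-point recombination estimates for all marker pairs
#'
#' For two-class backcross data (codes 0/1) the recombination fraction is
#' estimated by recombinant counting; for three-class (selfed) data by EM
#' over the standard F2/S1 coupling likelihood (initialised at r = 0.25, run
#' to `|dr| < 1e-8` or 200 iterations). The LOD score is
#' `log10 L(r_hat) - log10 L(0.5)`; estimates are truncated to `[0, 0.5]`.
#' Pairs involving a monomorphic marker are undefined (`NA`).
#'
#' @param geno A [beet_geno()] with complete codes.
#' @param scheme The [cross_scheme()] of the population; a scheme with any
#'   selfing step (or `NULL`) selects the three-class EM estimator.
#' @return A `beet_twopoint` object: list with symmetric matrices `r` and
#'   `lod` (markers x markers) and `n` individuals.
#' @export
estimate_twopoint <- function(geno, scheme = NULL) {
  codes <- geno$codes
  if (anyNA(codes)) rlang::abort("Two-point estimation needs complete genotypes.")
  n <- nrow(codes)
  mk <- colnames(codes)
  mono <- apply(codes, 2, function(x) length(unique(x)) == 1L)
  two_class <- !is.null(scheme) && !("self" %in% scheme$steps)

  if (two_class) {
    A0 <- (codes == 0L) * 1
    A1 <- (codes == 1L) * 1
    k_rec <- crossprod(A0, A1) + crossprod(A1, A0)
    r_raw <- k_rec / n
    r_hat <- pmin(r_raw, 0.5)
    l1 <- k_rec * log10(pmax(r_hat, 1e-300)) +
      (n - k_rec) * log10(pmax(1 - r_hat, 1e-300))
    lod <- l1 + n * log10(2)
  } else {
    Aj <- lapply(0:2, function(j) (codes == j) * 1)
    N <- vector("list", 9L)
    dim(N) <- c(3L, 3L)
    for (a in 1:3) for (b in 1:3) N[[a, b]] <- crossprod(Aj[[a]], Aj[[b]])
    # expected recombinant gametes per individual, by observed class
    rec1 <- N[[1, 2]] + N[[2, 1]] + N[[2, 3]] + N[[3, 2]]   # one recombinant gamete
    rec2 <- N[[1, 3]] + N[[3, 1]]                           # two
    dhet <- N[[2, 2]]                                       # double heterozygote
    r <- matrix(0.25, length(mk), length(mk))
    for (it in 1:200) {
      e_dh <- 2 * r^2 / ((1 - r)^2 + r^2)
      r_new <- (rec1 + 2 * rec2 + e_dh * dhet) / (2 * n)
      if (max(abs(r_new - r)) < 1e-8) { r <- r_new; break }
      r <- r_new
    }
    loglik10 <- function(rr) {
      rr <- pmin(pmax(rr, 1e-12), 1 - 1e-12)
      (N[[1, 1]] + N[[3, 3]]) * log10((1 - rr)^2 / 4) +
        rec2 * log10(rr^2 / 4) +
        rec1 * log10(rr * (1 - rr) / 2) +
        dhet * log10(((1 - rr)^2 + rr^2) / 2)
    }
    r_hat <- pmin(pmax(r, 0), 0.5)
    lod <- loglik10(r_hat) - loglik10(matrix(0.5, nrow(r), ncol(r)))
  }
  dimnames(r_hat) <- dimnames(lod) <- list(mk, mk)
  r_hat[mono, ] <- r_hat[, mono] <- NA_real_
  lod[mono, ] <- lod[, mono] <- NA_real_
  diag(r_hat) <- 0
  diag(lod) <- NA_real_
  lod <- pmax(lod, 0)
  structure(list(r = r_hat, lod = lod, n = n,
                 monomorphic = mk[mono]),
            class = "beet_twopoint")
}

#' @export
print.beet_twopoint <- function(x, ...) {
  cat(sprintf("<beet_twopoint> %d markers, n = %d individuals\n",
              ncol(x$r), x$n))
  invisible(x)
}

#' @export
tidy.beet_twopoint <- function(x, ...) {
  mk <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(marker1 = mk[idx[, 1]], marker2 = mk[idx[, 2]],
                 r_hat = x$r[idx], lod = x$lod[idx])
}

#' Transitive linkage grouping
#'
#' Groups markers by the connected components of the graph whose edges join
#' pairs with `r_hat < r_max` and `lod > lod_min`; components smaller than
#' `min_group` are moved to the unplaced set. The result is invariant to
#' marker input order.
#'
#' @param tp A `beet_twopoint` object.
#' @param r_max Maximum recombination fraction for an edge (default 0.35).
#' @param lod_min Minimum LOD for an edge (default 6).
#' @param min_group Minimum retained group size (default 5).
#' @return A `beet_groups` object: list with `groups` (list of sorted marker
#'   vectors, largest first) and `unplaced`.
#' @export
group_markers <- function(tp, r_max = 0.35, lod_min = 6, min_group = 5L) {
  adj <- !is.na(tp$r) & !is.na(tp$lod) & tp$r < r_max & tp$lod > lod_min
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  mk <- colnames(tp$r)
  parts <- split(mk, comp$membership)
  parts <- lapply(parts, sort)
  big <- vapply(parts, length, integer(1)) >= min_group
  groups <- parts[big]
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(x) x[1], character(1)))
  structure(list(groups = unname(groups[ord]),
                 unplaced = sort(unlist(parts[!big], use.names = FALSE))),
            class = "beet_groups")
}

#' @export
print.beet_groups <- function(x, ...) {
  cat(sprintf("<beet_groups> %d group(s): %s; %d unplaced\n",
              length(x$groups),
              paste(vapply(x$groups, length, integer(1)), collapse = ", "),
              length(x$unplaced)))
  invisible(x)
}

#' Assign linkage groups to chromosomes by majority vote
#'
#' Given a truth map, each group is attributed to the chromosome carrying
#' the majority of its markers.
#'
#' @param groups A `beet_groups` object.
#' @param map Truth map tibble.
#' @return Tibble `group`, `chrom`, `n_markers`, `agreement` (majority
#'   fraction).
#' @export
assign_groups <- function(groups, map) {
  purrr::imap_dfr(groups$groups, function(g, i) {
    ch <- map$chrom[match(g, map$marker)]
    tab <- sort(table(ch), decreasing = TRUE)
    tibble::tibble(group = i, chrom = names(tab)[1], n_markers = length(g),
                   agreement = as.numeric(tab[1]) / length(g))
  })
}

#' Consensus inter-marker distances across populations
#'
#' All maps must share one global marker order per chromosome (each map's
#' order being a sub-order of it). For each consecutive pair of markers in
#' the global order, the consensus interval is the arithmetic mean of that
#' interval over the maps containing both endpoints; a marker present in
#' only one map therefore splits its neighbourhood using that map's
#' distances only. Intervals defined in no map (endpoints never co-occur)
#' are filled by linear interpolation on the global marker index. Cumulative
#' positions start at 0 per chromosome.
#'
#' @param maps List of map tibbles (`marker`, `chrom`, `pos_cm`).
#' @return A consensus map tibble.
#' @export
consensus_distances <- function(maps) {
  if (length(maps) < 1L) rlang::abort("Need at least one map.")
  maps <- lapply(maps, validate_map)
  chroms <- sort(unique(unlist(lapply(maps, function(m) unique(m$chrom)))))
  out <- purrr::map_dfr(chroms, function(ch) {
    sub <- lapply(maps, function(m) m[m$chrom == ch, , drop = FALSE])
    sub <- sub[vapply(sub, nrow, integer(1)) > 0]
    # pairwise order-consistency check
    for (a in seq_along(sub)) {
      for (b in seq_along(sub)) {
        if (b <= a) next
        shared <- intersect(sub[[a]]$marker, sub[[b]]$marker)
        if (length(shared) < 2) next
        ra <- match(shared, sub[[a]]$marker)
        rb <- match(shared, sub[[b]]$marker)
        o <- order(ra)
        if (is.unsorted(rb[o])) {
          i <- which(diff(rb[o]) < 0)[1]
          rlang::abort(sprintf(
            "Conflicting marker order on %s: %s vs %s disagree between maps %d and %d.",
            ch, shared[o][i], shared[o][i + 1L], a, b))
        }
      }
    }
    # global order by topological merge of consecutive-pair edges
    verts <- unique(unlist(lapply(sub, function(m) m$marker)))
    edges <- do.call(rbind, lapply(sub, function(m) {
      if (nrow(m) < 2) return(NULL)
      cbind(m$marker[-nrow(m)], m$marker[-1])
    }))
    global <- if (is.null(edges)) {
      verts
    } else {
      g <- igraph::graph_from_edgelist(unique(edges), directed = TRUE)
      g <- g + igraph::vertices(setdiff(verts, igraph::V(g)$name))
      if (!igraph::is_dag(g)) {
        rlang::abort(sprintf("Conflicting marker orders on %s (cyclic adjacency).", ch))
      }
      igraph::V(g)$name[as.integer(igraph::topo_sort(g))]
    }
    if (length(global) == 1L) {
      return(tibble::tibble(marker = global, chrom = ch, pos_cm = 0))
    }
    k <- length(global)
    ivals <- vapply(seq_len(k - 1L), function(i) {
      a <- global[i]; b <- global[i + 1L]
      ds <- vapply(sub, function(m) {
        ia <- match(a, m$marker); ib <- match(b, m$marker)
        if (is.na(ia) || is.na(ib)) NA_real_ else m$pos_cm[ib] - m$pos_cm[ia]
      }, numeric(1))
      mean(ds, na.rm = TRUE)
    }, numeric(1))
    if (anyNA(ivals) || any(is.nan(ivals))) {
      # endpoints never co-occur: spread the enclosing defined span uniformly
      pos <- cumsum(c(0, ifelse(is.finite(ivals), ivals, NA)))
      known <- which(!is.na(pos))
      pos <- stats::approx(known, pos[known], xout = seq_len(k), rule = 2)$y
    } else {
      pos <- cumsum(c(0, ivals))
    }
    tibble::tibble(marker = global, chrom = ch, pos_cm = pos - pos[1])
  })
  validate_map(out)
  out
}
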