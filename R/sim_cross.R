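#' Define a crossing scheme
#'
#' A crossing scheme starts with an F1 between two fully homozygous founders
#' (elite x exotic) and is followed by any sequence of backcrosses to the
#' elite recurrent parent (`"BC"`) and selfing generations (`"self"`). Each
#' simulated individual descends through its own independent lineage, so
#' genotype frequencies follow the single-lineage Mendelian expectations
#' returned by [mendelian_expectation()].
#'
#' @param steps Character vector of steps; the first must be `"F1"`, the
#'   remainder `"BC"` or `"self"`.
#' @param n_individuals Number of individuals to produce (>= 1).
#' @param n_parents Optional integer vector of intermediate generation
#'   sizes, one per step after F1 except the last (whose size is
#'   `n_individuals`). `NULL` (default) gives each final individual its own
#'   independent lineage; e.g. `n_parents = 6` for a BC1S1 scheme derives
#'   the whole progeny from 6 BC1 plants (balanced families), the kind of
#'   pedigree bottleneck a real backcross progeny carries.
#' @return A `beet_scheme` object.
#' @export
#' @examples
#' cross_scheme(c("F1", "BC", "self"), 187)                 # independent lineages
#' cross_scheme(c("F1", "BC", "self"), 187, n_parents = 6)  # 6 BC1 plants
cross_scheme <- function(steps, n_individuals, n_parents = NULL) {
  steps <- as.character(steps)
  if (length(steps) < 1L || steps[1] != "F1") {
    rlang::abort("The first step of a crossing scheme must be \"F1\".")
  }
  if (length(steps) > 1L && !all(steps[-1] %in% c("BC", "self"))) {
    rlang::abort("Steps after F1 must be \"BC\" or \"self\".")
  }
  if (any(steps[-1] == "F1")) rlang::abort("\"F1\" may only appear first.")
  if (n_individuals < 1) rlang::abort("`n_individuals` must be >= 1.")
  if (!is.null(n_parents)) {
    n_parents <- as.integer(n_parents)
    if (length(n_parents) != length(steps) - 2L || any(n_parents < 1L)) {
      rlang::abort("`n_parents` needs one positive size per intermediate step.")
    }
  }
  structure(list(steps = steps, n_individuals = as.integer(n_individuals),
                 n_parents = n_parents),
            class = "beet_scheme")
}

#' @export
print.beet_scheme <- function(x, ...) {
  cat(sprintf("<beet_scheme> %s, n = %d\n",
              paste(x$steps, collapse = " -> "), x$n_individuals))
  invisible(x)
}

#' Single-locus Mendelian genotype expectations for a scheme
#'
#' Propagates the genotype-class distribution (codes 0/1/2, exotic-allele
#' dosage) through the scheme under independent lineages: a backcross draws
#' one gamete from the current individual and one elite (code-0) gamete; a
#' selfing draws two independent gametes from the current individual.
#'
#' @param scheme A [cross_scheme()].
#' @return Named numeric vector `c("0", "1", "2")` of genotype probabilities.
#' @export
#' @examples
#' mendelian_expectation(cross_scheme(c("F1", "BC"), 1))          # 1:1 on {0,1}
#' mendelian_expectation(cross_scheme(c("F1", "self"), 1))        # 1:2:1
#' mendelian_expectation(cross_scheme(c("F1", "BC", "self"), 1))  # 5:2:1
mendelian_expectation <- function(scheme) {
  stopifnot(inherits(scheme, "beet_scheme"))
  p <- c(`0` = 0, `1` = 1, `2` = 0)
  for (s in scheme$steps[-1]) {
    p <- if (s == "BC") {
      c(`0` = unname(p["0"] + p["1"] / 2),
        `1` = unname(p["1"] / 2 + p["2"]),
        `2` = 0)
    } else {
      c(`0` = unname(p["0"] + p["1"] / 4),
        `1` = unname(p["1"] / 2),
        `2` = unname(p["2"] + p["1"] / 4))
    }
  }
  p
}

# Draw one gamete (0/1 exotic-allele haplotype) from an individual given its
# two haplotypes on one chromosome. Crossovers: Poisson(length/100), uniform
# breakpoints, no interference (Haldane model).
gamete_one_chrom <- function(h1, h2, pos, length_cm) {
  n_co <- rpois(1L, length_cm / 100)
  phase <- rbinom(1L, 1L, 0.5)
  if (n_co == 0L) {
    if (phase == 0L) return(h1) else return(h2)
  }
  bp <- runif(n_co, 0, length_cm)
  # phase at each marker flips once per breakpoint to its left
  flips <- vapply(pos, function(p) sum(bp < p), integer(1))
  use2 <- (phase + flips) %% 2L == 1L
  ifelse(use2, h2, h1)
}

#' Simulate a biparental cross down a crossing scheme
#'
#' Meiosis follows the Haldane model: crossover counts are Poisson with mean
#' chromosome length / 100, breakpoints uniform, no interference. Founders
#' are fully homozygous; the elite founder carries allele 0 everywhere and
#' the exotic founder allele 1, so genotype codes are exotic-allele dosages
#' (0 = elite homozygote, 2 = exotic homozygote). Each individual descends
#' through its own independent lineage.
#'
#' @param map Map tibble (see [make_map()]).
#' @param scheme A [cross_scheme()].
#' @param seed Integer seed; output is a pure function of (map, scheme, seed).
#' @return A [beet_geno()] with `population = "progeny"`.
#' @export
#' @examples
#' map <- make_map(2, 10, 80, "uniform", seed = 1)
#' simulate_cross(map, cross_scheme(c("F1", "BC"), 20), seed = 2)
simulate_cross <- function(map, scheme, seed) {
  stopifnot(inherits(scheme, "beet_scheme"))
  map <- validate_map(map)
  if (nrow(map) == 0L) rlang::abort("Empty genetic map.")
  chroms <- split(map, map$chrom)
  n <- scheme$n_individuals
  post_f1 <- scheme$steps[-1]
  n_steps <- length(post_f1)
  sizes <- if (n_steps == 0L) integer(0) else {
    if (is.null(scheme$n_parents)) rep(n, n_steps)
    else c(scheme$n_parents, n)
  }
  with_seed(seed, {
    # population state: per chromosome, two haplotype matrices (pop x markers)
    pop <- lapply(chroms, function(cm) {
      m <- length(cm$pos_cm)
      list(h1 = matrix(0L, 1L, m), h2 = matrix(1L, 1L, m))  # the F1
    })
    n_prev <- 1L
    for (s in seq_len(n_steps)) {
      n_new <- sizes[s]
      parents <- if (n_prev == 1L) rep(1L, n_new)
        else if (is.null(scheme$n_parents)) rep_len(seq_len(n_prev), n_new)
        else rep_len(seq_len(n_prev), n_new)  # balanced families
      pop <- purrr::map2(pop, chroms, function(st, cm) {
        pos <- cm$pos_cm
        len <- max(pos)
        m <- length(pos)
        h1_new <- matrix(0L, n_new, m)
        h2_new <- matrix(0L, n_new, m)
        for (i in seq_len(n_new)) {
          pa <- parents[i]
          if (post_f1[s] == "BC") {
            h1_new[i, ] <- 0L
            h2_new[i, ] <- gamete_one_chrom(st$h1[pa, ], st$h2[pa, ], pos, len)
          } else {
            h1_new[i, ] <- gamete_one_chrom(st$h1[pa, ], st$h2[pa, ], pos, len)
            h2_new[i, ] <- gamete_one_chrom(st$h1[pa, ], st$h2[pa, ], pos, len)
          }
        }
        list(h1 = h1_new, h2 = h2_new)
      })
      n_prev <- n_new
    }
    if (n_prev != n) {
      # F1-only scheme: replicate the (deterministic) F1 genotype
      pop <- lapply(pop, function(st) {
        list(h1 = st$h1[rep(1L, n), , drop = FALSE],
             h2 = st$h2[rep(1L, n), , drop = FALSE])
      })
    }
    codes <- do.call(cbind, lapply(pop, function(st) st$h1 + st$h2))
    colnames(codes) <- unlist(lapply(chroms, function(cm) cm$marker), use.names = FALSE)
    rownames(codes) <- sprintf("ind%04d", seq_len(n))
    # restore the map's global marker order
    codes <- codes[, map$marker, drop = FALSE]
    beet_geno(codes, population = "progeny", scheme = scheme)
  })
}
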