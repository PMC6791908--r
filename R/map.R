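#' Build a synthetic genetic map
#'
#' Generates a genetic map of `n_chrom` chromosomes, each spanning
#' `[0, length_cm]` centimorgans (Haldane), with `markers_per_chrom` markers
#' either uniformly spaced or at sorted random positions (the two terminal
#' markers are pinned to the chromosome ends so every chromosome spans its
#' full length).
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param markers_per_chrom Markers per chromosome (>= 2).
#' @param length_cm Chromosome length in centimorgans (> 0).
#' @param spacing `"uniform"` or `"random"`.
#' @param seed Integer seed; the map is a pure function of the arguments.
#'
#' @return A tibble with columns `marker`, `chrom`, `pos_cm`, positions
#'   strictly increasing within each chromosome.
#' @export
#' @examples
#' make_map(2, 5, 100, "uniform", seed = 1)
make_map <- function(n_chrom, markers_per_chrom, length_cm,
                     spacing = c("uniform", "random"), seed = 1L) {
  spacing <- match.arg(spacing)
  if (n_chrom < 1) rlang::abort("`n_chrom` must be >= 1.")
  if (markers_per_chrom < 2) rlang::abort("`markers_per_chrom` must be >= 2.")
  if (length_cm <= 0) rlang::abort("`length_cm` must be positive.")
  m <- as.integer(markers_per_chrom)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_chrom), function(ch) {
      pos <- if (spacing == "uniform") {
        seq(0, length_cm, length.out = m)
      } else {
        inner <- sort(runif(m - 2L, 0, length_cm))
        # guard against coincident positions (zero-probability but cheap)
        while (anyDuplicated(inner) || any(inner <= 0) || any(inner >= length_cm)) {
          inner <- sort(runif(m - 2L, 0, length_cm))
        }
        c(0, inner, length_cm)
      }
      tibble::tibble(
        marker = sprintf("c%02d_m%04d", ch, seq_len(m)),
        chrom = sprintf("chr%d", ch),
        pos_cm = pos
      )
    })
  })
}

#' Validate a genetic-map table
#'
#' Checks the map invariants: columns `marker`, `chrom`, `pos_cm`; globally
#' unique marker ids; non-negative, strictly increasing positions within each
#' chromosome.
#'
#' @param map A map tibble.
#' @return The map, invisibly, ordered by (chrom, pos_cm).
#' @export
validate_map <- function(map) {
  need <- c("marker", "chrom", "pos_cm")
  if (!all(need %in% names(map))) {
    rlang::abort("Map must have columns marker, chrom, pos_cm.")
  }
  if (anyDuplicated(map$marker)) rlang::abort("Marker ids must be globally unique.")
  if (any(map$pos_cm < 0)) rlang::abort("Map positions must be non-negative.")
  map <- dplyr::arrange(map, .data$chrom, .data$pos_cm)
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos_cm) > 0) || dplyr::n() == 1L) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    rlang::abort(paste0("Non-increasing positions on chromosome(s): ",
                        paste(bad$chrom, collapse = ", ")))
  }
  invisible(map)
}

#' Haldane map-function conversions
#'
#' `haldane_r_to_cm()` converts a recombination fraction to a Haldane map
#' distance, `d = -50 * log(1 - 2r)` cM; `haldane_cm_to_r()` is its inverse,
#' `r = (1 - exp(-2d/100)) / 2`. The two are mutually inverse on their
#' domains; `r = 0.5` corresponds to infinite distance and is rejected.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @return Numeric vector of distances (cM) or recombination fractions.
#' @export
#' @examples
#' haldane_r_to_cm(0.25)         # 34.657...
#' haldane_cm_to_r(haldane_r_to_cm(0.1))
haldane_r_to_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    rlang::abort("Recombination fractions must lie in [0, 0.5); r = 0.5 maps to infinite distance.")
  }
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_r_to_cm
#' @export
haldane_cm_to_r <- function(d) {
  if (any(d < 0)) rlang::abort("Distances must be non-negative.")
  (1 - exp(-2 * d / 100)) / 2
}
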