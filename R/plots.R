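# ggplot2 displays for the main result types.

#' Heatmap of environment correlations
#'
#' @param object A `beet_env_cor` matrix from [env_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beet_env_cor <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("env1", "env2", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$env1, .data$env2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Manhattan plot of a GWAS forward step
#'
#' Plots `-log10(p)` of the Wald scan at a given step of the forward
#' selection against map position, with the cofactors already in the model
#' marked by stars.
#'
#' @param trace A `beet_gwas_trace` (must carry a map).
#' @param step Step index (0 = usual single-locus GWAS) or `"best"` for the
#'   eBIC-selected step.
#' @param criterion Criterion used when `step = "best"`.
#' @return A ggplot.
#' @export
plot_manhattan <- function(trace, step = 0L, criterion = "eBIC") {
  if (is.null(trace$map)) rlang::abort("Trace has no map; rerun forward_select() with one.")
  st <- if (identical(step, "best")) {
    select_best_model(trace, criterion = criterion)
  } else {
    trace$steps[[step + 1L]]
  }
  if (is.null(st$pvalues)) rlang::abort("Selected step has no scan (terminal step).")
  map <- trace$map
  df <- tibble::tibble(marker = names(st$pvalues), p = unname(st$pvalues)) |>
    dplyr::mutate(chrom = map$chrom[match(.data$marker, map$marker)],
                  pos_cm = map$pos_cm[match(.data$marker, map$marker)]) |>
    dplyr::filter(!is.na(.data$chrom), !is.na(.data$p))
  cof <- tibble::tibble(marker = st$cofactors) |>
    dplyr::mutate(chrom = map$chrom[match(.data$marker, map$marker)],
                  pos_cm = map$pos_cm[match(.data$marker, map$marker)])
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_cm, -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom), show.legend = FALSE,
                        size = 0.8) +
    ggplot2::geom_point(data = cof, ggplot2::aes(y = 0), shape = 8, size = 3,
                        colour = "black") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.beet_gwas_trace <- function(object, ...) plot_manhattan(object, step = 0L)

#' Chromosome alignment plot of QTL sets
#'
#' Draws QTL intervals per chromosome, one facet per chromosome, optionally
#' from two populations; favorable QTLs are marked with '+'.
#'
#' @param object A `beet_qtls` tibble (may carry `trait` and `favorable`).
#' @param population Label for the set (used when combining).
#' @param ... Further `beet_qtls` passed as named sets, e.g.
#'   `panel = qtls_panel`.
#' @return A ggplot.
#' @export
autoplot.beet_qtls <- function(object, population = "progeny", ...) {
  more <- list(...)
  df <- dplyr::mutate(flatten_qtls(object), population = population)
  for (nm in names(more)) {
    if (inherits(more[[nm]], "beet_qtls")) {
      df <- dplyr::bind_rows(df, dplyr::mutate(flatten_qtls(more[[nm]]),
                                               population = nm))
    }
  }
  df <- dplyr::filter(df, !is.na(.data$chrom))
  if (!"trait" %in% names(df)) df$trait <- "trait"
  if (!"favorable" %in% names(df)) df$favorable <- NA_character_
  df$ymid <- (df$start_cm + df$end_cm) / 2
  ggplot2::ggplot(df) +
    ggplot2::geom_linerange(
      ggplot2::aes(x = .data$trait, ymin = .data$start_cm - 0.5,
                   ymax = .data$end_cm + 0.5, colour = .data$population),
      linewidth = 3, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_text(data = dplyr::filter(df, .data$favorable %in% "yes"),
                       ggplot2::aes(x = .data$trait, y = .data$ymid,
                                    group = .data$population),
                       label = "+", fontface = "bold",
                       position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~chrom, nrow = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (cM)", colour = NULL) +
    ggplot2::theme_minimal()
}
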