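#' Adjust one field trial to genotype-level phenotypes
#'
#' Fits, by REML, a single-trial mixed model with fixed intercept, replicate
#' and check effects, a fixed polynomial surface in scaled (row, column)
#' coordinates of the given degree, and independent random row, column and
#' genotype effects plus residual. The adjusted phenotype of a genotype is
#' the fixed intercept plus its genotype BLUP. Checks enter as fixed levels
#' and share one dummy random genotype level, so they inform the spatial and
#' replicate terms without contributing to the genetic variance.
#'
#' The generalized heritability is the Cullis form
#' `h2 = 1 - mean(PEV) / sigma_g2` (mean prediction-error variance of the
#' genotype BLUPs over half the mean variance of a BLUP difference), clamped
#' to `[0, 1]`; `heritability = "entry_mean"` gives the classical
#' `sigma_g2 / (sigma_g2 + sigma_e2 / n_reps)` instead.
#'
#' @param trial Plot tibble with columns `env`, `genotype`, `row`, `col`,
#'   `rep`, `is_check` and one column per trait (see [simulate_trials()]).
#'   Must contain a single environment.
#' @param trait Name of the trait column to adjust.
#' @param surface_degree Degree of the fixed polynomial surface (0, 1 or 2;
#'   default 2).
#' @param heritability `"cullis"` (default) or `"entry_mean"`.
#' @return A `beet_adjusted` object: list with `env_id`, `trait`, `adjusted`
#'   (tibble `genotype`, `value`), `h2`, and `vc` (named vector `sigma_g2`,
#'   `sigma_row2`, `sigma_col2`, `sigma_e2`).
#' @export
adjust_environment <- function(trial, trait, surface_degree = 2L,
                               heritability = c("cullis", "entry_mean")) {
  heritability <- match.arg(heritability)
  if (!trait %in% names(trial)) {
    rlang::abort(sprintf("Unknown trait column `%s`.", trait))
  }
  env_ids <- unique(trial$env)
  if (length(env_ids) != 1L) {
    rlang::abort("`trial` must contain exactly one environment; split first.")
  }
  d <- tibble::as_tibble(trial)
  d$y <- d[[trait]]
  if (nrow(d) < 2L || length(unique(d$genotype[!d$is_check])) < 2L) {
    rlang::abort("Need at least two plots and two non-check genotypes.")
  }
  if (anyDuplicated(paste(d$row, d$col, sep = "/"))) {
    rlang::abort("(row, col) must be unique within an environment.")
  }
  d$row_f <- factor(d$row)
  d$col_f <- factor(d$col)
  d$rep_f <- factor(d$rep)
  d$check_f <- factor(ifelse(d$is_check, d$genotype, "entry"))
  d$check_f <- stats::relevel(d$check_f, ref = "entry")
  d$geno_r <- factor(ifelse(d$is_check, ".check.", d$genotype))
  d$u <- as.numeric(scale(d$row))
  d$v <- as.numeric(scale(d$col))
  if (all(!is.finite(d$u))) d$u <- 0
  if (all(!is.finite(d$v))) d$v <- 0

  fixed <- "y ~ 1"
  if (nlevels(d$rep_f) > 1L) fixed <- paste(fixed, "+ rep_f")
  if (nlevels(d$check_f) > 1L) fixed <- paste(fixed, "+ check_f")
  surf_terms <- switch(as.character(min(surface_degree, 2L)),
                       "0" = character(0),
                       "1" = c("u", "v"),
                       c("u", "v", "I(u*v)", "I(u^2)", "I(v^2)"))
  if (length(surf_terms) > 0 && stats::sd(d$u) > 0 && stats::sd(d$v) > 0) {
    fixed <- paste(fixed, "+", paste(surf_terms, collapse = " + "))
  }
  rand <- "(1 | geno_r)"
  if (nlevels(d$row_f) > 1L) rand <- paste(rand, "+ (1 | row_f)")
  if (nlevels(d$col_f) > 1L) rand <- paste(rand, "+ (1 | col_f)")
  fml <- stats::as.formula(paste(fixed, "+", rand))

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))
    )),
    error = function(e) rlang::abort(paste0("Mixed-model fit failed: ",
                                            conditionMessage(e)))
  )

  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    i <- which(vc_tab$grp == grp)
    if (length(i) == 0) 0 else vc_tab$vcov[i[1]]
  }
  vc <- c(sigma_g2 = get_vc("geno_r"), sigma_row2 = get_vc("row_f"),
          sigma_col2 = get_vc("col_f"), sigma_e2 = get_vc("Residual"))

  re <- lme4::ranef(fit, condVar = TRUE)$geno_r
  blup <- re[, 1]
  names(blup) <- rownames(re)
  pev <- as.vector(attr(re, "postVar"))
  names(pev) <- rownames(re)
  keep <- setdiff(names(blup), ".check.")
  intercept <- lme4::fixef(fit)[["(Intercept)"]]
  adjusted <- tibble::tibble(genotype = keep,
                             value = intercept + blup[keep])

  n_reps <- max(1L, nlevels(d$rep_f))
  h2 <- if (vc[["sigma_g2"]] <= 0) {
    0
  } else if (heritability == "cullis") {
    1 - mean(pev[keep]) / vc[["sigma_g2"]]
  } else {
    vc[["sigma_g2"]] / (vc[["sigma_g2"]] + vc[["sigma_e2"]] / n_reps)
  }
  h2 <- min(max(h2, 0), 1)

  structure(list(env_id = env_ids, trait = trait, adjusted = adjusted,
                 h2 = h2, vc = vc),
            class = "beet_adjusted")
}

#' @export
print.beet_adjusted <- function(x, ...) {
  cat(sprintf("<beet_adjusted> env %s, trait %s: %d genotypes, h2 = %.3f\n",
              x$env_id, x$trait, nrow(x$adjusted), x$h2))
  invisible(x)
}

#' @export
tidy.beet_adjusted <- function(x, ...) {
  dplyr::mutate(x$adjusted, env = x$env_id, trait = x$trait, .before = 1)
}

#' @export
glance.beet_adjusted <- function(x, ...) {
  tibble::tibble(env = x$env_id, trait = x$trait, h2 = x$h2,
                 sigma_g2 = x$vc[["sigma_g2"]], sigma_row2 = x$vc[["sigma_row2"]],
                 sigma_col2 = x$vc[["sigma_col2"]], sigma_e2 = x$vc[["sigma_e2"]],
                 n_genotypes = nrow(x$adjusted))
}

#' Adjust every environment of a multi-environment trial table
#'
#' Convenience wrapper splitting a plot table by environment and calling
#' [adjust_environment()] on each.
#'
#' @inheritParams adjust_environment
#' @param trials Plot tibble possibly holding several environments.
#' @return A list of `beet_adjusted` objects, named by environment.
#' @export
adjust_trials <- function(trials, trait, surface_degree = 2L,
                          heritability = c("cullis", "entry_mean")) {
  heritability <- match.arg(heritability)
  parts <- split(tibble::as_tibble(trials), trials$env)
  lapply(parts, adjust_environment, trait = trait,
         surface_degree = surface_degree, heritability = heritability)
}

#' Multi-environment mean phenotype
#'
#' Per genotype, the arithmetic mean of its adjusted values over the chosen
#' environments; a genotype missing from some environments is averaged over
#' those where it is present (with a warning), and genotypes absent from all
#' environments are dropped.
#'
#' @param adjusted List of `beet_adjusted` objects (same trait).
#' @param env_subset Optional character vector of environment ids to keep.
#' @return A tibble with columns `genotype`, `value`, plus attribute
#'   `"trait"`.
#' @export
mean_phenotype <- function(adjusted, env_subset = NULL) {
  envs <- vapply(adjusted, function(a) a$env_id, character(1))
  if (!is.null(env_subset)) {
    if (length(env_subset) == 0) rlang::abort("`env_subset` must be nonempty.")
    miss <- setdiff(env_subset, envs)
    if (length(miss) > 0) {
      rlang::abort(paste0("Unknown environment(s): ", paste(miss, collapse = ", ")))
    }
    adjusted <- adjusted[envs %in% env_subset]
    envs <- envs[envs %in% env_subset]
  }
  long <- purrr::map_dfr(adjusted, tidy)
  if (nrow(long) == 0) rlang::abort("No adjusted values to average.")
  sets <- lapply(adjusted, function(a) a$adjusted$genotype)
  inter <- Reduce(intersect, sets)
  if (length(inter) == 0) {
    rlang::abort("No genotype is present in every selected environment.")
  }
  partial <- setdiff(unique(long$genotype), inter)
  if (length(partial) > 0) {
    rlang::warn(sprintf(
      "%d genotype(s) missing from some environments; averaged over those present.",
      length(partial)))
  }
  out <- long |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(value = mean(.data$value), n_envs = dplyr::n()) |>
    dplyr::select("genotype", "value")
  attr(out, "trait") <- adjusted[[1]]$trait
  out
}

#' Pairwise environment correlations of adjusted phenotypes
#'
#' Pearson correlation of adjusted genotype values for every environment
#' pair, computed on the pair's genotype intersection. Pairs sharing fewer
#' than 3 genotypes get `NA`.
#'
#' @param adjusted List of `beet_adjusted` objects.
#' @return A symmetric correlation matrix with unit diagonal, class
#'   `beet_env_cor`.
#' @export
env_correlation <- function(adjusted) {
  if (length(adjusted) < 2L) rlang::abort("Need at least 2 environments.")
  envs <- vapply(adjusted, function(a) a$env_id, character(1))
  k <- length(envs)
  M <- matrix(NA_real_, k, k, dimnames = list(envs, envs))
  diag(M) <- 1
  vals <- lapply(adjusted, function(a) setNames(a$adjusted$value, a$adjusted$genotype))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      shared <- intersect(names(vals[[i]]), names(vals[[j]]))
      if (length(shared) >= 3L) {
        M[i, j] <- M[j, i] <- cor(vals[[i]][shared], vals[[j]][shared])
      }
    }
  }
  structure(M, class = c("beet_env_cor", "matrix", "array"))
}

#' White sugar and white sugar yield
#'
#' `white_sugar()` computes the extractable white sugar content
#' `WS = S - (0.14 * (K + Na) + 0.25 * N + 0.5)` (percent), where S is the
#' sucrose content (%) and K, Na, N the potassium, sodium and alpha-amino
#' nitrogen impurity contents (meq/100 g). `white_sugar_yield()` computes
#' `WSY = RY * WS / 100` (t/ha) from the root yield RY (t/ha).
#'
#' @param S Sucrose content (%), non-negative.
#' @param K,Na,N Impurity contents (meq/100 g), non-negative.
#' @param RY Root yield (t/ha), non-negative.
#' @param WS White sugar content (%).
#' @return Numeric vector.
#' @export
#' @examples
#' white_sugar(18, 5, 1, 2)          # 16.16
#' white_sugar_yield(80, 16.16)      # 12.928
white_sugar <- function(S, K, Na, N) {
  if (any(c(S, K, Na, N) < 0)) rlang::abort("Inputs must be non-negative.")
  ws <- S - (0.14 * (K + Na) + 0.25 * N + 0.5)
  if (any(ws < 0)) rlang::warn("Negative white sugar content produced.")
  ws
}

#' @rdname white_sugar
#' @export
white_sugar_yield <- function(RY, WS) {
  if (any(RY < 0)) rlang::abort("`RY` must be non-negative.")
  RY * WS / 100
}
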