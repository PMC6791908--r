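# Multi-locus mixed-model association: P3D Wald scans, forward selection,
# BIC/eBIC model choice, AD effect estimation, Tukey class comparison.

# Align a phenotype (tibble genotype/value or named vector) to individuals.
align_phenotype <- function(y, ids) {
  if (is.data.frame(y)) {
    if (!all(c("genotype", "value") %in% names(y))) {
      rlang::abort("Phenotype tibble needs columns `genotype` and `value`.")
    }
    y <- setNames(y$value, y$genotype)
  }
  if (!is.null(names(y))) {
    miss <- setdiff(ids, names(y))
    if (length(miss) > 0) {
      rlang::abort(sprintf("Phenotype missing for %d individual(s), e.g. %s.",
                           length(miss), miss[1]))
    }
    y <- y[ids]
  } else if (length(y) != length(ids)) {
    rlang::abort("Unnamed phenotype must match the number of individuals.")
  }
  as.numeric(y)
}

# Fixed base design: intercept + structure indicator columns.
base_design <- function(n, structure = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(structure)) {
    f <- factor(structure)
    if (nlevels(f) > 1L) {
      S <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(S) <- paste0("cluster", levels(f)[-1])
      X <- cbind(X, S)
    }
  }
  X
}

# Cofactor fixed columns for a marker set under a model.
cofactor_columns <- function(cof, cg, dd, model) {
  if (length(cof) == 0L) return(NULL)
  out <- cg$X[, cof, drop = FALSE]
  colnames(out) <- paste0("a_", cof)
  if (model == "AD") {
    Wc <- dd$W[, cof, drop = FALSE]
    colnames(Wc) <- paste0("d_", cof)
    out <- cbind(out, Wc)
  }
  out
}

build_V <- function(vc, Ks) {
  n <- nrow(Ks[[1]])
  V <- vc$sigma_a2 * Ks[[1]] + diag(vc$sigma_e2, n)
  if (length(Ks) > 1L && vc$sigma_d2 > 0) V <- V + vc$sigma_d2 * Ks[[2]]
  V
}

#' P3D Wald scan over candidate SNPs
#'
#' Generalized-least-squares Wald tests of each candidate marker added to
#' the fixed design (intercept, structure, current cofactors), with the
#' covariance `V = sigma_a2 K_a + sigma_d2 K_d + sigma_e2 I` held fixed at
#' the supplied variance components (P3D). Under the additive model the test
#' has 1 df on the centered-code coefficient; under the AD model it is the
#' joint 2-df test on the additive and dominance coefficients. Candidates
#' collinear with the current fixed design return `NA`.
#'
#' @param y Phenotype (tibble `genotype`/`value` or named/plain vector).
#' @param vc A `beet_vc` from [fit_reml()] under the current cofactor model.
#' @param cg,dd [center_genotypes()] and (for AD) [dominance_design()]
#'   objects.
#' @param kinships List of kinship matrices matching `vc` (A: `K_a`; AD:
#'   `K_a`, `K_d`).
#' @param model `"A"` or `"AD"`.
#' @param structure Optional cluster labels (fixed covariate).
#' @param cofactors Marker ids already selected as fixed regressors.
#' @param candidates Marker ids to test (default: all non-cofactors).
#' @return Named numeric vector of p-values (NA where undefined).
#' @export
wald_scan <- function(y, vc, cg, dd = NULL, kinships, model = c("A", "AD"),
                      structure = NULL, cofactors = character(0),
                      candidates = NULL) {
  model <- match.arg(model)
  if (model == "AD" && is.null(dd)) rlang::abort("AD model needs a dominance design.")
  ids <- rownames(cg$X)
  y <- align_phenotype(y, ids)
  n <- length(y)
  mk <- colnames(cg$X)
  candidates <- candidates %||% setdiff(mk, cofactors)
  if (inherits(kinships, "beet_kinship")) kinships <- list(kinships)
  Ks <- lapply(kinships, function(k) if (inherits(k, "beet_kinship")) k$K else k)
  V <- build_V(vc, Ks)
  chV <- chol(V)
  Vi <- chol2inv(chV)
  Xb <- cbind(base_design(n, structure), cofactor_columns(cofactors, cg, dd, model))
  ViXb <- Vi %*% Xb
  Viy <- Vi %*% y
  B11 <- crossprod(Xb, ViXb)
  b1 <- crossprod(Xb, Viy)
  Xc <- cg$X[, candidates, drop = FALSE]
  ViXc <- Vi %*% Xc
  if (model == "AD") {
    Wc <- dd$W[, candidates, drop = FALSE]
    ViWc <- Vi %*% Wc
  }
  df <- if (model == "A") 1L else 2L
  pvals <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (k in seq_along(candidates)) {
    if (model == "A") {
      C <- Xc[, k, drop = FALSE]
      ViC <- ViXc[, k, drop = FALSE]
    } else {
      C <- cbind(Xc[, k], Wc[, k])
      ViC <- cbind(ViXc[, k], ViWc[, k])
    }
    M <- rbind(cbind(B11, crossprod(Xb, ViC)),
               cbind(crossprod(C, ViXb), crossprod(C, ViC)))
    rhs <- c(b1, crossprod(C, Viy))
    sol <- tryCatch({
      chM <- chol(M)
      Minv <- chol2inv(chM)
      list(beta = Minv %*% rhs, cov = Minv)
    }, error = function(e) NULL)
    if (is.null(sol)) next
    idx <- ncol(Xb) + seq_len(df)
    bc <- sol$beta[idx]
    cov_cc <- sol$cov[idx, idx, drop = FALSE]
    wstat <- tryCatch(as.numeric(crossprod(bc, solve(cov_cc, bc))),
                      error = function(e) NA_real_)
    if (is.finite(wstat) && wstat >= 0) {
      pvals[k] <- pchisq(wstat, df = df, lower.tail = FALSE)
    }
  }
  pvals
}

step_criteria <- function(vc, n, m, s, gamma) {
  k <- vc$p
  bic <- -2 * vc$loglik_ml + k * log(n)
  ebic <- bic + 2 * gamma * lchoose(m, s)
  c(bic = bic, ebic = ebic)
}

#' Forward selection of SNP cofactors in a mixed model
#'
#' Multi-locus mixed-model scan: starting from no cofactors, variance
#' components are re-estimated by REML once per step under the current
#' cofactor model, a P3D Wald scan ranks the remaining candidates, and the
#' smallest-p-value SNP enters the fixed design (ties broken by lowest
#' chromosome then position then marker id). Selection stops when the
#' genetic variance share `(sigma_a2 + sigma_d2) / total` falls below
#' `var_stop`, when `max_steps` is reached, or when no candidate has a
#' defined p-value.
#'
#' @inheritParams wald_scan
#' @param geno A [beet_geno()] with complete codes.
#' @param map Optional map tibble (used for tie-breaking and downstream
#'   merging).
#' @param max_steps Maximum number of selected SNPs (default 20).
#' @param var_stop Genetic-variance share below which selection stops
#'   (default 1e-3).
#' @param gamma eBIC gamma recorded on the trace (default 1).
#' @return A `beet_gwas_trace` object; see [select_best_model()],
#'   [estimate_effects()], [tidy.beet_gwas_trace()].
#' @export
forward_select <- function(y, geno, model = c("A", "AD"), structure = NULL,
                           map = NULL, candidates = NULL, max_steps = 20L,
                           var_stop = 1e-3, gamma = 1) {
  model <- match.arg(model)
  if (anyNA(geno$codes)) rlang::abort("Complete genotypes required; impute first.")
  cg <- center_genotypes(geno)
  dd <- if (model == "AD") dominance_design(geno) else NULL
  Ka <- kinship(cg)
  Ks <- if (model == "AD") list(Ka$K, kinship(dd)$K) else list(Ka$K)
  eig <- if (model == "A") eigen(Ks[[1]], symmetric = TRUE) else NULL
  ids <- rownames(cg$X)
  yv <- align_phenotype(y, ids)
  n <- length(yv)
  mk <- colnames(cg$X)
  candidates <- candidates %||% mk
  m <- length(candidates)
  # tie-break ordering: (chrom, pos) when mapped, then marker id
  ord_key <- if (!is.null(map)) {
    pos <- map$pos_cm[match(mk, map$marker)]
    chr <- map$chrom[match(mk, map$marker)]
    order(is.na(chr), chr, pos, mk)
  } else {
    order(mk)
  }
  rank_of <- setNames(seq_along(mk), mk[ord_key])

  steps <- list()
  cof <- character(0)
  stop_reason <- NULL
  for (s in 0:max_steps) {
    Xb <- cbind(base_design(n, structure), cofactor_columns(cof, cg, dd, model))
    vc <- fit_reml(yv, Xb, Ks, eig = eig)
    crit <- step_criteria(vc, n, m, s, gamma)
    genetic_share <- (vc$sigma_a2 * mean(diag(Ks[[1]])) +
                        (if (model == "AD") vc$sigma_d2 * mean(diag(Ks[[2]])) else 0))
    genetic_share <- genetic_share / (genetic_share + vc$sigma_e2)
    step <- list(step_index = s, cofactors = cof, vc = vc,
                 pvalues = NULL, bic = crit[["bic"]], ebic = crit[["ebic"]],
                 genetic_share = genetic_share)
    if (genetic_share < var_stop) {
      steps[[s + 1L]] <- step
      stop_reason <- "variance_exhausted"
      break
    }
    if (s == max_steps) {
      steps[[s + 1L]] <- step
      stop_reason <- "max_steps"
      break
    }
    pv <- wald_scan(yv, vc, cg, dd, Ks, model = model, structure = structure,
                    cofactors = cof, candidates = setdiff(candidates, cof))
    step$pvalues <- pv
    steps[[s + 1L]] <- step
    if (all(is.na(pv))) {
      stop_reason <- "no_defined_candidate"
      break
    }
    # accept the smallest-p candidate whose columns keep the design full rank
    ord <- names(sort(pv, na.last = NA))
    ord <- ord[order(pv[ord], rank_of[ord])]
    best_mk <- NULL
    for (cand in ord) {
      Xtry <- cbind(Xb, cofactor_columns(cand, cg, dd, model))
      if (qr(Xtry)$rank == ncol(Xtry)) { best_mk <- cand; break }
    }
    if (is.null(best_mk)) {
      stop_reason <- "no_defined_candidate"
      break
    }
    cof <- c(cof, best_mk)
  }
  structure(list(steps = steps, model = model, structure = structure,
                 candidates = candidates, map = map, n = n,
                 n_candidates = m, gamma = gamma,
                 stop_reason = stop_reason %||% "max_steps"),
            class = "beet_gwas_trace")
}

#' @export
print.beet_gwas_trace <- function(x, ...) {
  cat(sprintf("<beet_gwas_trace> model %s, %d step(s), stop: %s\n",
              x$model, length(x$steps) - 1L, x$stop_reason))
  print(tidy(x))
  invisible(x)
}

#' Tidy a forward-selection trace
#'
#' @param x A `beet_gwas_trace`.
#' @param ... Unused.
#' @return One row per step: `step`, `added` (marker entering at that step),
#'   `min_p`, variance components, `genetic_share`, `bic`, `ebic`.
#' @export
tidy.beet_gwas_trace <- function(x, ...) {
  purrr::map_dfr(x$steps, function(st) {
    tibble::tibble(
      step = st$step_index,
      added = if (st$step_index == 0L) NA_character_ else st$cofactors[st$step_index],
      min_p = if (is.null(st$pvalues) || all(is.na(st$pvalues))) NA_real_
              else min(st$pvalues, na.rm = TRUE),
      sigma_a2 = st$vc$sigma_a2, sigma_d2 = st$vc$sigma_d2,
      sigma_e2 = st$vc$sigma_e2, genetic_share = st$genetic_share,
      bic = st$bic, ebic = st$ebic)
  })
}

#' @export
glance.beet_gwas_trace <- function(x, ...) {
  best <- select_best_model(x)
  tibble::tibble(model = x$model, n = x$n, n_candidates = x$n_candidates,
                 n_steps = length(x$steps) - 1L, stop_reason = x$stop_reason,
                 best_step = best$step_index,
                 n_selected = length(best$cofactors))
}

#' Select the best forward-selection step by BIC or eBIC
#'
#' `BIC = -2 loglik + k log n` with `k` the number of fixed-effect
#' coefficients (intercept and structure included);
#' `eBIC = BIC + 2 gamma log C(n_candidates, s)` with `s` the number of
#' selected SNPs. With `gamma = 0` the two criteria coincide.
#'
#' @param trace A `beet_gwas_trace`.
#' @param criterion `"eBIC"` (default) or `"BIC"`.
#' @param gamma eBIC penalty weight (default: the trace's gamma).
#' @return The selected step (a list with `step_index`, `cofactors`, `vc`,
#'   `pvalues`, `bic`, `ebic`), class `beet_gwas_step`.
#' @export
select_best_model <- function(trace, criterion = c("eBIC", "BIC"), gamma = NULL) {
  criterion <- match.arg(criterion)
  gamma <- gamma %||% trace$gamma
  if (gamma < 0) rlang::abort("`gamma` must be non-negative.")
  vals <- vapply(trace$steps, function(st) {
    if (criterion == "BIC") st$bic
    else st$bic + 2 * gamma * lchoose(trace$n_candidates, length(st$cofactors))
  }, numeric(1))
  best <- trace$steps[[which.min(vals)]]
  best$criterion <- criterion
  best$criterion_value <- min(vals)
  class(best) <- "beet_gwas_step"
  best
}

#' Estimate SNP effects in the full AD model
#'
#' Joint generalized-least-squares fit of the additive and dominance columns
#' of all selected SNPs in the additive+dominance mixed model at the chosen
#' step. Reports per SNP the additive effect, dominance effect, the share of
#' phenotypic variance explained by its fitted contribution
#' `var(x theta_a + w theta_d) / var(y)`, the empirical genotype-class means
#' and whether the exotic allele is favorable (the code-2 class mean shifts
#' the trait in the favorable direction relative to the code-0 class).
#' Rank-deficient column sets are resolved by dropping later-selected
#' columns with a warning.
#'
#' @param best A `beet_gwas_step` from [select_best_model()].
#' @param y Phenotype as in [wald_scan()].
#' @param geno A [beet_geno()] with complete codes.
#' @param structure Optional cluster labels.
#' @param trait_orientation `"lower_is_better"` (impurities; default) or
#'   `"higher_is_better"`.
#' @return A tibble with one row per selected SNP: `marker`, `theta_a`,
#'   `theta_d`, `pct_var`, `mean_class0`, `mean_class1`, `mean_class2`,
#'   `favorable_exotic`.
#' @export
estimate_effects <- function(best, y, geno, structure = NULL,
                             trait_orientation = c("lower_is_better",
                                                   "higher_is_better")) {
  trait_orientation <- match.arg(trait_orientation)
  sel <- best$cofactors
  cg <- center_genotypes(geno)
  dd <- dominance_design(geno)
  ids <- rownames(cg$X)
  yv <- align_phenotype(y, ids)
  n <- length(yv)
  if (length(sel) == 0L) {
    return(tibble::tibble(marker = character(0), theta_a = numeric(0),
                          theta_d = numeric(0), pct_var = numeric(0),
                          mean_class0 = numeric(0), mean_class1 = numeric(0),
                          mean_class2 = numeric(0),
                          favorable_exotic = logical(0)))
  }
  miss <- setdiff(sel, colnames(cg$X))
  if (length(miss) > 0) {
    rlang::abort(paste0("Selected marker(s) absent: ", paste(miss, collapse = ", ")))
  }
  Ks <- list(kinship(cg)$K, kinship(dd)$K)
  Xb0 <- base_design(n, structure)
  # build effect columns in selection order, dropping rank-deficient ones
  cols <- list()
  lab <- character(0)
  cur_rank <- qr(Xb0)$rank
  dropped <- character(0)
  for (mk in sel) {
    for (kind in c("a", "d")) {
      colv <- if (kind == "a") cg$X[, mk] else dd$W[, mk]
      r_full <- qr(cbind(Xb0, do.call(cbind, cols), colv))$rank
      if (r_full == cur_rank + length(cols) + 1L) {
        cols[[length(cols) + 1L]] <- colv
        lab <- c(lab, paste0(kind, "_", mk))
      } else {
        dropped <- c(dropped, paste0(kind, "_", mk))
      }
    }
  }
  if (length(dropped) > 0) {
    rlang::warn(paste0("Dropped rank-deficient effect column(s): ",
                       paste(dropped, collapse = ", ")))
  }
  Xeff <- do.call(cbind, cols)
  colnames(Xeff) <- lab
  X <- cbind(Xb0, Xeff)
  vc <- fit_reml(yv, X, Ks)
  beta <- vc$beta
  out <- purrr::map_dfr(sel, function(mk) {
    ta <- if (paste0("a_", mk) %in% lab) beta[[paste0("a_", mk)]] else 0
    td <- if (paste0("d_", mk) %in% lab) beta[[paste0("d_", mk)]] else 0
    contrib <- cg$X[, mk] * ta + dd$W[, mk] * td
    codes <- geno$codes[, mk]
    cmeans <- vapply(0:2, function(cl) {
      if (any(codes == cl)) mean(yv[codes == cl]) else NA_real_
    }, numeric(1))
    fitted_cl <- function(cl) {
      xc <- cl - mean(geno$codes[, mk])
      wrow <- dd$W[match(cl, geno$codes[, mk]), mk]
      xc * ta + (if (is.na(wrow)) 0 else wrow) * td
    }
    delta <- fitted_cl(2L) - fitted_cl(0L)
    fav <- if (trait_orientation == "lower_is_better") delta < 0 else delta > 0
    tibble::tibble(marker = mk, theta_a = ta, theta_d = td,
                   pct_var = var(contrib) / var(yv),
                   mean_class0 = cmeans[1], mean_class1 = cmeans[2],
                   mean_class2 = cmeans[3],
                   favorable_exotic = fav)
  })
  attr(out, "vc") <- vc
  out
}

#' Tukey comparison of the three genotype classes
#'
#' One-way layout of the phenotype by genotype class (0/1/2) with pairwise
#' Tukey HSD at the given level, summarised as a compact letter display:
#' two classes share a letter iff their means are not significantly
#' different.
#'
#' @param y Phenotype vector.
#' @param codes Genotype codes (0/1/2), same length; every observed class
#'   needs >= 2 observations.
#' @param alpha Significance level (default 0.05).
#' @return A tibble `class`, `n`, `mean`, `letters`, with the Tukey p-value
#'   table as attribute `"tukey"`.
#' @export
tukey_classes <- function(y, codes, alpha = 0.05) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(codes))
  f <- factor(codes, levels = sort(unique(codes)))
  cnt <- table(f)
  small <- names(cnt)[cnt < 2L]
  if (length(small) > 0) {
    rlang::abort(paste0("Genotype class(es) with fewer than 2 observations: ",
                        paste(small, collapse = ", ")))
  }
  if (nlevels(f) < 2L) rlang::abort("Need at least two genotype classes.")
  fit <- aov(y ~ f)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$f
  lv <- levels(f)
  k <- length(lv)
  ns <- matrix(TRUE, k, k, dimnames = list(lv, lv))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    sig <- tk[rn, "p adj"] < alpha
    ns[pair[1], pair[2]] <- ns[pair[2], pair[1]] <- !sig
  }
  g <- igraph::graph_from_adjacency_matrix(ns, mode = "undirected", diag = FALSE)
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(vapply(cliques, function(cl) min(as.integer(cl)), numeric(1)))]
  letters_of <- setNames(rep("", k), lv)
  for (i in seq_along(cliques)) {
    mem <- lv[as.integer(cliques[[i]])]
    letters_of[mem] <- paste0(letters_of[mem], letters[i])
  }
  means <- tapply(y, f, mean)
  tibble::tibble(class = as.integer(lv), n = as.integer(cnt),
                 mean = as.numeric(means),
                 letters = unname(letters_of)) |>
    structure(tukey = tk)
}
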