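#' Specify one simulated field trial
#'
#' Describes a lattice-style trial: a row-by-column grid of plots holding
#' `n_reps` complete replicates of all entries plus replicated check entries,
#' with random row and column effects, a smooth polynomial spatial trend, a
#' replicate effect, and plot residual noise. Exactly one of `sigma_e`
#' (residual SD in trait units) or `target_h2` (entry-mean generalized
#' heritability aimed for after adjustment) must be given; with `target_h2`
#' the residual variance is set to `n_reps * V_g * (1 - h2) / h2` from the
#' realized genetic variance.
#'
#' @param env_id Environment label.
#' @param n_rows,n_cols Grid dimensions; `n_rows * n_cols` must hold
#'   `n_reps * (n_entries + n_checks)` plots.
#' @param n_reps Number of complete replicates (default 2).
#' @param n_checks Number of replicated check entries (default 4).
#' @param env_mean Environment mean in trait units.
#' @param sigma_row,sigma_col SDs of random row and column effects.
#' @param sigma_spatial SD of the smooth degree-2 polynomial surface.
#' @param sigma_rep SD of the replicate effect (default `sigma_row`).
#' @param sigma_e Residual SD, or `NULL` when `target_h2` is used.
#' @param target_h2 Target heritability in `[0, 1]`, or `NULL`.
#' @return A `beet_trial_spec` object.
#' @export
field_trial_spec <- function(env_id, n_rows, n_cols, n_reps = 2L, n_checks = 4L,
                             env_mean = 0, sigma_row = 0, sigma_col = 0,
                             sigma_spatial = 0, sigma_rep = sigma_row,
                             sigma_e = NULL, target_h2 = NULL) {
  if (is.null(sigma_e) == is.null(target_h2)) {
    rlang::abort("Give exactly one of `sigma_e` and `target_h2`.")
  }
  if (!is.null(target_h2)) assert_scalar_number(target_h2, "target_h2", 0, 1)
  if (!is.null(sigma_e)) assert_scalar_number(sigma_e, "sigma_e", 0)
  structure(list(env_id = env_id, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), n_reps = as.integer(n_reps),
                 n_checks = as.integer(n_checks), env_mean = env_mean,
                 sigma_row = sigma_row, sigma_col = sigma_col,
                 sigma_spatial = sigma_spatial, sigma_rep = sigma_rep,
                 sigma_e = sigma_e, target_h2 = target_h2),
            class = "beet_trial_spec")
}

#' Specify planted QTLs
#'
#' @param marker Marker ids carrying planted QTLs.
#' @param theta_a Additive effects (trait units per exotic-allele count).
#' @param theta_d Dominance effects (trait units).
#' @param trait Trait label per QTL.
#' @return A tibble with columns `marker`, `theta_a`, `theta_d`, `trait`.
#' @export
qtl_spec <- function(marker, theta_a, theta_d = 0, trait = "y") {
  tibble::tibble(marker = marker, theta_a = theta_a,
                 theta_d = theta_d, trait = trait)
}

#' Simulate multi-environment field trials
#'
#' For each trait, the genetic value of individual `i` is
#' `g_i = sum_l x_il * theta_a_l + w_il * theta_d_l + polygenic_i`, with `x`
#' the centered codes and `w` the NOIA dominance codes of the simulated
#' population ([center_genotypes()], [dominance_design()]), and the
#' polygenic term multivariate normal with covariance `polygenic_var * K_a /
#' mean(diag(K_a))`. Each trial lays entries and checks on a grid and adds
#' row, column, spatial, replicate and residual noise per its
#' [field_trial_spec()]. Checks receive fixed genetic values (normal-score
#' offsets scaled to the entry genetic SD) identical across replicates and
#' environments.
#'
#' @param geno A [beet_geno()].
#' @param qtls A [qtl_spec()] tibble (may have zero rows for a pure
#'   polygenic trait named `"y"`).
#' @param specs List of [field_trial_spec()] objects, one per environment.
#' @param polygenic_var Polygenic variance (>= 0).
#' @param seed Integer seed.
#' @return A tibble of plots with columns `env`, `genotype`, `row`, `col`,
#'   `rep`, `is_check` and one numeric column per trait.
#' @export
simulate_trials <- function(geno, qtls, specs, polygenic_var = 0, seed = 1L) {
  if (inherits(specs, "beet_trial_spec")) specs <- list(specs)
  assert_scalar_number(polygenic_var, "polygenic_var", 0)
  if (is.null(qtls)) qtls <- qtl_spec(character(0), numeric(0))
  missing_mk <- setdiff(qtls$marker, marker_ids(geno))
  if (length(missing_mk) > 0) {
    rlang::abort(paste0("QTL marker(s) absent from genotype matrix: ",
                        paste(missing_mk, collapse = ", ")))
  }
  traits <- unique(qtls$trait)
  if (length(traits) == 0L) traits <- "y"
  cg <- center_genotypes(geno)
  dd <- dominance_design(geno)
  Ka <- kinship(cg)$K
  Kn <- Ka / mean(diag(Ka))
  n <- nrow(geno$codes)
  ids <- individual_ids(geno)

  with_seed(seed, {
    # genetic values per trait (shared across environments)
    gmat <- sapply(traits, function(tr) {
      qt <- qtls[qtls$trait == tr, , drop = FALSE]
      g <- rep(0, n)
      if (nrow(qt) > 0) {
        g <- as.vector(cg$X[, qt$marker, drop = FALSE] %*% qt$theta_a +
                         dd$W[, qt$marker, drop = FALSE] %*% qt$theta_d)
      }
      if (polygenic_var > 0) {
        ev <- eigen(Kn, symmetric = TRUE)
        lam <- pmax(ev$values, 0)
        g <- g + as.vector(ev$vectors %*% (sqrt(polygenic_var * lam) * rnorm(n)))
      }
      g
    })
    gmat <- matrix(gmat, nrow = n, dimnames = list(ids, traits))

    n_checks <- max(vapply(specs, function(s) s$n_checks, integer(1)))
    check_ids <- if (n_checks > 0) sprintf("check%02d", seq_len(n_checks)) else character(0)
    # fixed check genetic values, scaled to the entry genetic SD per trait
    check_g <- outer(
      if (n_checks > 0) stats::qnorm(seq_len(n_checks) / (n_checks + 1)) else numeric(0),
      apply(gmat, 2, sd)
    )
    if (n_checks > 0) dimnames(check_g) <- list(check_ids, traits)

    out <- purrr::map_dfr(specs, function(sp) {
      entries_per_rep <- n + sp$n_checks
      n_plots <- sp$n_reps * entries_per_rep
      if (sp$n_rows * sp$n_cols < n_plots) {
        rlang::abort(sprintf("Trial %s: grid %dx%d cannot hold %d plots.",
                             sp$env_id, sp$n_rows, sp$n_cols, n_plots))
      }
      plot_idx <- seq_len(n_plots)
      row_i <- ((plot_idx - 1L) %% sp$n_rows) + 1L
      col_i <- ((plot_idx - 1L) %/% sp$n_rows) + 1L
      rep_i <- ((plot_idx - 1L) %/% entries_per_rep) + 1L
      genos <- unlist(lapply(seq_len(sp$n_reps), function(r) {
        sample(c(ids, check_ids[seq_len(sp$n_checks)]))
      }))
      is_check <- genos %in% check_ids
      r_eff <- rnorm(sp$n_rows, 0, sp$sigma_row)
      c_eff <- rnorm(sp$n_cols, 0, sp$sigma_col)
      rep_eff <- rnorm(sp$n_reps, 0, sp$sigma_rep)
      # smooth degree-2 surface over scaled (row, col), normalised to SD 1
      u <- (row_i - mean(seq_len(sp$n_rows))) / max(1, sp$n_rows)
      v <- (col_i - mean(seq_len(sp$n_cols))) / max(1, sp$n_cols)
      if (sp$sigma_spatial > 0) {
        a <- rnorm(5L)
        surf <- a[1] * u + a[2] * v + a[3] * u * v + a[4] * u^2 + a[5] * v^2
        surf <- sp$sigma_spatial * (surf - mean(surf)) / max(sd(surf), 1e-12)
      } else {
        surf <- rep(0, n_plots)
      }
      base <- tibble::tibble(env = sp$env_id, genotype = genos,
                             row = row_i, col = col_i, rep = rep_i,
                             is_check = is_check)
      for (tr in traits) {
        g_plot <- numeric(n_plots)
        g_plot[!is_check] <- gmat[match(genos[!is_check], ids), tr]
        if (any(is_check)) {
          g_plot[is_check] <- check_g[match(genos[is_check], check_ids), tr]
        }
        sig_e <- if (!is.null(sp$sigma_e)) sp$sigma_e else {
          vg <- var(gmat[, tr])
          if (vg <= 0) {
            rlang::abort(sprintf(
              "Trial %s: target_h2 requires positive genetic variance for trait %s.",
              sp$env_id, tr))
          }
          if (sp$target_h2 <= 0) Inf
          else sqrt(sp$n_reps * vg * (1 - sp$target_h2) / sp$target_h2)
        }
        eps <- if (is.finite(sig_e) && sig_e > 0) rnorm(n_plots, 0, sig_e) else rep(0, n_plots)
        base[[tr]] <- sp$env_mean + g_plot + r_eff[row_i] + c_eff[col_i] +
          rep_eff[rep_i] + surf + eps
      }
      base
    })
    out
  })
}
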