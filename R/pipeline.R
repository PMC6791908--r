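#' Default pipeline configuration
#'
#' Configuration for an end-to-end demonstration run on synthetic data: a
#' BC1S1 (elite x exotic) progeny of 187 individuals with 9 chromosomes,
#' testcross phenotypes for three impurity traits in six lattice
#' environments, and a two-cluster elite panel of 400 individuals scored on
#' the same map. All module parameters and every seed are explicit.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return A nested list, class `beet_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    map = list(n_chrom = 9L, markers_per_chrom = 32L, length_cm = 90,
               spacing = "random"),
    progeny = list(
      scheme = c("F1", "BC", "self"), n = 187L, n_parents = 6L,
      qtls = list(
        list(marker_index = 10L, theta_a = -1.0, theta_d = 0, trait = "K"),
        list(marker_index = 60L, theta_a = -0.8, theta_d = 0, trait = "Na"),
        list(marker_index = 130L, theta_a = 0.7, theta_d = 0, trait = "N")),
      polygenic_var = 0.5,
      environments = sprintf("ENV%d", 1:6),
      n_rows = 20L, n_cols = 20L, n_reps = 2L, n_checks = 4L,
      target_h2 = 0.75, sigma_row = 0.3, sigma_col = 0.3, sigma_spatial = 0.5,
      env_subset = sprintf("ENV%d", 1:6),
      min_maf = 0.03, model = c("A", "AD"), criterion = "eBIC", gamma = 1,
      # the chi-square distortion filter assumes exact Mendelian sampling,
      # which a pedigree-bottlenecked progeny does not satisfy marginally
      skip_filters = c("swap", "distortion")),
    panel = list(
      n_clusters = 2L, families_per_cluster = 20L, family_size = 10L,
      founder_divergence = 0.4,
      qtls = list(
        list(marker_index = 10L, theta_a = -1.0, theta_d = 0, trait = "K"),
        list(marker_index = 100L, theta_a = -0.8, theta_d = 0, trait = "Na")),
      polygenic_var = 0.5, target_h2 = 0.8,
      min_maf = 0.05, model = c("A", "AD"), criterion = "BIC", gamma = 1),
    traits = c("K", "Na", "N"),
    ld = list(n_pairs = 2000L, q = 0.99),
    merge = list(max_gap_cm = 5, window_cm = 5),
    gwas = list(max_steps = 10L, var_stop = 1e-3),
    surface_degree = 2L
  )
  class(cfg) <- "beet_config"
  cfg
}

check_config <- function(config, template = default_config()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (blk in intersect(names(config), c("map", "progeny", "panel", "ld", "merge", "gwas"))) {
    unknown <- setdiff(names(config[[blk]]), names(template[[blk]]))
    if (length(unknown) > 0) {
      rlang::abort(paste0("Unknown config key(s) in `", blk, "`: ",
                          paste(unknown, collapse = ", ")))
    }
  }
  invisible(config)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("Pipeline stage `%s` failed: %s", stage,
                         conditionMessage(e)))
  })
}

#' Run the full synthetic-data QTL comparison pipeline
#'
#' Chains simulate -> adjust -> filter -> kinship/LD -> GWAS -> merge ->
#' compare on the configuration's two populations and writes all stage
#' tables plus a JSON run manifest to `out_dir`. Identical configurations
#' and seeds reproduce identical tables.
#'
#' @param config A `beet_config` (see [default_config()]).
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @return A list with elements `progeny`, `panel` (each holding the
#'   genotype object, phenotypes, trace list, effects, `qtls`), the
#'   `comparison` tibble, `thresholds`, and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  check_config(config)
  hash <- config_hash(config)
  seed <- config$seed

  map <- run_stage("simpop", make_map(config$map$n_chrom, config$map$markers_per_chrom,
                                      config$map$length_cm, config$map$spacing,
                                      seed = child_seed(seed, 1L)))

  ## ---- progeny ----
  pg <- config$progeny
  scheme <- cross_scheme(pg$scheme, pg$n, n_parents = pg$n_parents)
  geno_p <- run_stage("simpop", simulate_cross(map, scheme, seed = child_seed(seed, 2L)))
  qtls_p <- purrr::map_dfr(pg$qtls, function(q) {
    qtl_spec(map$marker[q$marker_index], q$theta_a, q$theta_d, q$trait)
  })
  specs <- lapply(pg$environments, function(e) {
    field_trial_spec(e, pg$n_rows, pg$n_cols, pg$n_reps, pg$n_checks,
                     env_mean = 40, sigma_row = pg$sigma_row,
                     sigma_col = pg$sigma_col, sigma_spatial = pg$sigma_spatial,
                     target_h2 = pg$target_h2)
  })
  trials <- run_stage("simpop", simulate_trials(geno_p, qtls_p, specs,
                                                polygenic_var = pg$polygenic_var,
                                                seed = child_seed(seed, 3L)))

  traits <- config$traits
  pheno_p <- list()
  h2_tab <- list()
  for (tr in traits) {
    adj <- run_stage("trial_adjust",
                     adjust_trials(trials, tr, surface_degree = config$surface_degree))
    pheno_p[[tr]] <- suppressWarnings(mean_phenotype(adj, pg$env_subset))
    h2_tab[[tr]] <- purrr::map_dfr(adj, glance)
  }
  h2_tab <- dplyr::bind_rows(h2_tab)

  filt_p <- run_stage("geno_filter",
                      filter_chain(geno_p, map, scheme, min_maf = pg$min_maf,
                                   skip = pg$skip_filters))
  geno_pf <- filt_p$geno

  thr_p <- run_stage("relatedness_ld",
                     ld_threshold(geno_pf, map, correction = "kinship",
                                  n_pairs = config$ld$n_pairs, q = config$ld$q,
                                  seed = child_seed(seed, 4L)))

  res_p <- run_stage("mlmm_gwas", gwas_all_traits(
    pheno_p, geno_pf, models = pg$model, structure = NULL, map = map,
    criterion = pg$criterion, gamma = pg$gamma,
    max_steps = config$gwas$max_steps, var_stop = config$gwas$var_stop))

  ldp_p <- ld_provider(geno_pf, "kinship")
  qtls_det_p <- run_stage("qtl_tools", merge_label_all(
    res_p$effects, map, ldp_p, thr_p, config$merge$max_gap_cm))

  ## ---- panel ----
  pn <- config$panel
  geno_q <- run_stage("simpop", simulate_panel(
    map, pn$n_clusters, pn$families_per_cluster, pn$family_size,
    founder_divergence = pn$founder_divergence, seed = child_seed(seed, 5L)))
  qtls_q <- purrr::map_dfr(pn$qtls, function(q) {
    qtl_spec(map$marker[q$marker_index], q$theta_a, q$theta_d, q$trait)
  })
  # panel testcross phenotypes simulated at the genotype-mean level:
  # y = g + N(0, Vg (1 - h2) / h2), one vector per trait
  cgq <- center_genotypes(geno_q)
  ddq <- dominance_design(geno_q)
  Kq <- kinship(cgq)$K
  pheno_q <- with_seed(child_seed(seed, 6L), {
    ev <- eigen(Kq / mean(diag(Kq)), symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    out <- list()
    for (tr in traits) {
      qt <- qtls_q[qtls_q$trait == tr, , drop = FALSE]
      g <- rep(0, nrow(geno_q$codes))
      if (nrow(qt) > 0) {
        g <- as.vector(cgq$X[, qt$marker, drop = FALSE] %*% qt$theta_a +
                         ddq$W[, qt$marker, drop = FALSE] %*% qt$theta_d)
      }
      g <- g + as.vector(ev$vectors %*% (sqrt(pn$polygenic_var * lam) * rnorm(length(g))))
      vg <- var(g)
      y <- g + rnorm(length(g), 0, sqrt(vg * (1 - pn$target_h2) / pn$target_h2))
      out[[tr]] <- tibble::tibble(genotype = rownames(geno_q$codes), value = y)
    }
    out
  })

  filt_q <- run_stage("geno_filter",
                      filter_chain(geno_q, map, scheme = NULL, min_maf = pn$min_maf,
                                   skip = "swap"))
  geno_qf <- filt_q$geno

  thr_q <- run_stage("relatedness_ld",
                     ld_threshold(geno_qf, map, correction = "structure",
                                  n_pairs = config$ld$n_pairs, q = config$ld$q,
                                  seed = child_seed(seed, 7L)))

  res_q <- run_stage("mlmm_gwas", gwas_all_traits(
    pheno_q, geno_qf, models = pn$model, structure = geno_qf$cluster, map = map,
    criterion = pn$criterion, gamma = pn$gamma,
    max_steps = config$gwas$max_steps, var_stop = config$gwas$var_stop))

  ldp_q <- ld_provider(geno_qf, "structure")
  qtls_det_q <- run_stage("qtl_tools", merge_label_all(
    res_q$effects, map, ldp_q, thr_q, config$merge$max_gap_cm))

  comparison <- run_stage("qtl_tools",
                          colocate(qtls_det_p, qtls_det_q,
                                   window_cm = config$merge$window_cm))

  manifest <- list(
    package_version = as.character(utils::packageVersion("beetqtl")),
    config_hash = hash, seed = seed,
    stage_seeds = setNames(as.list(vapply(1:7, function(i) child_seed(seed, i),
                                          numeric(1))),
                           c("map", "progeny_cross", "progeny_trials",
                             "progeny_ld", "panel", "panel_pheno", "panel_ld")),
    ld_thresholds = list(progeny = thr_p$value, panel = thr_q$value),
    counts = list(
      progeny_markers_raw = ncol(geno_p$codes),
      progeny_markers_kept = ncol(geno_pf$codes),
      panel_markers_raw = ncol(geno_q$codes),
      panel_markers_kept = ncol(geno_qf$codes),
      progeny_snps_detected = nrow(res_p$effects),
      panel_snps_detected = nrow(res_q$effects),
      progeny_qtls = nrow(qtls_det_p),
      panel_qtls = nrow(qtls_det_q),
      trial_plots = nrow(trials)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name, stage) write_tsv_stamped(as.data.frame(df),
                                                     file.path(out_dir, name),
                                                     stage, hash)
    write_map_tsv(map, file.path(out_dir, "map.tsv"), hash = hash)
    write_genotype_tsv(geno_pf, file.path(out_dir, "progeny_genotypes.tsv"), hash = hash)
    write_genotype_tsv(geno_qf, file.path(out_dir, "panel_genotypes.tsv"), hash = hash)
    write_trials_tsv(trials, file.path(out_dir, "progeny_trials.tsv"), hash = hash)
    w(h2_tab, "progeny_heritability.tsv", "trial_adjust")
    w(filt_p$report, "progeny_filter_report.tsv", "geno_filter")
    w(filt_q$report, "panel_filter_report.tsv", "geno_filter")
    w(res_p$effects, "progeny_snp_effects.tsv", "mlmm_gwas")
    w(res_q$effects, "panel_snp_effects.tsv", "mlmm_gwas")
    w(flatten_qtls(qtls_det_p), "progeny_qtls.tsv", "qtl_tools")
    w(flatten_qtls(qtls_det_q), "panel_qtls.tsv", "qtl_tools")
    w(flatten_qtls(comparison), "comparison.tsv", "qtl_tools")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(map = map,
       progeny = list(geno = geno_pf, phenotypes = pheno_p, traces = res_p$traces,
                      effects = res_p$effects, qtls = qtls_det_p,
                      heritability = h2_tab, filter_report = filt_p$report),
       panel = list(geno = geno_qf, phenotypes = pheno_q, traces = res_q$traces,
                    effects = res_q$effects, qtls = qtls_det_q,
                    filter_report = filt_q$report),
       thresholds = list(progeny = thr_p, panel = thr_q),
       comparison = comparison, manifest = manifest)
}

# GWAS over every trait and model; effects estimated in the AD model at the
# step selected by the criterion, labelled per trait/model.
gwas_all_traits <- function(phenos, geno, models, structure, map, criterion,
                            gamma, max_steps, var_stop) {
  traces <- list()
  effects <- list()
  for (tr in names(phenos)) {
    for (md in models) {
      trace <- forward_select(phenos[[tr]], geno, model = md,
                              structure = structure, map = map,
                              max_steps = max_steps, var_stop = var_stop,
                              gamma = gamma)
      best <- select_best_model(trace, criterion = criterion)
      traces[[paste(tr, md, sep = "_")]] <- trace
      if (length(best$cofactors) > 0) {
        eff <- estimate_effects(best, phenos[[tr]], geno, structure = structure)
        eff$trait <- tr
        eff$model <- md
        effects[[paste(tr, md, sep = "_")]] <- eff
      }
    }
  }
  eff_all <- dplyr::bind_rows(effects)
  if (nrow(eff_all) > 0) {
    # a SNP detected by both models is reported once, labelled "A+AD"
    eff_all <- eff_all |>
      dplyr::group_by(.data$trait, .data$marker) |>
      dplyr::summarise(theta_a = .data$theta_a[1], theta_d = .data$theta_d[1],
                       pct_var = .data$pct_var[1],
                       mean_class0 = .data$mean_class0[1],
                       mean_class1 = .data$mean_class1[1],
                       mean_class2 = .data$mean_class2[1],
                       favorable_exotic = .data$favorable_exotic[1],
                       model = paste(sort(unique(.data$model)), collapse = "+"),
                       .groups = "drop")
  }
  list(traces = traces, effects = eff_all)
}

# Merge and label per trait, then stack.
merge_label_all <- function(effects, map, ld, threshold, max_gap_cm) {
  if (nrow(effects) == 0) {
    out <- merge_into_qtls(effects, map)
    out$trait <- character(0)
    return(out)
  }
  parts <- lapply(split(effects, effects$trait), function(e) {
    q <- merge_into_qtls(e, map, ld = ld, threshold = threshold,
                         max_gap_cm = max_gap_cm)
    q$trait <- e$trait[1]
    label_favorable(q)
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) > 0) out$qtl_id <- sprintf("QTL_%03d", seq_len(nrow(out)))
  class(out) <- c("beet_qtls", class(out))
  out
}

# Flatten the members list-column for TSV export.
flatten_qtls <- function(qtls) {
  if (nrow(qtls) == 0) return(dplyr::select(tibble::as_tibble(qtls), -dplyr::any_of("members")))
  qtls |>
    tibble::as_tibble() |>
    dplyr::mutate(
      pct_var_sum = vapply(.data$members, function(g) {
        if ("pct_var" %in% names(g)) sum(g$pct_var) else NA_real_
      }, numeric(1)),
      members = vapply(.data$members, function(g) paste(g$marker, collapse = ","),
                       character(1)))
}
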