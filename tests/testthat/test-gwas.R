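# Independent restricted-likelihood evaluator used as a grid-search oracle:
# written directly from the profiled Harville criterion with dense algebra.
oracle_restricted_ll <- function(y, X, Ks, ratios) {
  n <- length(y); p <- ncol(X)
  H <- diag(1, n)
  for (i in seq_along(Ks)) H <- H + ratios[i] * Ks[[i]]
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  q <- as.numeric(t(r) %*% Hi %*% r)
  s2e <- q / (n - p)
  as.numeric(-0.5 * ((n - p) * (log(2 * pi * s2e) + 1) +
                       determinant(H)$modulus +
                       determinant(XtHiX)$modulus -
                       determinant(t(X) %*% X)$modulus))
}

test_that("REML estimates reach the brute-force grid maximum on toy instances", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      n <- 12
      M <- matrix(rnorm(n * 6), n, 6)
      Ka <- tcrossprod(M) / 6
      D <- matrix(rnorm(n * 6), n, 6)
      Kd <- tcrossprod(D) / 6
      X <- cbind(1, rnorm(n))
      y <- as.vector(M %*% rnorm(6) + rnorm(n))
    })
    # one kinship: 2500-point log-spaced grid
    vc1 <- fit_reml(y, X, list(Ka))
    grid <- exp(seq(-12, 8, length.out = 2500))
    best1 <- max(vapply(grid, function(g) oracle_restricted_ll(y, X, list(Ka), g),
                        numeric(1)))
    expect_gte(vc1$loglik_reml, best1 - 1e-4)

    # two kinships: 50 x 50 grid over the variance ratios (the optimum may
    # sit at the vanishing-residual boundary on these tiny instances)
    vc2 <- suppressWarnings(fit_reml(y, X, list(Ka, Kd)))
    g2 <- exp(seq(-10, 6, length.out = 50))
    best2 <- max(outer(g2, g2, Vectorize(function(a, b) {
      oracle_restricted_ll(y, X, list(Ka, Kd), c(a, b))
    })))
    expect_gte(vc2$loglik_reml, best2 - 1e-4)
  }
})

test_that("REML recognises null genetic variance and guards degeneracies", {
  # a related population gives an identifiable genetic-variance share
  map0 <- study_map(markers_per_chrom = 30)
  g <- simulate_cross(map0, cross_scheme(c("F1", "BC", "self"), 187), seed = 77)
  Ka <- kinship(center_genotypes(g))
  small <- vapply(1:20, function(r) {
    withr::with_seed(500 + r, y <- rnorm(187))
    vc <- fit_reml(y, NULL, list(Ka))
    md <- mean(diag(Ka$K))
    vc$sigma_a2 * md / (vc$sigma_a2 * md + vc$sigma_e2) < 0.1
  }, logical(1))
  expect_gte(sum(small), 18)

  # a phenotype lying exactly in the kinship span floors sigma_e2 with a warning
  M <- rbind(c(1, 0), c(1, 0), c(0, 1), c(2, 1), c(1, 1), c(0, 2))
  K <- tcrossprod(M)
  y <- as.vector(M %*% c(1, 2))
  expect_warning(vc <- fit_reml(y, NULL, list(K)), "floor")
  expect_gt(vc$sigma_e2, 0)

  expect_error(fit_reml(rnorm(10), matrix(1, 10, 2), list(diag(10))), "Singular")
})

test_that("restricted likelihood is invariant to phenotype shifts", {
  g <- iid_panel(50, 40, seed = 3)
  Ka <- kinship(center_genotypes(g))
  withr::with_seed(6, y <- rnorm(50))
  v1 <- fit_reml(y, NULL, list(Ka))
  v2 <- fit_reml(y + 57.3, NULL, list(Ka))
  expect_equal(v1$loglik_reml, v2$loglik_reml, tolerance = 1e-6)
  expect_equal(v1$sigma_e2, v2$sigma_e2, tolerance = 1e-6)
})

test_that("wald_scan flags collinear candidates and detects planted signal", {
  map <- study_map(markers_per_chrom = 30)
  g <- simulate_cross(map, cross_scheme(c("F1", "BC", "self"), 187), seed = 21)
  g <- drop_redundant(g)$geno
  cg <- center_genotypes(g)
  Ka <- kinship(cg)
  mk <- colnames(cg$X)
  withr::with_seed(22, y <- rnorm(187))
  vc <- fit_reml(y, NULL, list(Ka))
  # a candidate identical to an existing cofactor is undefined
  pv <- wald_scan(y, vc, cg, NULL, list(Ka$K), model = "A",
                  cofactors = mk[1], candidates = mk[1])
  expect_true(is.na(pv[[mk[1]]]))

  # a 20%-of-variance additive QTL is found at small p in most replicates
  vx <- apply(cg$X, 2, var)
  qi <- which(map$chrom[match(mk, map$marker)] == "chr3")[10]
  hits <- vapply(1:10, function(r) {
    withr::with_seed(600 + r, {
      yy <- cg$X[, qi] * sqrt(0.2 / vx[qi]) + rnorm(187, 0, sqrt(0.8))
    })
    vcr <- fit_reml(yy, NULL, list(Ka))
    p <- wald_scan(yy, vcr, cg, NULL, list(Ka$K), model = "A",
                   candidates = mk[qi])
    p < 1e-4
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("the two-kinship covariance reduces to the A model when sigma_d2 is 0", {
  g <- iid_panel(80, 40, seed = 31)
  cg <- center_genotypes(g)
  dd <- dominance_design(g)
  Ka <- kinship(cg)
  Kd <- kinship(dd)
  withr::with_seed(32, y <- rnorm(80))
  vc <- fit_reml(y, NULL, list(Ka))
  # assemble V through the AD path with sigma_d2 = 0: identical p-values
  pA <- wald_scan(y, vc, cg, NULL, list(Ka$K), model = "A",
                  candidates = colnames(cg$X)[1:10])
  pA2 <- wald_scan(y, vc, cg, NULL, list(Ka$K, Kd$K), model = "A",
                   candidates = colnames(cg$X)[1:10])
  expect_equal(pA, pA2, tolerance = 1e-10)
})

test_that("forward selection terminates deterministically with a stopping reason", {
  map <- study_map(markers_per_chrom = 20)
  g <- simulate_cross(map, cross_scheme(c("F1", "BC", "self"), 120), seed = 41)
  withr::with_seed(42, y <- rnorm(120))
  tr <- forward_select(y, g, model = "A", map = map, max_steps = 3)
  expect_true(tr$stop_reason %in%
                c("variance_exhausted", "max_steps", "no_defined_candidate"))
  last <- tr$steps[[length(tr$steps)]]
  expect_true(last$genetic_share < 1e-3 ||
                length(last$cofactors) == 3 ||
                tr$stop_reason == "no_defined_candidate")
  # cofactor sets grow strictly across steps
  sizes <- vapply(tr$steps, function(s) length(s$cofactors), integer(1))
  expect_true(all(diff(sizes) == 1))
  # rerunning reproduces the trace
  tr2 <- forward_select(y, g, model = "A", map = map, max_steps = 3)
  expect_identical(tidy(tr), tidy(tr2))
})

test_that("ties at machine precision resolve to the lowest map position", {
  # two identical markers => identical p-values; the lower position wins
  map <- tibble::tibble(marker = c("hi", "lo"), chrom = c("chr2", "chr1"),
                        pos_cm = c(5, 5))
  codes <- cbind(hi = rep(c(0L, 1L, 2L), 20), lo = rep(c(0L, 1L, 2L), 20))
  rownames(codes) <- sprintf("i%02d", 1:60)
  g <- beet_geno(codes, population = "progeny")
  withr::with_seed(43, y <- g$codes[, 1] + rnorm(60, 0, 0.5))
  tr <- forward_select(y, g, model = "A", map = map, max_steps = 1)
  expect_equal(tr$steps[[2]]$cofactors, "lo")
})

test_that("BIC and eBIC selection obey their formulas", {
  map <- study_map(markers_per_chrom = 20)
  g <- simulate_cross(map, cross_scheme(c("F1", "BC", "self"), 150), seed = 51)
  cg <- center_genotypes(g)
  vx <- apply(cg$X, 2, var)
  qi <- 25
  withr::with_seed(52, {
    y <- cg$X[, qi] * sqrt(0.3 / vx[qi]) + rnorm(150, 0, sqrt(0.7))
  })
  tr <- forward_select(y, g, model = "A", map = map, max_steps = 3)
  expect_identical(select_best_model(tr, "eBIC", gamma = 0)$step_index,
                   select_best_model(tr, "BIC")$step_index)
  st <- tr$steps[[2]]
  expect_equal(st$ebic - st$bic, 2 * lchoose(tr$n_candidates, 1))
  expect_error(select_best_model(tr, "eBIC", gamma = -1), "non-negative")
})

test_that("effect estimation recovers constructed effects and flags orientation", {
  g <- iid_panel(120, 30, seed = 61)
  cg <- center_genotypes(g)
  y <- as.vector(2 * cg$X[, 5])     # noise-free additive effect of 2
  best <- structure(list(step_index = 1L, cofactors = colnames(cg$X)[5]),
                    class = "beet_gwas_step")
  eff <- suppressWarnings(estimate_effects(best, y, g))
  expect_equal(eff$theta_a, 2, tolerance = 1e-6)
  expect_equal(eff$theta_d, 0, tolerance = 1e-6)
  expect_equal(eff$pct_var, 1, tolerance = 1e-6)
  # positive additive effect on an impurity: exotic allele is unfavorable
  expect_false(eff$favorable_exotic)
  eff2 <- suppressWarnings(estimate_effects(best, -y, g))
  expect_true(eff2$favorable_exotic)

  # pct_var decomposition is bounded on constructed orthogonal regressors
  codes <- cbind(a = rep(c(0L, 2L), each = 40),
                 b = rep(c(0L, 2L), times = 40))
  g4 <- geno_from(codes)
  withr::with_seed(62, y3 <- rnorm(80))
  best3 <- structure(list(step_index = 2L, cofactors = c("a", "b")),
                     class = "beet_gwas_step")
  eff3 <- suppressWarnings(estimate_effects(best3, y3, g4))
  expect_lte(sum(eff3$pct_var), 1 + 1e-8)
})

test_that("Tukey class comparison produces sensible letter displays", {
  withr::with_seed(71, {
    codes <- rep(0:2, each = 30)
    # equal means: one shared letter in most replicates
    same <- vapply(1:20, function(r) {
      tk <- tukey_classes(rnorm(90), codes)
      length(unique(tk$letters)) == 1
    }, logical(1))
    expect_gte(mean(same), 0.9)
    # classes 10 SDs apart: three distinct letters
    y2 <- rnorm(90, mean = rep(c(0, 10, 20), each = 30), sd = 1)
    tk2 <- tukey_classes(y2, codes)
    expect_equal(length(unique(tk2$letters)), 3)
    # two classes identical, third far away: two letter groups
    y3 <- rnorm(90, mean = rep(c(0, 0, 30), each = 30), sd = 1)
    tk3 <- tukey_classes(y3, codes)
    expect_equal(length(unique(tk3$letters)), 2)
    expect_equal(tk3$letters[1], tk3$letters[2])
  })
  expect_error(tukey_classes(rnorm(5), c(0, 0, 1, 1, 2)), "class")
})
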