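make_noise_free_trial <- function(n_geno = 30, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("g%02d", seq_len(n_geno))
    truth <- setNames(10 + rnorm(n_geno, sd = 3), ids)
    genos <- c(sample(ids), sample(ids))   # randomised layout
    grid <- expand.grid(row = 1:10, col = 1:6)
    plots <- grid[seq_len(2 * n_geno), ]
    list(truth = truth,
         trial = tibble::tibble(env = "E1", genotype = genos,
                                row = plots$row, col = plots$col,
                                rep = rep(1:2, each = n_geno),
                                is_check = FALSE,
                                y = unname(truth[genos])))
  })
}

test_that("noise-free trials are adjusted to the genotype constants with h2 ~ 1", {
  nf <- make_noise_free_trial()
  a <- adjust_environment(nf$trial, "y", surface_degree = 0)
  expect_gte(a$h2, 0.99)
  shift <- a$adjusted$value - nf$truth[a$adjusted$genotype]
  expect_lt(diff(range(shift)), 1e-2)
})

test_that("adjusted phenotypes are shift-invariant and h2 falls with noise", {
  map <- tiny_map()
  g <- simulate_cross(map, cross_scheme(c("F1", "BC", "self"), 60), seed = 1)
  sp <- function(se) field_trial_spec("E1", 12, 12, 2, 2, env_mean = 0,
                                      sigma_row = 0.2, sigma_col = 0.2,
                                      sigma_spatial = 0.3, sigma_e = se)
  tr <- simulate_trials(g, qtl_spec(map$marker[3], 1, trait = "K"), sp(0.5),
                        polygenic_var = 0.3, seed = 2)
  a1 <- adjust_environment(tr, "K")
  tr2 <- dplyr::mutate(tr, K = K + 100)
  a2 <- adjust_environment(tr2, "K")
  d <- a2$adjusted$value - a1$adjusted$value
  expect_lt(diff(range(d)), 1e-6)
  expect_equal(mean(d), 100, tolerance = 1e-6)

  # h2 non-increasing over a residual-SD grid (averaged over replicates)
  h2_at <- function(se) {
    mean(vapply(1:5, function(r) {
      trr <- simulate_trials(g, qtl_spec(map$marker[3], 1, trait = "K"), sp(se),
                             polygenic_var = 0.3, seed = 10 * se + r)
      adjust_environment(trr, "K")$h2
    }, numeric(1)))
  }
  hs <- vapply(c(0.2, 1, 4), h2_at, numeric(1))
  expect_true(all(diff(hs) < 0.05))
  expect_gt(hs[1] - hs[3], 0.2)
})

test_that("null genetic variance yields near-zero heritability", {
  hs <- vapply(1:20, function(r) {
    withr::with_seed(100 + r, {
      ids <- sprintf("g%03d", 1:187)
      genos <- c(sample(ids), sample(ids))
      n <- length(genos)
      tr <- tibble::tibble(env = "E", genotype = genos,
                           row = ((seq_len(n) - 1) %% 20) + 1,
                           col = ((seq_len(n) - 1) %/% 20) + 1,
                           rep = rep(1:2, each = 187), is_check = FALSE,
                           y = rnorm(n))
      adjust_environment(tr, "y", surface_degree = 0)$h2
    })
  }, numeric(1))
  expect_gte(sum(hs <= 0.1), 17)
})

test_that("adjust_environment validates its inputs", {
  tr <- make_noise_free_trial()$trial
  expect_error(adjust_environment(tr, "nope"), "Unknown trait")
  expect_error(adjust_environment(tr[1, ], "y"), "two plots")
  bad <- tr
  bad$row[2] <- bad$row[1]; bad$col[2] <- bad$col[1]
  expect_error(adjust_environment(bad, "y"), "unique")
})

test_that("mean_phenotype averages across environments and warns on gaps", {
  mk <- function(env, ids, vals) {
    structure(list(env_id = env, trait = "y",
                   adjusted = tibble::tibble(genotype = ids, value = vals),
                   h2 = 0.8, vc = c(sigma_g2 = 1, sigma_row2 = 0,
                                    sigma_col2 = 0, sigma_e2 = 1)),
              class = "beet_adjusted")
  }
  a <- mk("E1", c("g1", "g2"), c(10, 1))
  b <- mk("E2", c("g1", "g2"), c(20, 1))
  mp <- mean_phenotype(list(a, b))
  expect_equal(mp$value[mp$genotype == "g1"], 15)
  expect_equal(mp$value[mp$genotype == "g2"], 1)

  # identical environments are idempotent
  mp2 <- mean_phenotype(list(a, a))
  expect_equal(mp2$value, a$adjusted$value)

  # genotype present in 1 of 2 environments: averaged over those present
  c2 <- mk("E3", c("g1", "g2", "g3"), c(30, 1, 7))
  expect_warning(mp3 <- mean_phenotype(list(a, c2)), "missing from some")
  expect_equal(mp3$value[mp3$genotype == "g3"], 7)

  expect_error(mean_phenotype(list(a, b), character(0)), "nonempty")
  expect_error(mean_phenotype(list(a, mk("E9", "zz", 1))), "every selected")
})

test_that("environment correlations behave on duplicated, negated and null data", {
  mk <- function(env, vals) {
    structure(list(env_id = env, trait = "y",
                   adjusted = tibble::tibble(genotype = names(vals),
                                             value = unname(vals)),
                   h2 = 0.8, vc = c(sigma_g2 = 1, sigma_row2 = 0,
                                    sigma_col2 = 0, sigma_e2 = 1)),
              class = "beet_adjusted")
  }
  v <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  M <- env_correlation(list(mk("A", v), mk("B", v), mk("C", -v)))
  expect_equal(unname(M["A", "B"]), 1)
  expect_equal(unname(M["A", "C"]), -1)
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(M, t(M))

  # fewer than 3 shared genotypes: flagged missing
  M2 <- env_correlation(list(mk("A", v[1:2]), mk("B", v[1:2])))
  expect_true(is.na(M2["A", "B"]))

  # independent environments: |r| small in most replicates
  ok <- vapply(1:40, function(r) {
    withr::with_seed(r, {
      x <- setNames(rnorm(187), sprintf("g%03d", 1:187))
      y <- setNames(rnorm(187), sprintf("g%03d", 1:187))
      abs(env_correlation(list(mk("A", x), mk("B", y)))["A", "B"]) < 0.25
    })
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("white sugar formulas match their definitions", {
  expect_equal(white_sugar(18, 0, 0, 0), 17.5)
  expect_equal(white_sugar(18, 5, 1, 2), 16.16)
  # monotone decreasing in each impurity
  base <- white_sugar(18, 5, 1, 2)
  expect_lt(white_sugar(18, 6, 1, 2), base)
  expect_lt(white_sugar(18, 5, 2, 2), base)
  expect_lt(white_sugar(18, 5, 1, 3), base)
  expect_warning(white_sugar(0.1, 10, 10, 10), "Negative")
  expect_error(white_sugar(-1, 0, 0, 0), "non-negative")

  expect_equal(white_sugar_yield(0, 123), 0)
  expect_equal(white_sugar_yield(80, 16.16), 12.928)
  expect_equal(white_sugar_yield(100, 16.16), 16.16)
  expect_error(white_sugar_yield(-2, 10), "non-negative")
})
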