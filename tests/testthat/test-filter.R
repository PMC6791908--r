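test_that("missingness filter removes markers above the threshold", {
  codes <- matrix(0L, 100, 3)
  codes[1:6, 1] <- NA          # 6% missing -> removed
  codes[1:5, 2] <- NA          # exactly 5% -> kept
  codes[, 3] <- rep(c(0L, 1L, 2L), length.out = 100)
  g <- geno_from(codes)
  out <- filter_missingness(g, 0.05)
  expect_equal(out$report$kept, c(FALSE, TRUE, TRUE))
  expect_equal(colnames(out$geno$codes), c("m02", "m03"))
  # fully observed input is untouched
  g2 <- geno_from(matrix(1L, 10, 2))
  out2 <- filter_missingness(g2)
  expect_identical(out2$geno$codes, g2$codes)
})

test_that("segregation chi-square matches closed forms and removes distortion", {
  bc1 <- cross_scheme(c("F1", "BC"), 100)
  codes <- cbind(rep(c(0L, 1L), each = 50),            # 50:50, perfect fit
                 rep(c(0L, 1L), times = c(70, 30)))    # 70:30, chisq = 16
  g <- geno_from(codes)
  out <- test_segregation(g, bc1, alpha = 0.05)
  expect_equal(out$report$chisq, c(0, 16))
  expect_equal(out$report$p_value[1], 1)
  expect_equal(out$report$p_value[2], 6.334e-05, tolerance = 1e-3)
  expect_equal(out$report$kept, c(TRUE, FALSE))
  # observations in a zero-expectation class give p = 0
  g2 <- geno_from(cbind(c(rep(0L, 50), rep(1L, 49), 2L)))
  out2 <- test_segregation(g2, bc1)
  expect_equal(out2$report$p_value, 0)
})

test_that("swap detection flags a constructed inverted marker and warns on isolates", {
  map <- make_map(1, 20, 40, "uniform", seed = 2)
  g <- simulate_cross(map, cross_scheme(c("F1", "BC"), 200), seed = 3)
  swapped <- map$marker[10]
  g$codes[, swapped] <- 2L - g$codes[, swapped]
  rep <- detect_swapped_alleles(g, map)
  expect_equal(rep$marker[!rep$kept], swapped)

  # unperturbed chromosome: no flags in most replicates
  flags <- vapply(1:10, function(r) {
    gg <- simulate_cross(map, cross_scheme(c("F1", "BC"), 200), seed = 100 + r)
    sum(!detect_swapped_alleles(gg, map)$kept)
  }, numeric(1))
  expect_gte(mean(flags == 0), 0.95)

  # isolated marker: unflagged with a warning
  map2 <- tibble::tibble(marker = c("a", "b"), chrom = c("chr1", "chr2"),
                         pos_cm = c(0, 0))
  g2 <- geno_from(matrix(rep(c(0L, 1L), 50), 50, 2,
                         dimnames = list(NULL, c("a", "b"))))
  expect_warning(rep2 <- detect_swapped_alleles(g2, map2), "no linked neighbour")
  expect_true(all(rep2$kept))
})

test_that("flanking imputation fills gaps and recovers masked codes", {
  map <- tibble::tibble(marker = c("a", "b", "c"), chrom = "chr1",
                        pos_cm = c(0, 0.5, 1))
  codes <- matrix(c(1L, NA, 1L), 1, 3, dimnames = list("i1", c("a", "b", "c")))
  g <- impute_flanking(beet_geno(codes), map)
  expect_equal(unname(g$codes[1, "b"]), 1L)

  # terminal gap copies the nearest informative marker
  codes2 <- matrix(c(NA, 2L, 1L), 1, 3, dimnames = list("i1", c("a", "b", "c")))
  g2 <- impute_flanking(beet_geno(codes2), map)
  expect_equal(unname(g2$codes[1, "a"]), 2L)

  # an individual with nothing informative on a chromosome is an error
  codes3 <- matrix(NA_integer_, 1, 3, dimnames = list("lost", c("a", "b", "c")))
  expect_error(impute_flanking(beet_geno(codes3), map), "lost")

  # masking experiment at ~1 cM density: >= 95% of hidden codes recovered
  dense <- make_map(1, 90, 90, "uniform", seed = 4)
  gg <- simulate_cross(dense, cross_scheme(c("F1", "BC"), 100), seed = 5)
  truth <- gg$codes
  withr::with_seed(6, {
    mask <- sample(length(truth), round(0.05 * length(truth)))
  })
  gg$codes[mask] <- NA
  imp <- impute_flanking(gg, dense)
  expect_false(anyNA(imp$codes))
  expect_gte(mean(imp$codes[mask] == truth[mask]), 0.95)
})

test_that("redundancy, MAF and three-class filters apply their rules", {
  codes <- cbind(a = rep(c(0L, 1L, 2L), 10),
                 b = rep(c(0L, 1L, 2L), 10),      # duplicate of a
                 c = rep(c(2L, 1L, 0L), 10),      # distinct
                 d = rep(c(0L, 1L, 2L), 10))      # duplicate of a
  g <- geno_from(codes)
  out <- drop_redundant(g)
  expect_equal(colnames(out$geno$codes), c("a", "c"))
  expect_equal(out$report$representative[!out$report$kept], c("a", "a"))
  # all-distinct input is untouched
  out2 <- drop_redundant(out$geno)
  expect_identical(out2$geno$codes, out$geno$codes)

  codes2 <- cbind(mono = rep(0L, 100),
                  rare = c(rep(0L, 96), rep(1L, 4)),   # freq 0.02
                  mid = rep(c(0L, 2L), 50))            # freq 0.5
  g2 <- geno_from(codes2)
  out3 <- filter_maf(g2, 0.03)
  expect_equal(out3$report$kept, c(FALSE, FALSE, TRUE))
  expect_equal(out3$report$maf, c(0, 0.02, 0.5))

  codes3 <- cbind(two = rep(c(0L, 1L), 10),
                  three = rep(c(0L, 1L, 2L), length.out = 20),
                  empty = rep(NA_integer_, 20))
  out4 <- filter_three_classes(geno_from(codes3))
  expect_equal(out4$report$kept, c(FALSE, TRUE, FALSE))
})

test_that("the filter chain is idempotent and accounts for every marker", {
  map <- make_map(2, 30, 60, "uniform", seed = 7)
  sc <- cross_scheme(c("F1", "BC", "self"), 120)
  g <- simulate_cross(map, sc, seed = 8)
  withr::with_seed(9, {
    g$codes[sample(length(g$codes), 100)] <- NA
  })
  out <- suppressWarnings(filter_chain(g, map, sc))
  expect_false(anyNA(out$geno$codes))
  # per-stage accounting: kept + removed equals that stage's input
  stages <- split(out$report, out$report$stage)
  for (st in stages) expect_equal(nrow(st), length(unique(st$marker)))
  # rerunning the chain on its output changes nothing
  out2 <- suppressWarnings(filter_chain(out$geno, map, sc))
  expect_identical(out2$geno$codes, out$geno$codes)
})
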