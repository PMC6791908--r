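test_that("two-point estimates match closed forms for backcross data", {
  bc1 <- cross_scheme(c("F1", "BC"), 100)
  # 10 recombinants out of 100
  a <- rep(c(0L, 1L), each = 50)
  b <- a; b[c(1:5, 51:55)] <- 1L - b[c(1:5, 51:55)]
  g <- geno_from(cbind(a = a, b = b, c = a))
  tp <- estimate_twopoint(g, bc1)
  expect_equal(tp$r["a", "b"], 0.10)
  lod_expected <- 10 * log10(0.1) + 90 * log10(0.9) + 100 * log10(2)
  expect_equal(tp$lod["a", "b"], lod_expected, tolerance = 1e-9)
  expect_equal(lod_expected, 15.98, tolerance = 1e-2)
  # identical columns: r = 0, LOD = n log10 2
  expect_equal(tp$r["a", "c"], 0)
  expect_equal(tp$lod["a", "c"], 100 * log10(2))
  expect_equal(tp$r, t(tp$r))

  # monomorphic marker gives undefined pairs
  g2 <- geno_from(cbind(a = a, mono = rep(0L, 100)))
  tp2 <- estimate_twopoint(g2, bc1)
  expect_true(is.na(tp2$r["a", "mono"]))
  expect_equal(tp2$monomorphic, "mono")
})

test_that("EM three-class estimates are consistent and null pairs stay unlinked", {
  f2 <- cross_scheme(c("F1", "self"), 400)
  m2 <- tibble::tibble(marker = c("a", "b"), chrom = "chr1", pos_cm = c(0, 10))
  g <- simulate_cross(m2, f2, seed = 11)
  tp <- estimate_twopoint(g, f2)
  r_true <- haldane_cm_to_r(10)
  expect_lt(abs(tp$r["a", "b"] - r_true), 3 * sqrt(r_true * (1 - r_true) / 800))
  expect_gt(tp$lod["a", "b"], 6)

  # independent chromosomes: r near 0.5 and LOD < 3 for most pairs
  map <- tiny_map(2, 15)
  gg <- simulate_cross(map, cross_scheme(c("F1", "self"), 200), seed = 12)
  tp2 <- estimate_twopoint(gg, cross_scheme(c("F1", "self"), 200))
  cross <- outer(map$chrom[match(rownames(tp2$r), map$marker)],
                 map$chrom[match(colnames(tp2$r), map$marker)], "!=")
  cross[lower.tri(cross, diag = TRUE)] <- FALSE
  rr <- tp2$r[cross]; ll <- tp2$lod[cross]
  ok <- !is.na(rr) & abs(rr - 0.5) < 3 * sqrt(0.25 / 200) + 0.05 & ll < 3
  expect_gte(mean(ok), 0.95)
})

test_that("linkage grouping is transitive, size-filtered and order-invariant", {
  # constructed chain A-B-C with qualifying adjacent edges only
  r <- matrix(0.5, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  lod <- matrix(0, 3, 3, dimnames = dimnames(r))
  r["A", "B"] <- r["B", "A"] <- 0.1; lod["A", "B"] <- lod["B", "A"] <- 10
  r["B", "C"] <- r["C", "B"] <- 0.1; lod["B", "C"] <- lod["C", "B"] <- 10
  diag(r) <- 0
  tp <- structure(list(r = r, lod = lod, n = 100, monomorphic = character(0)),
                  class = "beet_twopoint")
  gr <- group_markers(tp, min_group = 2)
  expect_equal(gr$groups, list(c("A", "B", "C")))

  # a component smaller than min_group is unplaced
  gr2 <- group_markers(tp, min_group = 5)
  expect_equal(gr2$groups, list())
  expect_equal(gr2$unplaced, c("A", "B", "C"))

  # simulated two-chromosome F2: exactly 2 groups matching truth
  map <- tiny_map(2, 15)
  g <- simulate_cross(map, cross_scheme(c("F1", "self"), 200), seed = 13)
  tps <- estimate_twopoint(g, cross_scheme(c("F1", "self"), 200))
  grs <- group_markers(tps)
  expect_equal(length(grs$groups), 2)
  ag <- assign_groups(grs, map)
  expect_equal(sort(ag$chrom), c("chr1", "chr2"))
  expect_true(all(ag$agreement == 1))

  # order invariance
  perm <- withr::with_seed(14, sample(ncol(tps$r)))
  tpp <- structure(list(r = tps$r[perm, perm], lod = tps$lod[perm, perm],
                        n = tps$n, monomorphic = character(0)),
                   class = "beet_twopoint")
  grp <- group_markers(tpp)
  norm <- function(gr) lapply(gr$groups, sort)
  expect_setequal(norm(grp), norm(grs))
})

test_that("chromosome recovery holds across replicated simulations", {
  map <- make_map(3, 9, 80, "uniform", seed = 15)  # ~10 cM spacing
  hits <- vapply(1:20, function(r) {
    g <- simulate_cross(map, cross_scheme(c("F1", "BC"), 150), seed = 300 + r)
    tp <- estimate_twopoint(g, cross_scheme(c("F1", "BC"), 150))
    length(group_markers(tp)$groups) == 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("consensus distances average intervals and project absent markers", {
  m1 <- tibble::tibble(marker = c("a", "b", "c"), chrom = "chr1",
                       pos_cm = c(0, 10, 30))
  m2 <- tibble::tibble(marker = c("a", "b", "c"), chrom = "chr1",
                       pos_cm = c(0, 20, 50))
  cons <- consensus_distances(list(m1, m2))
  expect_equal(cons$pos_cm, c(0, 15, 40))
  # identical inputs are returned unchanged
  expect_equal(consensus_distances(list(m1, m1))$pos_cm, m1$pos_cm)

  # marker present in only one map contributes that map's intervals
  m3 <- tibble::tibble(marker = c("a", "c"), chrom = "chr1", pos_cm = c(0, 28))
  cons2 <- consensus_distances(list(m1, m3))
  expect_equal(cons2$marker, c("a", "b", "c"))
  expect_equal(cons2$pos_cm, c(0, 10, 30))   # b's intervals from m1 only

  # conflicting orders are rejected with the chromosome named
  m4 <- tibble::tibble(marker = c("b", "a"), chrom = "chr1", pos_cm = c(0, 5))
  expect_error(consensus_distances(list(m1, m4)), "chr1")
})
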