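mk_map <- function(pos, chrom = "chr1") {
  tibble::tibble(marker = names(pos), chrom = chrom, pos_cm = unname(pos))
}

const_ld <- function(value) function(a, b) value

test_that("QTL merging applies the gap and LD rules", {
  eff <- tibble::tibble(marker = c("s1", "s2"))
  map <- mk_map(c(s1 = 10, s2 = 13))
  # 3 cM apart, r2 0.50 > 0.33: one QTL of 2 members
  q1 <- merge_into_qtls(eff, map, ld = const_ld(0.50), threshold = 0.33)
  expect_equal(nrow(q1), 1)
  expect_equal(q1$n_members, 2L)
  expect_equal(c(q1$start_cm, q1$end_cm), c(10, 13))
  # 6 cM apart: two singletons regardless of LD
  map2 <- mk_map(c(s1 = 10, s2 = 16))
  q2 <- merge_into_qtls(eff, map2, ld = const_ld(0.99), threshold = 0.33)
  expect_equal(nrow(q2), 2)
  expect_true(all(q2$n_members == 1L))
  # 3 cM apart but r2 0.10 < threshold: two singletons
  q3 <- merge_into_qtls(eff, map, ld = const_ld(0.10), threshold = 0.33)
  expect_equal(nrow(q3), 2)
  # unmapped SNPs become singleton QTLs
  eff4 <- tibble::tibble(marker = c("s1", "ghost"))
  q4 <- merge_into_qtls(eff4, map, ld = const_ld(1), threshold = 0)
  expect_equal(nrow(q4), 2)
  expect_true(any(is.na(q4$chrom)))
})

test_that("merging equals the connected-component oracle on small cases", {
  # independent oracle: components of the position-sorted adjacency graph
  oracle_groups <- function(pos, chrom, r2mat, thr, gap = 5) {
    n <- length(pos)
    comp <- seq_len(n)
    ord <- order(chrom, pos)
    for (k in seq_len(n - 1)) {
      i <- ord[k]; j <- ord[k + 1]
      if (chrom[i] == chrom[j] && pos[j] - pos[i] <= gap && r2mat[i, j] > thr) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
    sort(table(comp), decreasing = TRUE)
  }
  set.seed(99)
  for (case in 1:40) {
    n <- sample(2:10, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos <- round(runif(n, 0, 30), 1)
    while (anyDuplicated(paste(chrom, pos))) pos <- round(runif(n, 0, 30), 1)
    r2 <- matrix(runif(n * n), n, n); r2 <- (r2 + t(r2)) / 2
    mk <- sprintf("s%02d", 1:n)
    dimnames(r2) <- list(mk, mk)
    map <- tibble::tibble(marker = mk, chrom = chrom, pos_cm = pos)
    thr <- 0.33
    got <- merge_into_qtls(tibble::tibble(marker = mk), map,
                           ld = function(a, b) r2[a, b], threshold = thr)
    want <- oracle_groups(pos, chrom, r2, thr)
    expect_equal(sort(got$n_members, decreasing = TRUE),
                 unname(as.integer(want)))
    # partition: every SNP in exactly one QTL
    all_members <- unlist(lapply(got$members, function(g) g$marker))
    expect_setequal(all_members, mk)
    expect_equal(length(all_members), n)
  }
})

test_that("merging is invariant to SNP input order", {
  withr::with_seed(7, {
    mk <- sprintf("s%02d", 1:8)
    map <- tibble::tibble(marker = mk, chrom = rep(c("chr1", "chr2"), each = 4),
                          pos_cm = rep(c(0, 3, 9, 11), 2))
    r2 <- matrix(runif(64), 8, 8, dimnames = list(mk, mk))
    r2 <- (r2 + t(r2)) / 2
    e1 <- tibble::tibble(marker = mk)
    e2 <- tibble::tibble(marker = rev(mk))
    q1 <- merge_into_qtls(e1, map, ld = function(a, b) r2[a, b], threshold = 0.33)
    q2 <- merge_into_qtls(e2, map, ld = function(a, b) r2[a, b], threshold = 0.33)
    expect_equal(q1[c("chrom", "start_cm", "end_cm", "n_members")],
                 q2[c("chrom", "start_cm", "end_cm", "n_members")])
  })
})

test_that("favorable labelling distinguishes yes, no and mixed QTLs", {
  eff <- tibble::tibble(marker = c("s1", "s2", "s3", "s4"),
                        favorable_exotic = c(TRUE, TRUE, FALSE, TRUE))
  map <- mk_map(c(s1 = 0, s2 = 2, s3 = 20, s4 = 40))
  q <- merge_into_qtls(eff, map, ld = const_ld(1), threshold = 0.3)
  q <- label_favorable(q)
  expect_equal(q$favorable, c("yes", "no", "yes"))
  # conflicting members mark the QTL mixed
  eff2 <- tibble::tibble(marker = c("s1", "s2"),
                         favorable_exotic = c(TRUE, FALSE))
  q2 <- label_favorable(merge_into_qtls(eff2, mk_map(c(s1 = 0, s2 = 2)),
                                        ld = const_ld(1), threshold = 0.3))
  expect_equal(q2$favorable, "mixed")
})

test_that("long QTLs split into 5 cM bins", {
  eff <- tibble::tibble(marker = sprintf("s%d", 1:4))
  map <- mk_map(c(s1 = 0, s2 = 4, s3 = 8, s4 = 12))
  q <- merge_into_qtls(eff, map, ld = const_ld(1), threshold = 0.1)
  expect_equal(nrow(q), 1)
  qs <- split_qtls(q, 5)
  expect_equal(nrow(qs), 3)
  expect_true(all(qs$end_cm - qs$start_cm <= 5))
})

test_that("colocation compares intervals within the window", {
  qa <- merge_into_qtls(tibble::tibble(marker = "s1"), mk_map(c(s1 = 10)))
  qb <- merge_into_qtls(tibble::tibble(marker = "t1"), mk_map(c(t1 = 10)))
  r1 <- colocate(qa, qb)
  expect_equal(r1$status, "colocated")
  expect_equal(r1$distance_cm, 0)
  # same position, different chromosome: novel
  qc <- merge_into_qtls(tibble::tibble(marker = "u1"),
                        mk_map(c(u1 = 10), chrom = "chr2"))
  expect_equal(colocate(qa, qc)$status, "novel")
  # intervals [10,12] and [16,18]: gap 4 <= 5 -> colocated
  qa2 <- merge_into_qtls(tibble::tibble(marker = c("s1", "s2")),
                         mk_map(c(s1 = 10, s2 = 12)), ld = const_ld(1),
                         threshold = 0)
  qb2 <- merge_into_qtls(tibble::tibble(marker = c("t1", "t2")),
                         mk_map(c(t1 = 16, t2 = 18)), ld = const_ld(1),
                         threshold = 0)
  r2 <- colocate(qa2, qb2, window_cm = 5)
  expect_equal(r2$status, "colocated")
  expect_equal(r2$distance_cm, 4)
  expect_s3_class(attr(r2, "summary"), "tbl_df")
})
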