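toy_se <- function(counts, cond) {
  starts <- seq(1L, by = 1000L, length.out = nrow(counts))
  sites <- make_sites("chr1", starts, starts + 99L)
  methseek:::make_count_matrix(sites, counts, cond)
}

test_that("size factors are median-of-ratios against a geometric-mean reference", {
  # identical columns -> factors exactly 1
  m <- matrix(c(5L, 9L, 20L, 5L, 9L, 20L), ncol = 2L,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # column b = 2 * column a: geometric-mean reference splits the ratio
  m2 <- matrix(c(4L, 10L, 30L, 8L, 20L, 60L), ncol = 2L,
               dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # random positive matrices match the direct oracle
  set.seed(601)
  for (i in 1:10) {
    m <- matrix(rpois(200L, 40) + 1L, nrow = 50L,
                dimnames = list(NULL, paste0("s", 1:4)))
    expect_equal(unname(size_factors(m)), unname(oracle_size_factors(m)))
  }

  # all-zero row alone is fine, but no qualifying site is an error
  expect_error(size_factors(matrix(c(0L, 3L, 1L, 0L), 2L,
                                   dimnames = list(NULL, c("a", "b")))),
               "size factors are undefined")
})

test_that("size factors agree with the reference differential tool", {
  skip_if_not_installed("DESeq2")
  # odd number of all-positive sites: the median is an order statistic, so
  # the ratio-space median used here equals the reference tool's log-space
  # median exactly (exp is monotone); even counts differ by arithmetic-vs-
  # geometric averaging of the two middle ratios
  set.seed(602)
  m <- matrix(rpois(404L, 60) + 1L, nrow = 101L,
              dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("log2 fold changes are symmetric and strictly thresholded", {
  cond <- c(a1 = "M1", a2 = "M1", b1 = "M2", b2 = "M2")

  # equal group means -> log2fc 0, not flagged
  m <- matrix(rep(c(10L, 20L, 30L), 4L), ncol = 4L,
              dimnames = list(NULL, names(cond)))
  res <- log2fc_screen(toy_se(m, cond), numerator = "M1")
  expect_equal(res$log2fc, rep(0, 3L))
  expect_false(any(res$flagged))

  # meanA + pc exactly twice meanB + pc at one site -> log2fc exactly 1,
  # NOT flagged (strict threshold); two constant companion sites pin every
  # size factor at exactly 1 so normalized counts equal raw counts
  m <- matrix(c(19L, 10L, 40L, 19L, 10L, 40L, 9L, 10L, 40L, 9L, 10L, 40L),
              ncol = 4L, dimnames = list(NULL, names(cond)))
  res <- log2fc_screen(toy_se(m, cond), numerator = "M1", pseudocount = 1)
  expect_equal(res$log2fc, c(1, 0, 0))
  expect_false(any(res$flagged))

  # swapping the numerator negates log2fc and keeps flags
  set.seed(603)
  m <- matrix(rpois(40L, 25) + 1L, ncol = 4L,
              dimnames = list(NULL, names(cond)))
  r1 <- log2fc_screen(toy_se(m, cond), numerator = "M1")
  r2 <- log2fc_screen(toy_se(m, cond), numerator = "M2")
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_identical(r1$flagged, r2$flagged)

  # a condition with no samples is an error
  expect_error(log2fc_screen(toy_se(m, cond), numerator = "M3"),
               "0 samples")
})

test_that("scaling one sample rescales its relative factor and keeps fold changes", {
  # size factors are defined up to one common constant (the geometric-mean
  # reference absorbs c^(1/m) of any single-sample scaling), so the exact
  # invariants are on factor ratios and on ratios of normalized group means
  set.seed(604)
  cond <- setNames(rep(c("M1", "M2"), each = 2L), paste0("s", 1:4))
  m <- matrix(rpois(200L, 50) + 1L, ncol = 4L,
              dimnames = list(NULL, names(cond)))
  base_f <- size_factors(m)
  base_r <- log2fc_screen(toy_se(m, cond), numerator = "M1")
  for (c_scale in c(0.5, 2, 10)) {
    m2 <- m
    m2[, 2L] <- m[, 2L] * c_scale
    f <- size_factors(m2)
    # the scaled sample's factor, relative to every other sample, gains c
    expect_equal(unname(f[2L] / f[-2L]),
                 unname(base_f[2L] / base_f[-2L]) * c_scale,
                 tolerance = 1e-9)
    # unscaled samples keep their relative factors
    expect_equal(unname(f[3L] / f[c(1L, 4L)]),
                 unname(base_f[3L] / base_f[c(1L, 4L)]), tolerance = 1e-9)
    # the normalized fold change (ratio of group means) is exactly invariant
    r <- log2fc_screen(toy_se(m2, cond), numerator = "M1")
    expect_equal(log2(r$mean_A / r$mean_B),
                 log2(base_r$mean_A / base_r$mean_B), tolerance = 1e-9)
  }
})

test_that("permutation p-values enumerate label splits and are reproducible", {
  cond <- c(a1 = "M1", a2 = "M1", b1 = "M2", b2 = "M2")

  # identical counts at every sample -> every split ties -> p = 1
  m <- matrix(rep(7L, 8L), ncol = 4L, dimnames = list(NULL, names(cond)))
  p <- permutation_test(toy_se(m, cond), numerator = "M1")
  expect_equal(p, rep(1, 2L))

  # 2v2: exactly choose(4,2)=6 splits; hand-enumerate a toy site
  m <- matrix(c(100L, 90L, 10L, 12L), ncol = 4L,
              dimnames = list(NULL, names(cond)))
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  splits <- combn(4L, 2L)
  null_stats <- apply(splits, 2L, function(ia)
    abs(log2((mean(norm[1L, ia]) + 1) / (mean(norm[1L, -ia]) + 1))))
  obs <- null_stats[1L]  # first split is the observed labeling (a1, a2)
  want <- (1 + sum(null_stats >= obs - 1e-12)) / (1 + length(null_stats))
  expect_equal(permutation_test(toy_se(m, cond), numerator = "M1"), want)
  expect_true(want %in% ((1:6 + 1) / 7))

  # random-draw branch: same seed -> identical p-values
  set.seed(605)
  cond8 <- setNames(rep(c("M1", "M2"), each = 4L), paste0("s", 1:8))
  m8 <- matrix(rpois(80L, 30) + 1L, ncol = 8L,
               dimnames = list(NULL, names(cond8)))
  p1 <- permutation_test(toy_se(m8, cond8), numerator = "M1",
                         n_permutations = 25L, seed = 99L)
  p2 <- permutation_test(toy_se(m8, cond8), numerator = "M1",
                         n_permutations = 25L, seed = 99L)
  expect_identical(p1, p2)

  # fewer than 2 samples per group is an error
  cond3 <- c(a1 = "M1", b1 = "M2", b2 = "M2")
  m3 <- matrix(rpois(30L, 30) + 1L, ncol = 3L,
               dimnames = list(NULL, names(cond3)))
  expect_error(permutation_test(toy_se(m3, cond3), numerator = "M1"),
               ">= 2 samples")
})

test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(rep(0.2, 5L)), rep(0.2, 5L))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")

  set.seed(606)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))                       # adjusted >= raw
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order-preserving
  }
})

test_that("the DE filter keeps strict double-threshold rows in order", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    padj = c(0.04, 0.05, 0.01, 0.001),
                    log2fc = c(1.5, 3.0, -1.0, -2.2))
  kept <- apply_de_filter(tab)
  expect_identical(kept$gene, c("g1", "g4"))  # strict on both cutoffs
  expect_error(apply_de_filter(tab[, c("gene", "padj")]), "log2fc")
  expect_error(apply_de_filter(tab[, c("gene", "log2fc")]), "padj")
})

test_that("screen_sites combines fold change, permutation p and BH flags", {
  set.seed(607)
  cond <- setNames(rep(c("M1", "M2"), each = 3L), paste0("s", 1:6))
  m <- matrix(rpois(120L, 40) + 1L, ncol = 6L,
              dimnames = list(NULL, names(cond)))
  m[1L, 1:3] <- m[1L, 1:3] * 20L  # one strongly enriched site
  res <- screen_sites(toy_se(m, cond), numerator = "M1", seed = 3L)
  expect_named(res, c("site", "mean_A", "mean_B", "log2fc", "perm_p",
                      "padj", "flagged"))
  expect_equal(res$padj, bh_adjust(res$perm_p))
  expect_identical(res$flagged,
                   res$padj < 0.05 & abs(res$log2fc) > 1.0)
  expect_true(res$log2fc[1L] > 1)

  # without permutations the flag is the fold-change criterion alone
  res2 <- screen_sites(toy_se(m, cond), numerator = "M1",
                       with_permutations = FALSE)
  expect_identical(res2$flagged, abs(res2$log2fc) > 1.0)
})
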