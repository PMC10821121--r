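test_that("Chao1 follows the singleton/doubleton formula and its bounds", {
  expect_equal(chao1(c(5, 3, 4)), 3)                 # F1 = 0
  expect_equal(chao1(c(5, 1, 1, 2)), 4 + 4 / 2)      # F2 > 0 branch
  expect_equal(chao1(c(1, 1, 0)), 2 + 2 * 1 / 2)     # F2 = 0 fallback
  expect_equal(chao1(integer(0)), 0)
  expect_equal(chao1(c(0, 0, 0)), 0)
  expect_error(chao1(c(-1, 2)), "non-negative")

  # bias-corrected variant agrees with vegan's estimator
  set.seed(21)
  for (i in 1:20) {
    x <- rpois(30, 1.2)
    if (sum(x) == 0) next
    expect_gte(chao1(x), sum(x > 0))
    vg <- unname(vegan::estimateR(x)["S.chao1"])
    expect_equal(chao1(x, bias_corrected = TRUE), vg, tolerance = 1e-8)
  }
})

test_that("Shannon and Gini-Simpson match hand values and vegan", {
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(shannon_index(c(0, 9, 0)), 0)
  expect_equal(shannon_index(c(1, 3)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_equal(shannon_index(c(1, 3)), 0.5623, tolerance = 1e-4)

  expect_equal(gini_simpson(c(4)), 0)
  expect_equal(gini_simpson(rep(1, 8)), 1 - 1 / 8)
  expect_equal(gini_simpson(c(1, 1, 2)), 0.625)

  set.seed(22)
  for (i in 1:25) {
    x <- rpois(20, 3) + (i %% 2)  # mix of sparse and dense
    if (sum(x) == 0) next
    expect_equal(shannon_index(x), unname(vegan::diversity(x, "shannon")),
                 tolerance = 1e-10)
    expect_equal(gini_simpson(x), unname(vegan::diversity(x, "simpson")),
                 tolerance = 1e-10)
  }
})

test_that("alpha_diversity tabulates all samples and respects invariants", {
  set.seed(23)
  m <- random_counts(6, 25, lambda = 2)
  a <- alpha_diversity(m)
  expect_identical(a$sample_id, rownames(m))
  expect_true(all(a$chao1 >= rowSums(m > 0)))
  expect_true(all(a$shannon >= 0))
  expect_true(all(a$gini_simpson >= 0 & a$gini_simpson < 1))
})

test_that("Jaccard, Bray-Curtis and Aitchison match definitions and vegan", {
  expect_equal(jaccard_distance(c("x", "y"), c("x", "y")), 0)
  expect_equal(jaccard_distance(c("x"), c("y")), 1)
  expect_equal(jaccard_distance(c("x", "y", "z"), c("y", "z", "w")), 0.5)
  expect_message(j0 <- jaccard_distance(character(), character()), "empty")
  expect_equal(j0, 0)

  x <- c(0.5, 0.5, 0); y <- c(0.25, 0.25, 0.5)
  expect_equal(bray_curtis(x, x), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(x, y), 0.5)

  expect_equal(aitchison_distance(c(0, 0), c(1, -1)), sqrt(2))
  expect_error(aitchison_distance(c(1, 2), c(1, 2, 3)), "length")

  set.seed(24)
  for (i in 1:20) {
    cx <- rpois(15, 4); cy <- rpois(15, 4)
    px <- cx / sum(cx); py <- cy / sum(cy)
    expect_equal(bray_curtis(px, py),
                 as.numeric(vegan::vegdist(rbind(px, py), "bray")),
                 tolerance = 1e-10)
    sx <- paste0("t", which(cx > 0)); sy <- paste0("t", which(cy > 0))
    expect_equal(jaccard_distance(sx, sy),
                 as.numeric(vegan::vegdist(rbind(cx, cy), "jaccard",
                                           binary = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(25)
  m <- random_counts(5, 20, lambda = 3) + 1L
  ids <- sprintf("asv%d", 1:20)
  tree <- fmtengraft:::with_seed(1, simulate_tree(ids))
  for (metric in c("jaccard", "bray_curtis", "aitchison", "unifrac")) {
    d <- distance_matrix(m, metric, tree = tree)
    expect_identical(dim(d), c(5L, 5L))
    expect_true(all(abs(d - t(d)) < 1e-12))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    if (metric != "aitchison") expect_true(all(d <= 1 + 1e-12))
  }
  expect_error(distance_matrix(m, "unifrac"), "tree")
})

test_that("weighted UniFrac matches hand computation on a two-leaf tree", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  x <- c(A = 10, B = 0)
  y <- c(A = 0, B = 5)
  expect_equal(weighted_unifrac(x, x, tree), 0)
  expect_equal(weighted_unifrac(x, y, tree, normalized = FALSE), 2)
  expect_equal(weighted_unifrac(x, y, tree, normalized = TRUE), 1)
  expect_equal(unifrac_similarity(x, y, tree), 0)
  expect_error(weighted_unifrac(c(A = 1, C = 1), y, tree), "absent")
})

test_that("weighted UniFrac equals the exhaustive branch-set oracle and is scale-invariant", {
  set.seed(26)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    ids <- sprintf("t%02d", seq_len(n))
    tree <- simulate_tree(ids)
    x <- setNames(rpois(n, 3), ids)
    y <- setNames(rpois(n, 3), ids)
    if (sum(x) == 0 || sum(y) == 0) next
    for (norm in c(TRUE, FALSE)) {
      expect_equal(weighted_unifrac(x, y, tree, normalized = norm),
                   bf_weighted_unifrac(x, y, tree, normalized = norm),
                   tolerance = 1e-8)
    }
    d <- weighted_unifrac(x, y, tree)
    expect_gte(d, 0); expect_lte(d, 1 + 1e-12)
    # invariant to rescaling either sample (depth independence)
    expect_equal(weighted_unifrac(x * 17, y * 3, tree), d, tolerance = 1e-12)
  }
})
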