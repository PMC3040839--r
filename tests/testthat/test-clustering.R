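test_that("degenerate and hand-checkable inputs cluster correctly", {
  # zero dispersion: every merge at height 0
  tr <- ward_merge_tree(rep(3.2, 5))
  expect_equal(tr$height, rep(0, 4))
  expect_equal(trimmed_max_height(tr)$stat, 0)

  # two tight pairs: first merges at 0, root joins them at the oracle height
  x <- c(0, 0, 10, 10)
  tr <- ward_merge_tree(x)
  expect_equal(sort(tr$height)[1:2], c(0, 0))
  om <- oracle_ward_d2(x)
  expect_equal(max(tr$height), max(vapply(om, function(m) m$height, 0)),
               tolerance = 1e-12)
  # root joins {1,2} with {3,4}
  expect_setequal(tr$left_members[[3]], 1:2)
  expect_setequal(tr$right_members[[3]], 3:4)
})

test_that("merge heights are permutation-invariant and monotone", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rnorm(sample(4:12, 1))
    tr <- ward_merge_tree(x)
    expect_true(all(diff(tr$height) >= -1e-10))  # Ward reducibility
    perm <- sample(length(x))
    expect_equal(sort(ward_merge_tree(x[perm])$height), sort(tr$height),
                 tolerance = 1e-10)
  }
})

test_that("merge trees match hclust for both height conventions", {
  set.seed(11)
  for (rep in 1:25) {
    x <- rnorm(sample(4:20, 1), sd = runif(1, 0.1, 3))
    for (v in c("D2", "D")) {
      tr <- ward_merge_tree(x, v)
      hc <- hclust(dist(x), method = paste0("ward.", v))
      expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-9)
    }
  }
})

test_that("tree and trimmed statistic equal the exhaustive greedy ESS oracle", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(4:8, 1)
    x <- rnorm(n, sd = runif(1, 0.2, 2))
    tr <- ward_merge_tree(x)
    om <- oracle_ward_d2(x)
    expect_equal(sort(tr$height),
                 sort(vapply(om, function(m) m$height, 0)),
                 tolerance = 1e-10)
    expect_equal(trimmed_max_height(tr)$stat, oracle_trimmed_stat(x, om),
                 tolerance = 1e-10)
  }
})

test_that("extreme-singleton trimming drops outlier merges but keeps true splits", {
  # a single high outlier: its (root) merge is excluded, leaving only the
  # small within-cluster heights
  x <- c(0.00, 0.05, -0.05, 0.10, 8.0)
  tr <- ward_merge_tree(x)
  tm <- trimmed_max_height(tr)
  expect_false(tm$degenerate)
  expect_lt(tm$stat, 1)              # well below the excluded root height
  expect_gt(max(tr$height), 10)
  expect_equal(tm$stat, oracle_trimmed_stat(x), tolerance = 1e-12)

  # two groups of three: no root child is an extreme singleton, so the
  # trimmed statistic is the untrimmed maximum (the gap itself)
  y <- c(0, 0.1, -0.1, 6, 6.1, 5.9)
  ty <- ward_merge_tree(y)
  expect_equal(trimmed_max_height(ty)$stat, max(ty$height))
})

test_that("edge-leaf trimming generalizes and flags degenerate cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  tr <- ward_merge_tree(x)
  p0 <- trim_policy("edge_leaves_k", 0L)   # trimming disabled
  expect_equal(trimmed_max_height(tr, policy = p0)$stat, max(tr$height))
  expect_error(trimmed_max_height(tr, policy = trim_policy("edge_leaves_k", 3L)),
               "k < n/2")
  # n = 4 with k = 1: some merges survive
  t4 <- ward_merge_tree(c(1, 2, 3, 4))
  expect_false(trimmed_max_height(t4, policy = trim_policy("edge_leaves_k", 1L))$degenerate)
})

test_that("the statistic is affine-equivariant and nonnegative", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rnorm(sample(5:15, 1))
    a <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    b <- rnorm(1, sd = 5)
    s1 <- trimmed_max_height(ward_merge_tree(x))$stat
    s2 <- trimmed_max_height(ward_merge_tree(a * x + b))$stat
    expect_gte(s1, 0)
    expect_equal(s2, abs(a) * s1, tolerance = 1e-9)
  }
})

test_that("widening a planted gap never shrinks the statistic", {
  set.seed(19)
  noise <- rnorm(15, sd = 0.5)
  grp <- rep(c(0, 1), c(10, 5))
  stats <- vapply(seq(0, 8, by = 0.5), function(gap) {
    trimmed_max_height(ward_merge_tree(noise + gap * grp))$stat
  }, numeric(1L))
  expect_true(all(diff(stats) >= -1e-9))
})
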