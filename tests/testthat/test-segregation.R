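test_that("contingency tables build from labels and reject mismatches", {
  g <- c(i1 = "hom_1G", i2 = "het", i3 = "hom_2G")
  cl <- c(i1 = "low", i2 = "high", i3 = "high")
  tab <- build_contingency(g, cl)
  expect_equal(tab$counts["hom_1G", "low"], 1L)
  expect_equal(tab$counts["het", "high"], 1L)
  expect_equal(tab$counts["hom_2G", "high"], 1L)
  expect_equal(sum(tab$counts), 3L)

  expect_error(build_contingency(character(0), character(0)), "empty")
  expect_error(build_contingency(g, cl[-2]), "i2")

  # invariant to permuting individual order
  perm <- c("i3", "i1", "i2")
  expect_equal(build_contingency(g[perm], cl[perm])$counts, tab$counts)
})

test_that("the 69-donor promoter-polymorphism fixture reproduces the published margins", {
  path <- system.file("extdata", "mmp1_segregation.tsv", package = "bimodr")
  df <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 69L)
  tab <- build_contingency(structure(df$genotype, names = df$individual_id),
                           structure(df$class, names = df$individual_id))
  expect_equal(unname(rowSums(tab$counts)[c("hom_1G", "hom_2G", "het")]),
               c(11L, 6L, 52L))
  expect_equal(unname(colSums(tab$counts)[c("high", "low")]), c(57L, 12L))
})

test_that("dominant-high concordance counts misclassified individuals", {
  tab <- segregation_table(matrix(c(0L, 5L, 52L, 11L, 1L, 0L), ncol = 2,
    dimnames = list(c("hom_1G", "hom_2G", "het"), c("high", "low"))))
  conc <- concordance(tab, "dominant_high", hom_high = "hom_2G",
                      het = "het", hom_low = "hom_1G")
  expect_equal(conc$misclassified, 1L)
  expect_equal(conc$total, 69L)
  expect_equal(conc$concordant_fraction, 1 - 1 / 69)

  perfect <- segregation_table(matrix(c(0L, 4L, 6L, 5L, 0L, 0L), ncol = 2,
    dimnames = list(c("hom_1G", "hom_2G", "het"), c("high", "low"))))
  expect_equal(concordance(perfect, "dominant_high", "hom_2G", "het",
                           "hom_1G")$misclassified, 0L)

  # recessive model cross-checked by enumerating individuals directly
  rec <- concordance(tab, "recessive_high", hom_high = "hom_2G",
                     het = "het", hom_low = "hom_1G")
  expected <- 0L
  for (g in rownames(tab$counts)) {
    pred <- if (g == "hom_2G") "high" else "low"
    for (cl in c("high", "low"))
      if (cl != pred) expected <- expected + tab$counts[g, cl]
  }
  expect_equal(rec$misclassified, expected)
  expect_equal(rec$concordant_fraction, 1 - expected / 69)
})

test_that("exact association p matches hypergeometric enumeration", {
  perfect <- matrix(c(5L, 0L, 0L, 5L), 2, 2)
  expect_equal(exact_association_p(perfect), oracle_fisher(perfect),
               tolerance = 1e-10)
  expect_equal(exact_association_p(matrix(c(2L, 2L, 2L, 2L), 2, 2)), 1)
  expect_equal(exact_association_p(matrix(c(0L, 0L, 3L, 4L), 2, 2)), 1)
  set.seed(41)
  for (rep in 1:25) {
    tb <- matrix(rpois(4, 4), 2, 2)
    if (sum(tb) == 0 || any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(exact_association_p(tb), oracle_fisher(tb),
                 tolerance = 1e-8)
  }
  expect_error(exact_association_p(matrix(c(1.5, 1, 1, 1), 2, 2)),
               "integer")
})

test_that("carrier collapse feeds the exact test with the right margins", {
  tab <- segregation_table(matrix(c(0L, 5L, 52L, 11L, 1L, 0L), ncol = 2,
    dimnames = list(c("hom_1G", "hom_2G", "het"), c("high", "low"))))
  two <- collapse_carriers(tab, "hom_2G", "het", "hom_1G")
  expect_equal(unname(two["carrier", ]), c(57L, 1L))
  expect_equal(unname(two["non_carrier", ]), c(0L, 11L))
  expect_lt(exact_association_p(two), 1e-8)
})
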