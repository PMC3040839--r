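#' Genotype-by-expression-class contingency table
#'
#' Counts of individuals cross-classified by promoter genotype category
#' (e.g. `hom_1G`, `het`, `hom_2G` for a biallelic insertion/deletion
#' polymorphism) and basal expression class (`high` / `low`).
#'
#' @param counts integer matrix, genotype categories in rows, expression
#'   classes (`"high"`, `"low"`) in columns.
#' @return object of class `segregation_table`.
#' @examples
#' segregation_table(matrix(c(0, 5, 52, 11, 1, 0), ncol = 2,
#'   dimnames = list(c("hom_1G", "hom_2G", "het"), c("high", "low"))))
#' @export
segregation_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have genotype rownames and class colnames")
  if (!setequal(colnames(counts), c("high", "low")))
    stop('expression classes must be exactly "high" and "low"')
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  counts <- counts[, c("high", "low"), drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts), class = "segregation_table")
}

#' @export
print.segregation_table <- function(x, ...) {
  m <- x$counts
  disp <- cbind(m, Total = rowSums(m))
  disp <- rbind(disp, Total = colSums(disp))
  cat("genotype x expression-class segregation\n")
  print(disp)
  invisible(x)
}

#' Cross-tabulate individual genotype and expression-class labels
#'
#' @param genotypes named vector: individual ID -> genotype category.
#' @param classes named vector: individual ID -> `"high"` or `"low"`.
#'   Both maps must cover exactly the same individuals.
#' @return a [segregation_table()].
#' @export
build_contingency <- function(genotypes, classes) {
  if (!length(genotypes) || !length(classes)) stop("empty input")
  if (is.null(names(genotypes)) || is.null(names(classes)))
    stop("genotypes and classes must be named by individual ID")
  miss_c <- setdiff(names(genotypes), names(classes))
  miss_g <- setdiff(names(classes), names(genotypes))
  if (length(miss_c) || length(miss_g))
    stop("individuals missing a label: ",
         paste(c(miss_c, miss_g), collapse = ", "))
  if (!all(classes %in% c("high", "low")))
    stop('expression classes must be "high" or "low"')
  classes <- classes[names(genotypes)]
  tab <- table(genotype = factor(genotypes),
               class = factor(classes, levels = c("high", "low")))
  segregation_table(unclass(as.matrix(tab)))
}

#' Concordance of observed expression class with a genotype model
#'
#' Predicts each individual's expression class from genotype under a
#' single-locus model — `dominant_high`: any carrier of the high allele
#' (heterozygote or high-allele homozygote) is predicted high;
#' `recessive_high`: only high-allele homozygotes are predicted high —
#' and counts the individuals whose observed class disagrees.
#'
#' @param table a [segregation_table()].
#' @param model `"dominant_high"` or `"recessive_high"`.
#' @param hom_high,het,hom_low row names of the table holding the
#'   high-allele homozygotes, heterozygotes and low-allele homozygotes.
#' @return list with `misclassified`, `total` and `concordant_fraction`.
#' @examples
#' tab <- segregation_table(matrix(c(0, 5, 52, 11, 1, 0), ncol = 2,
#'   dimnames = list(c("hom_1G", "hom_2G", "het"), c("high", "low"))))
#' concordance(tab, "dominant_high", hom_high = "hom_2G", het = "het",
#'             hom_low = "hom_1G")
#' @export
concordance <- function(table, model = c("dominant_high", "recessive_high"),
                        hom_high, het, hom_low) {
  model <- match.arg(model)
  stopifnot(inherits(table, "segregation_table"))
  m <- table$counts
  cats <- c(hom_high, het, hom_low)
  if (!all(cats %in% rownames(m)))
    stop("unknown genotype categories: ",
         paste(setdiff(cats, rownames(m)), collapse = ", "))
  predicted_high <- if (model == "dominant_high") c(hom_high, het)
                    else hom_high
  mis <- 0L
  for (g in rownames(m)) {
    pred <- if (g %in% predicted_high) "high" else "low"
    obs_other <- setdiff(c("high", "low"), pred)
    mis <- mis + m[g, obs_other]
  }
  total <- sum(m)
  list(misclassified = as.integer(mis), total = as.integer(total),
       concordant_fraction = 1 - mis / total)
}

#' Collapse a segregation table to carriers vs non-carriers
#'
#' @inheritParams concordance
#' @return 2x2 integer matrix (carrier/non_carrier x high/low).
#' @export
collapse_carriers <- function(table, hom_high, het, hom_low) {
  stopifnot(inherits(table, "segregation_table"))
  m <- table$counts
  rbind(carrier = colSums(m[c(hom_high, het), , drop = FALSE]),
        non_carrier = m[hom_low, ])
}

#' Two-sided Fisher exact test of a 2x2 segregation table
#'
#' Exact hypergeometric p-value for association between carrier status and
#' expression class — the natural quantitative companion to a descriptive
#' segregation table.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
exact_association_p <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  fisher.test(table)$p.value
}
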