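#' Trimming policy for the branch-height statistic
#'
#' Controls which merges are discarded before taking the maximum branch
#' height, so that a single outlying individual cannot masquerade as a
#' second expression mode.
#'
#' * `extreme_singleton` (default): discard every merge one of whose
#'   children is a singleton holding the sample minimum or maximum (ties
#'   resolved to the lowest individual index).  At most two merges are
#'   removed, and a genuine two-cluster split (both root children holding
#'   two or more individuals) is always retained.
#' * `edge_leaves_k`: discard merges attaching, as a singleton, any of the
#'   `k` lowest- or `k` highest-valued individuals.  `k = 0` disables
#'   trimming entirely; useful for sensitivity analysis.
#'
#' @param mode `"extreme_singleton"` or `"edge_leaves_k"`.
#' @param k nonnegative integer, only used by `edge_leaves_k`; must satisfy
#'   `k < n/2` at the time the policy is applied.
#' @return an object of class `trim_policy`.
#' @export
trim_policy <- function(mode = c("extreme_singleton", "edge_leaves_k"), k = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be a nonnegative integer")
  structure(list(mode = mode, k = k), class = "trim_policy")
}

ward_variant_code <- function(variant) {
  variant <- match.arg(variant, c("D2", "D"))
  if (variant == "D2") 0L else 1L
}

trim_mode_code <- function(policy) {
  if (policy$mode == "extreme_singleton") 0L else 1L
}

#' Ward agglomeration of one transcript's expression values
#'
#' Builds the full agglomerative merge tree of `n` one-dimensional values:
#' starting from `n` singleton clusters, repeatedly merge the pair
#' minimizing the Ward criterion, with pairwise dissimilarity between
#' individuals `|x_i - x_j|` and cluster distances updated by the
#' Lance-Williams recurrence.  The default `"D2"` height convention is the
#' minimum-variance form (recurrence on squared distances, heights reported
#' on the original scale, as in `hclust(method = "ward.D2")`); `"D"` applies
#' the recurrence to the raw distances.  Equal-cost candidate merges are
#' broken deterministically towards the smallest pair of minimum member
#' indices.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param variant `"D2"` (default) or `"D"`.
#' @return an object of class `merge_tree`: a list with `n`, `values`,
#'   `variant`, the `n - 1` row `merge` matrix in `hclust` convention
#'   (negative entries are leaves), the merge `height` vector, and
#'   `left_members` / `right_members`, lists giving the individual indices
#'   in each child of each merge.
#' @examples
#' tr <- ward_merge_tree(c(0, 0.1, 5, 5.2, 5.1))
#' tr$height
#' @export
ward_merge_tree <- function(values, variant = c("D2", "D")) {
  vcode <- ward_variant_code(match.arg(variant))
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to cluster")
  if (any(!is.finite(values))) stop("non-finite value in input")
  raw <- ward_tree_cpp(values, vcode)
  members <- vector("list", n - 1L)
  lm <- vector("list", n - 1L)
  rm_ <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    lm[[s]] <- merge_members(raw$merge[s, 1L], members)
    rm_[[s]] <- merge_members(raw$merge[s, 2L], members)
    members[[s]] <- sort(c(lm[[s]], rm_[[s]]))
  }
  structure(list(n = n, values = values,
                 variant = if (vcode == 0L) "D2" else "D",
                 merge = raw$merge, height = raw$height,
                 left_members = lm, right_members = rm_),
            class = "merge_tree")
}

merge_members <- function(code, members) {
  if (code < 0L) -code else members[[code]]
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("Ward merge tree (%s): %d individuals, %d merges\n",
              x$variant, x$n, x$n - 1L))
  cat("heights:", paste(signif(x$height, 4), collapse = " "), "\n")
  invisible(x)
}

#' Convert a merge tree to an `hclust` object (e.g. for dendrogram plots)
#' @param x a `merge_tree`.
#' @param ... ignored.
#' @return an object of class `hclust`.
#' @export
as.hclust.merge_tree <- function(x, ...) {
  # leaf order by recursive left-to-right traversal of the merge matrix
  ord <- function(code) {
    if (code < 0L) return(-code)
    c(ord(x$merge[code, 1L]), ord(x$merge[code, 2L]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = ord(x$n - 1L),
                 labels = as.character(seq_len(x$n)),
                 method = paste0("ward.", x$variant),
                 dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' Trimmed maximum branch height
#'
#' The bimodality statistic: the largest merge height remaining after
#' discarding merges attributable to single extreme individuals under the
#' given [trim_policy()].  If no merges remain the statistic is 0 and the
#' transcript is flagged degenerate.
#'
#' @param tree a [ward_merge_tree()] result.
#' @param values the vector the tree was built from; defaults to
#'   `tree$values`.
#' @param policy a [trim_policy()].
#' @return list with elements `stat` (nonnegative) and `degenerate`
#'   (logical).
#' @export
trimmed_max_height <- function(tree, values = tree$values,
                               policy = trim_policy()) {
  stopifnot(inherits(tree, "merge_tree"), inherits(policy, "trim_policy"))
  values <- as.numeric(values)
  if (length(values) != tree$n)
    stop("values length does not match the tree")
  n <- tree$n
  if (policy$mode == "extreme_singleton") {
    excluded <- unique(c(which.min(values), which.max(values)))
  } else {
    if (policy$k >= n / 2)
      stop("edge_leaves_k requires k < n/2")
    o <- order(values, seq_len(n))
    excluded <- unique(c(head(o, policy$k), head(rev(o), policy$k)))
  }
  keep <- vapply(seq_len(n - 1L), function(s) {
    l <- tree$left_members[[s]]
    r <- tree$right_members[[s]]
    !((length(l) == 1L && l %in% excluded) ||
        (length(r) == 1L && r %in% excluded))
  }, logical(1L))
  if (!any(keep)) return(list(stat = 0, degenerate = TRUE))
  list(stat = max(tree$height[keep]), degenerate = FALSE)
}
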