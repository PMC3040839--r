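# Independent oracles, deliberately written with none of the package's
# machinery: an exhaustive greedy minimum-variance agglomerator working
# directly from within-cluster sums of squares, plus direct-formula
# references for BH adjustment and the hypergeometric exact test.

# Exhaustive greedy Ward (minimum-variance) agglomeration: at every step
# compute, for every candidate pair, the increase in total within-cluster
# ESS from scratch, and merge the cheapest pair.  Heights follow the
# minimum-variance convention: h = sqrt(2 * delta-ESS), which for two
# singletons reduces to |x_i - x_j|.
oracle_ward_d2 <- function(x) {
  ess <- function(idx) {
    v <- x[idx]
    sum((v - mean(v))^2)
  }
  clusters <- as.list(seq_along(x))
  merges <- vector("list", length(x) - 1L)
  for (s in seq_len(length(x) - 1L)) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best) {
          best <- cost
          bi <- i
          bj <- j
        }
      }
    }
    merges[[s]] <- list(left = clusters[[bi]], right = clusters[[bj]],
                        height = sqrt(2 * max(best, 0)))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  merges
}

# Trimmed max height from the oracle agglomeration, re-deriving the
# extreme-singleton rule from first principles.
oracle_trimmed_stat <- function(x, merges = oracle_ward_d2(x)) {
  excl <- c(which.min(x), which.max(x))
  keep <- vapply(merges, function(m) {
    !((length(m$left) == 1L && m$left %in% excl) ||
        (length(m$right) == 1L && m$right %in% excl))
  }, logical(1L))
  if (!any(keep)) return(0)
  max(vapply(merges[keep], function(m) m$height, numeric(1L)))
}

# Benjamini-Hochberg step-up, straight from the formula:
# adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  pmin(adj, 1)[order(o)]
}

# Two-sided Fisher exact p by full enumeration of tables with the observed
# margins, summing the probabilities of all tables no more probable than
# the observed one.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1L))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small helper: an expression matrix of i.i.d. null-normal transcripts.
null_matrix <- function(nt, n, seed, mean = 6, sd = 0.8) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(nt * n, mean, sd), nt, n),
                    sprintf("t%03d", seq_len(nt)),
                    sprintf("s%02d", seq_len(n)))
}
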