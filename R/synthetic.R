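#' Describe a synthetic study: per-transcript generative truth
#'
#' Builds the per-transcript truth table for [simulate_matrix()].  Three
#' transcript labels are supported:
#'
#' * `null` — i.i.d. normal log-abundance, the single-population model the
#'   bootstrap assumes; each null transcript gets its own mean and sd drawn
#'   uniformly from `null_mean_range` / `null_sd_range`.
#' * `bimodal` — a two-component normal mixture.  The low-component mean is
#'   drawn from `null_mean_range` and the high component sits `separation`
#'   log2 units above it (default 6.64, i.e. just over 100-fold).  Class
#'   membership comes from `mixing`: `fixed_pi` (each individual high with
#'   probability `pi`), `hardy_weinberg` (biallelic genotype at high-allele
#'   frequency `allele_freq`; the high allele is dominant, so only
#'   homozygous low-allele individuals are in the low class), or `fixed_k`
#'   (exactly `k_high` individuals high — useful for planted, deterministic
#'   splits).
#' * `outlier` — a null transcript with a single individual displaced by
#'   `outlier_offset` standard deviations: the failure mode the trimming
#'   policy exists to reject.
#'
#' @param n_null,n_bimodal,n_outlier transcript counts per label.
#' @param null_mean_range,null_sd_range uniform ranges for null/outlier
#'   parameters (log2-scale units).
#' @param separation between-component distance in log2 units.
#' @param bimodal_sd shared within-component sd for bimodal transcripts.
#' @param mixing `"fixed_pi"`, `"hardy_weinberg"` or `"fixed_k"`.
#' @param pi high-class probability for `fixed_pi`, in (0, 1).
#' @param allele_freq high-allele frequency q for `hardy_weinberg`, in
#'   (0, 1); expected low-class fraction is `(1 - q)^2`.
#' @param k_high high-class count for `fixed_k`.
#' @param outlier_offset displacement of the outlying individual, in units
#'   of that transcript's sd.
#' @param seed optional seed for the parameter draws.
#' @return data frame of class `synthetic_truth`, one row per transcript.
#' @export
synthetic_truth <- function(n_null = 0L, n_bimodal = 0L, n_outlier = 0L,
                            null_mean_range = c(4, 12),
                            null_sd_range = c(0.2, 1),
                            separation = 6.64, bimodal_sd = 0.5,
                            mixing = c("fixed_pi", "hardy_weinberg",
                                       "fixed_k"),
                            pi = 0.3, allele_freq = 0.4, k_high = NULL,
                            outlier_offset = 8, seed = NULL) {
  mixing <- match.arg(mixing)
  nt <- n_null + n_bimodal + n_outlier
  if (nt < 1L) stop("need at least one transcript")
  if (bimodal_sd <= 0 || any(null_sd_range <= 0)) stop("sd must be positive")
  if (mixing == "fixed_pi" && (pi <= 0 || pi >= 1))
    stop("pi must be in (0, 1)")
  if (mixing == "hardy_weinberg" && (allele_freq <= 0 || allele_freq >= 1))
    stop("allele_freq must be in (0, 1)")
  if (mixing == "fixed_k" && is.null(k_high))
    stop("fixed_k mixing needs k_high")
  if (!is.null(seed)) set.seed(as.integer(seed))

  label <- rep(c("null", "bimodal", "outlier"),
               c(n_null, n_bimodal, n_outlier))
  mu <- runif(nt, null_mean_range[1L], null_mean_range[2L])
  s <- runif(nt, null_sd_range[1L], null_sd_range[2L])
  truth <- data.frame(
    transcript_id = sprintf("tr%05d", seq_len(nt)),
    label = label,
    mean = ifelse(label == "bimodal", NA_real_, mu),
    sd = ifelse(label == "bimodal", bimodal_sd, s),
    mu_low = ifelse(label == "bimodal", mu, NA_real_),
    mu_high = ifelse(label == "bimodal", mu + separation, NA_real_),
    mixing = ifelse(label == "bimodal", mixing, NA_character_),
    pi = ifelse(label == "bimodal" & mixing == "fixed_pi", pi, NA_real_),
    allele_freq = ifelse(label == "bimodal" & mixing == "hardy_weinberg",
                         allele_freq, NA_real_),
    k_high = ifelse(label == "bimodal" & mixing == "fixed_k",
                    if (is.null(k_high)) NA_integer_ else k_high,
                    NA_integer_),
    outlier_offset = ifelse(label == "outlier", outlier_offset, NA_real_),
    stringsAsFactors = FALSE)
  class(truth) <- c("synthetic_truth", "data.frame")
  truth
}

#' Simulate an expression matrix from a synthetic truth table
#'
#' Draws one value per transcript and individual according to the
#' transcript's generative label (see [synthetic_truth()]).  The returned
#' truth table is augmented with the realized class assignment per
#' transcript (`n_high`) and, for outlier transcripts, the index of the
#' displaced individual.
#'
#' @param truth a [synthetic_truth()] table.
#' @param n number of individuals, at least 4.
#' @param seed optional seed; fixed seed gives an identical matrix on
#'   re-run.
#' @return list with `matrix` (an [expression_matrix()]) and `truth` (the
#'   augmented truth table).
#' @examples
#' sim <- simulate_matrix(synthetic_truth(n_null = 3, n_bimodal = 1,
#'                                        seed = 1), n = 15, seed = 2)
#' sim$matrix
#' @export
simulate_matrix <- function(truth, n, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop("need n >= 4 individuals")
  bad_k <- truth$label == "bimodal" & !is.na(truth$k_high) &
    (truth$k_high < 0L | truth$k_high > n)
  if (any(bad_k)) stop("k_high outside 0..n")
  if (!is.null(seed)) set.seed(as.integer(seed))

  nt <- nrow(truth)
  vals <- matrix(NA_real_, nt, n)
  truth$n_high <- NA_integer_
  truth$outlier_index <- NA_integer_
  for (t in seq_len(nt)) {
    row <- truth[t, ]
    if (row$label == "bimodal") {
      high <- switch(row$mixing,
        fixed_pi = rbinom(n, 1L, row$pi) == 1L,
        hardy_weinberg = {
          # high-allele copies per individual; dominant high allele:
          # low class only when homozygous for the low allele
          copies <- rbinom(n, 2L, row$allele_freq)
          copies > 0L
        },
        fixed_k = seq_len(n) %in% sample.int(n, row$k_high))
      vals[t, ] <- rnorm(n, ifelse(high, row$mu_high, row$mu_low), row$sd)
      truth$n_high[t] <- sum(high)
    } else {
      vals[t, ] <- rnorm(n, row$mean, row$sd)
      if (row$label == "outlier") {
        idx <- sample.int(n, 1L)
        vals[t, idx] <- vals[t, idx] + row$outlier_offset * row$sd
        truth$outlier_index[t] <- idx
      }
    }
  }
  m <- expression_matrix(vals, truth$transcript_id,
                         sprintf("ind%02d", seq_len(n)))
  list(matrix = m, truth = truth)
}

#' Empirical type I error and power of the screen on simulated data
#'
#' Runs [bimodality_scan()] over `replicates` matrices simulated from the
#' given truth table and tabulates, per generative label, the fraction of
#' transcripts called at `config$alpha`: for null transcripts this is the
#' empirical type I error rate, for bimodal transcripts the power, and for
#' single-outlier transcripts the false-positive rate the trimming policy
#' is designed to suppress.
#'
#' @param truth a [synthetic_truth()] table.
#' @param n individuals per matrix.
#' @param config a [scan_config()]; its seed is overridden per replicate.
#' @param replicates number of simulated matrices.
#' @param seed master seed for the whole evaluation.
#' @return list with `type1_rate`, `power`, `outlier_fp_rate` (NA when the
#'   corresponding label is absent) and `table`, a per-replicate,
#'   per-label data frame of call fractions.
#' @export
estimate_error_rates <- function(truth, n, config = scan_config(),
                                 replicates = 1L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "scan_config"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  set.seed(as.integer(seed))
  repseeds <- matrix(sample.int(2147483646L, 2L * replicates), ncol = 2L)

  rows <- list()
  for (r in seq_len(replicates)) {
    sim <- simulate_matrix(truth, n, seed = repseeds[r, 1L])
    cfg <- config
    cfg$seed <- repseeds[r, 2L]
    res <- bimodality_scan(sim$matrix, cfg)
    hit <- res$p_max_height <= config$alpha
    lab <- sim$truth$label[match(res$transcript_id,
                                 sim$truth$transcript_id)]
    for (lv in unique(lab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, label = lv, n_transcripts = sum(lab == lv),
        n_called = sum(hit[lab == lv]),
        rate = mean(hit[lab == lv]), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rate_for <- function(lv) {
    sub <- tab[tab$label == lv, ]
    if (!nrow(sub)) return(NA_real_)
    sum(sub$n_called) / sum(sub$n_transcripts)
  }
  list(type1_rate = rate_for("null"), power = rate_for("bimodal"),
       outlier_fp_rate = rate_for("outlier"), table = tab)
}
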