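#' Configuration for a dataset-wide bimodality scan
#'
#' Defaults mirror the screen's standard operating point: 10,000 bootstrap
#' replicates per transcript, acceptance threshold `alpha = 0.1` on the
#' empirical p-value (an estimated type I error rate of 10%),
#' extreme-singleton trimming, the minimum-variance Ward height convention,
#' MLE standard deviation, plain `count / B` p-values, and no
#' multiple-testing adjustment (the adjustment does not change the
#' p-value ranking; see [adjust_bh()]).
#'
#' @param B bootstrap replicates per transcript.
#' @param seed master seed; per-transcript substream seeds are derived from
#'   it independently of the data, so scans are reproducible and the
#'   p-value of a transcript is unchanged by affine rescaling of its
#'   values.
#' @param alpha hit threshold on the empirical p-value, in `(0, 1]`.
#' @param trim a [trim_policy()].
#' @param ward_variant `"D2"` or `"D"`.
#' @param bh_adjust if `TRUE`, a Benjamini-Hochberg adjusted column `p_bh`
#'   is appended to scan results.
#' @param sd_denominator `"n"` or `"n_minus_1"` for the fitted null sd.
#' @param p_correction `"plain"` or `"plus_one"` (see [empirical_p()]).
#' @param comparison `"studentized"` (default; null datasets rescaled to
#'   the fitted sd, giving exactly calibrated p-values under normality) or
#'   `"raw"` (unconditional plug-in draws; conservative — see
#'   [null_stat_distribution()]).
#' @return object of class `scan_config`.
#' @export
scan_config <- function(B = 10000L, seed = 1L, alpha = 0.1,
                        trim = trim_policy(),
                        ward_variant = c("D2", "D"),
                        bh_adjust = FALSE,
                        sd_denominator = c("n", "n_minus_1"),
                        p_correction = c("plain", "plus_one"),
                        comparison = c("studentized", "raw")) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  stopifnot(inherits(trim, "trim_policy"))
  structure(list(B = B, seed = as.integer(seed), alpha = alpha, trim = trim,
                 ward_variant = match.arg(ward_variant),
                 bh_adjust = isTRUE(bh_adjust),
                 sd_denominator = match.arg(sd_denominator),
                 p_correction = match.arg(p_correction),
                 comparison = match.arg(comparison)),
            class = "scan_config")
}

#' Scan every transcript of an expression matrix for bimodality
#'
#' For each transcript: fit the normal null by maximum likelihood, build
#' the Ward merge tree of the individuals' values, take the trimmed
#' maximum branch height, and compare it with `B` parametric-bootstrap
#' replicates to obtain an empirical p-value.  Constant transcripts
#' (sd = 0) are flagged degenerate with p = 1 rather than aborting the
#' scan.  Results are sorted by ascending p, then descending statistic.
#'
#' @param matrix an [expression_matrix()] with at least 4 individuals.
#' @param config a [scan_config()].
#' @param progress if `TRUE`, log progress every 500 transcripts.
#' @return a data frame with columns `transcript_id`, `OGS`, `max_height`,
#'   `p_max_height`, `n_boot`, `degenerate` (plus `p_bh` when
#'   `config$bh_adjust`), one row per input transcript.
#' @examples
#' sim <- simulate_matrix(synthetic_truth(n_null = 5, seed = 1), n = 10,
#'                        seed = 2)
#' res <- bimodality_scan(sim$matrix, scan_config(B = 100, seed = 3))
#' head(res)
#' @export
bimodality_scan <- function(matrix, config = scan_config(),
                            progress = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(config, "scan_config"))
  vals <- matrix$values
  nt <- nrow(vals)
  n <- ncol(vals)
  if (n < 4L) stop("too few individuals: need n >= 4")
  if (config$trim$mode == "edge_leaves_k" && config$trim$k >= n / 2)
    stop("edge_leaves_k requires k < n/2")
  set.seed(config$seed)
  subseeds <- sample.int(2147483646L, nt)
  ann <- matrix$annotation

  max_height <- numeric(nt)
  pvals <- numeric(nt)
  degen <- logical(nt)
  for (t in seq_len(nt)) {
    x <- vals[t, ]
    tree <- ward_merge_tree(x, config$ward_variant)
    tm <- trimmed_max_height(tree, x, config$trim)
    max_height[t] <- tm$stat
    params <- fit_normal_mle(x, config$sd_denominator)
    if (params$sd == 0 || tm$degenerate) {
      pvals[t] <- 1
      degen[t] <- TRUE
      next
    }
    null <- null_stat_distribution(params, config$trim, config$B,
                                   seed = subseeds[t],
                                   variant = config$ward_variant,
                                   comparison = config$comparison)
    pvals[t] <- empirical_p(tm$stat, null, config$p_correction)
    if (progress && t %% 500L == 0L)
      message(sprintf("scanned %d / %d transcripts", t, nt))
  }

  res <- data.frame(
    transcript_id = rownames(vals),
    OGS = if (is.null(ann)) NA_character_ else
      unname(ann[rownames(vals)]),
    max_height = max_height,
    p_max_height = pvals,
    n_boot = config$B,
    degenerate = degen,
    stringsAsFactors = FALSE)
  if (config$bh_adjust) res$p_bh <- adjust_bh(res$p_max_height)
  res <- res[order(res$p_max_height, -res$max_height), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Transcripts below the p-value threshold in every condition
#'
#' Cross-condition intersection of hits: the transcript IDs whose
#' empirical p-value is `<= alpha` in each of two or more result tables
#' (e.g. an untreated and a treated dataset scanned separately), returned
#' in alphabetical order.
#'
#' @param tables list of two or more scan result data frames sharing a
#'   transcript-ID namespace.
#' @param alpha threshold on `p_max_height`.
#' @param use_adjusted if `TRUE`, threshold the `p_bh` column instead.
#' @return character vector of transcript IDs, alphabetical.
#' @export
intersect_hits <- function(tables, alpha = 0.1, use_adjusted = FALSE) {
  if (!is.list(tables) || !length(tables) || inherits(tables, "data.frame"))
    stop("tables must be a non-empty list of result tables")
  col <- if (use_adjusted) "p_bh" else "p_max_height"
  hit_sets <- lapply(tables, function(tab) {
    validate_results(tab)
    if (!col %in% colnames(tab)) stop("table lacks column ", col)
    tab$transcript_id[tab[[col]] <= alpha]
  })
  sort(Reduce(intersect, hit_sets))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR-controlling adjusted p-values (monotone, each at least the
#' raw p, capped at 1).  Off by default in the screen because it does not
#' alter the ranking of transcripts, only the threshold's interpretation.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Diagnostic plots for one transcript and for the whole scan
#'
#' Writes three PNG files into `outdir`: a dendrogram of the transcript's
#' values, a histogram of the bootstrap null statistics with the observed
#' statistic marked, and a dataset-level scatter of `max_height` against
#' `-log2(p)` with p floored at `1/B` so zero p-values stay plottable.
#'
#' @param transcript_id transcript to plot.
#' @param matrix the scanned [expression_matrix()].
#' @param result the scan result data frame.
#' @param null the transcript's [null_stat_distribution()] sample.
#' @param outdir output directory, created if needed.
#' @param variant Ward height convention used for the dendrogram.
#' @return invisible character vector of the three file paths.
#' @export
render_diagnostics <- function(transcript_id, matrix, result, null, outdir,
                               variant = c("D2", "D")) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(null, "null_sample"))
  validate_results(result)
  if (!transcript_id %in% rownames(matrix$values))
    stop("unknown transcript: ", transcript_id)
  if (!transcript_id %in% result$transcript_id)
    stop("transcript absent from result table: ", transcript_id)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  x <- matrix$values[transcript_id, ]
  row <- result[result$transcript_id == transcript_id, ]
  safe_id <- gsub("[^A-Za-z0-9._-]", "_", transcript_id)
  paths <- file.path(outdir, c(
    paste0(safe_id, "_dendrogram.png"),
    paste0(safe_id, "_null_histogram.png"),
    "max_height_vs_neglog2p.png"))

  grDevices::png(paths[1L], width = 640, height = 480)
  hc <- as.hclust.merge_tree(ward_merge_tree(x, match.arg(variant)))
  hc$labels <- colnames(matrix$values)
  plot(hc, main = paste(transcript_id, "dendrogram"),
       xlab = "individual", ylab = "branch height", sub = "")
  dev.off()

  grDevices::png(paths[2L], width = 640, height = 480)
  if (length(null$stats)) {
    hist(null$stats, breaks = 40, col = "grey80", border = "grey50",
         main = paste(transcript_id, "bootstrap null"),
         xlab = "maximum branch height",
         xlim = range(c(null$stats, row$max_height)))
  } else {
    plot(0, 0, type = "n", main = paste(transcript_id, "bootstrap null"),
         xlab = "maximum branch height", ylab = "Frequency")
  }
  abline(v = row$max_height, col = "darkgreen", lwd = 2)
  legend("topright", legend = "observed", col = "darkgreen", lwd = 2,
         bty = "n")
  dev.off()

  grDevices::png(paths[3L], width = 640, height = 480)
  pf <- pmax(result$p_max_height, 1 / result$n_boot)
  plot(result$max_height, -log2(pf), pch = 20,
       col = ifelse(result$transcript_id == transcript_id, "red", "grey40"),
       xlab = "max branch height", ylab = "-log2 empirical p",
       main = "bimodality scan")
  dev.off()

  invisible(paths)
}
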