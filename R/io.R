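#' Construct a validated expression matrix
#'
#' Container for a normalized, log-scale (log2 convention) transcript-by-
#' individual abundance matrix.  Values are taken as already normalized and
#' log-transformed; no transformation is ever applied by this package.
#'
#' @param values numeric matrix, one row per transcript, one column per
#'   individual.  All entries must be finite.
#' @param transcript_ids character vector of unique transcript identifiers;
#'   defaults to `rownames(values)`.
#' @param sample_ids character vector of unique individual identifiers;
#'   defaults to `colnames(values)`.
#' @param annotation optional named character vector mapping transcript IDs
#'   to gene symbols (the `OGS` column of result tables).
#' @return an object of class `expr_matrix` with elements `values` (the
#'   matrix, with dimnames set) and `annotation`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("tr", 1:4), paste0("s", 1:5)))
#' em <- expression_matrix(m)
#' dim(em$values)
#' @export
expression_matrix <- function(values, transcript_ids = rownames(values),
                              sample_ids = colnames(values),
                              annotation = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (is.null(transcript_ids))
    stop("transcript IDs are required (rownames or `transcript_ids`)")
  if (is.null(sample_ids))
    stop("sample IDs are required (colnames or `sample_ids`)")
  transcript_ids <- as.character(transcript_ids)
  sample_ids <- as.character(sample_ids)
  if (length(transcript_ids) != nrow(values))
    stop("length(transcript_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  dup <- transcript_ids[duplicated(transcript_ids)]
  if (length(dup))
    stop("duplicate transcript ID: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs")
  if (ncol(values) < 4L)
    stop("too few individuals: need n >= 4, got ", ncol(values))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite value at row %d (%s), column %d (%s)",
                 bad[1, 1], transcript_ids[bad[1, 1]],
                 bad[1, 2], sample_ids[bad[1, 2]]))
  dimnames(values) <- list(transcript_ids, sample_ids)
  if (!is.null(annotation)) {
    annotation <- annotation[intersect(names(annotation), transcript_ids)]
    if (!length(annotation)) annotation <- NULL
  }
  structure(list(values = values, annotation = annotation),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d transcripts x %d individuals\n",
              nrow(x$values), ncol(x$values)))
  cat("transcripts:", paste(head(rownames(x$values), 5), collapse = ", "),
      if (nrow(x$values) > 5) "..." else "", "\n")
  cat("individuals:", paste(head(colnames(x$values), 5), collapse = ", "),
      if (ncol(x$values) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: a header line of sample IDs whose first field names the
#' transcript-ID column, then one row per transcript.  GCT dialect
#' (v1.2): `#1.2` line, a `rows<TAB>columns` dimension line, then a header
#' with `Name` and `Description` columns; `Description` is stored as the
#' gene-symbol annotation.  Values are taken as already log-scale; cells
#' that are missing or non-numeric raise an error with their coordinates.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"gct"`.
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gct") return(read_gct(path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("matrix file needs at least one sample column")
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  parse_matrix_body(body, ids, colnames(body), annotation = NULL)
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2"))
    stop("not a GCT v1.2 file: ", path)
  dims <- as.integer(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]][1:2])
  df <- read.delim(text = lines[-(1:2)], header = TRUE, sep = "\t",
                   check.names = FALSE, colClasses = "character", quote = "")
  if (!all(c("Name", "Description") %in% colnames(df)[1:2]))
    stop("GCT header must start with Name and Description columns")
  body <- df[, -(1:2), drop = FALSE]
  if (nrow(df) != dims[1L] || ncol(body) != dims[2L])
    stop(sprintf("GCT declared dimensions %dx%d but body is %dx%d",
                 dims[1L], dims[2L], nrow(df), ncol(body)))
  ann <- structure(df$Description, names = df$Name)
  parse_matrix_body(body, df$Name, colnames(body), annotation = ann)
}

parse_matrix_body <- function(body, transcript_ids, sample_ids, annotation) {
  vals <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    raw <- body[[j]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | raw == "" | is.na(raw))
    if (length(bad))
      stop(sprintf("missing or non-numeric value at row %d (%s), column %d (%s)",
                   bad[1L], transcript_ids[bad[1L]], j, sample_ids[j]))
    vals[, j] <- v
  }
  expression_matrix(vals, transcript_ids, sample_ids, annotation)
}

#' Write a per-transcript result table to TSV
#'
#' Columns, in order: `transcript_id`, `OGS` (gene symbol, `NA` when
#' unknown), `max_height` (trimmed maximum branch height), `p_max_height`
#' (empirical bootstrap p-value), `n_boot`, `degenerate`.  Numeric columns
#' are written with 6 significant digits so repeated runs produce
#' byte-identical files.
#'
#' @param table result data frame as returned by [bimodality_scan()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_results <- function(table, path) {
  validate_results(table)
  out <- data.frame(
    transcript_id = table$transcript_id,
    OGS = ifelse(is.na(table$OGS), "NA", table$OGS),
    max_height = sprintf("%.6g", table$max_height),
    p_max_height = sprintf("%.6g", table$p_max_height),
    n_boot = table$n_boot,
    degenerate = table$degenerate,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path file path.
#' @return a result data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("transcript_id", "OGS", "max_height", "p_max_height",
            "n_boot", "degenerate")
  if (!all(need %in% colnames(df)))
    stop("not a results table; missing columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  df$transcript_id <- as.character(df$transcript_id)
  df$OGS <- as.character(df$OGS)
  df$degenerate <- as.logical(df$degenerate)
  validate_results(df)
  df
}

validate_results <- function(table) {
  need <- c("transcript_id", "OGS", "max_height", "p_max_height",
            "n_boot", "degenerate")
  if (!all(need %in% colnames(table)))
    stop("result table missing columns: ",
         paste(setdiff(need, colnames(table)), collapse = ", "))
  if (nrow(table)) {
    if (any(table$p_max_height < 0 | table$p_max_height > 1))
      stop("p_max_height outside [0, 1]")
    if (any(table$max_height < 0))
      stop("max_height must be nonnegative")
    if (anyDuplicated(table$transcript_id))
      stop("duplicate transcript IDs in result table")
  }
  invisible(table)
}
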