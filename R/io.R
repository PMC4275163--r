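#' Expression matrix container
#'
#' Light container for a log2-scale genes-by-samples matrix with feature
#' IDs (unique, e.g. probe IDs), gene symbols (may repeat across
#' features), and sample IDs.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param feature_ids unique character vector, one per row.
#' @param gene_symbols character vector parallel to rows.
#' @param sample_ids unique character vector, one per column.
#' @return object of class \code{hir_expr}.
#' @export
expression_matrix <- function(values, feature_ids, gene_symbols, sample_ids) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length must match row count", call. = FALSE)
  if (length(gene_symbols) != nrow(values))
    stop("gene_symbols length must match row count", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length must match column count", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs", call. = FALSE)
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  structure(list(values = values,
                 gene_symbols = as.character(gene_symbols)),
            class = "hir_expr")
}

#' @export
dim.hir_expr <- function(x) dim(x$values)

#' @export
print.hir_expr <- function(x, ...) {
  cat(sprintf("<hir_expr> %d features x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from disk
#'
#' Two dialects are supported. \code{tsv}: header row, first column
#' feature ID, second column gene symbol, remaining columns numeric
#' sample values. \code{series_matrix}: a minimal GEO series-matrix text
#' layout where the data table sits between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end};
#' the first column is the feature ID and gene symbols default to the
#' feature IDs. Gzipped files are accepted in either dialect.
#'
#' @param path file path (optionally .gz).
#' @param format \code{"tsv"} or \code{"series_matrix"}.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, format = c("tsv", "series_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!startsWith(lines, "#")]
  if (format == "series_matrix") {
    b <- grep("^!series_matrix_table_begin", lines)
    e <- grep("^!series_matrix_table_end", lines)
    if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
      stop("malformed series matrix: missing or empty table block",
           call. = FALSE)
    lines <- lines[(b + 1L):(e - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  if (!length(lines)) stop("empty expression file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_hdr <- length(cells[[1L]])
  min_cols <- if (format == "tsv") 3L else 2L
  if (ncol_hdr < min_cols)
    stop("malformed header: expected at least ", min_cols,
         " tab-separated columns", call. = FALSE)
  bad <- which(vapply(cells, length, 1L) != ncol_hdr)
  if (length(bad))
    stop("ragged row(s) at line ", paste(utils::head(bad, 3), collapse = ","),
         call. = FALSE)
  hdr <- cells[[1L]]
  body <- cells[-1L]
  ids <- vapply(body, `[[`, "", 1L)
  if (format == "tsv") {
    syms <- vapply(body, `[[`, "", 2L)
    first_val <- 3L
  } else {
    syms <- ids
    first_val <- 2L
  }
  vals <- matrix(NA_real_, length(body), ncol_hdr - first_val + 1L)
  for (j in seq.int(first_val, ncol_hdr)) {
    col <- vapply(body, `[[`, "", j)
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num) && !all(is.na(num) == (col %in% c("NA", "")))) {
      r <- which(is.na(num) & !col %in% c("NA", ""))[1L]
      stop(sprintf("non-numeric value '%s' at data row %d, column %d",
                   col[r], r, j), call. = FALSE)
    }
    vals[, j - first_val + 1L] <- num
  }
  expression_matrix(vals, feature_ids = ids, gene_symbols = syms,
                    sample_ids = hdr[first_val:ncol_hdr])
}

#' Write an expression matrix as TSV
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @export
write_expression <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "hir_expr"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  writeLines(paste(c("feature_id", "gene_symbol", sample_ids(x)),
                   collapse = "\t"), con)
  body <- cbind(feature_ids(x), x$gene_symbols,
                formatC(x$values, format = "g", digits = 15))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

provenance_header <- function(seed = NULL) {
  sprintf("# hirrecur %s%s",
          as.character(utils::packageVersion("hirrecur")),
          if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
}

#' Clinical table for a cohort
#'
#' Validates per-patient recurrence-free survival data plus the standard
#' baseline covariates (sex, age, AFP>300 ng/ml, HBV, cirrhosis, tumor
#' size>5 cm, multinodularity, vascular invasion, BCLC stage). BCLC may
#' be missing for some patients; such patients are dropped from
#' multivariate Cox fits that include BCLC.
#'
#' @param df data.frame with at least \code{patient_id},
#'   \code{time_months} (nonnegative), \code{event} (0/1).
#' @return the validated data.frame, classed \code{hir_clinical}.
#' @export
clinical_table <- function(df) {
  req <- c("patient_id", "time_months", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$time_months < 0, na.rm = TRUE))
    stop("time_months must be nonnegative", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("event must be 0/1", call. = FALSE)
  if ("bclc" %in% names(df)) {
    ok <- df$bclc %in% c("0", "A", "B", "C") | is.na(df$bclc)
    if (!all(ok)) stop("bclc must be one of 0/A/B/C or NA", call. = FALSE)
  }
  class(df) <- c("hir_clinical", "data.frame")
  df
}

#' Read / write a clinical TSV
#' @param path file path.
#' @return \code{read_clinical}: a \code{\link{clinical_table}}.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(if (grepl("\\.gz$", path)) gzfile(path) else path,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = NA)
  if ("bclc" %in% names(df)) df$bclc <- as.character(df$bclc)
  clinical_table(df)
}

#' @rdname read_clinical
#' @param x a clinical table.
#' @param seed optional seed recorded in the provenance header.
#' @export
write_clinical <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' value at within-column rank r becomes the mean across columns of each
#' column's r-th order statistic. Ties within a column receive the mean of
#' the tied ranks' reference values.
#'
#' @param x an \code{\link{expression_matrix}} with no missing values.
#' @return a normalized \code{\link{expression_matrix}}.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "hir_expr"))
  v <- x$values
  if (anyNA(v)) stop("missing values not allowed", call. = FALSE)
  if (ncol(v) == 1L) {
    warning("single-sample matrix returned unchanged")
    return(x)
  }
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    # tied values share the mean of their ranks' reference values
    stats::ave(res, col, FUN = mean)
  })
  expression_matrix(out, feature_ids(x), x$gene_symbols, sample_ids(x))
}

#' Restrict to signature genes and median-center rows
#'
#' Matches the signature to the cohort by gene symbol (platforms differ,
#' so probe IDs do not transfer), collapses duplicate symbols to the
#' highest-variance feature, and median-centers each retained gene across
#' the cohort's samples. Genes absent from the platform are reported, not
#' fatal, as long as at least one matches.
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param signature an \code{hir_signature} or character vector of gene
#'   symbols.
#' @return an \code{\link{expression_matrix}} with rows renamed to gene
#'   symbols and attribute \code{absent} listing unmatched symbols.
#' @export
match_and_center <- function(x, signature) {
  stopifnot(inherits(x, "hir_expr"))
  want <- if (inherits(signature, "hir_signature"))
    unique(signature_features(signature)$gene_symbol)
  else unique(as.character(signature))
  present <- intersect(want, x$gene_symbols)
  if (!length(present))
    stop("no signature genes present in the expression matrix",
         call. = FALSE)
  rows <- integer(length(present))
  vr <- apply(x$values, 1L, stats::var)
  for (i in seq_along(present)) {
    cand <- which(x$gene_symbols == present[i])
    rows[i] <- cand[which.max(vr[cand])]
  }
  v <- x$values[rows, , drop = FALSE]
  v <- v - apply(v, 1L, stats::median)
  out <- expression_matrix(v, feature_ids = present,
                           gene_symbols = present,
                           sample_ids = sample_ids(x))
  attr(out, "absent") <- setdiff(want, present)
  out
}
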