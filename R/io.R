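# Readers/writers: dense TSV/CSV and Matrix-Market sparse triplet
# expression, coordinate tables, and the '#'-headered TSV convention used
# by every pipeline output.

as_expression_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$expr))
    x <- x$expr
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  if (!all(is.finite(x))) stop("expression values must be finite")
  x
}

count_comment_lines <- function(path) {
  head_lines <- readLines(path, n = 200L)
  n <- 0L
  for (l in head_lines) {
    if (startsWith(l, "#")) n <- n + 1L else break
  }
  n
}

#' Write a TSV table with a `#` header block
#'
#' Every pipeline output is a TSV preceded by `#`-prefixed header lines
#' carrying the configuration and seed (never timestamps, so reruns are
#' byte-identical).
#'
#' @param tab data.frame.
#' @param path output path.
#' @param header_lines character vector; `# ` is prefixed if absent.
#' @export
write_tsv <- function(tab, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    header_lines <- ifelse(startsWith(header_lines, "#"), header_lines,
                           paste("#", header_lines))
    writeLines(header_lines, con)
  }
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    skip = count_comment_lines(path), ...)
}

#' Read an expression matrix
#'
#' Dense TSV/CSV (first column gene ids, header row of spot ids) or a
#' Matrix-Market MTX triplet (genes in rows) with companion gene and
#' barcode lists (first column of each file is used).
#'
#' @param path dense table, or `.mtx` file.
#' @param genes,barcodes companion id files, required with MTX input.
#' @return Dense genes x spots matrix with gene ids as rownames and spot
#'   ids as colnames.
#' @export
read_expression <- function(path, genes = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes) || is.null(barcodes))
      stop("MTX input needs companion genes and barcodes files")
    m <- as.matrix(Matrix::readMM(path))
    gid <- read_id_column(genes)
    bid <- read_id_column(barcodes)
    if (length(gid) != nrow(m))
      stop("genes file length does not match MTX rows")
    if (length(bid) != ncol(m))
      stop("barcodes file length does not match MTX columns")
    dimnames(m) <- list(gid, bid)
    expr <- m
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- data.table::fread(path, sep = sep, header = TRUE,
                             data.table = FALSE,
                             skip = count_comment_lines(path))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression cell")
    rownames(vals) <- as.character(tab[[1L]])
    expr <- vals
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  as_expression_matrix(expr)
}

read_id_column <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE,
                           skip = count_comment_lines(path))
  as.character(tab[[1L]])
}

#' Write an expression matrix
#'
#' `format = "tsv"` writes one dense table (`gene_id` column + one column
#' per spot). `format = "mtx"` writes a Matrix-Market triplet next to
#' `genes.tsv` and `barcodes.tsv` companions (paths derived from `path`).
#'
#' @param expr genes x spots matrix.
#' @param path output path (for mtx, the `.mtx` path).
#' @param format `"tsv"` or `"mtx"`.
#' @param header_lines optional header block for the tsv format.
#' @export
write_expression <- function(expr, path, format = c("tsv", "mtx"),
                             header_lines = NULL) {
  format <- match.arg(format)
  expr <- as_expression_matrix(expr)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    write_tsv(tab, path, header_lines)
  } else {
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(expr), file.path(dir, "genes.tsv"))
    writeLines(colnames(expr), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Filter sparse genes and optionally log-normalize
#'
#' Removes genes whose fraction of nonzero spots falls below
#' `min_nonzero_fraction`, optionally rescales every spot's library to the
#' median total followed by `log(1 + x)`, then removes genes constant
#' across spots.
#'
#' @param expr genes x spots matrix (counts or normalized values).
#' @param min_nonzero_fraction sparsity threshold in \[0, 1).
#' @param do_lognorm apply library-size scaling + log1p (for raw counts).
#' @return Filtered (and possibly normalized) matrix.
#' @export
normalize_and_filter <- function(expr, min_nonzero_fraction = 0.01,
                                 do_lognorm = FALSE) {
  expr <- as_expression_matrix(expr)
  if (min_nonzero_fraction < 0 || min_nonzero_fraction >= 1)
    stop("min_nonzero_fraction must be in [0, 1)")
  nzf <- rowMeans(expr != 0)
  expr <- expr[nzf >= min_nonzero_fraction, , drop = FALSE]
  if (do_lognorm) {
    lib <- colSums(expr)
    if (any(lib <= 0)) stop("spot with non-positive library size")
    expr <- log1p(sweep(expr, 2L, median(lib) / lib, "*"))
  }
  keep <- apply(expr, 1L, function(v) sd(v) > 0)
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0L) stop("all genes filtered out")
  expr
}
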