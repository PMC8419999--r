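#' Read a UMI count matrix from disk
#'
#' Supports the Matrix Market coordinate format with companion `genes.tsv`
#' and `barcodes.tsv` files (the 10x dialect, which stores genes as rows,
#' is handled with `orientation = "genes_rows"` and transposed on load so
#' that cells are always rows internally), and plain dense CSV for toy
#' inputs (first column = cell ids, header = gene ids).
#'
#' @param path path to a `.mtx` or `.csv` file
#' @param orientation `"cells_rows"` (default) or `"genes_rows"` describing
#'   the on-disk matrix; 1-based Matrix Market indices become 0-based
#'   internal offsets via the sparse Matrix machinery
#' @param genes_file,barcodes_file companion TSVs for `.mtx` input; default
#'   `genes.tsv` and `barcodes.tsv` next to the matrix. First column is
#'   used as identifier.
#' @return a [count_matrix()]
#' @export
read_counts <- function(path, orientation = c("cells_rows", "genes_rows"),
                        genes_file = NULL, barcodes_file = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_file)) {
      barcodes_file <- file.path(dirname(path), "barcodes.tsv")
    }
    if (!file.exists(genes_file)) stop("missing gene file: ", genes_file)
    if (!file.exists(barcodes_file)) {
      stop("missing barcode file: ", barcodes_file)
    }
    genes <- utils::read.delim(genes_file, header = FALSE,
                               stringsAsFactors = FALSE)[, 1]
    barcodes <- utils::read.delim(barcodes_file, header = FALSE,
                                  stringsAsFactors = FALSE)[, 1]
    if (orientation == "genes_rows") m <- Matrix::t(m)
    if (nrow(m) != length(barcodes)) {
      stop(sprintf("matrix has %d cells but %s lists %d barcodes",
                   nrow(m), barcodes_file, length(barcodes)))
    }
    if (ncol(m) != length(genes)) {
      stop(sprintf("matrix has %d genes but %s lists %d genes",
                   ncol(m), genes_file, length(genes)))
    }
    count_matrix(m, cell_ids = barcodes, gene_ids = genes)
  } else if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    cells <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (orientation == "genes_rows") {
      genes <- cells
      cells <- colnames(df)[-1]
      m <- t(m)
    } else {
      genes <- colnames(df)[-1]
    }
    count_matrix(m, cell_ids = cells, gene_ids = genes)
  } else {
    stop("unsupported file type (expected .mtx or .csv): ", path)
  }
}

#' Write a count matrix to disk
#'
#' Matrix Market output writes `matrix.mtx` (1-based coordinate format, as
#' the format requires), `genes.tsv`, and `barcodes.tsv` into `dir`. CSV
#' output writes a single dense table.
#'
#' @param X a [count_matrix()]
#' @param dir output directory for Matrix Market output
#' @param format `"mtx"` or `"csv"`
#' @param file output path for CSV output (default `counts.csv` in `dir`)
#' @return invisibly, the paths written
#' @export
write_counts <- function(X, dir, format = c("mtx", "csv"), file = NULL) {
  stopifnot(inherits(X, "CountMatrix"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx") {
    mtx <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(X$counts, mtx)
    writeLines(X$gene_ids, file.path(dir, "genes.tsv"))
    writeLines(X$cell_ids, file.path(dir, "barcodes.tsv"))
    invisible(c(mtx, file.path(dir, c("genes.tsv", "barcodes.tsv"))))
  } else {
    if (is.null(file)) file <- file.path(dir, "counts.csv")
    df <- data.frame(cell_id = X$cell_ids, as.matrix(X$counts),
                     check.names = FALSE)
    colnames(df) <- c("cell_id", X$gene_ids)
    utils::write.csv(df, file, row.names = FALSE)
    invisible(file)
  }
}

#' Write a dense matrix (residuals or transformed values) as CSV
#'
#' @param values dense cells-by-genes matrix
#' @param cell_ids,gene_ids identifiers
#' @param file output path
#' @export
write_dense_csv <- function(values, cell_ids, gene_ids, file) {
  df <- data.frame(cell_id = cell_ids, values, check.names = FALSE)
  colnames(df) <- c("cell_id", gene_ids)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

# machine-readable provenance record written next to every CLI output
write_provenance <- function(dir, command, params) {
  rec <- list(
    command = command,
    params = params,
    package = "umiresid",
    version = as.character(utils::packageVersion("umiresid")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}
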