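#' Read a barcodes x tags count matrix
#'
#' Accepts either a Matrix Market directory/file (`matrix.mtx` with
#' `barcodes.tsv` and `features.tsv` sidecars; features x barcodes on disk,
#' the common cell-ranger-style orientation) or a dense CSV with barcode rows
#' and tag columns (first column = barcode). The in-memory contract is always
#' barcodes x tags; MTX input is transposed on read.
#'
#' @param path Directory containing `matrix.mtx` + sidecars, a `.mtx` file
#'   (sidecars looked up next to it), or a `.csv` file.
#' @return Sparse `dgCMatrix`, barcodes x tags, integer counts.
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) {
      stop(sprintf("no matrix.mtx in directory '%s'", path), call. = FALSE)
    }
    return(read_mtx_dir(mtx))
  }
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path),
                               call. = FALSE)
  if (grepl("\\.mtx$", path)) return(read_mtx_dir(path))
  if (grepl("\\.csv$", path)) return(read_csv_matrix(path))
  stop(sprintf("unrecognized count matrix format: '%s' (expected .mtx or .csv)",
               path), call. = FALSE)
}

read_mtx_dir <- function(mtx_path) {
  dir <- dirname(mtx_path)
  bc_path <- file.path(dir, "barcodes.tsv")
  ft_path <- file.path(dir, "features.tsv")
  for (p in c(bc_path, ft_path)) {
    if (!file.exists(p)) stop(sprintf("missing sidecar '%s'", p),
                              call. = FALSE)
  }
  validate_mtx_header(mtx_path)
  m <- Matrix::readMM(mtx_path)
  barcodes <- readLines(bc_path)
  features <- readLines(ft_path)
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(paste0("MTX is %d x %d (features x barcodes) but sidecars ",
                        "list %d features and %d barcodes"),
                 nrow(m), ncol(m), length(features), length(barcodes)),
         call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    dup <- unique(barcodes[duplicated(barcodes)])
    stop("duplicate barcodes in barcodes.tsv: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (any(m@x != round(m@x))) {
    stop("matrix.mtx contains non-integer entries", call. = FALSE)
  }
  m <- Matrix::t(m)
  dimnames(m) <- list(barcodes, features)
  methods::as(m, "CsparseMatrix")
}

# Cross-check the declared nnz in the MTX header against the actual number
# of data lines, so a truncated or padded file fails loudly.
validate_mtx_header <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (length(body) < 1L) stop(sprintf("'%s' has no size line", path),
                              call. = FALSE)
  hdr <- as.numeric(strsplit(trimws(body[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 3L || anyNA(hdr)) {
    stop(sprintf("'%s' has a malformed size line: '%s'", path, body[1]),
         call. = FALSE)
  }
  nnz_declared <- hdr[3]
  nnz_actual <- length(body) - 1L
  if (nnz_declared != nnz_actual) {
    stop(sprintf("'%s' declares %.0f nonzero entries but contains %d data lines",
                 path, nnz_declared, nnz_actual), call. = FALSE)
  }
  invisible(TRUE)
}

read_csv_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("count CSV needs a barcode column plus tag columns",
                          call. = FALSE)
  barcodes <- as.character(df[[1]])
  if (anyDuplicated(barcodes)) {
    dup <- unique(barcodes[duplicated(barcodes)])
    stop("duplicate barcode rows in CSV: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)) || any(m < 0)) {
    bad <- which(is.na(m) | m != round(m) | m < 0, arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (first at row %d, column '%s')",
                                  bad[1, 1], colnames(m)[bad[1, 2]]) else ""
    stop("count CSV must contain non-negative integers", loc, call. = FALSE)
  }
  rownames(m) <- barcodes
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Write a count matrix as Matrix Market + sidecars
#'
#' Writes `matrix.mtx` (features x barcodes orientation), `barcodes.tsv` and
#' `features.tsv` into `dir`. Round-trips bit-exactly through
#' [read_count_matrix()] for integer data.
#'
#' @param counts Barcodes x tags matrix.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::t(Matrix::Matrix(counts, sparse = TRUE))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Write classification results, thresholds and run metadata
#'
#' Writes `classification.tsv` (barcode, global_class, hash_id,
#' n_positive_tags, plus per-tag raw count and CLR columns when available),
#' `thresholds.json` (the per-tag background model, with a version string)
#' and `run_metadata.json` (parameters and seed) into `dir`.
#'
#' @param result A `hash_demux` object from [demultiplex()], or a
#'   classification data.frame (then `model` must be given and per-tag
#'   columns are omitted unless `counts`/`normalized` are supplied).
#' @param dir Output directory.
#' @param model Background model data.frame (ignored when `result` is a
#'   `hash_demux`).
#' @param counts,normalized Optional matrices for the per-tag columns.
#' @return `dir`, invisibly.
#' @export
write_classification <- function(result, dir, model = NULL, counts = NULL,
                                 normalized = NULL) {
  if (inherits(result, "hash_demux")) {
    model <- result$background
    counts <- result$counts
    normalized <- result$normalized
    params <- result$params
    classification <- result$classification
  } else {
    classification <- result
    params <- list()
  }
  if (is.null(model)) stop("a background model is required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- classification
  if (!is.null(counts) && nrow(classification) > 0L) {
    idx <- match(classification$barcode, rownames(counts))
    cnt <- as.matrix(counts)[idx, , drop = FALSE]
    colnames(cnt) <- paste0("count.", colnames(cnt))
    out <- cbind(out, cnt)
  }
  if (!is.null(normalized) && nrow(classification) > 0L) {
    idx <- match(classification$barcode, rownames(normalized))
    nrm <- as.matrix(normalized)[idx, , drop = FALSE]
    colnames(nrm) <- paste0("clr.", colnames(nrm))
    out <- cbind(out, nrm)
  }
  tsv <- file.path(dir, "classification.tsv")
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  jsonlite::write_json(
    list(version = pkg_version_string(),
         tags = model[, c("tag", "mu", "size", "dist", "threshold", "q",
                          "n_background")]),
    file.path(dir, "thresholds.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(version = pkg_version_string(), params = params),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read back a thresholds JSON as a background model
#' @param path Path to a `thresholds.json` written by [write_classification()].
#' @return Background model data.frame (one row per tag).
#' @export
read_thresholds <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.data.frame(j$tags, stringsAsFactors = FALSE)
  m$size <- as.numeric(m$size)  # "Inf" round-trips as character
  class(m) <- c("hash_background", class(m))
  m
}
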