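#' Tag library (HTO/ADT panel)
#'
#' A named set of tag barcode sequences, one per sample or antibody. All
#' sequences must have equal length; at load time the pairwise hamming
#' distances are checked against `2 * max_hamming` and a warning is raised if
#' any pair is too close to resolve unambiguously.
#'
#' @param names Character vector of sample/antibody names.
#' @param sequences Character vector of DNA tag barcodes (equal length,
#'   typically 12 bp).
#' @param max_hamming Mismatch tolerance the library will be used with
#'   (for the separation check only).
#' @return A `tag_library` data.frame with columns `name`, `sequence`.
#' @export
tag_library <- function(names, sequences, max_hamming = 1L) {
  if (length(names) != length(sequences) || length(names) < 1L) {
    stop("'names' and 'sequences' must be non-empty and of equal length",
         call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (anyDuplicated(names)) stop("duplicate tag names", call. = FALSE)
  if (anyDuplicated(sequences)) stop("duplicate tag sequences", call. = FALSE)
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("all tag sequences must have the same length", call. = FALSE)
  }
  if (!all(grepl("^[ACGTN]+$", sequences))) {
    stop("tag sequences must be DNA (A/C/G/T/N)", call. = FALSE)
  }
  if (length(sequences) > 1L) {
    d <- hamming_matrix(sequences, sequences)
    d[upper.tri(d, diag = TRUE)] <- NA
    if (any(d <= 2L * max_hamming, na.rm = TRUE)) {
      warning(sprintf(paste0("some tag barcodes are within hamming distance ",
                             "%d of each other; matches at max_hamming = %d ",
                             "can be ambiguous"), 2L * max_hamming,
                      max_hamming))
    }
  }
  structure(data.frame(name = names, sequence = sequences,
                       stringsAsFactors = FALSE),
            class = c("tag_library", "data.frame"),
            barcode_length = len)
}

#' Read a tag library from a 2-column CSV (name,sequence)
#' @param path CSV path; a header line `name,sequence` is accepted.
#' @param max_hamming Passed to [tag_library()].
#' @return A `tag_library`.
#' @export
read_tag_library <- function(path, max_hamming = 1L) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        strip.white = TRUE)
  if (ncol(df) < 2L) stop("tag library CSV needs 2 columns (name,sequence)",
                          call. = FALSE)
  if (tolower(df[1, 1]) == "name") df <- df[-1, , drop = FALSE]
  tag_library(df[[1]], df[[2]], max_hamming = max_hamming)
}

# Pairwise hamming distances between equal-length strings; case-insensitive,
# N counts as a mismatch (even against another N).
hamming_matrix <- function(obs, ref) {
  om <- do.call(rbind, strsplit(toupper(obs), ""))
  rm_ <- do.call(rbind, strsplit(toupper(ref), ""))
  d <- matrix(0L, length(obs), length(ref))
  for (j in seq_along(ref)) {
    cmp <- om != matrix(rm_[j, ], nrow(om), ncol(om), byrow = TRUE)
    cmp <- cmp | om == "N" | matrix(rm_[j, ] == "N", nrow(om), ncol(om),
                                    byrow = TRUE)
    d[, j] <- rowSums(cmp)
  }
  d
}

#' Match an observed tag sequence against a library
#'
#' Returns the name of the unique library entry within `max_hamming`
#' mismatches of `observed`; `NA` when no entry is close enough or when two
#' or more entries tie at the minimal distance (ambiguous reads are
#' discarded, never split).
#'
#' @param observed DNA string, same length as the library barcodes.
#' @param library A [tag_library()].
#' @param max_hamming Maximum number of mismatches tolerated (default 1).
#' @return Sample name, or `NA_character_` for no match / ambiguous.
#' @export
match_tag <- function(observed, library, max_hamming = 1L) {
  if (nchar(observed) != attr(library, "barcode_length")) {
    stop(sprintf("observed tag length %d != library barcode length %d",
                 nchar(observed), attr(library, "barcode_length")),
         call. = FALSE)
  }
  if (max_hamming < 0) stop("'max_hamming' must be >= 0", call. = FALSE)
  d <- hamming_matrix(observed, library$sequence)[1, ]
  best <- min(d)
  if (best > max_hamming || sum(d == best) > 1L) return(NA_character_)
  library$name[which.min(d)]
}

#' Read layout for paired tag reads
#'
#' 1-based (start, length) spans locating the cell barcode and UMI on read 1
#' and the tag barcode on read 2. The default is the common 10x 3' v2 layout:
#' 16 bp cell barcode + 10 bp UMI, tag at the start of read 2.
#'
#' @param cell_barcode,umi,tag Integer vectors `c(start, length)`.
#' @return A `read_layout` list.
#' @export
read_layout <- function(cell_barcode = c(1L, 16L), umi = c(17L, 10L),
                        tag = c(1L, 12L)) {
  spans <- list(cell_barcode = cell_barcode, umi = umi, tag = tag)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2L || any(sp < 1L)) {
      stop(sprintf("'%s' must be c(start, length) with both >= 1", nm),
           call. = FALSE)
    }
  }
  if (cell_barcode[1] < umi[1] + umi[2] && umi[1] < cell_barcode[1] +
      cell_barcode[2]) {
    stop("cell barcode and UMI spans overlap on read 1", call. = FALSE)
  }
  structure(spans, class = "read_layout")
}

span_end <- function(sp) sp[1] + sp[2] - 1L

read_fastq_seqs <- function(path) {
  seqs <- tryCatch(
    as.character(Biostrings::readBStringSet(path, format = "fastq")),
    error = function(e) {
      stop(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  unname(seqs)
}

#' Count tag UMIs per cell barcode from paired reads
#'
#' Read 1 carries the cell barcode and UMI; read 2 carries the tag sequence.
#' Each read's tag is assigned to the library by [match_tag()] semantics
#' (unique best hit within `max_hamming`), reads with unmatched or ambiguous
#' tags or with off-whitelist cell barcodes are dropped, and one UMI is
#' counted per distinct (cell barcode, UMI, tag) triple.
#'
#' @param r1,r2 Paths to the paired FASTQ files (plain or gzipped), in the
#'   same read order.
#' @param library A [tag_library()].
#' @param layout A [read_layout()].
#' @param max_hamming Mismatch tolerance for tag assignment (default 1).
#' @param whitelist Optional character vector of allowed cell barcodes.
#' @return Sparse barcodes x tags count matrix with a `summary` attribute:
#'   `n_read_pairs`, `n_tag_no_match`, `n_off_whitelist`, `n_too_short`,
#'   `n_umi_duplicates`, `n_counted`. Matrix totals plus the drop tallies
#'   account for every read pair.
#' @export
count_tags <- function(r1, r2, library, layout = read_layout(),
                       max_hamming = 1L, whitelist = NULL) {
  s1 <- read_fastq_seqs(r1)
  s2 <- read_fastq_seqs(r2)
  if (length(s1) != length(s2)) {
    stop(sprintf("read pairing broken: %d reads in '%s' vs %d in '%s'",
                 length(s1), r1, length(s2), r2), call. = FALSE)
  }
  n <- length(s1)
  need1 <- max(span_end(layout$cell_barcode), span_end(layout$umi))
  need2 <- span_end(layout$tag)
  if (attr(library, "barcode_length") != layout$tag[2]) {
    stop("layout tag span length differs from library barcode length",
         call. = FALSE)
  }
  too_short <- nchar(s1) < need1 | nchar(s2) < need2
  if (any(too_short)) {
    first <- which(too_short)[1]
    warning(sprintf("%d read pairs shorter than the layout (first at record %d) were dropped",
                    sum(too_short), first))
  }
  keep <- !too_short
  cell <- substr(s1[keep], layout$cell_barcode[1],
                 span_end(layout$cell_barcode))
  umi <- substr(s1[keep], layout$umi[1], span_end(layout$umi))
  tag_seq <- toupper(substr(s2[keep], layout$tag[1], span_end(layout$tag)))
  # assign unique observed tag sequences once
  uniq <- unique(tag_seq)
  d <- hamming_matrix(uniq, library$sequence)
  best <- apply(d, 1L, min)
  n_best <- rowSums(d == best)
  assigned <- ifelse(best <= max_hamming & n_best == 1L,
                     library$name[apply(d, 1L, which.min)], NA_character_)
  tag <- assigned[match(tag_seq, uniq)]
  no_match <- is.na(tag)
  off_wl <- if (!is.null(whitelist)) !(cell %in% whitelist) else
    rep(FALSE, length(cell))
  ok <- !no_match & !off_wl
  triple <- paste(cell[ok], umi[ok], tag[ok], sep = "\r")
  dup <- duplicated(triple)
  cell_u <- cell[ok][!dup]
  tag_u <- tag[ok][!dup]
  barcodes <- sort(unique(cell_u))
  mat <- Matrix::sparseMatrix(i = match(cell_u, barcodes),
                              j = match(tag_u, library$name),
                              x = 1,
                              dims = c(length(barcodes), nrow(library)),
                              dimnames = list(barcodes, library$name))
  attr(mat, "summary") <- list(n_read_pairs = n,
                               n_too_short = sum(too_short),
                               n_tag_no_match = sum(no_match & !off_wl),
                               n_off_whitelist = sum(off_wl),
                               n_umi_duplicates = sum(dup),
                               n_counted = sum(!dup))
  mat
}
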