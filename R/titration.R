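#' Staining index
#'
#' Flow-cytometry-style signal-to-noise metric for an antibody:
#' `SI = (median(pos) - median(neg)) / (2 * mad(neg))`, where `mad` here is
#' the MEAN absolute deviation of the negative values about their median --
#' not the median absolute deviation, despite the common flow abbreviation.
#'
#' @param pos_values Numeric vector from the positive peak.
#' @param neg_values Numeric vector from the negative peak; must have
#'   non-zero spread.
#' @return The staining index (dimensionless).
#' @examples
#' staining_index(c(9, 9, 9), 1:5)  # (9 - 3) / (2 * 1.2) = 2.5
#' @export
staining_index <- function(pos_values, neg_values) {
  if (length(pos_values) == 0L || length(neg_values) == 0L) {
    stop("'pos_values' and 'neg_values' must be non-empty", call. = FALSE)
  }
  neg_med <- stats::median(neg_values)
  spread <- 2 * mean(abs(neg_values - neg_med))
  if (spread == 0) {
    stop("negative peak has zero spread; staining index is undefined",
         call. = FALSE)
  }
  (stats::median(pos_values) - neg_med) / spread
}

#' Locate the positive peak of a stained sample
#'
#' Clusters cells on Euclidean distances of their normalized tag values
#' (seeded k-medoids, `k = 2` by default: stained vs unstained) and returns
#' the values of the antibody under test within the cluster whose mean for
#' that antibody is highest.
#'
#' @param normalized Cells x antibodies matrix of CLR values for one stained
#'   condition.
#' @param antibody Column name of the antibody under test.
#' @param k Number of clusters (default 2).
#' @param seed Integer seed.
#' @return Numeric vector of positive-peak values.
#' @export
find_positive_peak <- function(normalized, antibody, k = 2L, seed = 1L) {
  normalized <- as.matrix(normalized)
  if (!antibody %in% colnames(normalized)) {
    stop(sprintf("antibody '%s' not found among columns", antibody),
         call. = FALSE)
  }
  n_distinct <- nrow(unique(normalized))
  if (n_distinct < k) {
    stop(paste0("no separable positive population (fewer distinct ",
                "expression profiles than clusters); raise the antibody ",
                "concentration or lower k"), call. = FALSE)
  }
  cl <- kmedoids(normalized, k = k, seed = seed)
  v <- normalized[, antibody]
  cl_means <- tapply(v, cl$labels, mean)
  idx <- as.integer(names(cl_means))
  top <- idx[order(-cl_means, idx)[1L]]
  unname(v[cl$labels == top])
}

#' Staining-index titration curve
#'
#' Computes one staining index per staining concentration. All condition
#' matrices and the unstained control are pooled and CLR-normalized jointly
#' (one experiment, one normalization), the negative peak is always the
#' control cells' values, and each condition's positive peak is found with
#' [find_positive_peak()].
#'
#' @param stained Named list of barcodes x antibodies count matrices, one per
#'   staining condition.
#' @param concentrations Numeric vector of concentrations (e.g. ug/test),
#'   one per element of `stained`. Duplicates are allowed and reported
#'   separately, in stable order.
#' @param control Count matrix of unstained control cells (same antibody
#'   columns).
#' @param antibody Antibody under test (a column name).
#' @param seed Integer seed for peak detection.
#' @param pseudocount CLR pseudocount (default 1).
#' @return data.frame with one row per condition, sorted by concentration:
#'   `antibody`, `concentration`, `si`, `pos_median`, `neg_median`,
#'   `neg_spread` (2 x mean absolute deviation, CLR units), `n_pos`, `n_neg`.
#' @export
titration_curve <- function(stained, concentrations, control, antibody,
                            seed = 1L, pseudocount = 1) {
  if (is.null(control)) stop("an unstained control matrix is required",
                             call. = FALSE)
  if (length(stained) != length(concentrations)) {
    stop("'stained' and 'concentrations' must have equal length",
         call. = FALSE)
  }
  mats <- c(stained, list(control))
  # internal group ids: conditions may be unnamed or share a concentration
  names(mats) <- c(sprintf("cond%03d", seq_along(stained)), ".control")
  mats <- lapply(mats, as_count_matrix)
  cols <- colnames(mats[[1]])
  if (!all(vapply(mats, function(m) identical(colnames(m), cols), logical(1)))) {
    stop("all condition matrices must share the same antibody columns",
         call. = FALSE)
  }
  if (!antibody %in% cols) {
    stop(sprintf("antibody '%s' not found among columns", antibody),
         call. = FALSE)
  }
  grp <- rep(names(mats), vapply(mats, nrow, integer(1)))
  pooled <- do.call(rbind, mats)
  rownames(pooled) <- paste(grp, unlist(lapply(mats, rownames)), sep = ":")
  normalized <- clr_normalize(pooled, pseudocount)
  neg <- normalized[grp == ".control", antibody]
  neg_med <- stats::median(neg)
  neg_spread <- 2 * mean(abs(neg - neg_med))
  if (neg_spread == 0) {
    stop("unstained control has zero spread; staining index is undefined",
         call. = FALSE)
  }
  rows <- lapply(seq_along(stained), function(i) {
    sub <- normalized[grp == names(mats)[i], , drop = FALSE]
    pos <- find_positive_peak(sub, antibody, seed = seed)
    data.frame(antibody = antibody,
               concentration = concentrations[i],
               si = (stats::median(pos) - neg_med) / neg_spread,
               pos_median = stats::median(pos),
               neg_median = neg_med,
               neg_spread = neg_spread,
               n_pos = length(pos),
               n_neg = length(neg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$concentration), , drop = FALSE]
}

#' Read a titration manifest CSV
#'
#' Columns: `condition`, `antibody`, `concentration`, `path`, `is_control`
#' (logical or 0/1). Each `path` points to a count matrix readable by
#' [read_count_matrix()]. Exactly one control row is required.
#'
#' @param path Manifest CSV path.
#' @return data.frame with the manifest, `is_control` as logical.
#' @export
read_titration_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("condition", "antibody", "concentration", "path", "is_control")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m$is_control <- as.logical(m$is_control)
  if (sum(m$is_control) != 1L) {
    stop("manifest must contain exactly one control row", call. = FALSE)
  }
  m
}
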