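#' Centered log-ratio normalization of tag counts
#'
#' For each tag independently, counts are divided by the geometric mean of
#' that tag across cells and natural-log transformed:
#' `x'_i = ln(x_i + pc) - mean_i ln(x_i + pc)`. A pseudocount (default 1)
#' keeps the transform finite when counts of zero are present, which they
#' almost always are.
#'
#' @param counts Barcodes x tags matrix of non-negative integer UMI counts
#'   (dense or sparse, with dimnames).
#' @param pseudocount Non-negative value added to every count before the log.
#' @return Dense numeric matrix of the same shape; each tag's values average
#'   to zero.
#' @examples
#' m <- matrix(c(1, 10, 100), ncol = 1,
#'             dimnames = list(c("b1", "b2", "b3"), "HTO1"))
#' clr_normalize(m, pseudocount = 0)  # -log(10), 0, log(10)
#' @export
clr_normalize <- function(counts, pseudocount = 1) {
  counts <- as_count_matrix(counts)
  if (pseudocount < 0) stop("'pseudocount' must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(counts == 0)) {
    stop("counts contain zeros; a pseudocount of 0 would give -Inf ",
         "(use pseudocount >= 1)", call. = FALSE)
  }
  l <- log(counts + pseudocount)
  sweep(l, 2L, colMeans(l), "-")
}

#' Seeded k-medoids clustering
#'
#' Partitions rows into `k` clusters around medoids (PAM objective: total
#' Euclidean distance of points to their medoid; medoids are data rows).
#' Small inputs are clustered with exact PAM; larger inputs with CLARA
#' (PAM on seeded subsamples), which keeps the cost linear in the number of
#' rows. Both routes are deterministic given `seed`.
#'
#' @param x Numeric matrix (rows = observations).
#' @param k Number of clusters (>= 2; needs at least `k` distinct rows).
#' @param seed Integer seed.
#' @param exact_max Row-count threshold below which exact PAM is used.
#' @return A list with `labels` (integer vector, named by rownames of `x`),
#'   `k`, and `medoids` (matrix of medoid rows).
#' @export
kmedoids <- function(x, k, seed = 1L, exact_max = 3000L) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    stop(sprintf("need at least k = %d distinct rows, found %d", k,
                 n_distinct), call. = FALSE)
  }
  with_seed(seed, {
    if (nrow(x) <= exact_max) {
      fit <- cluster::pam(x, k = k, metric = "euclidean", pamonce = 2,
                          keep.diss = FALSE, keep.data = FALSE)
      labels <- fit$clustering
      medoids <- x[fit$id.med, , drop = FALSE]
    } else {
      sampsize <- min(nrow(x), max(200L, 20L * k))
      fit <- cluster::clara(x, k = k, metric = "euclidean", samples = 20,
                            sampsize = sampsize, pamLike = TRUE, rngR = TRUE,
                            medoids.x = TRUE)
      labels <- fit$clustering
      medoids <- fit$medoids
    }
    names(labels) <- rownames(x)
    list(labels = labels, k = k, medoids = medoids)
  })
}

#' Maximum-likelihood negative binomial fit
#'
#' Fits `NB(mu, size)` to a non-negative integer vector by maximum likelihood
#' (method-of-moments initialization). Underdispersed data fall back to a
#' Poisson fit (`size = Inf`) with a warning; an all-equal vector is treated
#' as a point mass.
#'
#' @param x Non-negative integer vector.
#' @return List with `mu`, `size` (`Inf` for the Poisson/point-mass fall-backs)
#'   and `dist` (`"nbinom"`, `"poisson"` or `"degenerate"`).
#' @export
fit_nbinom <- function(x) {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(x < 0) || max(abs(x - round(x))) > 1e-8) {
    stop("'x' must be non-negative integers", call. = FALSE)
  }
  x <- round(x)
  m <- mean(x)
  v <- stats::var(x)
  if (v == 0) {
    warning("zero-variance data: point-mass fit (size = Inf)")
    return(list(mu = m, size = Inf, dist = "degenerate"))
  }
  if (v <= m) {
    warning("data not overdispersed: Poisson fall-back (size = Inf)")
    return(list(mu = m, size = Inf, dist = "poisson"))
  }
  size0 <- m^2 / (v - m)
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "negative binomial",
                                    start = list(size = size0, mu = m),
                                    lower = c(1e-6, 1e-10))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # method-of-moments estimate when the ML optimizer fails
    return(list(mu = m, size = size0, dist = "nbinom"))
  }
  list(mu = unname(fit$estimate["mu"]), size = unname(fit$estimate["size"]),
       dist = "nbinom")
}

# q-quantile of the fitted count distribution: smallest integer c with
# CDF(c) >= q.
nb_quantile <- function(mu, size, q, dist = "nbinom") {
  switch(dist,
         degenerate = as.integer(round(mu)),
         poisson = stats::qpois(q, lambda = mu),
         stats::qnbinom(q, size = size, mu = mu))
}

#' Fit the negative binomial background for one tag
#'
#' Implements the per-tag background procedure: cells in the k-medoids
#' cluster with the highest mean normalized value for this tag are excluded
#' (they are the tag's positive population), the top `outlier_fraction` of
#' the remaining cells by raw count are excluded as potential outliers, and a
#' negative binomial is fitted to the remaining raw counts. The positivity
#' threshold is the smallest integer count whose fitted CDF reaches `q`.
#'
#' @param raw_counts Integer vector of raw counts for the tag (one per cell).
#' @param labels Integer cluster labels, as from [kmedoids()].
#' @param normalized Numeric vector of CLR values for the tag (same cells).
#' @param outlier_fraction Fraction in `[0, 0.05]` of background cells to
#'   drop from the top of the raw-count distribution. Default 0.005.
#' @param q Quantile in `(0.5, 1)` defining the threshold. Default 0.99.
#' @return List with `mu`, `size`, `dist`, `threshold` (integer count; cells
#'   strictly above it are positive), `q`, `n_background`.
#' @export
fit_background <- function(raw_counts, labels, normalized,
                           outlier_fraction = 0.005, q = 0.99) {
  if (length(raw_counts) != length(labels) ||
      length(raw_counts) != length(normalized)) {
    stop("'raw_counts', 'labels' and 'normalized' must have equal length",
         call. = FALSE)
  }
  if (outlier_fraction < 0 || outlier_fraction > 0.05) {
    stop("'outlier_fraction' must lie in [0, 0.05]", call. = FALSE)
  }
  if (q <= 0.5 || q >= 1) stop("'q' must lie in (0.5, 1)", call. = FALSE)
  cl_means <- tapply(normalized, labels, mean)
  idx <- as.integer(names(cl_means))
  top <- idx[order(-cl_means, idx)[1L]]  # highest mean; ties to lowest index
  bg <- raw_counts[labels != top]
  n_out <- floor(outlier_fraction * length(bg))
  if (n_out > 0) {
    ord <- order(bg, decreasing = TRUE)
    bg <- bg[-ord[seq_len(n_out)]]
  }
  if (length(bg) < 20L) {
    stop(sprintf("only %d background cells after exclusions; fit would be unstable",
                 length(bg)), call. = FALSE)
  }
  fit <- fit_nbinom(bg)
  list(mu = fit$mu, size = fit$size, dist = fit$dist,
       threshold = nb_quantile(fit$mu, fit$size, q, fit$dist),
       q = q, n_background = length(bg))
}

# Assemble per-tag fit_background results into a background-model data.frame.
background_model <- function(fits, tags) {
  out <- data.frame(tag = tags,
                    mu = vapply(fits, `[[`, numeric(1), "mu"),
                    size = vapply(fits, `[[`, numeric(1), "size"),
                    dist = vapply(fits, `[[`, character(1), "dist"),
                    threshold = vapply(fits, function(f) as.numeric(f$threshold),
                                       numeric(1)),
                    q = vapply(fits, `[[`, numeric(1), "q"),
                    n_background = vapply(fits, function(f)
                      as.numeric(f$n_background), numeric(1)),
                    stringsAsFactors = FALSE)
  class(out) <- c("hash_background", class(out))
  out
}

#' Classify barcodes against fitted background thresholds
#'
#' A barcode is positive for a tag when its raw count exceeds (strictly) that
#' tag's threshold. Zero positive tags gives a negative call; one, a singlet
#' carrying that sample identity; two or more, a multiplet named after its
#' two most highly expressed tags (by normalized value, descending) joined
#' with `+`.
#'
#' @param counts Barcodes x tags count matrix.
#' @param model Background model data.frame from [demultiplex()] (or built
#'   from [fit_background()] results), one row per tag with a `threshold`.
#' @param normalized Matching CLR matrix, used to rank tags within a barcode.
#' @return data.frame with `barcode`, `global_class` (`singlet`, `multiplet`,
#'   `negative`), `hash_id`, `n_positive_tags`.
#' @export
classify_hashes <- function(counts, model, normalized) {
  counts <- as_count_matrix(counts)
  if (!all(colnames(counts) %in% model$tag)) {
    stop("background model does not cover every tag in 'counts'",
         call. = FALSE)
  }
  normalized <- as.matrix(normalized)
  stopifnot(identical(dim(counts), dim(normalized)))
  thr <- model$threshold[match(colnames(counts), model$tag)]
  pos <- sweep(counts, 2L, thr, ">")
  n_pos <- rowSums(pos)
  tags <- colnames(counts)
  hash_id <- character(nrow(counts))
  global <- ifelse(n_pos == 0L, "negative",
                   ifelse(n_pos == 1L, "singlet", "multiplet"))
  hash_id[n_pos == 0L] <- "negative"
  one <- which(n_pos == 1L)
  if (length(one)) {
    hash_id[one] <- tags[max.col(pos[one, , drop = FALSE], "first")]
  }
  multi <- which(n_pos >= 2L)
  for (i in multi) {
    cand <- which(pos[i, ])
    top2 <- cand[order(normalized[i, cand], decreasing = TRUE)[1:2]]
    hash_id[i] <- paste(tags[top2], collapse = "+")
  }
  data.frame(barcode = rownames(counts),
             global_class = global,
             hash_id = hash_id,
             n_positive_tags = as.integer(n_pos),
             stringsAsFactors = FALSE)
}

#' Demultiplex hashed cells
#'
#' The full classification pipeline: CLR-normalize the tag counts, cluster
#' all cells with seeded k-medoids (`k` = number of tags + 1 by default: one
#' cluster per tag plus one background cluster), fit a negative binomial
#' background per tag with [fit_background()], and call every barcode
#' singlet / multiplet / negative with [classify_hashes()].
#'
#' When per-barcode RNA UMI totals are supplied, barcodes below
#' `min_rna_umi` are excluded from fitting and classification and can later
#' be classified with the frozen thresholds via [rescue_low_umi()].
#'
#' @param counts Barcodes x tags UMI count matrix (sparse or dense).
#' @param rna_umi Optional named numeric vector of RNA UMI totals; names must
#'   cover all barcodes in `counts`.
#' @param k Number of k-medoids clusters (default `ncol(counts) + 1`).
#' @param q Background quantile defining positivity (default 0.99).
#' @param outlier_fraction Top fraction of background counts dropped before
#'   the NB fit (default 0.005).
#' @param min_rna_umi RNA UMI inclusion cutoff (default 200); ignored when
#'   `rna_umi` is `NULL`.
#' @param pseudocount CLR pseudocount (default 1).
#' @param seed Integer seed for the clustering.
#' @return Object of class `hash_demux`: a list with `classification`
#'   (data.frame as from [classify_hashes()]), `background` (per-tag model
#'   data.frame with thresholds), `normalized`, `counts`, `params` and
#'   `diagnostics` (per-class counts, per-tag thresholds, numbers of
#'   classified and held-out barcodes).
#' @export
demultiplex <- function(counts, rna_umi = NULL, k = NULL, q = 0.99,
                        outlier_fraction = 0.005, min_rna_umi = 200,
                        pseudocount = 1, seed = 1L) {
  counts <- as_count_matrix(counts)
  if (is.null(k)) k <- ncol(counts) + 1L
  held <- character(0)
  if (!is.null(rna_umi)) {
    if (is.null(names(rna_umi)) || !all(rownames(counts) %in% names(rna_umi))) {
      stop("'rna_umi' must be named and cover every barcode in 'counts'",
           call. = FALSE)
    }
    rna_umi <- rna_umi[rownames(counts)]
    held <- rownames(counts)[rna_umi < min_rna_umi]
    counts_fit <- counts[rna_umi >= min_rna_umi, , drop = FALSE]
  } else {
    counts_fit <- counts
  }
  if (nrow(counts_fit) < 2L * k) {
    stop(sprintf("only %d barcodes pass the RNA UMI gate; too few to fit",
                 nrow(counts_fit)), call. = FALSE)
  }
  normalized <- clr_normalize(counts_fit, pseudocount)
  cl <- kmedoids(normalized, k = k, seed = seed)
  tags <- colnames(counts_fit)
  fits <- lapply(tags, function(t) {
    fit_background(counts_fit[, t], cl$labels, normalized[, t],
                   outlier_fraction = outlier_fraction, q = q)
  })
  model <- background_model(fits, tags)
  classification <- classify_hashes(counts_fit, model, normalized)
  diag <- list(n_classified = nrow(counts_fit),
               n_held_low_umi = length(held),
               class_counts = table(classification$global_class),
               thresholds = stats::setNames(model$threshold, model$tag))
  structure(list(classification = classification,
                 background = model,
                 normalized = normalized,
                 counts = counts_fit,
                 held_barcodes = held,
                 params = list(k = k, q = q,
                               outlier_fraction = outlier_fraction,
                               min_rna_umi = min_rna_umi,
                               pseudocount = pseudocount, seed = seed),
                 diagnostics = diag),
            class = "hash_demux")
}

#' @export
print.hash_demux <- function(x, ...) {
  cat("Hash demultiplexing of", x$diagnostics$n_classified, "barcodes,",
      ncol(x$counts), "tags\n")
  print(x$diagnostics$class_counts)
  cat("per-tag thresholds (count units):\n")
  print(x$diagnostics$thresholds)
  invisible(x)
}

#' Re-classify low-UMI barcodes with frozen thresholds
#'
#' Applies previously fitted per-tag thresholds to barcodes that were held
#' out of the fit, typically those with 50-200 RNA UMIs, distinguishing
#' low-RNA cells (which still carry a clean hashtag signal) from ambient-RNA
#' barcodes (which do not). Counts are CLR-normalized within the rescue set
#' (used only to rank tags within a barcode); positivity uses the frozen raw
#' count thresholds, so rescue applied to the originally classified set
#' reproduces its calls exactly.
#'
#' @param counts Barcodes x tags count matrix for the rescue candidates.
#' @param model Fitted background model (`$background` of a `hash_demux`
#'   object, or that object itself).
#' @param rna_umi Optional named RNA UMI totals; if given, `counts` is
#'   restricted to barcodes with `low <= rna_umi < high`.
#' @param low,high RNA UMI rescue window (defaults 50 and 200).
#' @param pseudocount CLR pseudocount (default 1).
#' @return Classification data.frame as from [classify_hashes()]; zero rows
#'   if no barcode falls in the window.
#' @export
rescue_low_umi <- function(counts, model, rna_umi = NULL, low = 50,
                           high = 200, pseudocount = 1) {
  if (inherits(model, "hash_demux")) model <- model$background
  counts <- as_count_matrix(counts)
  if (!is.null(rna_umi)) {
    if (is.null(names(rna_umi)) || !all(rownames(counts) %in% names(rna_umi))) {
      stop("'rna_umi' must be named and cover every barcode in 'counts'",
           call. = FALSE)
    }
    rna_umi <- rna_umi[rownames(counts)]
    counts <- counts[rna_umi >= low & rna_umi < high, , drop = FALSE]
  }
  if (nrow(counts) == 0L) {
    return(data.frame(barcode = character(0), global_class = character(0),
                      hash_id = character(0), n_positive_tags = integer(0),
                      stringsAsFactors = FALSE))
  }
  normalized <- clr_normalize(counts, pseudocount)
  classify_hashes(counts, model, normalized)
}
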