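# Internal helpers shared across modules.

#' @keywords internal
#' @importFrom methods as
#' @importFrom stats median
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Negative binomial draws in (mean, size) parameterization; size = Inf is the
# Poisson limit. Zero mean yields exact zeros.
rnb <- function(n, mu, size) {
  if (length(mu) == 1L) mu <- rep(mu, n)
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (is.infinite(size)) {
      stats::rpois(sum(pos), mu[pos])
    } else {
      stats::rnbinom(sum(pos), size = size, mu = mu[pos])
    }
  }
  out
}

# Coerce a counts container (sparse Matrix, matrix or data.frame) to a dense
# integer-valued barcodes x tags matrix, validating the TagCountMatrix
# invariants.
as_count_matrix <- function(counts, what = "counts") {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(sprintf("'%s' must be a numeric barcodes x tags matrix", what),
         call. = FALSE)
  }
  if (anyNA(counts)) stop(sprintf("'%s' contains NA values", what), call. = FALSE)
  if (any(counts < 0)) {
    stop(sprintf("'%s' contains negative values", what), call. = FALSE)
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop(sprintf("'%s' contains non-integer values", what), call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop(sprintf("'%s' must have barcode rownames and tag colnames", what),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop(sprintf("duplicate barcodes in '%s': %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop(sprintf("duplicate tag names in '%s'", what), call. = FALSE)
  }
  storage.mode(counts) <- "double"
  round(counts)
}

# Deterministic random DNA barcodes, guaranteed unique.
random_barcodes <- function(n, width = 16L) {
  bases <- c("A", "C", "G", "T")
  draw <- function(m) {
    apply(matrix(sample(bases, m * width, replace = TRUE), nrow = m), 1, paste,
          collapse = "")
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

pkg_version_string <- function() {
  paste0("hashdemux ", as.character(utils::packageVersion("hashdemux")))
}
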