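#' Droplet loading model
#'
#' Describes how cells are loaded into droplets: occupancy is Poisson with
#' rate `lambda_cells`, each cell is drawn from one of `length(sample_proportions)`
#' pooled samples, and a fraction of cells carry no hashtag (unstained
#' negative-control cells spiked into the pool).
#'
#' The defaults describe a "super-loaded" run of a droplet platform: at
#' `lambda_cells = 0.43`, 80% of occupied droplets hold a single cell, so a
#' run at this rate targeting 20,000 singlets carries roughly 5,000
#' multiplets; eight equally pooled samples plus roughly one
#' sample-equivalent of unstained control cells (`unlabeled_fraction = 1/9`).
#'
#' @param lambda_cells Mean number of cells per droplet (Poisson rate, > 0).
#' @param sample_proportions Non-negative vector of sample mixing fractions,
#'   summing to 1. Its length sets the number of hashtags. Names, if present,
#'   are used as tag names; otherwise `HTO1..HTOs`.
#' @param n_droplets Number of droplets to emit (>= 1).
#' @param unlabeled_fraction Fraction in `[0, 1)` of cells carrying no
#'   hashtag.
#' @return A `loading_model` list.
#' @export
loading_model <- function(lambda_cells = 0.43,
                          sample_proportions = rep(1 / 8, 8),
                          n_droplets = 20000L,
                          unlabeled_fraction = 1 / 9) {
  if (!is.numeric(lambda_cells) || length(lambda_cells) != 1L ||
      !is.finite(lambda_cells) || lambda_cells <= 0) {
    stop("'lambda_cells' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sample_proportions) || any(sample_proportions < 0)) {
    stop("'sample_proportions' must be non-negative", call. = FALSE)
  }
  if (abs(sum(sample_proportions) - 1) > 1e-12) {
    stop("'sample_proportions' must sum to 1 (within 1e-12)", call. = FALSE)
  }
  n_droplets <- as.integer(n_droplets)
  if (is.na(n_droplets) || n_droplets < 1L) {
    stop("'n_droplets' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(unlabeled_fraction) || unlabeled_fraction < 0 ||
      unlabeled_fraction >= 1) {
    stop("'unlabeled_fraction' must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(names(sample_proportions))) {
    names(sample_proportions) <- paste0("HTO", seq_along(sample_proportions))
  }
  structure(list(lambda_cells = lambda_cells,
                 sample_proportions = sample_proportions,
                 n_droplets = n_droplets,
                 unlabeled_fraction = unlabeled_fraction),
            class = "loading_model")
}

#' Tag signal model
#'
#' Count-level model for simulated hashtag data. A cell's own tag contributes
#' negative binomial counts with mean `signal_mean`; every tag also receives
#' ambient background counts with mean `background_mean` in every droplet.
#' Sizes are NB size (dispersion) parameters; `size = Inf` gives the Poisson
#' limit. Per-cell RNA UMI totals are lognormal and exist only to drive the
#' 200-UMI inclusion gate and the 50-200-UMI rescue window.
#'
#' @param signal_mean NB mean of a cell's own tag count.
#' @param signal_dispersion NB size for the signal component (> 0, may be `Inf`).
#' @param background_mean NB mean of ambient counts for every tag.
#' @param background_dispersion NB size for the background component.
#' @param rna_umi_meanlog,rna_umi_sdlog Lognormal parameters for per-cell
#'   RNA UMI totals.
#' @return A `signal_model` list.
#' @export
signal_model <- function(signal_mean = 100,
                         signal_dispersion = 10,
                         background_mean = 2,
                         background_dispersion = 2,
                         rna_umi_meanlog = log(2000),
                         rna_umi_sdlog = 1) {
  if (signal_mean < 0 || background_mean < 0) {
    stop("NB means must be >= 0", call. = FALSE)
  }
  if (signal_dispersion <= 0 || background_dispersion <= 0) {
    stop("NB dispersions (sizes) must be > 0", call. = FALSE)
  }
  if (signal_mean <= background_mean) {
    warning("signal_mean <= background_mean: simulated tags will be inseparable")
  }
  structure(list(signal_mean = signal_mean,
                 signal_dispersion = signal_dispersion,
                 background_mean = background_mean,
                 background_dispersion = background_dispersion,
                 rna_umi_meanlog = rna_umi_meanlog,
                 rna_umi_sdlog = rna_umi_sdlog),
            class = "signal_model")
}

#' Closed-form Poisson loading expectations
#'
#' For droplets loaded at Poisson rate `lambda_cells` with cells drawn
#' independently from samples with mixing `proportions`, returns the expected
#' fractions of occupied droplets that are singlets and multiplets, and
#' splits multiplets into cross-sample (members from at least two samples,
#' detectable by hashing) and unresolved (all members from one sample,
#' invisible to hashing).
#'
#' All fractions are conditional on occupancy >= 1. With occupancy
#' `K ~ Poisson(lambda)` the unresolved mass is
#' `sum_k P(K = k) sum_j p_j^k = sum_j exp(-lambda) (exp(lambda p_j) - 1 - lambda p_j)`
#' over `k >= 2`, which is evaluated in closed form.
#'
#' @param lambda_cells Poisson loading rate (> 0).
#' @param proportions Sample mixing fractions summing to 1; one sample
#'   (`length 1`) yields zero cross-sample multiplets.
#' @return A list with `frac_singlet`, `frac_multiplet`,
#'   `frac_cross_sample_multiplet`, `frac_unresolved_multiplet`.
#' @examples
#' expected_loading_stats(0.43, rep(1 / 8, 8))
#' @export
expected_loading_stats <- function(lambda_cells, proportions) {
  if (!is.numeric(lambda_cells) || length(lambda_cells) != 1L ||
      !is.finite(lambda_cells) || lambda_cells <= 0) {
    stop("'lambda_cells' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(proportions) || length(proportions) < 1L ||
      any(proportions < 0)) {
    stop("'proportions' must be a non-negative vector", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-12) {
    stop("'proportions' must sum to 1 (within 1e-12)", call. = FALSE)
  }
  lam <- lambda_cells
  p_occ <- -expm1(-lam)                      # P(K >= 1)
  p1 <- lam * exp(-lam)                      # P(K = 1)
  frac_singlet <- p1 / p_occ
  # P(K >= 2) = e^-lam (e^lam - 1 - lam), written via expm1 so the
  # cancellation at small lam does not destroy the multiplet mass
  frac_multiplet <- exp(-lam) * (expm1(lam) - lam) / p_occ
  # sum over k>=2 of P(K=k) * sum_j p_j^k, in closed form per sample
  unresolved_mass <- sum(exp(-lam) * (expm1(lam * proportions) -
                                        lam * proportions))
  frac_unresolved <- unresolved_mass / p_occ
  frac_cross <- frac_multiplet - frac_unresolved
  # numerical guard for the one-sample case
  if (length(proportions) == 1L) frac_cross <- 0
  list(frac_singlet = frac_singlet,
       frac_multiplet = frac_multiplet,
       frac_cross_sample_multiplet = max(frac_cross, 0),
       frac_unresolved_multiplet = frac_unresolved)
}

#' Simulate a hashed droplet experiment with known ground truth
#'
#' Draws droplet occupancies from `Poisson(lambda_cells)`, assigns each cell a
#' sample label (or no label, for negative-control cells), and emits a
#' barcodes x tags UMI count matrix: a droplet containing `m` cells of sample
#' `t` contributes `NB(signal_mean * m, signal_dispersion)` counts for tag `t`
#' on top of an ambient `NB(background_mean, background_dispersion)` draw that
#' every tag receives in every droplet. Empty droplets appear in the truth
#' table but emit no matrix row. Identical inputs and seed give bit-identical
#' output.
#'
#' @param loading A [loading_model()].
#' @param signal A [signal_model()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list with
#'   \describe{
#'     \item{counts}{sparse `dgCMatrix`, barcodes x tags, integer UMI counts}
#'     \item{truth}{data.frame with `droplet_id`, `true_class` (one of
#'       `singlet`, `multiplet`, `negative-control-only`, `empty`),
#'       `member_samples` (comma-separated labels of the member cells,
#'       unlabeled cells as `"unlabeled"`, empty string for empty droplets)
#'       and `rna_umi` (total RNA UMIs in the droplet)}
#'   }
#' @export
simulate_experiment <- function(loading = loading_model(),
                                signal = signal_model(),
                                seed = 1L) {
  stopifnot(inherits(loading, "loading_model"), inherits(signal, "signal_model"))
  with_seed(seed, {
    s <- length(loading$sample_proportions)
    tags <- names(loading$sample_proportions)
    nd <- loading$n_droplets
    occ <- stats::rpois(nd, loading$lambda_cells)
    droplet_id <- random_barcodes(nd)
    n_cells <- sum(occ)
    # per-cell labels: 0 = unlabeled negative-control cell
    cell_lab <- ifelse(stats::runif(n_cells) < loading$unlabeled_fraction, 0L,
                       sample.int(s, n_cells, replace = TRUE,
                                  prob = loading$sample_proportions))
    cell_drop <- rep.int(seq_len(nd), occ)
    # labeled-cell copy number per droplet x tag
    copies <- matrix(0L, nd, s)
    lab_ok <- cell_lab > 0L
    if (any(lab_ok)) {
      tb <- table(factor(cell_drop[lab_ok], levels = seq_len(nd)),
                  factor(cell_lab[lab_ok], levels = seq_len(s)))
      copies <- matrix(as.integer(tb), nd, s)
    }
    keep <- occ > 0L
    n_keep <- sum(keep)
    counts <- matrix(0L, n_keep, s, dimnames = list(droplet_id[keep], tags))
    if (n_keep > 0) {
      sig_mu <- signal$signal_mean * copies[keep, , drop = FALSE]
      sig <- matrix(rnb(n_keep * s, as.vector(sig_mu),
                        signal$signal_dispersion), n_keep, s)
      bg <- matrix(rnb(n_keep * s, signal$background_mean,
                       signal$background_dispersion), n_keep, s)
      counts[] <- sig + bg
    }
    rna_cell <- stats::rlnorm(n_cells, signal$rna_umi_meanlog,
                              signal$rna_umi_sdlog)
    rna <- as.vector(tapply(c(rna_cell, rep(0, nd)),
                            c(cell_drop, seq_len(nd)), sum))
    by_drop <- split(cell_lab, factor(cell_drop, levels = seq_len(nd)))
    member <- vapply(by_drop, function(m) {
      if (length(m) == 0L) return("")
      paste(ifelse(m == 0L, "unlabeled", tags[m]), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    n_labeled <- vapply(by_drop, function(m) sum(m > 0L), integer(1),
                        USE.NAMES = FALSE)
    true_class <- ifelse(occ == 0L, "empty",
                  ifelse(n_labeled == 0L, "negative-control-only",
                  ifelse(n_labeled == 1L, "singlet", "multiplet")))
    truth <- data.frame(droplet_id = droplet_id,
                        true_class = true_class,
                        member_samples = member,
                        rna_umi = round(rna),
                        stringsAsFactors = FALSE)
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         truth = truth)
  })
}

#' Read a flat key/value simulator configuration (YAML)
#'
#' Keys are the argument names of [loading_model()] and [signal_model()]
#' (e.g. `lambda_cells`, `n_droplets`, `signal_mean`, ...);
#' `sample_proportions` may be a YAML sequence. Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `loading` and `signal`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  l_args <- names(formals(loading_model))
  s_args <- names(formals(signal_model))
  unknown <- setdiff(names(cfg), c(l_args, s_args))
  if (length(unknown)) {
    stop("unknown simulator config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(loading = do.call(loading_model, cfg[intersect(names(cfg), l_args)]),
       signal = do.call(signal_model, cfg[intersect(names(cfg), s_args)]))
}

#' Write simulator ground truth as TSV
#' @param truth Truth data.frame from [simulate_experiment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
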