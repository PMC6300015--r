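mat1 <- function(x, tag = "HTO1") {
  matrix(x, ncol = 1, dimnames = list(sprintf("b%03d", seq_along(x)), tag))
}

test_that("CLR normalization matches the closed form", {
  expect_equal(as.vector(clr_normalize(mat1(c(1, 1, 1)), pseudocount = 0)),
               c(0, 0, 0))
  # geometric mean of (1, 10, 100) is 10
  expect_equal(as.vector(clr_normalize(mat1(c(1, 10, 100)), pseudocount = 0)),
               c(-log(10), 0, log(10)))
  expect_equal(as.vector(clr_normalize(mat1(c(0, 0, 0)), pseudocount = 1)),
               c(0, 0, 0))
  expect_error(clr_normalize(mat1(c(0, 1, 2)), pseudocount = 0), "zero")
})

test_that("CLR values average to zero per tag on arbitrary count matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnbinom(400, size = 1, mu = 8), 50, 8,
                dimnames = list(sprintf("b%02d", 1:50), paste0("T", 1:8)))
    norm <- clr_normalize(m)
    expect_lt(max(abs(colMeans(norm))), 1e-9)
    expect_true(all(is.finite(norm)))
  }
})

test_that("k-medoids recovers separated clouds and is deterministic", {
  set.seed(2)
  x <- matrix(c(rnorm(40, -10, 0.1), rnorm(40, 0, 0.1), rnorm(40, 10, 0.1)),
              ncol = 1, dimnames = list(sprintf("c%03d", 1:120), "v"))
  cl <- kmedoids(x, k = 3, seed = 9)
  truth <- rep(1:3, each = 40)
  # same partition up to label permutation
  expect_equal(length(unique(paste(cl$labels, truth))), 3L)
  cl2 <- kmedoids(x, k = 3, seed = 9)
  expect_identical(cl$labels, cl2$labels)
  expect_error(kmedoids(x[c(1, 1, 1), , drop = FALSE], k = 3), "distinct")
})

test_that("k-medoids objective beats random medoid choices", {
  set.seed(5)
  x <- matrix(rnorm(120), 60, 2, dimnames = list(sprintf("c%02d", 1:60), NULL))
  cl <- kmedoids(x, k = 3, seed = 4)
  objective <- function(medoids) {
    d <- as.matrix(dist(rbind(medoids, x)))[-(1:3), 1:3]
    sum(apply(d, 1, min))
  }
  obj_fit <- objective(cl$medoids)
  for (i in 1:100) {
    rnd <- x[sample(60, 3), , drop = FALSE]
    expect_lte(obj_fit, objective(rnd) + 1e-9)
  }
})

test_that("NB fit recovers parameters and falls back gracefully", {
  set.seed(8)
  x <- rnbinom(10000, size = 2, mu = 5)
  fit <- fit_nbinom(x)
  expect_equal(fit$dist, "nbinom")
  expect_lt(abs(fit$mu - 5) / 5, 0.05)
  expect_lt(abs(fit$size - 2) / 2, 0.25)

  expect_warning(f0 <- fit_nbinom(rep(3L, 50)), "zero-variance")
  expect_identical(f0$dist, "degenerate")
  expect_warning(fp <- fit_nbinom(rep(c(3L, 4L), 50)), "Poisson")
  expect_identical(fp$size, Inf)
})

test_that("background fit excludes the positive cluster and thresholds at q", {
  set.seed(3)
  n_bg <- 400; n_pos <- 100
  raw <- c(rnbinom(n_bg, size = 2, mu = 4), rnbinom(n_pos, size = 10, mu = 200))
  labels <- rep(c(1L, 2L), c(n_bg, n_pos))
  normalized <- c(rnorm(n_bg, -1, 0.2), rnorm(n_pos, 3, 0.2))
  bgm <- fit_background(raw, labels, normalized, outlier_fraction = 0.005,
                        q = 0.99)
  # the fit must see only background-scale counts
  expect_lt(bgm$mu, 10)
  expect_equal(bgm$n_background, n_bg - floor(0.005 * n_bg))
  # threshold equals the brute-force pmf-summation quantile
  cdf <- cumsum(dnbinom(0:10000, size = bgm$size, mu = bgm$mu))
  expect_identical(as.integer(bgm$threshold),
                   as.integer(which(cdf >= 0.99)[1] - 1L))

  # degenerate background: point mass at c gives threshold c
  expect_warning(
    deg <- fit_background(c(rep(7L, 50), rep(100L, 30)),
                          rep(c(1L, 2L), c(50, 30)),
                          c(rep(-1, 50), rep(3, 30))),
    "zero-variance")
  expect_equal(deg$threshold, 7)

  expect_error(fit_background(raw[1:25], labels[1:25], normalized[1:25]),
               "background cells")
  expect_error(fit_background(raw, labels, normalized, q = 0.4), "'q'")
  expect_error(fit_background(raw, labels, normalized,
                              outlier_fraction = 0.2), "outlier_fraction")
})

test_that("thresholds are monotone in q and positives shrink as q grows", {
  set.seed(14)
  raw <- c(rnbinom(500, size = 2, mu = 4), rnbinom(80, size = 10, mu = 150))
  labels <- rep(c(1L, 2L), c(500, 80))
  normalized <- c(rnorm(500, -1, 0.2), rnorm(80, 3, 0.2))
  qs <- c(0.9, 0.95, 0.99, 0.999)
  thr <- vapply(qs, function(q)
    fit_background(raw, labels, normalized, q = q)$threshold, numeric(1))
  expect_true(all(diff(thr) >= 0))
  n_pos <- vapply(thr, function(t) sum(raw > t), numeric(1))
  expect_true(all(diff(n_pos) <= 0))
})

test_that("classification follows the positivity-count rule", {
  tags <- c("A", "B", "C")
  counts <- matrix(c(50, 2, 1,    # singlet A
                     40, 30, 0,   # multiplet, A higher
                     5, 60, 12,   # multiplet, B higher
                     1, 2, 3),    # negative
                   4, 3, byrow = TRUE,
                   dimnames = list(paste0("b", 1:4), tags))
  model <- data.frame(tag = tags, mu = 2, size = 2, dist = "nbinom",
                      threshold = c(9, 9, 9), q = 0.99, n_background = 100)
  normalized <- clr_normalize(counts)
  cls <- classify_hashes(counts, model, normalized)
  expect_identical(cls$global_class, c("singlet", "multiplet", "multiplet",
                                       "negative"))
  expect_identical(cls$hash_id, c("A", "A+B", "B+C", "negative"))
  expect_identical(cls$n_positive_tags, c(1L, 2L, 2L, 0L))
})

test_that("demultiplexing recovers simulated ground truth", {
  sim <- small_sim(seed = 31, n_droplets = 6000, s = 8)
  res <- demultiplex(sim$counts, seed = 31)
  tr <- truth_for(res$classification, sim$truth)

  singlets <- tr$true_class == "singlet"
  acc <- mean(res$classification$global_class[singlets] == "singlet" &
                res$classification$hash_id[singlets] ==
                true_singlet_tag(tr$member_samples)[singlets])
  expect_gte(acc, 0.98)

  cross <- is_cross_sample(tr$member_samples)
  expect_gte(mean(res$classification$global_class[cross] == "multiplet"), 0.9)

  negs <- tr$true_class == "negative-control-only"
  expect_gte(mean(res$classification$global_class[negs] == "negative"), 0.95)
})

test_that("row order does not change per-barcode calls", {
  sim <- small_sim(seed = 17, n_droplets = 3000, s = 4)
  res <- demultiplex(sim$counts, seed = 17)
  set.seed(1)
  perm <- sample(nrow(sim$counts))
  res_p <- demultiplex(sim$counts[perm, ], seed = 17)
  a <- res$classification[order(res$classification$barcode), ]
  b <- res_p$classification[order(res_p$classification$barcode), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("rescaling one tag leaves other tags' thresholds alone", {
  sim <- small_sim(seed = 23, n_droplets = 3000, s = 4)
  counts <- as.matrix(sim$counts)
  res <- demultiplex(counts, seed = 23)

  # exact at the fit level: a tag's background fit sees only its own counts
  normalized <- res$normalized
  labels <- kmedoids(normalized, k = 5, seed = 23)$labels
  before <- fit_background(counts[, 2], labels, normalized[, 2])
  counts_scaled <- counts
  counts_scaled[, 1] <- counts_scaled[, 1] * 3L
  after <- fit_background(counts_scaled[, 2], labels, normalized[, 2])
  expect_identical(before$threshold, after$threshold)
  expect_identical(before$mu, after$mu)
  # the rescaled tag's own threshold does move, of course
  own <- fit_background(counts_scaled[, 1], labels, normalized[, 1])
  expect_gt(own$threshold, fit_background(counts[, 1], labels,
                                          normalized[, 1])$threshold)
})

test_that("low-UMI rescue applies frozen thresholds", {
  sim <- small_sim(seed = 41, n_droplets = 6000, s = 4)
  rna <- setNames(sim$truth$rna_umi, sim$truth$droplet_id)
  res <- demultiplex(sim$counts, rna_umi = rna, seed = 41)
  expect_true(all(rna[res$classification$barcode] >= 200))

  rescued <- rescue_low_umi(sim$counts, res, rna_umi = rna)
  expect_true(all(rna[rescued$barcode] >= 50 & rna[rescued$barcode] < 200))
  # rescued low-RNA singlets really carry a single strong tag
  tr <- truth_for(rescued, sim$truth)
  r_singlet <- rescued$global_class == "singlet"
  if (any(r_singlet)) {
    expect_gte(mean(rescued$hash_id[r_singlet] ==
                      true_singlet_tag(tr$member_samples)[r_singlet]), 0.9)
  }

  # empty window is not an error
  none <- rescue_low_umi(sim$counts, res, rna_umi = rna, low = 1, high = 2)
  expect_identical(nrow(none), 0L)

  # self-consistency: rescue on the classified set reproduces its calls
  again <- rescue_low_umi(res$counts, res)
  expect_identical(again, res$classification)
})
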