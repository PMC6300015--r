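# Shared fixture builders. Everything is generated in code under fixed seeds.

# Small, well-separated hashed experiment (exact-PAM scale).
small_sim <- function(seed = 101, n_droplets = 4000, s = 4,
                      unlabeled_fraction = 1 / 9) {
  simulate_experiment(
    loading_model(lambda_cells = 0.43, sample_proportions = rep(1 / s, s),
                  n_droplets = n_droplets,
                  unlabeled_fraction = unlabeled_fraction),
    signal_model(), seed = seed)
}

# Truth helpers operating on the simulator's member_samples encoding.
labeled_members <- function(member_samples) {
  lapply(strsplit(member_samples, ","), function(m) m[m != "unlabeled"])
}

true_singlet_tag <- function(member_samples) {
  vapply(labeled_members(member_samples), function(m) {
    if (length(m) == 1L) m else NA_character_
  }, character(1))
}

is_cross_sample <- function(member_samples) {
  vapply(labeled_members(member_samples),
         function(m) length(unique(m)) >= 2L, logical(1))
}

# Align truth rows with a classification data.frame.
truth_for <- function(classification, truth) {
  truth[match(classification$barcode, truth$droplet_id), ]
}

# Write a 4-line-per-record FASTQ (constant qualities).
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", ids), seqs, "+",
                   vapply(nchar(seqs), function(n)
                     paste(rep("I", n), collapse = ""), character(1))), con)
  invisible(path)
}

mutate_seq <- function(seq, positions, bases) {
  s <- strsplit(seq, "")[[1]]
  s[positions] <- bases
  paste(s, collapse = "")
}

random_dna <- function(n, width) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
               nrow = n), 1, paste, collapse = "")
}

demo_library <- function() {
  tag_library(paste0("HTO", 1:4),
              c("ACGTACGTACGT", "TTTTCCCCGGGG", "GAGAGAGATCTC",
                "CACACACAGTGT"))
}

# Brute-force hamming distance used as the independent oracle in tests.
oracle_hamming <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}
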