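# Independent oracles used across tests. These deliberately avoid the
# package's own counting/ranking code paths.

# Brute-force dictionary count of K-mer relative frequencies: for each
# key, count matching windows by direct comparison.
oracle_kmer_freq <- function(reduced, keys, k) {
  L <- nchar(reduced)
  if (L < k) return(stats::setNames(rep(0, length(keys)), keys))
  starts <- seq_len(L - k + 1)
  windows <- vapply(starts, function(s) substr(reduced, s, s + k - 1),
                    character(1))
  counts <- vapply(keys, function(key) sum(windows == key), numeric(1))
  counts / length(windows)
}

# Pairwise Mann-Whitney AUC: wins + half-ties over all pos x neg pairs.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

random_canonical_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

write_temp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fasta")
  write_fasta(records, path)
  path
}

# Small labeled synthetic sets reused in classifier tests.
planted_dataset <- function(n_per_class, delta, seed,
                            effect_group = "E") {
  generate_dataset(synthetic_spec(n_pos = n_per_class, n_neg = n_per_class,
                                  effect_group = effect_group,
                                  delta = delta, seed = seed))
}
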