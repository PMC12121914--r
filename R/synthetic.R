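# Background residue frequencies (approximate vertebrate proteome
# composition); normalized at use.
.background_composition <- c(
  A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07, H = 2.27,
  I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06, P = 4.70, Q = 3.93,
  R = 5.53, S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
)

#' Specification for a synthetic labeled protein dataset
#'
#' Describes a two-class set of i.i.d.-residue protein sequences with a
#' planted composition difference: positives carry `delta` extra
#' probability mass on the residues of one reduced-alphabet group
#' (spread proportionally within the group, with the rest of the
#' alphabet down-weighted proportionally), negatives follow the
#' background composition. Lengths are log-normal with a floor and cap,
#' emulating real protein-length distributions in which sequences are
#' at least 50 residues and roughly 90% fall under 1000.
#'
#' @param n_pos,n_neg Class sizes (positives / negatives); both > 0.
#' @param effect_group Symbol of the reduced-alphabet group carrying the
#'   planted signal (must exist in `scheme`).
#' @param delta Excess probability mass on `effect_group` in positives
#'   (0 = null, identical emission distributions).
#' @param scheme Scheme defining the group (default `"Op11"`).
#' @param length_median,length_sigma Log-normal length law parameters
#'   (median on the natural scale, sigma on the log scale).
#' @param min_length,max_length Floor and truncation cap for lengths.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `synthetic_spec` list (including the per-class residue
#'   emission probabilities `p_pos`, `p_neg`).
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 200L,
                           effect_group = "E", delta = 0,
                           scheme = "Op11",
                           length_median = 400, length_sigma = 0.7,
                           min_length = 50L, max_length = 5000L,
                           seed = 1L) {
  if (n_pos <= 0L || n_neg <= 0L)
    stop("n_pos and n_neg must both be positive")
  if (delta < 0) stop("delta must be >= 0")
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  if (!effect_group %in% scheme$symbols)
    stop("effect_group '", effect_group, "' is not a symbol of scheme ",
         scheme$name)
  p <- .background_composition / sum(.background_composition)
  members <- scheme$groups[[effect_group]]
  mass <- sum(p[members])
  if (mass + delta >= 1)
    stop("delta too large: group mass would reach ", mass + delta)
  if (delta == 0) {
    p_pos <- p  # exactly shared emission distribution under the null
  } else {
    p_pos <- p
    p_pos[members] <- p[members] * (mass + delta) / mass
    p_pos[setdiff(names(p), members)] <-
      p[setdiff(names(p), members)] * (1 - mass - delta) / (1 - mass)
  }
  stopifnot(abs(sum(p_pos) - 1) < 1e-12, all(p_pos >= 0))
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    effect_group = effect_group, delta = delta,
    scheme_name = scheme$name,
    p_pos = p_pos, p_neg = p,
    length_median = length_median, length_sigma = length_sigma,
    min_length = as.integer(min_length), max_length = as.integer(max_length),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic labeled dataset
#'
#' Sequences are emitted residue-by-residue i.i.d. from the class
#' emission distribution (positional structure is deliberately absent:
#' the downstream classifier at its K = 1 optimum sees composition
#' only). Reproducible byte-for-byte from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `labeled_dataset` (positives first, labeled 1), whose
#'   records can be written with [write_fasta()].
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  draw_lengths <- function(n) {
    L <- round(stats::rlnorm(n, meanlog = log(spec$length_median),
                             sdlog = spec$length_sigma))
    pmin(pmax(L, spec$min_length), spec$max_length)
  }
  draw_class <- function(n, p, prefix) {
    L <- draw_lengths(n)
    seqs <- vapply(L, function(len)
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
      character(1))
    protein_records(sprintf("%s%04d", prefix, seq_len(n)), seqs)
  }
  pos <- draw_class(spec$n_pos, spec$p_pos, "POS")
  neg <- draw_class(spec$n_neg, spec$p_neg, "NEG")
  records <- rbind(pos, neg)
  class(records) <- c("protein_records", "data.frame")
  labeled_dataset(records, c(rep(1L, spec$n_pos), rep(0L, spec$n_neg)),
                  task = "synthetic")
}

#' Small fixed worked-example records
#'
#' Hand-checkable fixtures for regression tests of the encoding chain:
#' the six-residue sequence `"ACDEFG"` with its expected 3-mers and its
#' 11-group reduced image, and the full canonical alphabet with its
#' expected number of distinct reduced symbols.
#'
#' @return A list: `sequence`, `kmers_k3`, `reduced_op11`,
#'   `full_alphabet`, `n_op11_symbols`.
#' @export
worked_example_fixtures <- function() {
  list(
    sequence = "ACDEFG",
    kmers_k3 = c("ACD", "CDE", "DEF", "EFG"),
    reduced_op11 = "AVNEFG",
    full_alphabet = paste(CANONICAL_RESIDUES, collapse = ""),
    n_op11_symbols = 11L
  )
}
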