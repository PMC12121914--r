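#' Reduce sequences to a reduced-alphabet representation
#'
#' Replaces each canonical residue by its group symbol under a
#' [reduction_scheme]; length is preserved (reduction is residue-wise).
#'
#' @param x Character vector of canonical amino-acid sequences, or a
#'   `protein_records` data frame.
#' @param scheme A [reduction_scheme] or a name accepted by
#'   [load_scheme()].
#' @return Character vector of reduced sequences (named by record id
#'   when `x` is a `protein_records`), with attribute `scheme_name`.
#' @examples
#' reduce_sequence("ACDEFG", "Op11")  # "AVNEFG"
#' @export
reduce_sequence <- function(x, scheme) {
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  seqs <- if (inherits(x, "protein_records")) {
    structure(x$sequence, names = x$id)
  } else as.character(x)
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    ch <- substring(seqs[i], bad[i], bad[i])
    stop("cannot reduce: non-canonical residue '", ch, "' at position ",
         bad[i], if (!is.null(names(seqs))) paste0(" of '", names(seqs)[i], "'"),
         call. = FALSE)
  }
  out <- chartr(paste(names(scheme$map), collapse = ""),
                paste(unname(scheme$map), collapse = ""), seqs)
  attr(out, "scheme_name") <- scheme$name
  out
}

#' Extract overlapping K-mers by sliding window
#'
#' Moves a window of length `k` across the sequence one position at a
#' time, yielding the `L - k + 1` overlapping windows in order.
#'
#' @param x A single sequence (character scalar).
#' @param k Window length (positive integer).
#' @return Character vector of K-mers; empty (with a warning) if the
#'   sequence is shorter than `k`.
#' @examples
#' extract_kmers("ACDEFG", 3)  # "ACD" "CDE" "DEF" "EFG"
#' @export
extract_kmers <- function(x, k) {
  stopifnot(length(x) == 1L, k >= 1L)
  k <- as.integer(k)
  L <- nchar(x)
  if (L < k) {
    warning("sequence of length ", L, " is shorter than k = ", k,
            "; no windows", call. = FALSE)
    return(character())
  }
  starts <- seq_len(L - k + 1L)
  substring(x, starts, starts + k - 1L)
}

#' Enumerate all K-mers over a scheme's symbols
#'
#' Order is lexicographic over the scheme's declared symbol order (the
#' first position is most significant), fixed and identical across all
#' sequences so that feature matrices are reproducible bit-for-bit.
#'
#' @param scheme A [reduction_scheme].
#' @param k K-mer length.
#' @return Character vector of length `size^k`.
#' @export
kmer_alphabet <- function(scheme, k) {
  stopifnot(k >= 1L)
  kmers <- scheme$symbols
  if (k > 1L) for (i in 2:k)
    kmers <- as.vector(t(outer(kmers, scheme$symbols, paste0)))
  kmers
}

#' K-mer relative-frequency feature vectors
#'
#' Counts each sliding window and divides by the number of windows
#' (`L - k + 1`), so every row is a relative-frequency vector summing to
#' one. Relative frequencies (rather than raw counts) keep sequences of
#' very different lengths on a common scale, which the radial-kernel
#' classifier relies on.
#'
#' @param reduced Character vector of reduced sequences (see
#'   [reduce_sequence()]).
#' @param scheme The [reduction_scheme] the sequences were reduced with
#'   (or its name).
#' @param k K-mer length.
#' @param on_short What to do with sequences shorter than `k`:
#'   `"error"` (default, strict mode) or `"zero"` (lenient batch mode:
#'   an all-zero row plus a warning, so one short protein cannot abort a
#'   proteome screen).
#' @return Numeric matrix, one row per sequence, `size^k` columns named
#'   by K-mer, with attribute `n_windows` (integer vector of window
#'   counts per sequence).
#' @examples
#' f <- kmer_features(reduce_sequence("ACDEFG", "Op11"), "Op11", k = 1)
#' f[, c("A", "V", "N", "E", "F", "G")]  # 1/6 each
#' @export
kmer_features <- function(reduced, scheme, k, on_short = c("error", "zero")) {
  if (is.character(scheme) && length(scheme) == 1L &&
      !inherits(scheme, "reduction_scheme"))
    scheme <- load_scheme(scheme)
  on_short <- match.arg(on_short)
  k <- as.integer(k)
  alphabet <- kmer_alphabet(scheme, k)
  n <- length(reduced)
  out <- matrix(0, nrow = n, ncol = length(alphabet),
                dimnames = list(names(reduced), alphabet))
  n_windows <- integer(n)
  short <- which(nchar(reduced) < k)
  if (length(short) && on_short == "error")
    stop("sequence(s) shorter than k = ", k, " at position(s) ",
         paste(utils::head(short, 5), collapse = ", "),
         "; use on_short = \"zero\" for lenient batch mode", call. = FALSE)
  for (i in seq_len(n)) {
    L <- nchar(reduced[i])
    if (L < k) next
    kmers <- suppressWarnings(extract_kmers(reduced[i], k))
    idx <- match(kmers, alphabet)
    if (anyNA(idx))
      stop("sequence ", i, " contains symbols outside scheme '",
           scheme$name, "'", call. = FALSE)
    counts <- tabulate(idx, nbins = length(alphabet))
    n_windows[i] <- L - k + 1L
    out[i, ] <- counts / n_windows[i]
  }
  if (length(short) && on_short == "zero")
    warning(length(short), " sequence(s) shorter than k = ", k,
            " encoded as zero vectors", call. = FALSE)
  attr(out, "n_windows") <- n_windows
  attr(out, "scheme_name") <- scheme$name
  attr(out, "k") <- k
  out
}

#' Encode protein records end-to-end (reduce + featurize)
#'
#' @param records `protein_records` data frame or character vector of
#'   canonical sequences.
#' @param scheme Scheme or scheme name (see [load_scheme()]).
#' @param k K-mer length.
#' @inheritParams kmer_features
#' @return Feature matrix as in [kmer_features()].
#' @export
encode_records <- function(records, scheme, k, on_short = c("error", "zero")) {
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  kmer_features(reduce_sequence(records, scheme), scheme, k,
                on_short = match.arg(on_short))
}

#' Write a feature matrix as a delimited table
#'
#' @param features Matrix from [kmer_features()].
#' @param path Output path (tab-separated, header row of K-mer labels,
#'   first column `id`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(id = rownames(features) %||% seq_len(nrow(features)),
                   features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
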