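TOKEN_CLS <- "[CLS]"
TOKEN_SEP <- "[SEP]"
TOKEN_PAD <- "[PAD]"
TOKEN_UNK <- "X"

# Residue vocabulary seen by the tokenizer: 20 canonical residues plus
# 'X' for non-standard or unseen amino acids.
TOKEN_VOCAB <- c(CANONICAL_RESIDUES, TOKEN_UNK)

#' Tokenizer configuration for the TF screening stage
#'
#' Every sequence is standardized to exactly `max_len` tokens: a leading
#' CLS token (whose contextual embedding summarizes the sequence), the
#' residues, a SEP boundary token, and PAD tokens to fill. The budget
#' includes CLS and SEP (standard BERT-style accounting), so a
#' `max_len = 1000` sequence carries at most 998 residues.
#'
#' @param max_len Total token budget (default 1000; must be >= 3).
#' @return A `tokenizer_config` list.
#' @export
tokenizer_config <- function(max_len = 1000L) {
  max_len <- as.integer(max_len)
  if (max_len < 3L) stop("max_len must be >= 3 (room for CLS, SEP, one residue)")
  structure(list(max_len = max_len, vocabulary = TOKEN_VOCAB),
            class = "tokenizer_config")
}

#' Tokenize a protein sequence
#'
#' Layout is `[CLS, r1 ... rm, SEP, PAD...]` with
#' `m = min(L, max_len - 2)`; truncation keeps the N-terminal prefix.
#' Residues outside the 20 canonical amino acids are mapped to `"X"`.
#'
#' @param sequence A single amino-acid sequence (character scalar), or a
#'   one-row `protein_records`.
#' @param cfg A [tokenizer_config()].
#' @return A `tokenized_sequence` list with `tokens` (character, length
#'   exactly `max_len`) and `attention_mask` (integer 0/1 vector, 1 for
#'   real tokens including CLS/SEP).
#' @examples
#' tk <- tokenize("ACDE", tokenizer_config(max_len = 8))
#' tk$tokens  # [CLS] A C D E [SEP] [PAD] [PAD]
#' @export
tokenize <- function(sequence, cfg = tokenizer_config()) {
  if (inherits(sequence, "protein_records")) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(toupper(sequence), "")[[1]]
  res[!res %in% CANONICAL_RESIDUES] <- TOKEN_UNK
  m <- min(length(res), cfg$max_len - 2L)
  res <- res[seq_len(m)]
  body <- c(TOKEN_CLS, res, TOKEN_SEP)
  pad <- cfg$max_len - length(body)
  structure(list(
    tokens = c(body, rep(TOKEN_PAD, pad)),
    attention_mask = c(rep(1L, length(body)), rep(0L, pad))
  ), class = "tokenized_sequence")
}

#' Deterministic stub embedding backend
#'
#' A fixed random projection of the token composition, standing in for a
#' protein language model so the screening head, loss and metrics can be
#' exercised quickly and deterministically. The projection matrix is
#' drawn once from `seed` at construction; thereafter identical token
#' sequences always map to identical vectors. It captures residue
#' composition and (coarsely) length - not contextual structure - which
#' is sufficient to test the classification plumbing end-to-end.
#'
#' @param dim Embedding dimension (the real protein-language-model
#'   backend declares 1024; the stub defaults to 32).
#' @param seed Seed for the fixed projection.
#' @return An `embedding_backend`: list with `dim`, `name`, and
#'   `embed(tokenized)` returning a numeric vector of length `dim`.
#' @export
stub_backend <- function(dim = 32L, seed = 101L) {
  dim <- as.integer(dim)
  set.seed(seed)
  proj <- matrix(stats::rnorm((length(TOKEN_VOCAB) + 1L) * dim),
                 nrow = length(TOKEN_VOCAB) + 1L, ncol = dim)
  embed <- function(tokenized) {
    tok <- tokenized$tokens[tokenized$attention_mask == 1L]
    tok <- tok[!tok %in% c(TOKEN_CLS, TOKEN_SEP)]
    counts <- tabulate(match(tok, TOKEN_VOCAB), nbins = length(TOKEN_VOCAB))
    n <- max(sum(counts), 1L)
    feats <- c(counts / n, log1p(sum(counts)) / 10)
    tanh(as.numeric(feats %*% proj))
  }
  structure(list(dim = dim, name = "stub", embed = embed),
            class = "embedding_backend")
}

#' Classification head: linear + sigmoid on a CLS embedding
#'
#' @param embedding Numeric CLS vector.
#' @param params List with `weights` (length matching the embedding) and
#'   `bias` (scalar).
#' @param threshold Decision threshold on the probability; the label is
#'   1 iff `probability >= threshold` (inclusive, so a probability of
#'   exactly 0.5 is called positive under the default).
#' @return List with `probability` and `label`.
#' @export
classify_head <- function(embedding, params, threshold = 0.5) {
  if (length(embedding) != length(params$weights))
    stop("embedding dimension (", length(embedding),
         ") does not match head weights (", length(params$weights), ")")
  p <- stats::plogis(sum(params$weights * embedding) + params$bias)
  list(probability = p, label = as.integer(p >= threshold))
}

#' Binary cross-entropy loss
#'
#' `L = -(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with
#' probabilities clipped to `[eps, 1 - eps]` for numerical safety.
#'
#' @param labels Binary vector.
#' @param probabilities Predicted probabilities in (0, 1), same length.
#' @param eps Clipping constant.
#' @return Mean loss (non-negative scalar).
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
bce_loss <- function(labels, probabilities, eps = 1e-12) {
  if (!length(labels)) stop("bce_loss undefined for empty input")
  if (length(labels) != length(probabilities))
    stop("labels and probabilities must have equal length")
  y <- as.numeric(labels)
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the classification head by full-batch gradient descent
#'
#' Minimizes the binary cross-entropy of the linear + sigmoid head over
#' a matrix of embeddings. Initialization is at zero and updates are
#' deterministic, so results are reproducible bit-for-bit.
#'
#' @param embeddings Numeric matrix, one row per sequence.
#' @param labels Binary vector, one per row.
#' @param lr Learning rate.
#' @param epochs Number of full-batch updates (the default is generous
#'   so that linearly separable embeddings are driven to zero training
#'   error).
#' @return Head parameters: list with `weights`, `bias`, and the
#'   training `loss` trajectory (first and final values).
#' @export
train_head <- function(embeddings, labels, lr = 0.5, epochs = 2000L) {
  stopifnot(nrow(embeddings) == length(labels))
  y <- as.numeric(labels)
  w <- numeric(ncol(embeddings)); b <- 0
  n <- nrow(embeddings)
  loss0 <- NA_real_
  for (e in seq_len(epochs)) {
    p <- stats::plogis(as.numeric(embeddings %*% w) + b)
    if (e == 1L) loss0 <- bce_loss(y, p)
    g <- p - y
    w <- w - lr * as.numeric(crossprod(embeddings, g)) / n
    b <- b - lr * mean(g)
  }
  p <- stats::plogis(as.numeric(embeddings %*% w) + b)
  list(weights = w, bias = b,
       loss = c(initial = loss0, final = bce_loss(y, p)))
}

#' Screen protein records for transcription-factor potential
#'
#' Runs tokenize -> embed -> classify_head for each record, preserving
#' input order. With the stub backend this is fully deterministic and
#' fast; a real protein-language-model backend can be plugged in via the
#' same `embedding_backend` contract.
#'
#' @param records `protein_records` data frame.
#' @param backend An `embedding_backend` (e.g. [stub_backend()]).
#' @param params Head parameters (see [train_head()]).
#' @param cfg A [tokenizer_config()].
#' @param threshold Probability threshold (inclusive).
#' @return Data frame with `id`, `probability`, `label`, in input order.
#' @export
screen_tf <- function(records, backend, params, cfg = tokenizer_config(),
                      threshold = 0.5) {
  n <- nrow(records)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    emb <- backend$embed(tokenize(records$sequence[i], cfg))
    prob[i] <- classify_head(emb, params, threshold)$probability
  }
  data.frame(id = records$id, probability = prob,
             label = as.integer(prob >= threshold),
             stringsAsFactors = FALSE)
}

#' Embed a batch of records with a backend
#'
#' @inheritParams screen_tf
#' @return Numeric matrix, one embedding row per record.
#' @export
embed_records <- function(records, backend, cfg = tokenizer_config()) {
  out <- matrix(0, nrow = nrow(records), ncol = backend$dim,
                dimnames = list(records$id, NULL))
  for (i in seq_len(nrow(records)))
    out[i, ] <- backend$embed(tokenize(records$sequence[i], cfg))
  out
}
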