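#' Hyperparameters for the TFPM classifier
#'
#' The four knobs of the reduced-alphabet K-mer SVM: the number of
#' reduced-alphabet groups (`op`), the K-mer length (`k`), the SVM cost
#' `C` and the radial-kernel width `gamma`. The defaults are the
#' pipeline's operating point for the methylation-preference task:
#' `op = 11`, `k = 1`, `C = 0.01`, `gamma = 1`.
#'
#' @param op Scheme size; must name a registered scheme (`Op<op>`).
#' @param k K-mer length (>= 1).
#' @param C SVM regularization (positive).
#' @param gamma Literal RBF kernel coefficient in
#'   `exp(-gamma * ||x - x'||^2)` (positive; not a data-dependent
#'   heuristic).
#' @return A `tfpm_hyperparams` list.
#' @export
tfpm_hyperparams <- function(op = 11, k = 1, C = 0.01, gamma = 1) {
  stopifnot(op > 0, k >= 1, C > 0, gamma > 0)
  structure(list(op = as.integer(op), k = as.integer(k),
                 C = C, gamma = gamma),
            class = "tfpm_hyperparams")
}

# Platt-style sigmoid calibration on decision values (smoothed targets,
# deterministic BFGS). P(y = 1 | f) = 1 / (1 + exp(A f + B)).
platt_fit <- function(f, y) {
  y <- as.integer(y)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  t <- ifelse(y == 1L, t_pos, t_neg)
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # -sum(t*log(p) + (1-t)*log(1-p)) written stably in terms of z
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  init <- c(A = -1, B = log((n_neg + 1) / (n_pos + 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

platt_prob <- function(platt, f) stats::plogis(-(platt$A * f + platt$B))

#' Train the reduced-alphabet K-mer SVM for methylation preference
#'
#' Encodes every training sequence as a K-mer relative-frequency vector
#' over the `Op<op>` reduced alphabet and fits a C-classification SVM
#' with radial kernel `exp(-gamma * ||x - x'||^2)`. No feature scaling
#' beyond the frequency normalization, and no class weighting. A
#' Platt-style sigmoid is fitted on the training decision values so that
#' predictions also carry calibrated probabilities.
#'
#' @param dataset A `labeled_dataset` containing both classes.
#' @param hp [tfpm_hyperparams()].
#' @param seed Integer recorded in the model metadata (the fit itself is
#'   deterministic given the dataset order and `hp`).
#' @return A `tfpm_model`: hyperparameters, scheme, fitted SVM, sigmoid
#'   calibration, and training metadata.
#' @export
tfpm_train <- function(dataset, hp = tfpm_hyperparams(), seed = 1L) {
  y <- dataset$labels
  if (length(unique(y)) < 2L)
    stop("training requires both classes in the dataset")
  scheme <- load_scheme(paste0("Op", hp$op))
  X <- encode_records(dataset$records, scheme, hp$k, on_short = "error")
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(x = X, y = yf, type = "C-classification",
                    kernel = "radial", cost = hp$C, gamma = hp$gamma,
                    scale = FALSE, probability = FALSE)
  pr <- stats::predict(fit, X, decision.values = TRUE)
  sgn <- {
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    if (identical(first, "1")) 1 else -1
  }
  f_train <- sgn * as.numeric(attr(pr, "decision.values"))
  structure(list(
    hyperparams = hp,
    scheme = scheme,
    svm_fit = fit,
    decision_sign = sgn,
    platt = platt_fit(f_train, y),
    feature_dim = ncol(X),
    n_pos = sum(y == 1L), n_neg = sum(y == 0L),
    seed = as.integer(seed),
    version = 1L
  ), class = "tfpm_model")
}

#' @export
print.tfpm_model <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(paste0("TFPM classifier: scheme %s, k = %d (%d features), ",
                     "C = %g, gamma = %g\n"),
              x$scheme$name, hp$k, x$feature_dim, hp$C, hp$gamma))
  cat(sprintf("  trained on %d positives / %d negatives; %d support vectors\n",
              x$n_pos, x$n_neg, nrow(x$svm_fit$SV)))
  invisible(x)
}

#' Predict methylation preference for protein records
#'
#' @param object A `tfpm_model`.
#' @param records `protein_records` data frame (or character vector of
#'   sequences). In the default lenient mode, non-canonical residues are
#'   stripped and too-short sequences are encoded as zero vectors (with
#'   warnings) so that a proteome screen never aborts on one record; in
#'   strict mode these are errors.
#' @param threshold Probability threshold; `label = 1` iff
#'   `probability >= threshold` (the inclusive 0.5-or-higher rule by
#'   default).
#' @param strict Validation mode (see above).
#' @param ... Unused.
#' @return Data frame with columns `id`, `score` (signed decision
#'   value, positive favors TFPM), `probability` (Platt-calibrated) and
#'   `label`, in input order.
#' @export
predict.tfpm_model <- function(object, records, threshold = 0.5,
                               strict = FALSE, ...) {
  if (is.character(records)) records <- protein_records(
    sprintf("seq%d", seq_along(records)), records)
  if (nrow(records) == 0L)
    return(data.frame(id = character(), score = numeric(),
                      probability = numeric(), label = integer()))
  records <- validate_records(records, strict = strict)
  X <- encode_records(records, object$scheme, object$hyperparams$k,
                      on_short = if (strict) "error" else "zero")
  pr <- stats::predict(object$svm_fit, X, decision.values = TRUE)
  f <- object$decision_sign * as.numeric(attr(pr, "decision.values"))
  prob <- platt_prob(object$platt, f)
  data.frame(id = records$id, score = f, probability = prob,
             label = as.integer(prob >= threshold),
             stringsAsFactors = FALSE)
}

# Stratified fold assignment: within each class, indices are shuffled
# with the given seed and dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  if (folds < 2L) stop("folds must be >= 2")
  if (min(table(labels)) < folds)
    stop("smallest class (", min(table(labels)),
         ") is too small for ", folds, "-fold stratification")
  fold <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the TFPM classifier
#'
#' Folds are stratified by class and derived deterministically from
#' `seed`. Held-out decision values are pooled across folds for the
#' overall report (AUC on raw decision values); per-fold reports are
#' also returned.
#'
#' @inheritParams tfpm_train
#' @param folds Number of folds (default 5).
#' @return List with `pooled` (a `metrics_report` including AUC),
#'   `per_fold` (list of `metrics_report`), and `predictions` (data
#'   frame of held-out id / fold / label / score / probability / pred).
#' @export
tfpm_cross_validate <- function(dataset, hp = tfpm_hyperparams(),
                                folds = 5L, seed = 1L) {
  y <- dataset$labels
  fold <- stratified_folds(y, folds, seed)
  res <- vector("list", folds)
  per_fold <- vector("list", folds)
  for (fd in seq_len(folds)) {
    tr <- fold != fd
    model <- tfpm_train(
      labeled_dataset(dataset$records[tr, , drop = FALSE], y[tr]),
      hp, seed = seed)
    pred <- predict(model, dataset$records[!tr, , drop = FALSE])
    pred$fold <- fd
    pred$label_true <- y[!tr]
    res[[fd]] <- pred
    per_fold[[fd]] <- compute_metrics(
      confusion(pred$label_true, pred$label),
      auc = roc_auc(pred$label_true, pred$score))
  }
  pred <- do.call(rbind, res)
  pooled <- compute_metrics(confusion(pred$label_true, pred$label),
                            auc = roc_auc(pred$label_true, pred$score))
  list(pooled = pooled, per_fold = per_fold, predictions = pred)
}

#' Exhaustive grid search over (op, K, C, gamma)
#'
#' Every combination is evaluated by stratified cross-validation and the
#' full table is returned (and optionally persisted); the best setting
#' maximizes cross-validated AUC, with ties broken by lexicographic
#' (op, k, C, gamma) order (earlier wins, logged as a message).
#'
#' @inheritParams tfpm_cross_validate
#' @param op,k,C,gamma Numeric vectors spanning the grid. Defaults: the
#'   five scheme sizes, K in 1..5, and logarithmic grids
#'   `C in 10^(-3..2)`, `gamma in 10^(-2..1)`.
#' @param table_path Optional path to persist the full grid table (TSV).
#' @return A `tfpm_grid` list: `table` (data frame with cv metrics per
#'   combination) and `best` (a [tfpm_hyperparams()]).
#' @export
tfpm_grid_search <- function(dataset, op = c(5, 8, 9, 11, 13), k = 1:5,
                             C = 10^(-3:2), gamma = 10^(-2:1),
                             folds = 5L, seed = 1L, table_path = NULL) {
  grid <- expand.grid(gamma = sort(gamma), C = sort(C), k = sort(k),
                      op = sort(op), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$op, grid$k, grid$C, grid$gamma), , drop = FALSE]
  grid <- grid[, c("op", "k", "C", "gamma")]
  if (!nrow(grid)) stop("empty hyperparameter grid")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- tfpm_hyperparams(grid$op[i], grid$k[i], grid$C[i], grid$gamma[i])
    cv <- tfpm_cross_validate(dataset, hp, folds = folds, seed = seed)
    p <- cv$pooled
    rows[[i]] <- data.frame(op = hp$op, k = hp$k, C = hp$C,
                            gamma = hp$gamma, cv_auc = p$auc,
                            cv_acc = p$accuracy, cv_sn = p$sensitivity,
                            cv_sp = p$specificity, cv_mcc = p$mcc)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best_auc <- max(tab$cv_auc)
  ties <- which(tab$cv_auc == best_auc)
  if (length(ties) > 1L)
    message(length(ties), " settings tie on cv AUC = ",
            format(best_auc), "; keeping the earliest in (op, k, C, gamma) order")
  b <- tab[ties[1L], ]
  if (!is.null(table_path))
    utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  structure(list(table = tab,
                 best = tfpm_hyperparams(b$op, b$k, b$C, b$gamma)),
            class = "tfpm_grid")
}

#' @export
print.tfpm_grid <- function(x, ...) {
  b <- x$best
  cat(sprintf("Grid search over %d settings; best (op = %d, k = %d, C = %g, gamma = %g)\n",
              nrow(x$table), b$op, b$k, b$C, b$gamma))
  cat(sprintf("  best cv AUC = %.4f\n",
              max(x$table$cv_auc)))
  invisible(x)
}

#' Rank a proteome by predicted TFPM probability
#'
#' @param model A `tfpm_model`.
#' @param proteome Non-empty `protein_records` data frame.
#' @param top_n Number of top-ranked rows to return (default 20).
#' @return Data frame of the `top_n` highest-probability predictions,
#'   sorted by probability descending with ties broken by id ascending,
#'   with a `rank` column; the full ranked table is attached as
#'   attribute `"full_table"`.
#' @export
rank_proteome <- function(model, proteome, top_n = 20L) {
  if (top_n <= 0L) stop("top_n must be positive")
  if (nrow(proteome) == 0L) stop("proteome is empty")
  pred <- predict(model, proteome)
  ord <- order(-pred$probability, pred$id)
  full <- pred[ord, , drop = FALSE]
  full$rank <- seq_len(nrow(full))
  rownames(full) <- NULL
  top <- utils::head(full, top_n)
  attr(top, "full_table") <- full
  top
}

#' Serialize / restore a trained TFPM model
#'
#' The model is written as a single versioned file (RDS payload holding
#' the scheme, hyperparameters, SVM state and training metadata).
#'
#' @param model A `tfpm_model`.
#' @param path File path.
#' @return `path` invisibly ([write_tfpm_model()]); the model
#'   ([read_tfpm_model()]).
#' @export
write_tfpm_model <- function(model, path) {
  stopifnot(inherits(model, "tfpm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_tfpm_model
#' @export
read_tfpm_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tfpm_model"))
    stop("'", path, "' does not contain a tfpm_model")
  model
}
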