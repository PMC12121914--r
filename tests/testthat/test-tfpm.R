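# Classifier tests run on small planted-composition datasets; a
# nearest-centroid check guards that "separable" sets really are.

test_that("strongly planted composition classes are separable and learned", {
  ds <- planted_dataset(20, delta = 0.3, seed = 101)
  X <- encode_records(ds$records, "Op11", k = 1)
  # nearest-centroid oracle: classes must be separable before we ask
  # the SVM to separate them
  mu1 <- colMeans(X[ds$labels == 1, ]); mu0 <- colMeans(X[ds$labels == 0, ])
  d1 <- rowSums((X - matrix(mu1, nrow(X), ncol(X), byrow = TRUE))^2)
  d0 <- rowSums((X - matrix(mu0, nrow(X), ncol(X), byrow = TRUE))^2)
  expect_identical(as.integer(d1 < d0), ds$labels)

  model <- tfpm_train(ds, tfpm_hyperparams(11, 1, 1, 1))
  pred <- predict(model, ds$records)
  expect_identical(pred$label, ds$labels)  # training-set accuracy 1
  expect_identical(model$feature_dim, 11L)
})

test_that("training demands both classes and featurizable sequences", {
  ds <- planted_dataset(10, delta = 0.2, seed = 103)
  pos_only <- labeled_dataset(ds$records[ds$labels == 1, , drop = FALSE],
                              rep(1L, 10))
  expect_error(tfpm_train(pos_only), "both classes")
  expect_error(tfpm_hyperparams(op = 11, k = 0), "k >= 1")
  expect_error(tfpm_hyperparams(C = -1), "C > 0")
})

test_that("fits and predictions are deterministic given dataset, hp, seed", {
  ds <- planted_dataset(15, delta = 0.15, seed = 107)
  probe <- planted_dataset(5, delta = 0.15, seed = 108)$records
  m1 <- tfpm_train(ds, tfpm_hyperparams(11, 1, 0.01, 1), seed = 3)
  m2 <- tfpm_train(ds, tfpm_hyperparams(11, 1, 0.01, 1), seed = 3)
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_identical(m1$platt, m2$platt)
})

test_that("labels follow the inclusive probability threshold exactly", {
  ds <- planted_dataset(25, delta = 0.1, seed = 109)
  model <- tfpm_train(ds, tfpm_hyperparams(11, 1, 0.01, 1))
  pred <- predict(model, planted_dataset(25, delta = 0.1, seed = 110)$records)
  expect_identical(mean(pred$label), mean(pred$probability >= 0.5))
  pred9 <- predict(model, planted_dataset(25, delta = 0.1, seed = 110)$records,
                   threshold = 0.9)
  expect_identical(pred9$label, as.integer(pred9$probability >= 0.9))
})

test_that("prediction is order-preserving, lenient by default, total", {
  ds <- planted_dataset(15, delta = 0.25, seed = 113)
  model <- tfpm_train(ds, tfpm_hyperparams(11, 1, 1, 1))
  empty <- predict(model, ds$records[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
  # identical sequences get identical probabilities
  twin <- protein_records(c("a", "b"), rep(ds$records$sequence[1], 2))
  ptwin <- predict(model, twin)
  expect_identical(ptwin$probability[1], ptwin$probability[2])
  # lenient mode survives a non-canonical residue; strict mode refuses
  odd <- protein_records("odd", paste0(ds$records$sequence[1], "X"))
  expect_warning(pod <- predict(model, odd), "non-canonical")
  expect_identical(nrow(pod), 1L)
  expect_error(predict(model, odd, strict = TRUE), "non-canonical")
})

test_that("stratified cross-validation pools held-out predictions", {
  ds <- planted_dataset(30, delta = 0.3, seed = 127)
  cv <- tfpm_cross_validate(ds, tfpm_hyperparams(11, 1, 1, 1),
                            folds = 5, seed = 5)
  expect_identical(cv$pooled$accuracy, 1)     # separable by construction
  expect_identical(nrow(cv$predictions), 60L)
  expect_identical(length(cv$per_fold), 5L)
  # every fold held out both classes (stratification)
  tab <- table(cv$predictions$fold, cv$predictions$label_true)
  expect_true(all(tab > 0))
  expect_error(tfpm_cross_validate(ds, folds = 1), "folds must be >= 2")
  tiny <- labeled_dataset(ds$records[c(1:3, 31:33), , drop = FALSE],
                          c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_error(tfpm_cross_validate(tiny, folds = 5), "too small")
})

test_that("permuted labels drive cross-validated AUC to chance", {
  ds <- planted_dataset(25, delta = 0.3, seed = 131)
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    perm <- labeled_dataset(ds$records, sample(ds$labels))
    tfpm_cross_validate(perm, tfpm_hyperparams(11, 1, 1, 1),
                        folds = 5, seed = s)$pooled$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("grid search is exhaustive, persists its table, recovers k = 1", {
  ds <- planted_dataset(75, delta = 0.1, seed = 137)
  path <- tempfile(fileext = ".tsv")
  gs <- tfpm_grid_search(ds, op = 11, k = 1:3, C = 1, gamma = 1,
                         folds = 3, seed = 7, table_path = path)
  expect_identical(nrow(gs$table), 3L)
  expect_identical(gs$best$k, 1L)  # the planted signal is composition-only
  expect_identical(nrow(read.delim(path)), 3L)
  expect_error(tfpm_grid_search(ds, op = numeric(), k = 1, C = 1, gamma = 1),
               "empty")
})

test_that("singleton grids and AUC ties resolve by documented rules", {
  ds <- planted_dataset(15, delta = 0.25, seed = 139)
  gs1 <- tfpm_grid_search(ds, op = 11, k = 1, C = 0.01, gamma = 1,
                          folds = 3, seed = 7)
  expect_identical(unclass(gs1$best)[c("op", "k")], list(op = 11L, k = 1L))
  expect_identical(gs1$best$C, 0.01)
  # two costs that both separate perfectly tie on AUC = 1; the earlier
  # setting in (op, k, C, gamma) order wins and the tie is logged
  ds2 <- planted_dataset(30, delta = 0.3, seed = 141)
  expect_message(
    gs2 <- tfpm_grid_search(ds2, op = 11, k = 1, C = c(1, 10), gamma = 1,
                            folds = 3, seed = 7),
    "tie")
  expect_identical(gs2$best$C, 1)
})

test_that("proteome ranking sorts by probability with id tie-break", {
  ds <- planted_dataset(15, delta = 0.25, seed = 149)
  model <- tfpm_train(ds, tfpm_hyperparams(11, 1, 1, 1))
  proteome <- planted_dataset(10, delta = 0.25, seed = 150)$records
  top <- rank_proteome(model, proteome, top_n = 5)
  expect_identical(nrow(top), 5L)
  expect_true(all(diff(top$probability) <= 0))
  full <- attr(top, "full_table")
  expect_identical(nrow(full), 20L)
  expect_identical(full$rank, 1:20)
  # top_n beyond the proteome returns the full sorted list
  all_rows <- rank_proteome(model, proteome, top_n = 100)
  expect_identical(nrow(all_rows), 20L)
  # identical sequences: identical probabilities, adjacent ranks, id order
  twins <- protein_records(c("zz", "aa"), rep(proteome$sequence[1], 2))
  rt <- rank_proteome(model, twins, top_n = 2)
  expect_identical(rt$id, c("aa", "zz"))
  expect_error(rank_proteome(model, proteome, top_n = 0), "positive")
  expect_error(rank_proteome(model, proteome[0, , drop = FALSE]), "empty")
})

test_that("models round-trip through their serialized form", {
  ds <- planted_dataset(15, delta = 0.25, seed = 151)
  model <- tfpm_train(ds, tfpm_hyperparams(11, 1, 0.01, 1))
  path <- tempfile(fileext = ".rds")
  write_tfpm_model(model, path)
  back <- read_tfpm_model(path)
  probe <- planted_dataset(5, delta = 0.25, seed = 152)$records
  expect_identical(predict(back, probe), predict(model, probe))
  saveRDS(list(), path)
  expect_error(read_tfpm_model(path), "tfpm_model")
})
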