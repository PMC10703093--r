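test_that("stratified splitting respects per-class fractions and the seed", {
  m <- data.frame(path = sprintf("v%02d.nii.gz", 1:30),
                  label = rep(c("AD", "MCI", "NC"), each = 10))
  s <- splitDataset(m, 0.7, seed = 5)
  expect_identical(nrow(s$train), 21L)
  expect_identical(nrow(s$test), 9L)
  expect_true(all(table(s$train$label) == 7))
  expect_true(all(table(s$test$label) == 3))
  expect_length(intersect(s$train$path, s$test$path), 0L)
  expect_identical(splitDataset(m, 0.7, seed = 5), s)
  expect_false(identical(splitDataset(m, 0.7, seed = 6)$train$path,
                         s$train$path))
  expect_error(splitDataset(m, 1.0, seed = 1), "parameter error")
  expect_error(splitDataset(m[m$label != "AD", ], 0.7, 1),
               "validation error.*AD")
})

test_that("k-fold splits are disjoint, exhaustive and stratified", {
  m <- data.frame(path = sprintf("v%02d", 1:30),
                  label = rep(c("AD", "MCI", "NC"), each = 10))
  folds <- splitFolds(m, k = 5, seed = 2)
  expect_length(folds, 5L)
  test_paths <- unlist(lapply(folds, function(f) f$test$path))
  expect_setequal(test_paths, m$path)
  expect_identical(length(test_paths), 30L)
  for (f in folds) expect_true(all(table(f$test$label) == 2))
})

test_that("training reduces the loss on a small phantom set", {
  ds <- makeDataset(n_per_class = 4L, side = 16L, seed = 31)
  cfg <- tinyModelConfig("amsf", seed = 2)
  tc <- trainConfig(batch_size = 4, epochs = 20, learning_rate = 0.005,
                    momentum = 0.9, seed = 2)
  fit <- trainModel(buildModel(cfg),
                    within(ds@manifest, path <- file.path(ds@dir, path)), tc)
  expect_lt(fit$history$train_loss[20], fit$history$train_loss[1])
  expect_identical(nrow(fit$history), 20L)
})

test_that("a zero learning rate with zero momentum changes nothing", {
  ds <- makeDataset(n_per_class = 2L, side = 16L, seed = 13)
  cfg <- tinyModelConfig("2d3d", seed = 4)
  m0 <- buildModel(cfg)
  tc <- trainConfig(batch_size = 3, epochs = 1, learning_rate = 0,
                    momentum = 0, seed = 4)
  fit <- trainModel(m0, within(ds@manifest, path <- file.path(ds@dir, path)),
                    tc)
  # weights are bit-identical; only bn running statistics may move
  expect_identical(fit$model@params$fc, m0@params$fc)
  expect_identical(fit$model@params$gfe$blocks$block1$W,
                   m0@params$gfe$blocks$block1$W)
  expect_identical(fit$model@params$sfen$axial$blocks$block4$W,
                   m0@params$sfen$axial$blocks$block4$W)
})

test_that("seeded training is bit-reproducible on one machine", {
  ds <- makeDataset(n_per_class = 2L, side = 16L, seed = 17)
  man <- within(ds@manifest, path <- file.path(ds@dir, path))
  run <- function() {
    cfg <- tinyModelConfig("amsf", seed = 9)
    tc <- trainConfig(batch_size = 3, epochs = 3, learning_rate = 0.01,
                      momentum = 0.9, seed = 9)
    trainModel(buildModel(cfg), man, tc, val_manifest = man)$history
  }
  expect_identical(run(), run())
})

test_that("metrics match the hand-computed confusion-matrix example", {
  cm <- matrix(c(8, 0, 1,   # column 1: predicted class 1
                 1, 9, 0,
                 1, 1, 9), 3, 3)
  # rows = truth: [[8,1,1],[0,9,1],[1,0,9]]
  expect_identical(cm[1, ], c(8, 1, 1))
  met <- confusionMetrics(cm)
  expect_equal(round(met$acc, 4), 0.8667)
  expect_equal(round(met$sen, 4), 0.8667)   # (8/10 + 9/10 + 9/10)/3
  perfect <- diag(c(5, 5, 5))
  mp <- confusionMetrics(perfect)
  expect_equal(unlist(mp[c("acc", "sen", "spe", "pre", "f1")]),
               c(acc = 1, sen = 1, spe = 1, pre = 1, f1 = 1))
})

test_that("macro metrics equal an explicit one-vs-rest loop on random matrices", {
  set.seed(77)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 8), 3, 3)
    if (sum(cm) == 0) next
    met <- confusionMetrics(cm)
    expect_equal(met$acc, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
    sen <- spe <- pre <- f1 <- numeric(3)
    for (k in 1:3) {
      tp <- cm[k, k]; fn <- sum(cm[k, -k])
      fp <- sum(cm[-k, k]); tn <- sum(cm[-k, -k])
      sen[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
      spe[k] <- if (tn + fp > 0) tn / (tn + fp) else 0
      pre[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
      f1[k] <- if (pre[k] + sen[k] > 0)
        2 * pre[k] * sen[k] / (pre[k] + sen[k]) else 0
    }
    expect_equal(met$sen, mean(sen), tolerance = 1e-12)
    expect_equal(met$spe, mean(spe), tolerance = 1e-12)
    expect_equal(met$pre, mean(pre), tolerance = 1e-12)
    expect_equal(met$f1, mean(f1), tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone with AUC in [0, 1], and 1 when separable", {
  set.seed(3)
  lab <- rep(c("AD", "MCI", "NC"), each = 10)
  probs <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("AD", "MCI", "NC")))
  probs <- probs / rowSums(probs)
  r <- rocCurves(probs, lab)
  expect_true(r$auc >= 0 && r$auc <= 1)
  for (cv in r$curves) {
    expect_true(all(diff(cv$tpr) >= -1e-12))
    expect_true(all(diff(cv$fpr) >= -1e-12))
  }
  # perfectly separable scores
  sep <- matrix(0.01, 30, 3, dimnames = list(NULL, c("AD", "MCI", "NC")))
  sep[cbind(1:30, match(lab, colnames(sep)))] <- 0.98
  expect_equal(rocCurves(sep, lab)$auc, 1)
})

test_that("evaluation produces a coherent metrics object", {
  ds <- makeDataset(n_per_class = 3L, side = 16L, seed = 23)
  man <- within(ds@manifest, path <- file.path(ds@dir, path))
  m <- buildModel(tinyModelConfig("3d", seed = 1))
  met <- evaluateModel(m, man)
  expect_s4_class(met, "AmsfMetrics")
  expect_identical(sum(confusionMatrix(met)), 9L)
  tab <- metricsTable(met)
  expect_true(all(tab[, c("acc", "sen", "spe", "pre", "f1")] >= 0 &
                    tab[, c("acc", "sen", "spe", "pre", "f1")] <= 1))
  expect_error(evaluateModel(m, man[0, ]), "validation error")
})

test_that("the ablation table covers every variant on one shared split", {
  ds <- makeDataset(n_per_class = 4L, side = 16L, seed = 41)
  man <- within(ds@manifest, path <- file.path(ds@dir, path))
  tc <- trainConfig(batch_size = 4, epochs = 2, learning_rate = 0.01,
                    momentum = 0.9, train_fraction = 0.7, seed = 3)
  tab <- runAblation(man, config = tc, model_args = list(
    side = 16L, n_slices = 4L, feature_dim = 8L,
    sfen_widths = c(2L, 2L, 4L, 8L), global_dim = 8L,
    gfe_widths = c(2L, 2L, 4L, 8L), reduction = 2L, se_reduction = 2L))
  expect_identical(nrow(tab), 5L)
  expect_setequal(tab$variant, c("3d", "2d", "2d3d", "se2d3d", "amsf"))
  expect_true(all(c("acc", "sen", "spe", "pre", "f1") %in% names(tab)))
  sp <- attr(tab, "split")
  expect_identical(splitDataset(man, 0.7, 3), sp)
  expect_length(attr(tab, "histories"), 5L)
})
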