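test_that("classifier input widths follow the variant arithmetic", {
  cfg <- modelConfig("amsf")
  expect_identical(cfg$fc_in, 3L * 128L + 64L)   # 448
  expect_identical(modelConfig("3d")$fc_in, 64L)
  expect_identical(modelConfig("2d")$fc_in, 3L * 128L)
  expect_identical(modelConfig("2d3d")$fc_in, 3L * 128L + 64L)
  expect_identical(modelConfig("2d", n_slices = 40, fusion = "concat")$fc_in,
                   3L * 40L * 128L)
  expect_error(modelConfig("cnn"), "config error.*variant")
})

test_that("each variant instantiates exactly its own branches", {
  m3 <- buildModel(tinyModelConfig("3d"))
  expect_null(m3@params$sfen)
  expect_null(m3@params$sfa)
  expect_false(is.null(m3@params$gfe))

  m2 <- buildModel(tinyModelConfig("2d"))
  expect_null(m2@params$gfe)
  expect_length(m2@params$sfen, 3L)

  mse <- buildModel(tinyModelConfig("se2d3d"))
  expect_length(mse@params$se, 3L)
  expect_null(mse@params$sfa)

  ma <- buildModel(tinyModelConfig("amsf"))
  expect_length(ma@params$sfa, 3L)
  expect_null(ma@params$se)
})

test_that("parameter counts differ across variants exactly by their blocks", {
  ns <- asNamespace("amsf")
  n <- vapply(c("3d", "2d", "2d3d", "se2d3d", "amsf"), function(v)
    ns$countParams(buildModel(tinyModelConfig(v))@params), 0L)
  cfg <- tinyModelConfig()
  gfe_n <- ns$countParams(initGfe(cfg$gfe_widths, cfg$global_dim, 1))
  sfa_n <- 3L * ns$countParams(initSfa(cfg$feature_dim, cfg$reduction, 1))
  se_n <- 3L * ns$countParams(initSe(cfg$n_slices, cfg$se_reduction, 1))
  # adding the 3D branch on top of 2d: gfe params + wider classifier rows
  expect_identical(n[["2d3d"]] - n[["2d"]], gfe_n + 3L * cfg$global_dim)
  # attention and SE variants differ from plain 2d3d by their fuser params
  expect_identical(n[["amsf"]] - n[["2d3d"]], sfa_n)
  expect_identical(n[["se2d3d"]] - n[["2d3d"]], se_n)
})

test_that("probabilities are a strict softmax and eval is deterministic", {
  m <- buildModel(tinyModelConfig())
  v <- preprocessVolume(generatePhantom("MCI", phantomSpec(side = 16), 2), 16)
  p1 <- predictVolume(m, v)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-12)
  expect_true(all(p1$probabilities > 0))
  expect_identical(p1$probabilities, predictVolume(m, v)$probabilities)
  expect_named(p1$probabilities, c("AD", "MCI", "NC"))
  expect_named(p1$attention, c("sagittal", "coronal", "axial"))
  expect_error(predictVolume(m, array(0, c(8, 8, 8))), "shape error")
})

test_that("the assembled forward equals the composition of module calls", {
  cfg <- tinyModelConfig("amsf", seed = 23)
  m <- buildModel(cfg)
  v <- preprocessVolume(generatePhantom("AD", phantomSpec(side = 16), 5), 16)
  got <- predictVolume(m, v)

  cl <- sliceViews(v, cfg$n_slices)
  feats <- list()
  scores <- list()
  for (vw in c("sagittal", "coronal", "axial")) {
    Tf <- sfenForward(cl[[vw]], m@params$sfen[[vw]])
    out <- sfaForward(Tf, m@params$sfa[[vw]])
    feats[[vw]] <- fusedFeature(out)
    scores[[vw]] <- attScores(out)
  }
  feats$global <- gfeForward(v, m@params$gfe)
  x <- c(feats$sagittal, feats$coronal, feats$axial, feats$global)
  logits <- drop(x %*% m@params$fc$W) + m@params$fc$b
  probs <- exp(logits - max(logits)); probs <- probs / sum(probs)
  expect_equal(unname(got$probabilities), probs, tolerance = 1e-10)
  for (vw in names(scores))
    expect_equal(got$attention[[vw]], scores[[vw]], tolerance = 1e-10)
})

test_that("checkpoints round-trip through save and load", {
  m <- buildModel(tinyModelConfig())
  v <- preprocessVolume(generatePhantom("NC", phantomSpec(side = 16), 7), 16)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(predictVolume(m2, v)$probabilities,
                   predictVolume(m, v)$probabilities)
  expect_error(loadModel({
    f2 <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), f2); f2
  }), "I/O error")
})

test_that("attention tables cover every volume, view and slice", {
  m <- buildModel(tinyModelConfig())
  v <- preprocessVolume(generatePhantom("NC", phantomSpec(side = 16), 3), 16)
  tab <- attentionTable(m, list(v, v), ids = c("a", "b"))
  expect_identical(nrow(tab), 2L * 3L * 4L)
  expect_setequal(unique(tab$view), c("sagittal", "coronal", "axial"))
  expect_equal(sum(tab$score[tab$volume_id == "a" & tab$view == "axial"]), 1,
               tolerance = 1e-9)
  expect_error(attentionTable(buildModel(tinyModelConfig("2d3d")), list(v)),
               "config error")
})
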