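test_that("noise-free phantoms take exactly the two tissue intensities", {
  sp <- tinyPhantomSpec(noise_sd = 0)
  v <- volData(generatePhantom("MCI", sp, seed = 2))
  vals <- sort(unique(as.vector(v)))
  expect_identical(vals, sort(c(0, sp$inner_intensity, sp$fg_intensity)))
})

test_that("class structure is strictly larger for later disease stages", {
  sp <- tinyPhantomSpec(noise_sd = 0)
  for (seed in 1:5) {
    nAD <- sum(volData(generatePhantom("AD", sp, seed)) == sp$inner_intensity)
    nMCI <- sum(volData(generatePhantom("MCI", sp, seed)) ==
                  sp$inner_intensity)
    nNC <- sum(volData(generatePhantom("NC", sp, seed)) == sp$inner_intensity)
    expect_gt(nAD, nMCI)
    expect_gt(nMCI, nNC)
  }
})

test_that("voxels outside the informative band are class-indistinguishable", {
  sp <- tinyPhantomSpec()
  band <- sp$band
  outside <- setdiff(seq_len(sp$side) - 1L, band[1]:band[2])
  grab <- function(label, seed) {
    x <- volData(generatePhantom(label, sp, seed))
    # voxels outside the band along the axial axis, foreground only
    v <- x[, , outside + 1L]
    v[v != 0]
  }
  ad <- unlist(lapply(1:50, function(s) grab("AD", 1000 + s)))
  nc <- unlist(lapply(1:50, function(s) grab("NC", 2000 + s)))
  ks <- suppressWarnings(ks.test(sample(ad, 4000), sample(nc, 4000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the inner structure stays inside the informative band", {
  sp <- tinyPhantomSpec(noise_sd = 0)
  for (label in c("AD", "NC")) for (seed in 1:5) {
    x <- volData(generatePhantom(label, sp, seed))
    hit <- which(x == sp$inner_intensity, arr.ind = TRUE) - 1L
    expect_true(all(hit >= sp$band[1] & hit <= sp$band[2]))
  }
})

test_that("datasets are written completely and reproducibly", {
  d1 <- tempfile("ds"); d2 <- tempfile("ds"); d3 <- tempfile("ds")
  sp <- phantomSpec(side = 16, n_per_class = 5, seed = 3)
  ds <- generateDataset(sp, d1, seed = 3)
  expect_identical(nrow(ds@manifest), 15L)
  expect_identical(sum(file.exists(file.path(d1, ds@manifest$path))), 15L)
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_identical(unlist(gt$band$axial), sp$band)

  generateDataset(sp, d2, seed = 3)
  f <- ds@manifest$path[1]
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
  generateDataset(sp, d3, seed = 4)
  expect_false(identical(
    volData(loadVolume(file.path(d1, f))),
    volData(loadVolume(file.path(d3, f)))))
})

test_that("impossible phantom geometries are rejected", {
  expect_error(phantomSpec(class_scales = c(NC = 1.2, MCI = 1.1, AD = 1.3)),
               "spec error.*ordered")
  expect_error(phantomSpec(side = 32, band_fraction = 0.1,
                           inner_radius_frac = 0.12),
               "spec error.*band")
  expect_error(phantomSpec(noise_sd = -1), "spec error")
  expect_error(generatePhantom("CN", tinyPhantomSpec()), "validation error")
})

test_that("masking the informative band erases linear class separability", {
  sp <- phantomSpec(side = 16, n_per_class = 50, seed = 6)
  band <- sp$band[1]:sp$band[2] + 1L
  feats <- NULL; labs <- character(0)
  for (label in c("AD", "MCI", "NC")) for (i in 1:50) {
    x <- volData(generatePhantom(label, sp,
                                 deriveSeed(6, paste0(label, i))))
    fg <- mean(x[x != 0])
    x[band, band, band] <- ifelse(x[band, band, band] != 0, fg,
                                  x[band, band, band])
    # coarse 4x4x4 block means as linear-probe features
    blk <- sapply(0:3, function(a) sapply(0:3, function(b)
      sapply(0:3, function(c)
        mean(x[a * 4 + 1:4, b * 4 + 1:4, c * 4 + 1:4]))))
    feats <- rbind(feats, as.vector(blk))
    labs <- c(labs, label)
  }
  keep <- apply(feats, 2, sd) > 1e-8
  feats <- feats[, keep, drop = FALSE]
  set.seed(1)
  tr <- sample(150, 100)
  fit <- suppressWarnings(MASS::lda(feats[tr, ], grouping = labs[tr]))
  acc <- mean(predict(fit, feats[-tr, ])$class == labs[-tr])
  expect_lt(acc, 0.45)
})
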