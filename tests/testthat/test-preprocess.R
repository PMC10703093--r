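test_that("NIfTI volumes round-trip with voxel values and spacing intact", {
  v <- generatePhantom("NC", tinyPhantomSpec(), seed = 4)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  v2 <- loadVolume(f)
  expect_equal(volData(v2), volData(v), tolerance = 1e-7)
  expect_equal(volSpacing(v2), c(1, 1, 1))
})

test_that("non-3D NIfTI input is rejected with a dimensionality error", {
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 2))), f)
  expect_error(loadVolume(f), "dimensionality error")
  expect_error(loadVolume(tempfile(fileext = ".nii")), "I/O error")
})

test_that("background cropping finds the minimal non-zero bounding box", {
  full <- new("BrainVolume", data = array(1, c(20, 20, 20)))
  expect_identical(dim(volData(cropBackground(full))), c(20L, 20L, 20L))

  x <- array(0, c(30, 30, 30))
  x[6:25, 6:25, 6:25] <- runif(20^3) + 0.5
  v <- cropBackground(new("BrainVolume", data = x))
  # brute-force scan for the expected extents
  nz <- which(x != 0, arr.ind = TRUE)
  expect_identical(dim(volData(v)),
                   unname(apply(nz, 2, max) - apply(nz, 2, min) + 1L))
  expect_equal(volMeta(v)$crop_offset, c(5, 5, 5))

  expect_error(cropBackground(new("BrainVolume", data = array(0, c(5, 5, 5)))),
               "degenerate input")
})

test_that("cropped volumes never retain an all-zero boundary plane", {
  set.seed(42)
  for (i in 1:10) {
    x <- array(0, c(18, 18, 18))
    lo <- sample(3:8, 3, replace = TRUE)
    hi <- lo + sample(2:6, 3, replace = TRUE)
    x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      rbinom((hi[1] - lo[1] + 1) * (hi[2] - lo[2] + 1) * (hi[3] - lo[3] + 1),
             1, 0.4) * runif(1, 0.5, 2)
    if (all(x == 0)) next
    y <- volData(cropBackground(new("BrainVolume", data = x)))
    d <- dim(y)
    expect_true(any(y[1, , ] != 0) && any(y[d[1], , ] != 0))
    expect_true(any(y[, 1, ] != 0) && any(y[, d[2], ] != 0))
    expect_true(any(y[, , 1] != 0) && any(y[, , d[3]] != 0))
  }
})

test_that("trilinear resize honors shape, identity and constants", {
  x <- array(runif(32^3), c(32, 32, 32))
  v <- new("BrainVolume", data = x)
  same <- resizeVolume(v, 32)
  expect_equal(volData(same), x, tolerance = 1e-12)

  odd <- new("BrainVolume", data = array(runif(24 * 28 * 20), c(24, 28, 20)))
  out <- resizeVolume(odd, 32)
  expect_identical(dim(volData(out)), c(32L, 32L, 32L))
  expect_true(all(is.finite(volData(out))))

  const <- new("BrainVolume", data = array(3.5, c(9, 9, 9)))
  expect_equal(volData(resizeVolume(const, 18)),
               array(3.5, c(18, 18, 18)), tolerance = 1e-12)

  expect_error(resizeVolume(v, 1), "parameter error")
})

test_that("intensity normalization standardizes exactly the non-zero region", {
  x <- array(0, c(5, 5, 5))
  x[1, 1, 1:5] <- 1:5
  v <- normalizeIntensity(new("BrainVolume", data = x))
  nz <- volData(v)[x != 0]          # original non-zero positions
  expect_equal(mean(nz), 0, tolerance = 1e-12)
  expect_equal(sd(nz), 1, tolerance = 1e-12)
  expect_true(all(volData(v)[x == 0] == 0))

  const <- array(0, c(4, 4, 4)); const[1:2, 1, 1] <- 2
  expect_error(normalizeIntensity(new("BrainVolume", data = const)),
               "degenerate input")
})

test_that("normalization invariants hold on random volumes", {
  set.seed(7)
  for (i in 1:5) {
    x <- array(0, c(12, 12, 12))
    mask <- array(rbinom(12^3, 1, 0.3) == 1, c(12, 12, 12))
    x[mask] <- rnorm(sum(mask), 5, 2)
    v <- normalizeIntensity(new("BrainVolume", data = x))
    nz <- volData(v)[x != 0]
    expect_lt(abs(mean(nz)), 1e-4)
    expect_lt(abs(sd(nz) - 1), 1e-4)
  }
})

test_that("full preprocessing yields a normalized cube and is deterministic", {
  v <- generatePhantom("AD", tinyPhantomSpec(), seed = 9)
  p <- preprocessVolume(v, 32)
  expect_identical(dim(volData(p)), c(32L, 32L, 32L))
  nz <- volData(p)[volData(p) != 0]
  expect_lt(abs(mean(nz)), 1e-10)
  expect_lt(abs(sd(nz) - 1), 1e-10)
  # idempotence of the shape contract and determinism
  p2 <- preprocessVolume(p, 32)
  expect_identical(dim(volData(p2)), dim(volData(p)))
  expect_identical(volData(preprocessVolume(v, 32)), volData(p))
  expect_error(preprocessVolume(new("BrainVolume", data = array(0, c(8, 8, 8)))),
               "degenerate input")
})

test_that("slicing takes the centered window with the documented tie-break", {
  # brute force: among all length-n windows of 0..S-1, pick the one
  # minimizing |left margin - right margin|, preferring the smaller left
  bruteWindow <- function(S, n) {
    starts <- 0:(S - n)
    margins <- abs(starts - (S - n - starts))
    starts[which.min(margins)]
  }
  for (S in c(90L, 32L, 17L)) for (n in c(1L, 5L, 16L)) {
    if (n > S) next
    v <- new("BrainVolume", data = array(runif(S^3), c(S, S, S)))
    cl <- sliceViews(v, n)
    expect_identical(sliceIndices(cl$axial)[1], bruteWindow(S, n))
  }
  # the documented full-scale instance: S = 90, n = 40 -> indices 25..64
  v90 <- new("BrainVolume", data = array(0.5, c(90, 90, 90)))
  idx <- sliceIndices(sliceViews(v90, 40)$sagittal)
  expect_identical(idx, 25:64)
})

test_that("slices are exact planes of the source cube in all three views", {
  S <- 20L
  x <- array(runif(S^3), c(S, S, S))
  v <- new("BrainVolume", data = x)
  cl <- sliceViews(v, 6)
  r <- sliceIndices(cl$sagittal) + 1L
  for (j in seq_along(r)) {
    expect_identical(clusterSlices(cl$sagittal)[, , j], x[r[j], , ])
    expect_identical(clusterSlices(cl$coronal)[, , j], x[, r[j], ])
    expect_identical(clusterSlices(cl$axial)[, , j], x[, , r[j]])
  }
  full <- sliceViews(v, S)
  expect_identical(sliceIndices(full$axial), 0:(S - 1L))
  expect_error(sliceViews(v, S + 1L), "parameter error")
})

test_that("manifests round-trip and reject bad labels", {
  m <- data.frame(path = c("a.nii.gz", "b.nii.gz", "c.nii.gz"),
                  label = c("AD", "MCI", "NC"))
  f <- tempfile(fileext = ".csv")
  writeManifest(m, f)
  expect_identical(loadManifest(f), m)
  b1 <- readBin(f, "raw", file.size(f))
  writeManifest(loadManifest(f), f)
  expect_identical(readBin(f, "raw", file.size(f)), b1)

  bad <- data.frame(path = "a.nii.gz", label = "CN")
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(loadManifest(f2), "validation error.*row 1")

  f3 <- tempfile(fileext = ".csv")
  file.create(f3)
  expect_error(loadManifest(f3), "validation error")
})
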