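tinySfa <- function(d = 4, r = 2, seed = 1, bn = FALSE)
  initSfa(feature_dim = d, reduction = r, seed = seed, bn = bn)

test_that("attention scores are a softmax over slices", {
  # constant pre-softmax values -> uniform scores
  p <- tinySfa(d = 4)
  p$ws <- rep(0, 4); p$bs <- 2
  Tm <- matrix(rnorm(40 * 4), 40, 4)
  expect_equal(attentionScores(Tm, p), rep(1 / 40, 40), tolerance = 1e-12)

  # closed form: pre-softmax (0, ln 3) -> (0.25, 0.75)
  p1 <- tinySfa(d = 1, r = 1)
  p1$ws <- 1; p1$bs <- 0
  expect_equal(attentionScores(matrix(c(0, log(3)), 2, 1), p1),
               c(0.25, 0.75), tolerance = 1e-12)

  # random case against the explicit-loop oracle
  set.seed(21)
  p5 <- tinySfa(d = 4)
  T5 <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(attentionScores(T5, p5), bruteSfa(T5, p5)$scores,
               tolerance = 1e-12)
  expect_error(attentionScores(matrix(c(1, NA, 1, 1), 2, 2), tinySfa(d = 2)),
               "numeric error")
})

test_that("softmax scores are shift-invariant, non-negative and sum to 1", {
  set.seed(8)
  for (i in 1:20) {
    p <- tinySfa(d = 6, seed = i)
    Tm <- matrix(rnorm(7 * 6), 7, 6)
    sc <- attentionScores(Tm, p)
    expect_true(all(sc >= 0))
    expect_lt(abs(sum(sc) - 1), 1e-12)
    # adding a constant to all pre-softmax values leaves scores unchanged
    p2 <- p; p2$bs <- p$bs + 3.7
    expect_equal(attentionScores(Tm, p2), sc, tolerance = 1e-9)
  }
})

test_that("context weighting scales each slice row by its score", {
  Tm <- matrix(rnorm(4 * 3), 4, 3)
  expect_equal(contextWeighting(Tm, rep(1 / 4, 4)), Tm / 4,
               tolerance = 1e-12)
  onehot <- c(0, 0, 1, 0)
  Sc <- contextWeighting(Tm, onehot)
  expect_equal(Sc[3, ], Tm[3, ], tolerance = 1e-12)
  expect_true(all(Sc[-3, ] == 0))
  # explicit loop oracle
  sc <- runif(4); sc <- sc / sum(sc)
  ref <- Tm
  for (i in 1:4) ref[i, ] <- sc[i] * Tm[i, ]
  expect_identical(contextWeighting(Tm, sc), ref)
  expect_error(contextWeighting(Tm, c(0.5, 0.5)), "shape error")
})

test_that("the bottleneck re-weighting matches explicit matrix arithmetic", {
  p <- tinySfa(d = 4, r = 2, seed = 5)
  Sv <- matrix(rnorm(3 * 4), 3, 4)
  A <- sliceWeights(Sv, p)
  expect_identical(dim(A), c(3L, 4L))
  # oracle path: H = relu(Sv W1 + b1); A = H W2 + b2
  H <- Sv %*% p$W1 + matrix(p$b1, 3, 2, byrow = TRUE)
  H[H < 0] <- 0
  expect_equal(A, H %*% p$W2 + matrix(p$b2, 3, 4, byrow = TRUE),
               tolerance = 1e-12)
  # zero input with zero biases and bn bypass -> zero output
  expect_true(all(sliceWeights(matrix(0, 3, 4), p) ==
                    matrix(p$b2, 3, 4, byrow = TRUE)))
  p0 <- p; p0$b1 <- rep(0, 2); p0$b2 <- rep(0, 4)
  expect_true(all(sliceWeights(matrix(0, 3, 4), p0) == 0))
  expect_error(initSfa(feature_dim = 6, reduction = 4), "config error")
})

test_that("fusion is the slice-sum of elementwise products", {
  Tm <- matrix(rnorm(5 * 3), 5, 3)
  expect_equal(fuseSlices(Tm, matrix(1, 5, 3)), colSums(Tm),
               tolerance = 1e-12)
  onehot <- matrix(0, 5, 3); onehot[2, ] <- 1
  expect_equal(fuseSlices(Tm, onehot), Tm[2, ], tolerance = 1e-12)
  A <- matrix(rnorm(5 * 3), 5, 3)
  ref <- numeric(3)
  for (j in 1:3) for (i in 1:5) ref[j] <- ref[j] + Tm[i, j] * A[i, j]
  expect_equal(fuseSlices(Tm, A), ref, tolerance = 1e-12)
  expect_error(fuseSlices(Tm, matrix(1, 4, 3)), "shape error")
})

test_that("fusion is linear in T and in A separately", {
  set.seed(12)
  Tm <- matrix(rnorm(6 * 4), 6, 4); T2 <- matrix(rnorm(6 * 4), 6, 4)
  A <- matrix(rnorm(6 * 4), 6, 4); A2 <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(fuseSlices(Tm + T2, A),
               fuseSlices(Tm, A) + fuseSlices(T2, A), tolerance = 1e-10)
  expect_equal(fuseSlices(Tm, A + A2),
               fuseSlices(Tm, A) + fuseSlices(Tm, A2), tolerance = 1e-10)
  # constant weights a: F = a * column sums of T
  a <- 0.37
  expect_equal(fuseSlices(Tm, matrix(a, 6, 4)), a * colSums(Tm),
               tolerance = 1e-12)
})

test_that("the composed SFA equals the staged brute-force oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(2:8, 1); d <- 2 * sample(1:4, 1)
    p <- tinySfa(d = d, r = 2, seed = i)
    Tm <- matrix(rnorm(n * d), n, d)
    out <- sfaForward(Tm, p)
    ref <- bruteSfa(Tm, p)
    expect_equal(attScores(out), ref$scores, tolerance = 1e-5)
    expect_equal(out@context, ref$S, tolerance = 1e-5)
    expect_equal(sliceWeightMatrix(out), ref$A, tolerance = 1e-5)
    expect_equal(fusedFeature(out), ref$F, tolerance = 1e-5)
    expect_lt(abs(sum(attScores(out)) - 1), 1e-12)
  }
})

test_that("mean fusion averages slice rows", {
  v <- rnorm(6)
  Tm <- matrix(rep(v, each = 4), 4, 6)
  expect_equal(meanFuse(Tm), v, tolerance = 1e-12)
  ab <- rbind(rnorm(6), rnorm(6))
  expect_equal(meanFuse(ab), colMeans(ab), tolerance = 1e-12)
  r <- matrix(rnorm(5 * 6), 5, 6)
  ref <- numeric(6)
  for (j in 1:6) ref[j] <- mean(r[, j])
  expect_equal(meanFuse(r), ref, tolerance = 1e-12)
})

test_that("squeeze-and-excitation gates behave in the closed-form limits", {
  p <- initSe(n_slices = 4, se_reduction = 2, seed = 3)
  # saturate every gate at ~1: huge positive bias after the bottleneck
  p1 <- p; p1$U2[] <- 0; p1$c2 <- rep(50, 4)
  Tm <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(seFuse(Tm, p1), meanFuse(Tm), tolerance = 1e-6)
  # identical rows v with gate vector g -> mean(g) * v
  v <- rnorm(6)
  Tv <- matrix(rep(v, each = 4), 4, 6)
  s <- rowMeans(Tv)
  z <- pmax(drop(s %*% p$U1) + p$c1, 0)
  g <- 1 / (1 + exp(-(drop(z %*% p$U2) + p$c2)))
  expect_equal(seFuse(Tv, p), mean(g) * v, tolerance = 1e-10)
  # tiny case against an explicit-loop oracle
  ref <- numeric(6)
  s2 <- rowMeans(Tm)
  z2 <- pmax(drop(s2 %*% p$U1) + p$c1, 0)
  g2 <- 1 / (1 + exp(-(drop(z2 %*% p$U2) + p$c2)))
  for (j in 1:6) ref[j] <- mean(g2 * Tm[, j])
  expect_equal(seFuse(Tm, p), ref, tolerance = 1e-12)
  expect_error(initSe(n_slices = 5, se_reduction = 2), "config error")
})
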