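workedMixture <- function() {
  A <- matrix(c(2, 0, 0, 4, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("P1", "P2")))
  P <- matrix(c(1, .5, 0, 0, .5, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("P1", "P2"), paste0("s", 1:3)))
  list(A = A, P = P, X = A %*% P)
}

test_that("marker initialisation reproduces the worked proportions", {
  w <- workedMixture()
  mk <- MarkerSets(list(P1 = "g1", P2 = "g2"))
  expect_equal(initProportionsFromMarkers(w$X, mk), w$P,
               tolerance = 1e-12)
  # one process: everything is that process (g3 is expressed everywhere)
  mk1 <- MarkerSets(list(P1 = "g3"))
  expect_equal(unname(initProportionsFromMarkers(w$X, mk1)),
               matrix(1, 1, 3))
  # a duplicated profile averages to the same answer
  X2 <- rbind(w$X, g4 = w$X["g1", ])
  mk2 <- MarkerSets(list(P1 = c("g1", "g4"), P2 = "g2"))
  expect_equal(initProportionsFromMarkers(X2, mk2), w$P,
               tolerance = 1e-12)
  expect_error(initProportionsFromMarkers(w$X,
    MarkerSets(list(P1 = "nope", P2 = "g2"))), "nope")
})

test_that("batch NNLS matches the single-RHS reference solver", {
  skip_if_not_installed("pracma")
  for (seed in 1:25) {
    withr::with_seed(seed, {
      C <- matrix(runif(24), 6, 4)
      B <- matrix(runif(6 * 10, -2, 8), 6, 10)
    })
    Xhat <- anchorDeconv:::.nnlsBatch(C, B)
    for (j in seq_len(ncol(B))) {
      ref <- pracma::lsqnonneg(C, B[, j])$x
      expect_equal(Xhat[, j], ref, tolerance = 1e-7,
                   ignore_attr = TRUE)
    }
  }
})

test_that("signature fitting solves the consistent system exactly", {
  w <- workedMixture()
  expect_equal(fitSignatures(w$X, w$P), w$A, tolerance = 1e-8)
  X0 <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3),
                                        paste0("s", 1:3)))
  expect_equal(unname(fitSignatures(X0, w$P)), matrix(0, 3, 2))
  # rank-deficient proportions are refused
  Pbad <- matrix(c(.5, .5, .5, .5, .5, .5), 2, 3)
  expect_error(fitSignatures(w$X, Pbad), "not identifiable")
})

test_that("NNLS clamps a gene that no process can explain", {
  P <- matrix(c(.5, .9, .5, .1), 2, 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  X <- matrix(c(0, 1), 1, 2, dimnames = list("g1", c("s1", "s2")))
  A <- fitSignatures(X, P)
  # unconstrained solution is (1.25, -1.25); NNLS pins P2 at the boundary
  # and the P1 coefficient becomes <p1, x>/<p1, p1> = 0.9/1.06
  expect_identical(unname(A[1, "P2"]), 0)
  expect_equal(unname(A[1, "P1"]), 0.9 / 1.06, tolerance = 1e-12)
  resid <- X - A %*% P
  expect_gt(sqrt(sum(resid^2)), 0.1)
})

test_that("proportion fitting recovers, normalises, and is scale free", {
  w <- workedMixture()
  expect_equal(fitProportions(w$X, w$A), w$P, tolerance = 1e-8)
  # a pure sample maps to an indicator column
  Xp <- w$A %*% diag(2)
  colnames(Xp) <- c("s1", "s2")
  expect_equal(unname(fitProportions(Xp, w$A)), diag(2),
               tolerance = 1e-10)
  # tripling a sample column leaves its proportions unchanged
  X3 <- w$X
  X3[, 2] <- 3 * X3[, 2]
  expect_equal(fitProportions(X3, w$A)[, 2], w$P[, 2],
               tolerance = 1e-10)
})

test_that("marker-seeded deconvolution recovers noiseless mixtures", {
  w <- workedMixture()
  mk <- MarkerSets(list(P1 = "g1", P2 = "g2"))
  fit <- deconvolveByDistinguishers(w$X, mk)
  expect_lt(proportionsRMSE(w$P, sampleProportions(fit)), 1e-6)
  expect_true(fit@converged)
  # signatures correlate perfectly with the pure columns
  ds <- simulateDataset(g = 80L, b = 3L, s = 9L, sigmaRel = 0, seed = 4)
  fit2 <- deconvolveByDistinguishers(observedMatrix(ds),
                                     MarkerSets(anchorTruth(ds)))
  ev <- evaluateDeconvolution(sampleProportions(ds),
                              sampleProportions(fit2),
                              processSignatures(ds),
                              processSignatures(fit2))
  expect_lt(ev@meanRMSE, 1e-6)
  expect_true(all(ev@perProcessPearson > 0.999))
})

test_that("maxIter = 0 returns the initialisation and one signature fit", {
  w <- workedMixture()
  mk <- MarkerSets(list(P1 = "g1", P2 = "g2"))
  fit <- deconvolveByDistinguishers(w$X, mk, maxIter = 0L)
  expect_identical(fit@nIterations, 0L)
  expect_equal(sampleProportions(fit),
               initProportionsFromMarkers(w$X, mk), tolerance = 1e-12)
  expect_equal(fit@signatures,
               fitSignatures(w$X, sampleProportions(fit), mk),
               tolerance = 1e-12)
})

test_that("the reconstruction residual never increases", {
  for (seed in 1:6) {
    ds <- simulateDataset(g = 120L, b = 3L, s = 10L, sigmaRel = 0.3,
                          replicates = 1L, seed = seed)
    fit <- deconvolveByDistinguishers(observedMatrix(ds),
                                      MarkerSets(anchorTruth(ds)))
    expect_true(all(diff(fit@objectiveTrace) <= 1e-9))
  }
})

test_that("composition error grows with the noise level", {
  sigmas <- c(0, 0.1, 0.2, 0.4)
  means <- vapply(sigmas, function(sig) {
    rmse <- vapply(1:20, function(seed) {
      ds <- simulateDataset(g = 300L, b = 4L, s = 10L, sigmaRel = sig,
                            seed = 1000L + seed)
      fit <- deconvolveByDistinguishers(observedMatrix(ds),
                                        MarkerSets(anchorTruth(ds)))
      ev <- evaluateDeconvolution(sampleProportions(ds),
                                  sampleProportions(fit))
      ev@meanRMSE
    }, numeric(1))
    mean(rmse)
  }, numeric(1))
  expect_false(is.unsorted(means))
})
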