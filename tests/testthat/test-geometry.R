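# worked instance used throughout: X = [[1,0],[0,1],[1,1]] gives
# Q-bar = [[.5,0,.5],[0,.5,.5],[.25,.25,.5]] (Q = XX^T, row sums 2,2,4)
workedX <- function() {
  matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
         dimnames = list(paste0("g", 1:3), c("s1", "s2")))
}

test_that("explicit conditional matrix matches hand computation", {
  Qb <- explicitConditionalMatrix(workedX())
  expect_equal(unname(Qb),
               matrix(c(.5, 0, .5, 0, .5, .5, .25, .25, .5),
                      3, 3, byrow = TRUE))
  expect_equal(unname(explicitConditionalMatrix(
    matrix(c(2, 3), 1, 2, dimnames = list("g1", c("A", "B"))))),
    matrix(1, 1, 1))
  for (seed in 1:5) {
    X <- randomExpression(seed)
    expect_equal(rowSums(explicitConditionalMatrix(X)),
                 rep(1, nrow(X)), ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("explicit matrix refuses large instances and zero rows", {
  Xbig <- matrix(1, 2001, 2,
                 dimnames = list(paste0("g", 1:2001), c("A", "B")))
  expect_error(explicitConditionalMatrix(Xbig), "2000")
  X0 <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("gz", "g2"), c("A", "B")))
  expect_error(buildGeometry(X0), "gz")
})

test_that("factored distances reproduce the worked hand computations", {
  geom <- buildGeometry(workedX())
  expect_equal(affineResidualDistance(geom, 1, integer(0)), sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(affineResidualDistance(geom, 2, 1), sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(affineResidualDistance(geom, 3, 1), sqrt(0.125),
               tolerance = 1e-12)
  expect_identical(affineResidualDistance(geom, 1, c(1, 2)), 0)
})

test_that("a single sample collapses all rows to one point", {
  X <- matrix(c(1, 2, 5), 3, 1,
              dimnames = list(paste0("g", 1:3), "s1"))
  geom <- buildGeometry(X)
  for (i in 1:3) for (j in 1:3)
    expect_equal(affineResidualDistance(geom, i, j), 0, tolerance = 1e-12)
})

test_that("factored geometry agrees with the dense oracle everywhere", {
  for (seed in 1:20) {
    X <- randomExpression(seed, gMax = 40L, sMax = 6L)
    geom <- buildGeometry(X)
    Qb <- oracleQbar(X)
    anchors <- withr::with_seed(seed,
      sample(nrow(X), min(3L, ncol(X) - 1L)))
    genes <- seq_len(nrow(X))
    expect_dist_equal(
      vapply(genes, function(i)
        affineResidualDistance(geom, i, anchors), numeric(1)),
      vapply(genes, function(i)
        oracleAffineDist(Qb, i, anchors), numeric(1)))
    target <- setdiff(genes, anchors)[1L]
    expect_dist_equal(
      vapply(genes, function(i)
        signedDirectionDistance(geom, i, anchors, target), numeric(1)),
      vapply(genes, function(i)
        oracleSignedDist(Qb, i, anchors, target), numeric(1)))
  }
})

test_that("signed distance self- and duplicate-row identities hold", {
  X <- workedX()
  X <- rbind(X, g4 = X[1, ])   # duplicate of gene 1
  geom <- buildGeometry(X)
  # self-projection equals the residual distance
  expect_equal(signedDirectionDistance(geom, 3, anchors = 2, target = 3),
               affineResidualDistance(geom, 3, 2), tolerance = 1e-12)
  # anchors project to zero
  expect_identical(signedDirectionDistance(geom, 2, anchors = 2,
                                           target = 3), 0)
  # a row identical to the target scores the target's own distance
  expect_equal(signedDirectionDistance(geom, 4, anchors = 2, target = 1),
               affineResidualDistance(geom, 1, 2), tolerance = 1e-12)
  # a target inside the anchor hull has no direction
  expect_error(signedDirectionDistance(geom, 2, anchors = c(1, 4),
                                       target = 4))
  expect_error(signedDirectionDistance(geom, 2, anchors = 1, target = 4),
               "hull")
})

test_that("the conditional geometry is scale invariant", {
  X <- randomExpression(7)
  geom1 <- buildGeometry(X)
  geom2 <- buildGeometry(X * 37.5)
  anchors <- c(2L, 5L)
  for (gene in seq_len(nrow(X)))
    expect_equal(affineResidualDistance(geom1, gene, anchors),
                 affineResidualDistance(geom2, gene, anchors),
                 tolerance = 1e-12)
})

test_that("projection bases are orthonormal under the induced product", {
  X <- withr::with_seed(11,
    matrix(runif(30 * 6, 0, 10), 30, 6,
           dimnames = list(paste0("g", 1:30), paste0("s", 1:6))))
  geom <- buildGeometry(X)
  pb <- projectionBasis(geom, c(3L, 1L, 7L, 9L))
  U <- pb@directions
  expect_identical(ncol(U), 3L)
  G <- t(U) %*% geom@S %*% U
  expect_equal(G, diag(3), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("anchor selection costs O(gsb) row passes after construction", {
  X <- blockPureExpression(b = 8L)
  geom <- buildGeometry(X)
  counter <- anchorDeconv:::.opReset
  counts <- anchorDeconv:::.opCounts
  counter()
  anchors <- firstPass(geom, 8L)
  c1 <- counts()
  expect_identical(c1$basisAdds, 8L)   # one g-row pass per anchor added
  counter()
  secondPass(geom, anchors)
  c2 <- counts()
  # divide-and-conquer leave-one-out: b log2(b) = 24 basis additions,
  # against b (b - 1) = 56 for naive per-position reconstruction
  expect_lte(c2$basisAdds, 24L)
  expect_lt(c2$basisAdds, 56L)
})
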