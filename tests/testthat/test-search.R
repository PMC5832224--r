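test_that("greedy first pass picks the worked anchors with tie-breaking", {
  X <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  geom <- buildGeometry(X)
  # genes 1 and 2 tie on row norm (sqrt(.5)); lowest index wins, then gene 2
  # is farther (sqrt(.5)) than gene 3 (sqrt(.125))
  expect_identical(firstPass(geom, 2), c(1L, 2L))
  expect_error(firstPass(geom, 3), "b must satisfy")
})

test_that("block-pure designs yield one anchor per process", {
  X <- blockPureExpression(b = 3L)
  geom <- buildGeometry(X)
  anchors <- firstPass(geom, 3L)
  expect_identical(sort(as.integer((anchors + 1L) %/% 2L)), 1:3)  # one per block
  expect_identical(secondPass(geom, anchors), anchors)       # fixed point
  res <- runnersUp(geom, anchors, 1L)
  expect_identical(unname(vapply(runnerUpTables(res),
                                 function(t) t$gene_id[1], "")),
                   rownames(X)[anchors])
})

test_that("both passes agree with the dense sequential oracle", {
  for (seed in 21:40) {
    X <- randomExpression(seed, gMax = 40L, sMax = 6L, sMin = 3L)
    b <- withr::with_seed(seed + 1000, sample(2:min(4L, ncol(X)), 1L))
    geom <- buildGeometry(X)
    Qb <- oracleQbar(X)
    a1 <- firstPass(geom, b)
    expect_identical(a1, oracleFirstPass(Qb, b))
    a2 <- secondPass(geom, a1)
    expect_identical(a2, oracleSecondPass(Qb, a1))
    # when the sweep made no replacement the anchor set is a fixed point:
    # every anchor maximises its own leave-one-out distance (after a
    # replacement only later positions see the updated set, so the
    # property is a single-sweep guarantee, not a global one)
    if (identical(a2, a1)) {
      for (k in seq_along(a2)) {
        d <- vapply(seq_len(nrow(X)), function(i)
          oracleAffineDist(Qb, i, a2[-k]), numeric(1))
        expect_identical(which.max(d), a2[k])
      }
    }
  }
})

test_that("leave-one-out reuse equals naive recomputation of distances", {
  for (seed in 41:55) {
    X <- randomExpression(seed, gMax = 40L, sMax = 6L, sMin = 4L)
    geom <- buildGeometry(X)
    Qb <- oracleQbar(X)
    b <- min(4L, ncol(X))
    anchors <- firstPass(geom, b)
    for (k in seq_along(anchors)) {
      st <- anchorDeconv:::.buildBasis(geom, anchors[-k])
      dense <- vapply(seq_len(nrow(X)), function(i)
        oracleAffineDist(Qb, i, anchors[-k]), numeric(1))
      dense[anchors[-k]] <- 0
      expect_dist_equal(sqrt(st$res2), dense)
    }
  }
})

test_that("runners-up rank duplicates together and stay sorted", {
  X <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  X <- rbind(X, g4 = X[1, ])
  geom <- buildGeometry(X)
  res <- runnersUp(geom, c(1L, 2L), 4L)
  t1 <- runnerUpTables(res)[[1L]]
  expect_true(all(c("g1", "g4") %in% t1$gene_id))
  expect_equal(t1$distance[t1$gene_id == "g1"],
               t1$distance[t1$gene_id == "g4"], tolerance = 1e-12)
  for (t in runnerUpTables(res)) {
    expect_true(all(t$distance >= 0))
    expect_false(is.unsorted(rev(t$distance)))
  }
  expect_equal(bestLengths(res)[1L, ],
               vapply(runnerUpTables(res), function(t) t$distance[1L],
                      numeric(1)), ignore_attr = TRUE)
  expect_error(runnersUp(geom, c(1L, 2L), 0L), "positive")
})

test_that("selection is equivariant under gene and sample permutations", {
  X <- randomExpression(77, gMax = 30L, sMax = 6L, sMin = 3L)
  b <- 3L
  a0 <- secondPass(buildGeometry(X), firstPass(buildGeometry(X), b))
  withr::with_seed(7, {
    pg <- sample(nrow(X))
    ps <- sample(ncol(X))
  })
  Xg <- X[pg, ]
  ag <- secondPass(buildGeometry(Xg), firstPass(buildGeometry(Xg), b))
  expect_identical(rownames(Xg)[ag], rownames(X)[a0])
  Xs <- X[, ps]
  as_ <- secondPass(buildGeometry(Xs), firstPass(buildGeometry(Xs), b))
  expect_identical(as_, a0)
})

test_that("zero-noise separable mixtures give back the planted anchors", {
  for (seed in 1:10) {
    b <- 2L + (seed %% 4L)
    ds <- simulateDataset(g = 60L, b = b, s = b + 5L,
                          anchorsPerProcess = 2L, sigmaRel = 0,
                          seed = seed)
    res <- findDistinguishers(observedMatrix(ds), b = b,
                              nPerProcess = 2L, spikeValue = 0)
    truth <- anchorTruth(ds)
    hits <- vapply(truth, function(g) sum(anchorGenes(res) %in% g),
                   integer(1))
    expect_identical(unname(hits), rep(1L, b))
  }
})

test_that("the default spike keeps anchors on a high-expression design", {
  ds <- simulateDataset(g = 60L, b = 3L, s = 8L, anchorsPerProcess = 2L,
                        sigmaRel = 0, seed = 5)
  r0 <- findDistinguishers(observedMatrix(ds), b = 3L, nPerProcess = 2L,
                           spikeValue = 0)
  r75 <- findDistinguishers(observedMatrix(ds), b = 3L, nPerProcess = 2L,
                            spikeQuantile = 0.75)
  truth <- unlist(anchorTruth(ds))
  expect_true(all(anchorGenes(r0) %in% truth))
  expect_true(all(anchorGenes(r75) %in% truth))
})

test_that("the bestLengths scan has sane shape and non-negative entries", {
  ds <- simulateDataset(g = 80L, b = 3L, s = 8L, sigmaRel = 0.1, seed = 3)
  tab <- bestLengthsScan(observedMatrix(ds), bMax = 2L)
  expect_identical(dim(tab), c(1L, 2L))
  tab6 <- bestLengthsScan(observedMatrix(ds), bMax = 6L)
  expect_identical(dim(tab6), c(5L, 6L))
  for (b in 2:6) {
    expect_true(all(!is.na(tab6[b - 1L, seq_len(b)])))
    expect_true(all(is.na(tab6[b - 1L, -seq_len(b)])))
  }
  expect_true(all(tab6[!is.na(tab6)] >= 0))
})

test_that("marker sets built from results are disjoint and capped", {
  ds <- simulateDataset(g = 100L, b = 4L, s = 10L, sigmaRel = 0.3,
                        seed = 9)
  res <- findDistinguishers(observedMatrix(ds), b = 4L, nPerProcess = 8L)
  mk <- markersFromDistinguishers(res, nPerProcess = 5L)
  genes <- unlist(markerList(mk))
  expect_identical(anyDuplicated(genes), 0L)
  expect_true(all(lengths(markerList(mk)) <= 5L))
  expect_identical(length(markerList(mk)), 4L)
})
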