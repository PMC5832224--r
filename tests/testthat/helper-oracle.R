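# Dense, from-scratch reference implementations used as independent
# oracles: they materialise the full conditional-expression matrix and use
# explicit Gram-Schmidt, the opposite of the factored production path.

oracleQbar <- function(X) {
  Q <- tcrossprod(X)
  Q / rowSums(Q)
}

# residual vector of a gene's row after affine projection onto the
# anchors' rows (recentre on first anchor, Gram-Schmidt the rest)
oracleResidual <- function(Qb, gene, anchors) {
  z <- Qb[gene, ]
  if (length(anchors) == 0L) return(z)
  o <- Qb[anchors[1L], ]
  z <- z - o
  if (length(anchors) > 1L) {
    U <- NULL
    tol <- 1e-9 * max(sqrt(rowSums(Qb^2)))
    for (a in anchors[-1L]) {
      v <- Qb[a, ] - o
      if (!is.null(U)) v <- v - as.vector(U %*% crossprod(U, v))
      n <- sqrt(sum(v^2))
      if (n > tol) U <- cbind(U, v / n)
    }
    if (!is.null(U)) z <- z - as.vector(U %*% crossprod(U, z))
  }
  z
}

oracleAffineDist <- function(Qb, gene, anchors) {
  if (gene %in% anchors) return(0)
  sqrt(sum(oracleResidual(Qb, gene, anchors)^2))
}

oracleSignedDist <- function(Qb, gene, anchors, target) {
  if (gene %in% anchors) return(0)
  w <- oracleResidual(Qb, target, anchors)
  u <- w / sqrt(sum(w^2))
  sum(oracleResidual(Qb, gene, anchors) * u)
}

oracleFirstPass <- function(Qb, b) {
  anchors <- integer(0)
  for (k in seq_len(b)) {
    d <- vapply(seq_len(nrow(Qb)), function(i)
      oracleAffineDist(Qb, i, anchors), numeric(1))
    anchors <- c(anchors, which.max(d))
  }
  anchors
}

# sequential single sweep, every leave-one-out distance recomputed densely
oracleSecondPass <- function(Qb, anchors) {
  for (pos in seq_along(anchors)) {
    d <- vapply(seq_len(nrow(Qb)), function(i)
      oracleAffineDist(Qb, i, anchors[-pos]), numeric(1))
    best <- which.max(d)
    if (best != anchors[pos] && !(best %in% anchors))
      anchors[pos] <- best
  }
  anchors
}

# Compare distance vectors at the stated tolerance; values that are zero
# to numerical precision on either route (Q-bar row norms are <= 1, so
# 1e-8 is far below any meaningful distance) count as equal zeros --
# squared-residual bookkeeping and dense Gram-Schmidt round them
# differently.
expect_dist_equal <- function(actual, expected, tol = 1e-9, zero = 1e-8) {
  actual <- unname(actual)
  expected <- unname(expected)
  ok <- abs(actual - expected) <= tol |
    (abs(actual) < zero & abs(expected) < zero)
  expect_true(all(ok))
}

randomExpression <- function(seed, gMax = 50L, sMax = 8L, sMin = 2L) {
  withr::with_seed(seed, {
    g <- sample(5:gMax, 1L)
    s <- sample(sMin:sMax, 1L)
    matrix(runif(g * s, 0, 10), g, s,
           dimnames = list(paste0("g", seq_len(g)),
                           paste0("s", seq_len(s))))
  })
}

# block-pure design: one pair of exclusive genes per process, pure samples
blockPureExpression <- function(b = 3L, high = c(10, 5)) {
  g <- 2L * b
  X <- matrix(0, g, b,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("s", seq_len(b))))
  for (k in seq_len(b)) {
    X[2L * k - 1L, k] <- high[1L]
    X[2L * k, k] <- high[2L]
  }
  X
}
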