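# discretize a bivariate normal sample through equal-probability thresholds
.latent_pair <- function(n, rho, C, seed) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cuts <- qnorm(seq_len(C - 1) / C)
  cbind(findInterval(z1, cuts), findInterval(z2, cuts))
}

test_that("bivariate normal CDF matches a univariate-integral oracle", {
  cases <- expand.grid(a = c(-1.5, 0, 0.8), b = c(-0.5, 1.2),
                       rho = c(-0.85, -0.3, 0.5, 0.95))
  for (i in seq_len(nrow(cases))) {
    a <- cases$a[i]; b <- cases$b[i]; rho <- cases$rho[i]
    oracle <- integrate(function(x)
      dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2)),
      -Inf, a, rel.tol = 1e-10)$value
    expect_equal(pbinorm(a, b, rho), oracle, tolerance = 1e-6)
  }
  # vectorized over rho
  expect_equal(pbinorm(c(0, 0), c(0, 0), c(0, 0.5)),
               c(0.25, 1 / 4 + asin(0.5) / (2 * pi)), tolerance = 1e-6)
  expect_equal(pbinorm(Inf, -0.3, 0.7), pnorm(-0.3))
  expect_equal(pbinorm(-Inf, 0.3, 0.7), 0)
})

test_that("polychoric estimation recovers the generating latent correlation", {
  for (rho in c(0, 0.5)) {
    xy <- .latent_pair(10000, rho, C = 5, seed = 31)
    est <- polychoric_pair(xy[, 1], xy[, 2], 5L, 5L)
    expect_equal(est$rho, rho, tolerance = 0.03)
    # step-1 thresholds approach the generating equal-probability cuts
    expect_equal(est$thresholds_x, qnorm((1:4) / 5), tolerance = 0.05)
  }
  # matrix route agrees with the pairwise route
  xy <- .latent_pair(2000, 0.4, C = 3, seed = 8)
  Rm <- polychoric_matrix(xy, C = 3L)
  pr <- polychoric_pair(xy[, 1], xy[, 2], 3L, 3L)
  expect_equal(Rm$matrix[1, 2], pr$rho, tolerance = 1e-4)
  expect_equal(diag(Rm$matrix), rep(1, 2))
})

test_that("identical items give a clamped polychoric correlation near 1", {
  x <- .latent_pair(500, 0.3, C = 4, seed = 2)[, 1]
  est <- polychoric_pair(x, x, 4L, 4L)
  expect_true(est$clamped || est$rho > 0.99)
  expect_true(est$rho <= 1 - 1e-6 + 1e-12)
})

test_that("polychoric exceeds Pearson in magnitude for discretized normals", {
  diffs <- vapply(1:8, function(s) {
    xy <- .latent_pair(600, 0.45, C = 3, seed = 100 + s)
    abs(polychoric_pair(xy[, 1], xy[, 2], 3L, 3L)$rho) -
      abs(cor(xy[, 1], xy[, 2]))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  # and Pearson underestimates the latent correlation on average
  pearsons <- vapply(1:8, function(s) {
    xy <- .latent_pair(600, 0.5, C = 3, seed = 200 + s)
    cor(xy[, 1], xy[, 2])
  }, numeric(1))
  expect_lt(mean(pearsons), 0.5)
})

test_that("pearson_matrix flags zero-variance items by name", {
  x <- cbind(X1 = c(1L, 1L, 1L, 1L), X2 = c(0L, 1L, 0L, 1L))
  expect_error(pearson_matrix(x), "X1")
})

test_that("KMO matches a direct textbook-formula oracle", {
  kmo_oracle <- function(R) {
    S <- solve(R)
    A <- -S / sqrt(outer(diag(S), diag(S)))
    num <- sum(R[upper.tri(R)]^2)
    num / (num + sum(A[upper.tri(A)]^2))
  }
  # equicorrelation rho = 0.5, J = 6
  R <- matrix(0.5, 6, 6); diag(R) <- 1
  expect_equal(kmo(R), kmo_oracle(R), tolerance = 1e-12)
  # a structured low-rank-plus-noise matrix
  set.seed(4)
  L <- matrix(runif(10, 0.3, 0.7), 5, 2)
  R2 <- tcrossprod(L); diag(R2) <- 1
  expect_equal(kmo(R2), kmo_oracle(R2), tolerance = 1e-12)
  # permutation invariance
  p <- c(3, 1, 5, 2, 4)
  expect_equal(kmo(R2[p, p]), kmo(R2), tolerance = 1e-12)
  # identity: no common variance, 0 by convention
  expect_equal(kmo(diag(4)), 0)
  expect_true(kmo(R) >= 0 && kmo(R) <= 1)
})

test_that("CAF is exactly 1 - KMO and behaves at the extremes", {
  expect_equal(caf(diag(5)), 1)                       # q = 0, no structure
  R <- matrix(0.6, 8, 8); diag(R) <- 1
  expect_equal(caf(R), 1 - kmo(R))
  expect_lt(caf(R), 0.25)   # strongly equicorrelated: most variance common
  # residual of a perfectly fitting model is diagonal -> CAF = 1
  expect_equal(caf(NULL, residual = diag(6)), 1)
})

test_that("PSD smoothing is recorded and yields a usable matrix", {
  # force an indefinite pairwise assembly via tiny n and many items
  set.seed(6)
  R <- matrix(0.95, 4, 4); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.9            # wildly inconsistent entries
  sm <- arsefa:::.smooth_psd(R)
  expect_true(sm$smoothed)
  ev <- eigen(sm$R, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_equal(diag(sm$R), rep(1, 4))
})
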