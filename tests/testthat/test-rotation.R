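# simple-structure loadings used across rotation tests
.simple_L <- function() {
  cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.7, 0.8, 0.6))
}

test_that("oblimin is a fixed point at perfect simple structure", {
  L <- .simple_L()
  rot <- oblimin_rotate(L, seed = 1)
  # same loadings up to column permutation / sign
  best <- rot$loadings
  agree <- max(abs(abs(crossprod(best, L)) /
                     sqrt(outer(colSums(best^2), colSums(L^2)))))
  expect_gt(agree, 0.9999)
  expect_lt(rotation_fit_error(rot, L), 1e-8)
  expect_lt(rot$criterion, 1e-6)
})

test_that("oblimin is deterministic given a seed and preserves fit", {
  set.seed(5)
  A <- matrix(rnorm(36), 12, 3)
  r1 <- oblimin_rotate(A, seed = 9)
  r2 <- oblimin_rotate(A, seed = 9)
  expect_identical(r1$loadings, r2$loadings)
  expect_lt(rotation_fit_error(r1, A), 1e-8)
  # Phi symmetric PD with unit diagonal
  expect_equal(diag(r1$Phi), rep(1, 3))
  expect_true(min(eigen(r1$Phi, symmetric = TRUE)$values) > 0)
  # single factor: returned unchanged up to sign
  r3 <- oblimin_rotate(A[, 1, drop = FALSE])
  expect_equal(abs(r3$loadings), abs(A[, 1, drop = FALSE]))
})

test_that("targets reproduce the published specification pattern", {
  des <- scale_design(Q = 2, J = 12, C = 5, balanced = TRUE,
                      ars_strength = "large", N = 250, replication = FALSE)
  fst <- build_target(des, include_ars = TRUE, kind = "fst")
  # multidimensional FST: +/-1 on the alternating content pattern, 1 on ARS
  expect_equal(unname(fst$values[1:4, "F1"]), c(1, 0, -1, 0))
  expect_equal(unname(fst$values[1:4, "F2"]), c(0, 1, 0, -1))
  expect_true(all(fst$values[, "ARS"] == 1))
  expect_true(all(fst$specified))
  sst <- build_target(des, include_ars = TRUE, kind = "sst")
  # SST: only content zeros specified; ARS column entirely unspecified
  expect_true(all(is.na(sst$values[, "ARS"])))
  expect_equal(unname(sst$values[1:4, "F1"]), c(NA, 0, NA, 0))
  expect_equal(sum(sst$specified), 12L)
  # unbalanced: no negative target entries
  desu <- scale_design(Q = 2, J = 12, C = 5, balanced = FALSE,
                       ars_strength = "large", N = 250, replication = FALSE)
  expect_true(all(build_target(desu, TRUE, "fst")$values >= 0))
  # SST undefined for unidimensional designs
  des1 <- scale_design(Q = 1, J = 12, C = 5, balanced = TRUE,
                       ars_strength = "large", N = 250)
  expect_error(build_target(des1, TRUE, "sst"), "multidimensional")
  # CSV round trip keeps the NA dialect
  f <- tempfile(fileext = ".csv")
  write_target_csv(sst, f)
  sst2 <- read_target_csv(f, "sst")
  expect_equal(sst2$values, sst$values)
  unlink(f)
})

test_that("Procrustes toward a matching fully specified target is a fixed point", {
  L <- .simple_L()
  tg <- target_spec(L, "fst")
  rot <- procrustes_oblique(L, tg)
  expect_equal(unname(rot$loadings), unname(L), tolerance = 1e-8)
  expect_lt(rot$criterion, 1e-12)
  expect_equal(rot$Phi, diag(2), tolerance = 1e-8)
})

test_that("Procrustes column solutions match a numeric-optimizer oracle", {
  # oracle: general-purpose optimizer on the same masked per-column LS
  # problem, followed by the identical unit-variance normalization
  set.seed(14)
  for (rep in 1:5) {
    A0 <- matrix(rnorm(8 * 3), 8, 3)
    V <- matrix(rnorm(24), 8, 3)
    for (k in 1:3) V[sample(8, 2), k] <- NA   # partially specified
    V[, 2][!is.na(V[, 2])] <- 0          # one homogeneous (all-zero) column
    tg <- suppressWarnings(target_spec(V, "fst"))
    rot <- procrustes_oblique(A0, tg)
    B_oracle <- sapply(1:3, function(k) {
      rows <- tg$specified[, k]
      y <- tg$values[rows, k]
      obj <- function(b) {
        r <- A0[rows, , drop = FALSE] %*% b - y
        pen <- if (all(y == 0)) (sum(b^2) - 1)^2 * 1e4 else 0
        sum(r^2) + pen
      }
      # multistart: the penalized homogeneous problem has stationary points
      # at every eigen-direction
      fits <- lapply(1:8, function(s) {
        optim(rnorm(3), obj, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
      })
      fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]$par
    })
    # column-wise masked-LS criteria agree to 1e-4 with the oracle
    B_mine <- sapply(1:3, function(k)
      arsefa:::.procrustes_column(A0, tg$specified[, k], tg$values[, k]))
    for (k in 1:3) {
      rows <- tg$specified[, k]; y <- tg$values[rows, k]
      lsq <- function(b) {
        b <- b / if (all(y == 0)) sqrt(sum(b^2)) else 1
        sum((A0[rows, , drop = FALSE] %*% b - y)^2)
      }
      expect_lt(abs(lsq(B_mine[, k]) - lsq(B_oracle[, k])), 1e-4)
    }
    # and the assembled rotation preserves the common part exactly
    expect_lt(rotation_fit_error(rot, A0), 1e-8)
    expect_equal(diag(rot$Phi), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("semi-specified rotation of the worked example recovers the truth", {
  m <- build_worked_example()
  d <- generate_dataset(m, 10000, seed = 55)
  sol <- fit_efa(pearson_matrix(d), 3, 10000)
  des <- scale_design(Q = 2, J = 12, C = 5, balanced = TRUE,
                      ars_strength = "none", N = 250, replication = FALSE)
  sst <- procrustes_oblique(sol, build_target(des, TRUE, "sst"))
  # near-orthogonal recovered factors and near-zero hypothesized zeros
  expect_lt(max(abs(sst$Phi[upper.tri(sst$Phi)])), 0.05)
  al <- align_solution(sst, m, ars_extracted = TRUE)
  zeros <- m$loadings[, 1:2] == 0
  expect_lt(max(abs(al$loadings[, 1:2][zeros])), 0.05)
  # rotating toward the generating values and toward the 0/1 target gives
  # near-identical loadings
  f1 <- procrustes_oblique(sol, target_spec(m$loadings, "fst"))
  f2 <- procrustes_oblique(sol, build_target(des, TRUE, "fst"))
  a1 <- align_solution(f1, m, TRUE); a2 <- align_solution(f2, m, TRUE)
  expect_lt(max(abs(a1$loadings - a2$loadings)), 0.02)
})

test_that("degenerate rotation inputs raise errors", {
  L <- cbind(c(1, 1, 1, 1), c(1, 1, 1, 1))  # rank 1
  tg <- target_spec(matrix(c(1, 0, 0, 1, 0, 1, 1, 0), 4, 2), "fst")
  expect_error(procrustes_oblique(L, tg), "rank")
})
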