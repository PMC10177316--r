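.truth2 <- function() build_worked_example()   # Q = 2, ARS present

test_that("alignment is invariant to column permutation and sign flips", {
  m <- .truth2()
  set.seed(41)
  est <- m$loadings + matrix(rnorm(36, sd = 0.03), 12, 3)
  base <- align_solution(est, m, ars_extracted = TRUE, informed = FALSE)
  for (i in 1:5) {
    p <- sample(3); s <- sample(c(-1, 1), 3, replace = TRUE)
    shuffled <- est[, p] %*% diag(s)
    al <- align_solution(shuffled, m, ars_extracted = TRUE, informed = FALSE)
    expect_equal(al$loadings, base$loadings, tolerance = 1e-12)
    expect_equal(rmse_loadings(al, m, "content"),
                 rmse_loadings(base, m, "content"), tolerance = 1e-12)
    expect_equal(max_abs_bias_zero(al, m), max_abs_bias_zero(base, m),
                 tolerance = 1e-12)
    expect_equal(rmse_factor_corr(al, m), rmse_factor_corr(base, m),
                 tolerance = 1e-12)
  }
})

test_that("alignment equals exhaustive search over assignments", {
  m <- .truth2()
  set.seed(42)
  for (i in 1:10) {
    est <- matrix(rnorm(36), 12, 3)
    al <- align_solution(est, m, ars_extracted = TRUE, informed = FALSE)
    # brute force over ordered pairs of distinct estimated columns
    best <- -Inf
    for (c1 in 1:3) for (c2 in setdiff(1:3, c1)) {
      v <- abs(tucker_congruence(est[, c1], m$loadings[, 1])) +
        abs(tucker_congruence(est[, c2], m$loadings[, 2]))
      best <- max(best, v)
    }
    got <- abs(tucker_congruence(al$loadings[, 1], m$loadings[, 1])) +
      abs(tucker_congruence(al$loadings[, 2], m$loadings[, 2]))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("informed rotations keep the ARS column in target position", {
  m <- .truth2()
  d <- generate_dataset(m, 2000, seed = 19)
  sol <- fit_efa(pearson_matrix(d), 3, 2000)
  des <- scale_design(Q = 2, J = 12, C = 5, balanced = TRUE,
                      ars_strength = "none", N = 250, replication = FALSE)
  rot <- procrustes_oblique(sol, build_target(des, TRUE, "fst"))
  al <- align_solution(rot, m, ars_extracted = TRUE)
  expect_equal(al$assignment[3], 3L)
  expect_gt(tucker_congruence(al$loadings[, 3], m$loadings[, 3]), 0.8)
})

test_that("loading RMSE matches direct formulas and scales linearly", {
  m <- .truth2()
  est <- m$loadings
  al_perfect <- align_solution(est, m, TRUE, informed = FALSE)
  expect_equal(rmse_loadings(al_perfect, m, "content"), 0)
  expect_equal(rmse_loadings(al_perfect, m, "ars"), 0)
  expect_equal(max_abs_bias_zero(al_perfect, m), 0)

  # single content loading off by 0.1 in a 12 x 1 content block
  des1 <- scale_design(Q = 1, J = 12, C = 3, balanced = TRUE,
                       ars_strength = "small", N = 250)
  m1 <- build_population_model(des1)
  est1 <- m1$loadings
  est1[1, 1] <- est1[1, 1] + 0.1
  al1 <- align_solution(est1, m1, TRUE, informed = FALSE)
  expect_equal(rmse_loadings(al1, m1, "content"), sqrt(0.01 / 12),
               tolerance = 1e-9)
  expect_equal(rmse_loadings(al1, m1, "content"), 0.0289, tolerance = 5e-3)

  # doubling every deviation doubles the RMSE
  est2 <- m$loadings + 0.05
  est4 <- m$loadings + 0.10
  a2 <- align_solution(est2, m, TRUE, informed = FALSE)
  a4 <- align_solution(est4, m, TRUE, informed = FALSE)
  expect_equal(rmse_loadings(a4, m, "content"),
               2 * rmse_loadings(a2, m, "content"), tolerance = 1e-9)

  # max-abs-bias identifies a single planted cross-loading
  est3 <- m$loadings
  est3[2, 1] <- 0.25                      # a true-zero content cell
  al3 <- align_solution(est3, m, TRUE, informed = FALSE)
  expect_equal(max_abs_bias_zero(al3, m), 0.25)
  # equals an exhaustive scan of zero cells
  zeros <- m$loadings[, 1:2] == 0
  expect_equal(max_abs_bias_zero(al3, m),
               max(abs(al3$loadings[, 1:2][zeros])))
})

test_that("metric preconditions are enforced", {
  des1 <- scale_design(Q = 1, J = 12, C = 3, balanced = FALSE,
                       ars_strength = "none", N = 250)
  m1 <- build_population_model(des1)
  al <- align_solution(m1$loadings[, 1, drop = FALSE], m1, FALSE)
  expect_error(rmse_loadings(al, m1, "ars"), "extracted")
  expect_error(max_abs_bias_zero(al, m1), "zero cells")
  expect_error(rmse_factor_corr(al, m1), "Q = 2")
})

test_that("factor-correlation recovery and TPR arithmetic", {
  m <- .truth2()
  est <- m$loadings
  al <- align_solution(est, m, TRUE, informed = FALSE)
  expect_equal(rmse_factor_corr(al, m), 0)
  al$Phi[1, 2] <- al$Phi[2, 1] <- 0.07
  expect_equal(rmse_factor_corr(al, m), 0.07)
  expect_equal(tpr(c(3L, 3L, 3L), 3L), 1)
  expect_equal(tpr(c(2L, 2L), 3L), 0)
  expect_equal(tpr(c(rep(3L, 9), 2L), 3L), 0.9)
  expect_error(tpr(integer(0), 2L), "empty")
})
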