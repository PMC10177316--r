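# Standard bivariate normal CDF P(X <= a, Y <= b) with correlation rho,
# vectorized over (a, b). Uses the identity
#   Phi2(a, b; rho) = Phi(a) Phi(b) + int_0^rho phi2(a, b; r) dr
# with Gauss-Legendre quadrature on the correlation path; phi2 is the
# bivariate normal density. Accurate to ~1e-7 for |rho| <= 0.99 with 24
# nodes, ample for likelihood work on contingency tables.
.gl24 <- local({
  gl <- NULL
  function() {
    if (is.null(gl)) {
      # Golub-Welsch: nodes/weights on [-1, 1] from the Jacobi matrix
      n <- 24L
      i <- seq_len(n - 1L)
      b <- i / sqrt(4 * i^2 - 1)
      Jm <- matrix(0, n, n)
      Jm[cbind(i, i + 1L)] <- b; Jm[cbind(i + 1L, i)] <- b
      e <- eigen(Jm, symmetric = TRUE)
      gl <<- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
    }
    gl
  }
})

#' Bivariate standard normal CDF
#'
#' `P(X <= a, Y <= b)` for standard normal `(X, Y)` with correlation `rho`,
#' vectorized over `a`, `b` and `rho` (recycled). Infinite bounds are
#' handled.
#'
#' @param a,b Numeric vectors of upper bounds.
#' @param rho Correlation(s) in `(-1, 1)`.
#' @return Numeric vector of probabilities.
#' @export
pbinorm <- function(a, b, rho) {
  stopifnot(all(abs(rho) < 1))
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(a, n); b <- rep_len(b, n); rho <- rep_len(rho, n)
  out <- stats::pnorm(a) * stats::pnorm(b)
  fin <- is.finite(a) & is.finite(b) & rho != 0
  # infinite bounds: reduce to univariate / trivial cases
  out[a == -Inf | b == -Inf] <- 0
  ia <- a == Inf & b > -Inf; out[ia] <- stats::pnorm(b[ia])
  ib <- b == Inf & a > -Inf; out[ib] <- stats::pnorm(a[ib])
  if (any(fin)) {
    gl <- .gl24()
    af <- a[fin]; bf <- b[fin]; rf <- rho[fin]
    acc <- 0
    for (k in seq_along(gl$x)) {
      rk <- rf / 2 * (gl$x[k] + 1)      # node on [0, rho], per element
      wk <- rf / 2 * gl$w[k]
      om <- 1 - rk^2
      acc <- acc + wk / (2 * pi * sqrt(om)) *
        exp(-(af^2 - 2 * rk * af * bf + bf^2) / (2 * om))
    }
    out[fin] <- out[fin] + acc
  }
  pmin(pmax(out, 0), 1)
}

# Bivariate standard normal density, vectorized; 0 at infinite coordinates.
.dbinorm <- function(a, b, rho) {
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(a, n); b <- rep_len(b, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  fin <- is.finite(a) & is.finite(b)
  om <- 1 - rho[fin]^2
  out[fin] <- exp(-(a[fin]^2 - 2 * rho[fin] * a[fin] * b[fin] + b[fin]^2) /
                    (2 * om)) / (2 * pi * sqrt(om))
  out
}

# Threshold estimates from one item's marginal: inverse-normal of the
# cumulative proportions at the C-1 internal cuts.
.item_thresholds <- function(x, C) {
  p <- cumsum(tabulate(x + 1L, nbins = C)) / length(x)
  stats::qnorm(p[-C])
}

# Profiled log-likelihood of one pair's contingency table at correlation rho.
.pair_loglik <- function(rho, tab, ta, tb) {
  Ca <- length(ta) + 1L; Cb <- length(tb) + 1L
  a <- c(-Inf, ta, Inf); b <- c(-Inf, tb, Inf)
  Pcum <- matrix(pbinorm(rep(a, times = Cb + 1L), rep(b, each = Ca + 1L), rho),
                 Ca + 1L, Cb + 1L)
  P <- Pcum[-1, -1] - Pcum[-(Ca + 1L), -1] - Pcum[-1, -(Cb + 1L)] +
    Pcum[-(Ca + 1L), -(Cb + 1L)]
  sum(tab * log(pmax(P, 1e-12)))
}

#' Two-step polychoric correlation of one item pair
#'
#' Step 1 estimates each item's thresholds from the inverse-normal of its
#' cumulative marginal proportions; step 2 maximizes the bivariate-normal
#' likelihood of the observed contingency table over the latent correlation.
#'
#' @param x,y Integer response vectors coded `0..C-1`.
#' @param Cx,Cy Category counts (defaults: observed maxima + 1).
#' @return List with `rho`, `thresholds_x`, `thresholds_y`, `clamped`.
#' @export
polychoric_pair <- function(x, y, Cx = max(x) + 1L, Cy = max(y) + 1L) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("polychoric correlation needs at least 2 observed categories per item")
  ta <- .item_thresholds(x, Cx); tb <- .item_thresholds(y, Cy)
  tab <- table(factor(x, levels = 0:(Cx - 1L)), factor(y, levels = 0:(Cy - 1L)))
  opt <- stats::optimize(function(r) -.pair_loglik(r, tab, ta, tb),
                         interval = c(-0.999, 0.999), tol = 1e-5)
  rho <- opt$minimum
  clamped <- FALSE
  if (abs(rho) > 1 - 1e-6) {
    rho <- sign(rho) * (1 - 1e-6)
    clamped <- TRUE
  }
  list(rho = rho, thresholds_x = ta, thresholds_y = tb, clamped = clamped)
}

# Eigenvalue-clipping PSD smoothing; rescales back to unit diagonal.
.smooth_psd <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(R = R, smoothed = FALSE))
  v <- pmax(e$values, eps)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  list(R = S, smoothed = TRUE)
}

.correlation_estimate <- function(R, method, thresholds = NULL,
                                  smoothed = FALSE) {
  structure(list(matrix = R, method = method, thresholds = thresholds,
                 smoothed = smoothed),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("correlation_estimate: %d x %d, %s%s\n", nrow(x$matrix),
              ncol(x$matrix), x$method, if (x$smoothed) " (smoothed)" else ""))
  invisible(x)
}

#' Pearson correlation matrix of ordinal responses
#'
#' Product-moment correlations treating the integer category codes as
#' numeric scores.
#'
#' @param data An `ordinal_dataset` or integer matrix.
#' @return A `correlation_estimate` with method `"pearson"`.
#' @export
pearson_matrix <- function(data) {
  x <- if (inherits(data, "ordinal_dataset")) data$responses else as.matrix(data)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance item(s): ",
         paste(colnames(x)[v == 0], collapse = ", "))
  R <- stats::cor(x)
  .correlation_estimate(R, "pearson")
}

#' Polychoric correlation matrix of ordinal responses
#'
#' Pairwise two-step maximum-likelihood polychoric correlations (see
#' [polychoric_pair()]), assembled into a matrix and eigenvalue-clipped to
#' positive semidefiniteness when necessary (recorded in the `smoothed`
#' flag).
#'
#' @param data An `ordinal_dataset` or integer matrix coded `0..C-1`.
#' @param C Number of categories (shared across items).
#' @return A `correlation_estimate` with method `"polychoric"` and per-item
#'   threshold estimates.
#' @export
polychoric_matrix <- function(data, C = NULL) {
  x <- if (inherits(data, "ordinal_dataset")) data$responses else as.matrix(data)
  if (is.null(C))
    C <- if (inherits(data, "ordinal_dataset")) data$C else max(x) + 1L
  J <- ncol(x)
  N <- nrow(x)
  stopifnot(J >= 2L)
  taus <- lapply(seq_len(J), function(j) .item_thresholds(x[, j], C))
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  K <- nrow(pairs)
  G <- C + 1L                            # corner count per axis
  # per-pair contingency counts (K x C^2) and padded corner thresholds
  counts <- matrix(0, K, C * C)
  Ta <- matrix(0, K, G); Tb <- matrix(0, K, G)
  for (k in seq_len(K)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    counts[k, ] <- tabulate((x[, i] + 1L) + C * x[, j], nbins = C * C)
    Ta[k, ] <- c(-Inf, taus[[i]], Inf)
    Tb[k, ] <- c(-Inf, taus[[j]], Inf)
  }
  corner_i <- rep(seq_len(G), times = G)   # corner column layout: i + G*(j-1)
  corner_j <- rep(seq_len(G), each = G)
  Abig <- Ta[, corner_i, drop = FALSE]
  Bbig <- Tb[, corner_j, drop = FALSE]
  cx <- rep(seq_len(C), times = C); cy <- rep(seq_len(C), each = C)
  i11 <- (cx + 1L) + G * cy; i01 <- cx + G * cy
  i10 <- (cx + 1L) + G * (cy - 1L); i00 <- cx + G * (cy - 1L)
  cell_diff <- function(M) {
    M[, i11, drop = FALSE] - M[, i01, drop = FALSE] -
      M[, i10, drop = FALSE] + M[, i00, drop = FALSE]
  }
  # damped Newton scoring on the pairwise profile likelihood, vectorized
  # across pairs; dP/drho is a difference of bivariate normal densities
  rho <- stats::cor(x)[pairs]            # Pearson start values
  rho <- pmin(pmax(rho, -0.95), 0.95)
  active <- rep(TRUE, K)
  for (iter in 1:30) {
    rr <- rep(rho[active], times = G * G)
    Pc <- matrix(pbinorm(Abig[active, ], Bbig[active, ], rr),
                 sum(active), G * G)
    Dc <- matrix(.dbinorm(Abig[active, ], Bbig[active, ], rr),
                 sum(active), G * G)
    P <- pmax(cell_diff(Pc), 1e-12)
    dP <- cell_diff(Dc)
    nA <- counts[active, , drop = FALSE]
    score <- rowSums(nA * dP / P)
    info <- N * rowSums(dP^2 / P)
    step <- score / pmax(info, 1e-8)
    step <- pmin(pmax(step, -0.2), 0.2)
    rho[active] <- pmin(pmax(rho[active] + step, -0.9995), 0.9995)
    done <- abs(step) < 1e-7
    active[active] <- !done
    if (!any(active)) break
  }
  # fallback for pairs the scoring iteration left unconverged or on the
  # boundary: golden-section search on the same likelihood
  clamped <- FALSE
  redo <- which(active | abs(rho) >= 0.999)
  for (k in redo) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    tab <- matrix(counts[k, ], C, C)
    opt <- stats::optimize(
      function(r) -.pair_loglik(r, tab, taus[[i]], taus[[j]]),
      interval = c(-0.999, 0.999), tol = 1e-6)
    rho[k] <- opt$minimum
  }
  if (any(abs(rho) > 1 - 1e-6)) {
    rho <- sign(rho) * pmin(abs(rho), 1 - 1e-6)
    clamped <- TRUE
  }
  R <- diag(J)
  R[pairs] <- rho
  R[pairs[, 2:1, drop = FALSE]] <- rho
  if (clamped) warning("polychoric estimate(s) clamped to +/- (1 - 1e-6)")
  sm <- .smooth_psd(R)
  dimnames(sm$R) <- list(colnames(x), colnames(x))
  est <- .correlation_estimate(sm$R, "polychoric", thresholds = taus,
                               smoothed = sm$smoothed)
  est
}

#' Kaiser-Meyer-Olkin index
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum a_ij^2)` over off-diagonal cells,
#' where `a_ij` are the anti-image (negative partial) correlations obtained
#' from the inverse of `R`. A matrix with all-zero off-diagonals (no common
#' variance at all) returns 0 by convention, so `caf()` of such a residual
#' is 1.
#'
#' @param R Correlation matrix (or `correlation_estimate`).
#' @return Scalar in `[0, 1]`.
#' @export
kmo <- function(R) {
  if (inherits(R, "correlation_estimate")) R <- R$matrix
  R <- as.matrix(R)
  off <- upper.tri(R)
  ssr <- sum(R[off]^2)
  if (ssr == 0) return(0)
  Ri <- tryCatch(solve(R), error = function(e) {
    e <- eigen(R, symmetric = TRUE)
    v <- ifelse(e$values > 1e-10, 1 / e$values, 0)
    e$vectors %*% diag(v) %*% t(e$vectors)   # pseudo-inverse fallback
  })
  d <- 1 / sqrt(diag(Ri))
  A <- -Ri * tcrossprod(d)                   # anti-image correlations
  ssa <- sum(A[off]^2)
  ssr / (ssr + ssa)
}

#' Common part accounted for (CAF)
#'
#' `CAF_q = 1 - KMO(residual)` for the residual correlation matrix of a
#' q-factor model; for `q = 0` the residual is the observed correlation
#' matrix itself. Values near 1 mean no substantial common variance is left
#' after extraction.
#'
#' @param R Correlation matrix (used when `residual` is `NULL`, i.e. q = 0).
#' @param residual Residual correlation matrix for a fitted model, or
#'   `NULL`.
#' @return Scalar in `[0, 1]`.
#' @export
caf <- function(R, residual = NULL) {
  1 - kmo(if (is.null(residual)) R else residual)
}
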