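# Maximum-likelihood discrepancy of (Lambda, psi) against correlation R:
#   F = log|Sigma| + tr(Sigma^-1 R) - log|R| - J,  Sigma = Lambda Lambda' + psi
.ml_discrepancy <- function(R, loadings, uniquenesses) {
  J <- nrow(R)
  Sigma <- if (is.null(loadings) || NCOL(loadings) == 0L)
    diag(uniquenesses, J)
  else tcrossprod(as.matrix(loadings)) + diag(uniquenesses, J)
  cS <- chol(Sigma)
  ldS <- 2 * sum(log(diag(cS)))
  ldR <- determinant(R, logarithm = TRUE)$modulus[1]
  ldS + sum(diag(chol2inv(cS) %*% R)) - ldR - J
}

#' Free-parameter count of an orthogonal q-factor model
#'
#' `fp = J q + J - q (q - 1) / 2`: loadings plus uniquenesses minus the
#' rotational indeterminacy of an orthogonal solution.
#'
#' @param J Number of items.
#' @param q Number of factors (>= 0).
#' @return Integer count.
#' @export
efa_free_parameters <- function(J, q) {
  as.integer(J * q + J - q * (q - 1) / 2)
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Fits an orthogonal q-factor model to a correlation matrix by maximum
#' likelihood (profile optimization over uniquenesses with eigen-based
#' loadings, Heywood-guarded, with restarts), returning the unrotated
#' loadings, uniquenesses, ML discrepancy, a log-likelihood on a constant
#' convention shared across q (so BIC differences are valid), the
#' free-parameter count and the residual correlation matrix. `q = 0` is the
#' independence model: the residual equals the input matrix.
#'
#' @param R Correlation matrix or `correlation_estimate`.
#' @param q Number of factors (>= 0, at most the Ledermann bound).
#' @param N Sample size behind `R`.
#' @param nstart Maximum number of starting values tried on non-convergence.
#' @return An object of class `efa_solution` with fields `q`, `loadings`,
#'   `uniquenesses`, `F` (ML discrepancy), `logLik`, `fp`, `converged`,
#'   `heywood`, `residual`, `N`, `method`.
#' @export
fit_efa <- function(R, q, N, nstart = 10L) {
  method <- "unknown"
  if (inherits(R, "correlation_estimate")) {
    method <- R$method
    R <- R$matrix
  }
  R <- as.matrix(R)
  J <- nrow(R)
  q <- as.integer(q)
  ledermann <- floor((2 * J + 1 - sqrt(8 * J + 1)) / 2)
  if (q > ledermann)
    stop("q = ", q, " exceeds the Ledermann bound (", ledermann,
         ") for J = ", J)
  if (N <= J) warning("N <= J: ML fit is ill-conditioned")
  if (q == 0L) {
    Fd <- .ml_discrepancy(R, NULL, rep(1, J))
    sol <- list(q = 0L, loadings = matrix(0, J, 0), uniquenesses = rep(1, J),
                F = Fd, logLik = -(N - 1) / 2 * Fd,
                fp = efa_free_parameters(J, 0L), converged = TRUE,
                heywood = FALSE, residual = R, N = N, method = method)
    return(structure(sol, class = "efa_solution"))
  }
  fa <- NULL
  converged <- FALSE
  for (ns in unique(pmin(c(1L, 5L, nstart), nstart))) {
    fa <- tryCatch(
      stats::factanal(factors = q, covmat = R, n.obs = N, rotation = "none",
                      control = list(nstart = ns, lower = 0.001)),
      error = function(e) NULL)
    if (!is.null(fa)) { converged <- fa$converged; if (converged) break }
  }
  if (is.null(fa)) {
    sol <- list(q = q, loadings = matrix(NA_real_, J, q),
                uniquenesses = rep(NA_real_, J), F = NA_real_,
                logLik = NA_real_, fp = efa_free_parameters(J, q),
                converged = FALSE, heywood = FALSE, residual = NULL,
                N = N, method = method)
    warning("ML EFA did not converge for q = ", q)
    return(structure(sol, class = "efa_solution"))
  }
  L <- matrix(fa$loadings, J, q)
  rownames(L) <- rownames(R)
  psi <- pmax(as.numeric(fa$uniquenesses), 0.001)
  Fd <- .ml_discrepancy(R, L, psi)
  residual <- R - tcrossprod(L)
  sol <- list(q = q, loadings = L, uniquenesses = psi, F = Fd,
              logLik = -(N - 1) / 2 * Fd, fp = efa_free_parameters(J, q),
              converged = converged, heywood = any(psi <= 0.001 + 1e-12),
              residual = residual, N = N, method = method)
  structure(sol, class = "efa_solution")
}

#' @export
print.efa_solution <- function(x, ...) {
  cat(sprintf(
    "efa_solution: q = %d, J = %d, F = %.5f, fp = %d%s%s\n",
    x$q, length(x$uniquenesses), x$F, x$fp,
    if (!x$converged) " [non-converged]" else "",
    if (isTRUE(x$heywood)) " [Heywood-guarded]" else ""))
  invisible(x)
}

#' Residual correlation matrix of an EFA solution
#'
#' `R - Lambda Lambda'`, standardized back to unit diagonal so that KMO/CAF
#' can treat it as a correlation matrix. For `q = 0` this is the observed
#' correlation matrix.
#'
#' @param solution An `efa_solution`.
#' @return Correlation-scale residual matrix.
#' @export
residual_correlation <- function(solution) {
  E <- solution$residual
  if (is.null(E)) stop("no residual available (non-converged solution)")
  d <- diag(E)
  if (any(d <= 0)) d <- pmax(d, 1e-8)
  S <- E / tcrossprod(sqrt(d))
  diag(S) <- 1
  S
}

#' Descending eigenvalues of a correlation matrix
#'
#' @param R Correlation matrix or `correlation_estimate`.
#' @return Numeric vector, descending; sums to `J`.
#' @export
eigenvalues_desc <- function(R) {
  if (inherits(R, "correlation_estimate")) R <- R$matrix
  sort(eigen(as.matrix(R), symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Fit EFA models over a candidate range
#'
#' @param R Correlation matrix or `correlation_estimate`.
#' @param q_max Largest candidate factor count.
#' @param N Sample size.
#' @param q_min Smallest candidate (0 includes the independence model).
#' @return List of `efa_solution` objects indexed `q_min..q_max`.
#' @export
fit_efa_range <- function(R, q_max, N, q_min = 0L) {
  lapply(q_min:q_max, function(q) fit_efa(R, q, N))
}
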