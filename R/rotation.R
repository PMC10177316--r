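# Quartimin criterion and gradient for pattern L (direct oblimin, delta = 0):
#   f = sum_j sum_{k != l} L_jk^2 L_jl^2 / 4
.vgQ_quartimin <- function(L) {
  q <- ncol(L)
  L2 <- L^2
  M <- matrix(1, q, q) - diag(q)
  X <- L2 %*% M
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

.random_oblique_start <- function(q) {
  Tm <- qr.Q(qr(matrix(stats::rnorm(q * q), q, q)))
  Tm %*% diag(1 / sqrt(colSums(Tm^2)), q)
}

# Oblique gradient projection (Jennrich 2002 / Bernaards & Jennrich 2005)
# for the quartimin criterion, from one start.
.gpa_oblq <- function(A, Tmat, maxit = 500L, eps = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- .vgQ_quartimin(L)
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  f <- vg$f
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Tti <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Tti)) {
        Lt <- A %*% t(Tti)
        vgt <- .vgQ_quartimin(Lt)
        if (vgt$f < f - 0.5 * s^2 * al) break
      }
      al <- al / 2
    }
    Tmat <- Tt; Ti <- Tti; L <- Lt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Ti)
  }
  Phi <- t(Tmat) %*% Tmat
  list(loadings = L, Phi = Phi, f = f, converged = converged, iter = iter)
}

.rotated_solution <- function(loadings, Phi, method, criterion = NA_real_,
                              n_starts = NA_integer_) {
  dimnames(Phi) <- NULL
  structure(list(loadings = loadings, Phi = Phi, method = method,
                 criterion = criterion, n_starts = n_starts),
            class = "rotated_solution")
}

#' @export
print.rotated_solution <- function(x, ...) {
  cat(sprintf("rotated_solution: %s, %d x %d pattern, criterion %.6g\n",
              x$method, nrow(x$loadings), ncol(x$loadings), x$criterion))
  invisible(x)
}

#' Oblimin (quartimin) rotation by gradient projection
#'
#' Minimizes the direct oblimin criterion with `delta = 0` (quartimin) over
#' oblique rotations of an unrotated loading matrix, using the gradient
#' projection algorithm from `n_starts` random orthonormal starts; the best
#' criterion value is kept. No Kaiser normalization is applied. With a
#' single factor there is no rotational freedom beyond sign and the input
#' is returned with its sign fixed so the column sums positive.
#'
#' @param loadings `J x q` unrotated loading matrix (or `efa_solution`).
#' @param delta Oblimin delta; only 0 (quartimin) is supported.
#' @param n_starts Number of random starts.
#' @param seed Optional integer seed making the starts reproducible.
#' @return A `rotated_solution` with pattern loadings, factor correlation
#'   matrix `Phi`, criterion value and start count.
#' @export
oblimin_rotate <- function(loadings, delta = 0, n_starts = 10L, seed = NULL) {
  if (inherits(loadings, "efa_solution")) loadings <- loadings$loadings
  A <- as.matrix(loadings)
  if (delta != 0) stop("only delta = 0 (quartimin) is implemented")
  q <- ncol(A)
  if (q < 2L) {
    s <- if (sum(A) < 0) -1 else 1
    return(.rotated_solution(A * s, diag(1), "oblimin", 0, 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_starts)) {
    Tm <- if (i == 1L) diag(q) else .random_oblique_start(q)
    res <- tryCatch(.gpa_oblq(A, Tm), error = function(e) NULL)
    if (is.null(res) || !res$converged) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$f < best$f - 1e-10) best <- res
  }
  if (is.null(best))
    stop("oblimin rotation failed: no gradient-projection start converged")
  .rotated_solution(best$loadings, best$Phi, "oblimin", best$f, n_ok)
}

#' Build a rotation target for a design cell
#'
#' Fully specified targets (FST) put +/-1 at the hypothesized content
#' loadings (signs following the generating pattern), 0 elsewhere on the
#' content columns, and 1 on the ARS column when it is included.
#' Semi-specified targets (SST) specify only the hypothesized *zero* cells
#' of the content columns; all other cells, including the entire ARS
#' column, are unspecified (`NA`).
#'
#' @param design A [scale_design()].
#' @param include_ars Append an ARS column to the target?
#' @param kind `"fst"` or `"sst"`.
#' @return An object of class `target_spec` with `values` (numeric matrix,
#'   `NA` = unspecified), `specified` (logical mask) and `kind`.
#' @export
build_target <- function(design, include_ars = TRUE, kind = c("fst", "sst")) {
  kind <- match.arg(kind)
  if (kind == "sst" && design$Q < 2L)
    stop("semi-specified targets are defined for multidimensional designs only")
  P <- sign(.content_pattern(design$Q, design$J_pf, design$balanced, 1))
  if (kind == "fst") {
    V <- P
    if (include_ars) V <- cbind(V, 1)
  } else {
    V <- ifelse(P == 0, 0, NA_real_)
    if (include_ars) V <- cbind(V, NA_real_)
  }
  dimnames(V) <- list(paste0("X", seq_len(nrow(V))),
                      c(paste0("F", seq_len(design$Q)),
                        if (include_ars) "ARS"))
  target_spec(V, kind = kind)
}

#' Construct a target specification
#'
#' @param values Numeric matrix; `NA` marks unspecified cells.
#' @param kind `"fst"` or `"sst"`.
#' @return A `target_spec`.
#' @export
target_spec <- function(values, kind = c("fst", "sst")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  specified <- !is.na(values)
  if (sum(specified) < ncol(values)^2)
    warning("fewer than q^2 specified target cells; rotation may be ",
            "under-determined")
  structure(list(values = values, specified = specified, kind = kind),
            class = "target_spec")
}

#' Write / read targets as CSV (NA = unspecified)
#' @param target A `target_spec`.
#' @param file File path.
#' @param kind Target kind used when reading.
#' @return `read_target_csv()` returns a `target_spec`.
#' @export
write_target_csv <- function(target, file) {
  utils::write.csv(as.data.frame(target$values), file)
  invisible(target)
}

#' @rdname write_target_csv
#' @export
read_target_csv <- function(file, kind = c("fst", "sst")) {
  target_spec(as.matrix(utils::read.csv(file, row.names = 1)),
              kind = match.arg(kind))
}

# Unit-variance normalization of the transformation: with pattern
# P = Lambda B, rescaling B's columns by D = diag(sqrt(diag((B'B)^-1)))
# makes the implied factor correlation matrix Phi = ((BD)'(BD))^-1 have a
# unit diagonal. Column orthogonality in B is preserved.
.procrustes_A <- function(B) {
  if (rcond(crossprod(B)) < 1e-12)
    stop("target columns are linearly dependent over the loading space; ",
         "the oblique transformation is not identified (e.g. an all-ones ",
         "ARS column on an unbalanced scale)")
  G <- solve(crossprod(B))
  B %*% diag(sqrt(diag(G)), ncol(B))
}

# Masked least-squares solution for one transformation column: rows with
# specified values give an ordinary LS problem; all-zero specified values
# give the homogeneous problem (smallest eigenvector of the specified
# cross-product, unit length); no specified values returns NULL (column
# completed orthogonally afterwards).
.procrustes_column <- function(A0, rows, y) {
  q <- ncol(A0)
  if (!any(rows)) return(NULL)
  X <- A0[rows, , drop = FALSE]
  y <- y[rows]
  if (any(y != 0)) {
    if (qr(X)$rank < q)
      stop("rank-deficient loadings over the specified target cells")
    b <- stats::lm.fit(X, y)$coefficients
  } else {
    e <- eigen(crossprod(X), symmetric = TRUE)
    b <- e$vectors[, q]
  }
  unname(b)
}

#' Oblique Procrustes rotation toward a (partially specified) target
#'
#' Classical no-rescaling target rotation: each transformation column is
#' the least-squares solution over that target column's specified cells
#' (for columns whose specified values are all zero — the content columns
#' of a semi-specified target — the homogeneous solution, i.e. the
#' direction minimizing the specified loadings; for entirely unspecified
#' columns — the ARS column of a semi-specified target — the orthogonal
#' completion of the solved columns, which leaves those factors
#' uncorrelated with the rest). The transformation is then normalized so
#' all rotated factors have unit variance. The factors are *not* rescaled
#' toward the target: a +/-1 target for loadings of magnitude 0.5 yields
#' rotated loadings near 0.5, not near 1.
#'
#' @param loadings `J x q` unrotated loading matrix (or `efa_solution`).
#' @param target A `target_spec` with matching shape.
#' @return A `rotated_solution` with method `"fst"` or `"sst"`; `criterion`
#'   is the sum of squared deviations over specified cells at the solution.
#' @export
procrustes_oblique <- function(loadings, target) {
  if (inherits(loadings, "efa_solution")) loadings <- loadings$loadings
  A0 <- as.matrix(loadings)
  stopifnot(inherits(target, "target_spec"),
            all(dim(target$values) == dim(A0)))
  q <- ncol(A0)
  if (qr(A0)$rank < q) stop("rank-deficient loadings cannot be rotated")
  if (q == 1L) {
    spec <- target$specified
    s <- if (any(spec) && sum(A0[spec] * target$values[spec]) < 0) -1 else 1
    crit <- if (any(spec)) sum((A0[spec] * s - target$values[spec])^2) else 0
    return(.rotated_solution(A0 * s, diag(1), target$kind, crit, 1L))
  }
  B <- matrix(NA_real_, q, q)
  solved <- logical(q)
  for (k in seq_len(q)) {
    b <- .procrustes_column(A0, target$specified[, k], target$values[, k])
    if (!is.null(b)) { B[, k] <- b; solved[k] <- TRUE }
  }
  if (!any(solved)) stop("the target specifies no cells at all")
  if (any(!solved)) {
    # orthogonal completion of unspecified columns
    base <- B[, solved, drop = FALSE]
    qrB <- qr(cbind(base, diag(q)))
    comp <- qr.Q(qrB)[, (sum(solved) + 1L):q, drop = FALSE]
    B[, !solved] <- comp
  }
  # disambiguate the sign of homogeneous / completed columns: largest
  # pattern element positive
  P0 <- A0 %*% B
  for (k in seq_len(q)) {
    if (!solved[k] || all(target$values[target$specified[, k], k] == 0)) {
      if (P0[which.max(abs(P0[, k])), k] < 0) B[, k] <- -B[, k]
    }
  }
  Am <- .procrustes_A(B)
  P <- A0 %*% Am
  Phi <- solve(crossprod(Am))
  Phi <- (Phi + t(Phi)) / 2
  dimnames(P) <- dimnames(target$values)
  crit <- sum((P[target$specified] - target$values[target$specified])^2)
  .rotated_solution(P, Phi, target$kind, crit, 1L)
}

#' Fit invariance check for a rotated solution
#'
#' Maximum absolute element of `P Phi P' - Lambda Lambda'`, which must
#' vanish for any admissible oblique rotation of `Lambda`.
#'
#' @param rotated A `rotated_solution`.
#' @param unrotated The unrotated loading matrix it came from.
#' @return Scalar maximum absolute discrepancy.
#' @export
rotation_fit_error <- function(rotated, unrotated) {
  if (inherits(unrotated, "efa_solution")) unrotated <- unrotated$loadings
  common <- rotated$loadings %*% rotated$Phi %*% t(rotated$loadings)
  max(abs(common - tcrossprod(as.matrix(unrotated))))
}
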