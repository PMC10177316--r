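# All permutations of 1..n (n small: q <= 4 in practice).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Tucker congruence between two loading columns
#'
#' Cosine similarity `sum(x y) / sqrt(sum(x^2) sum(y^2))`.
#'
#' @param x,y Numeric vectors.
#' @return Scalar in `[-1, 1]` (0 when either vector is null).
#' @export
tucker_congruence <- function(x, y) {
  d <- sqrt(sum(x^2) * sum(y^2))
  if (d == 0) return(0)
  sum(x * y) / d
}

#' Align an estimated solution with the generating truth
#'
#' Matches estimated columns to true content columns by maximizing the
#' total absolute Tucker congruence over all assignments (exhaustive search
#' over permutations; the factor counts here never exceed 4). Each matched
#' column is sign-flipped to positive congruence. When an extra ARS column
#' was extracted, informed rotations pin it to the target's ARS position
#' (the last column), whereas for uninformed rotations it is the column
#' left over after content matching.
#'
#' @param est A `rotated_solution` (or plain loading matrix).
#' @param truth A [population_model()] (content columns of its loadings are
#'   the reference).
#' @param ars_extracted Was an extra factor extracted beyond the content
#'   factors?
#' @param informed For informed rotations the ARS column position is fixed
#'   by the target; defaults to `TRUE` for methods `"fst"`/`"sst"`.
#' @return An object of class `aligned_solution`: `loadings` (aligned
#'   pattern, content columns first, ARS last when present), `Phi`
#'   (factor correlations, same ordering), `assignment`, `signs`,
#'   `congruence`, `ars_extracted`.
#' @export
align_solution <- function(est, truth, ars_extracted = FALSE,
                           informed = NULL) {
  P <- if (inherits(est, "rotated_solution")) est$loadings else as.matrix(est)
  Phi <- if (inherits(est, "rotated_solution")) est$Phi else diag(ncol(P))
  method <- if (inherits(est, "rotated_solution")) est$method else "none"
  if (is.null(informed)) informed <- method %in% c("fst", "sst")
  Q <- truth$Q
  Ltrue <- truth$loadings[, seq_len(Q), drop = FALSE]
  k <- ncol(P)
  stopifnot(k == Q + as.integer(ars_extracted))
  cand <- seq_len(k)
  ars_col <- NA_integer_
  if (ars_extracted && informed) {
    ars_col <- k                       # target convention: ARS last
    cand <- seq_len(k - 1L)
  }
  # congruence of every candidate estimated column with every true column
  Cg <- matrix(0, length(cand), Q)
  for (i in seq_along(cand))
    for (q in seq_len(Q))
      Cg[i, q] <- tucker_congruence(P[, cand[i]], Ltrue[, q])
  perms <- .permutations(length(cand))
  best <- NULL; best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    sel <- perms[r, seq_len(Q), drop = TRUE]  # candidate index per true factor
    val <- sum(abs(Cg[cbind(sel, seq_len(Q))]))
    if (val > best_val) { best_val <- val; best <- sel }
  }
  content_cols <- cand[best]
  if (ars_extracted && !informed)
    ars_col <- setdiff(seq_len(k), content_cols)
  ord <- c(content_cols, if (ars_extracted) ars_col)
  signs <- numeric(length(ord))
  for (q in seq_len(Q)) {
    cg <- Cg[best[q], q]
    signs[q] <- if (cg < 0) -1 else 1
  }
  if (ars_extracted) {
    s <- sum(P[, ars_col])
    signs[Q + 1L] <- if (s < 0) -1 else 1
  }
  A <- P[, ord, drop = FALSE] %*% diag(signs, length(ord))
  Phi2 <- diag(signs, length(ord)) %*% Phi[ord, ord, drop = FALSE] %*%
    diag(signs, length(ord))
  colnames(A) <- c(paste0("F", seq_len(Q)), if (ars_extracted) "ARS")
  cong <- vapply(seq_len(Q),
                 function(q) abs(Cg[best[q], q]), numeric(1))
  structure(list(loadings = A, Phi = Phi2, assignment = ord, signs = signs,
                 congruence = cong, ars_extracted = ars_extracted,
                 method = method),
            class = "aligned_solution")
}

#' Loading RMSE against the generating model
#'
#' Root mean squared deviation between aligned estimated loadings and the
#' generating loadings over the `J x Q` content cells (`scope = "content"`)
#' or the `J` ARS cells (`scope = "ars"`).
#'
#' @param aligned An `aligned_solution`.
#' @param truth A [population_model()].
#' @param scope `"content"` or `"ars"`.
#' @return Scalar RMSE (>= 0).
#' @export
rmse_loadings <- function(aligned, truth, scope = c("content", "ars")) {
  scope <- match.arg(scope)
  Q <- truth$Q
  if (scope == "ars") {
    if (!aligned$ars_extracted)
      stop("ARS loading RMSE requires an extracted ARS factor")
    d <- aligned$loadings[, Q + 1L] - truth$loadings[, Q + 1L]
  } else {
    d <- aligned$loadings[, seq_len(Q), drop = FALSE] -
      truth$loadings[, seq_len(Q), drop = FALSE]
  }
  sqrt(mean(d^2))
}

#' Maximum absolute bias over true-zero content loadings
#'
#' The per-replicate ingredient of the mean maximum absolute bias (MMAB):
#' the largest absolute estimated loading over cells that are zero in the
#' generating content columns. Averaging these maxima across replicates
#' gives the MMAB.
#'
#' @param aligned An `aligned_solution`.
#' @param truth A [population_model()] with at least one zero content cell.
#' @return Scalar maximum absolute bias.
#' @export
max_abs_bias_zero <- function(aligned, truth) {
  Q <- truth$Q
  zero <- truth$loadings[, seq_len(Q), drop = FALSE] == 0
  if (!any(zero))
    stop("no zero cells in the generating content loadings")
  max(abs(aligned$loadings[, seq_len(Q), drop = FALSE][zero]))
}

#' Absolute error of the content-factor correlation
#'
#' `|phi_hat_12 - phi_12|` between the two content factors, computed after
#' alignment (so sign reflections cancel). Defined for `Q = 2`.
#'
#' @param aligned An `aligned_solution`.
#' @param truth A [population_model()] with `Q = 2`.
#' @return Scalar absolute deviation.
#' @export
rmse_factor_corr <- function(aligned, truth) {
  if (truth$Q != 2L)
    stop("factor-correlation recovery is defined for Q = 2")
  abs(aligned$Phi[1, 2] - truth$phi[1, 2])
}

#' Retention rate of the target dimensionality
#'
#' Proportion of selection results choosing `q_target` factors. In the ARS
#' scenarios the target is `Q + 1` (the additional ARS factor retained); in
#' the null scenario it is `Q` itself.
#'
#' @param selections List of `selection_result` objects (or integer vector
#'   of selected q).
#' @param q_target Target factor count.
#' @return Proportion in `[0, 1]`.
#' @export
tpr <- function(selections, q_target) {
  sel <- if (is.numeric(selections)) selections
         else vapply(selections, `[[`, integer(1), "selected")
  if (!length(sel)) stop("empty selection list")
  mean(sel == q_target)
}
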