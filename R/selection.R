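.selection_result <- function(criterion, method, selected, scores) {
  structure(list(criterion = criterion, method = method,
                 selected = as.integer(selected), scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %s (%s) selects q = %d\n",
              x$criterion, x$method, x$selected))
  invisible(x)
}

#' BIC of an EFA solution
#'
#' `BIC = -2 logLik + fp log(N)` with the package's log-likelihood
#' convention (constant shared across q, so only BIC differences are
#' meaningful).
#'
#' @param solution An `efa_solution`.
#' @return Scalar BIC value.
#' @export
efa_bic <- function(solution) {
  -2 * solution$logLik + solution$fp * log(solution$N)
}

#' Select the number of factors by BIC
#'
#' Computes `BIC_q` for every converged candidate solution and selects the
#' minimizer; ties are broken toward the smaller q.
#'
#' @param solutions List of `efa_solution` objects (q >= 1 candidates).
#' @return A `selection_result` with per-q BIC scores.
#' @export
select_bic <- function(solutions) {
  solutions <- Filter(function(s) s$q >= 1L, solutions)
  qs <- vapply(solutions, `[[`, integer(1), "q")
  conv <- vapply(solutions, `[[`, logical(1), "converged")
  if (sum(conv) < 1L) stop("no converged candidate solutions for BIC")
  if (any(!conv))
    warning("non-converged solutions excluded from BIC selection: q = ",
            paste(qs[!conv], collapse = ", "))
  bic <- rep(NA_real_, length(qs))
  bic[conv] <- vapply(solutions[conv], efa_bic, numeric(1))
  ord <- order(qs)
  qs <- qs[ord]; bic <- bic[ord]
  sel <- qs[which.min(bic)]            # first minimum = smallest q on ties
  .selection_result("bic", solutions[[1]]$method, sel,
                    stats::setNames(bic, paste0("q", qs)))
}

#' Reduced-correlation (common-factor) eigenvalues
#'
#' Eigenvalues of the correlation matrix with squared multiple correlations
#' (SMC) on the diagonal — the factor-solution spectrum parallel analysis
#' compares when factors rather than components are of interest.
#'
#' @param R Correlation matrix or `correlation_estimate`.
#' @return Descending numeric vector.
#' @export
eigenvalues_reduced <- function(R) {
  if (inherits(R, "correlation_estimate")) R <- R$matrix
  R <- as.matrix(R)
  smc <- tryCatch(1 - 1 / diag(solve(R)),
                  error = function(e) rep(0.5, ncol(R)))
  Rr <- R
  diag(Rr) <- smc
  sort(eigen(Rr, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Parallel analysis on ordinal data
#'
#' Compares the eigenvalues of the observed correlation matrix (Pearson or
#' polychoric) position-wise with a percentile of the eigenvalues of
#' reference datasets of identical size. Reference data are built by
#' independently resampling each item's observed responses with
#' replacement, which preserves the marginal distributions while destroying
#' inter-item structure. Factors are retained while the empirical
#' eigenvalue exceeds its reference cut-off, stopping at the first failure.
#' By default the comparison uses the reduced (common-factor) spectrum of
#' [eigenvalues_reduced()] on both sides; `eigen_type = "full"` switches to
#' principal-component eigenvalues.
#'
#' @param data An `ordinal_dataset` or integer matrix coded `0..C-1`.
#' @param method `"pearson"` or `"polychoric"`.
#' @param n_sets Number of reference datasets.
#' @param percentile Reference percentile (e.g. 95).
#' @param seed Optional integer seed.
#' @param q_max Optional cap on the retained count.
#' @param eigen_type `"reduced"` (factor eigenvalues, default) or `"full"`.
#' @param max_retry Resampling cap for reference sets whose correlation
#'   estimation fails (degenerate polychoric tables).
#' @return A `selection_result`; `scores` holds the empirical eigenvalues
#'   and the reference cut-offs.
#' @export
parallel_analysis <- function(data, method = c("pearson", "polychoric"),
                              n_sets = 20L, percentile = 95, seed = NULL,
                              q_max = NULL,
                              eigen_type = c("reduced", "full"),
                              max_retry = 20L) {
  method <- match.arg(method)
  eigen_type <- match.arg(eigen_type)
  stopifnot(n_sets >= 1L)
  x <- if (inherits(data, "ordinal_dataset")) data$responses else as.matrix(data)
  C <- if (inherits(data, "ordinal_dataset")) data$C else max(x) + 1L
  if (!is.null(seed)) set.seed(seed)
  eigf <- if (eigen_type == "reduced") eigenvalues_reduced
          else eigenvalues_desc
  corr <- function(m) {
    if (method == "pearson") pearson_matrix(m)$matrix
    else polychoric_matrix(m, C = C)$matrix
  }
  emp <- eigf(corr(x))
  N <- nrow(x); J <- ncol(x)
  ref <- matrix(NA_real_, n_sets, J)
  for (s in seq_len(n_sets)) {
    for (tr in seq_len(max_retry)) {
      xr <- apply(x, 2, function(col) col[sample.int(N, N, replace = TRUE)])
      ev <- tryCatch(eigf(corr(xr)), error = function(e) NULL)
      if (!is.null(ev)) { ref[s, ] <- ev; break }
    }
    if (anyNA(ref[s, ]))
      stop("reference correlation estimation failed ", max_retry,
           " times in a row")
  }
  cut <- apply(ref, 2, stats::quantile, probs = percentile / 100,
               names = FALSE, type = 7)
  keep <- emp > cut
  sel <- if (keep[1]) which(c(!keep, TRUE))[1] - 1L else 0L
  if (!is.null(q_max)) sel <- min(sel, as.integer(q_max))
  .selection_result("pa", method, sel,
                    list(eigenvalues = emp, cutoffs = cut))
}

#' Scree ratios on the upper convex hull (CHull)
#'
#' Retains the candidate points on the upper convex hull of fit (CAF)
#' versus complexity (free-parameter count), computes the scree ratio
#' `st_i = [(f_i - f_{i-1}) / (c_i - c_{i-1})] / [(f_{i+1} - f_i) / (c_{i+1} - c_i)]`
#' for the interior hull points, and selects the point with the largest
#' ratio. With fewer than three hull points the procedure degenerates and
#' the point with the largest fit gain per parameter is returned with a
#' warning.
#'
#' @param caf_values Per-candidate CAF values (including q = 0).
#' @param fp_values Per-candidate free-parameter counts.
#' @param q_values Candidate factor counts (default `0:(K-1)`).
#' @return A `selection_result`; `scores` holds the hull membership and the
#'   scree ratios.
#' @export
chull_select <- function(caf_values, fp_values,
                         q_values = seq_along(caf_values) - 1L) {
  stopifnot(length(caf_values) == length(fp_values),
            length(caf_values) == length(q_values))
  if (length(caf_values) < 3L)
    stop("CHull needs at least 3 candidate points (including q = 0)")
  ord <- order(fp_values, q_values)
  f <- caf_values[ord]; c_ <- fp_values[ord]; q <- q_values[ord]
  keep <- !is.na(f)
  f <- f[keep]; c_ <- c_[keep]; q <- q[keep]
  # drop candidates not improving on a simpler model
  mono <- rep(TRUE, length(f))
  best <- -Inf
  for (i in seq_along(f)) {
    if (f[i] <= best) mono[i] <- FALSE else best <- f[i]
  }
  f <- f[mono]; c_ <- c_[mono]; q <- q[mono]
  # upper convex hull by monotone chain
  hull <- seq_along(f)
  repeat {
    if (length(hull) < 3L) break
    dropped <- FALSE
    for (i in 2:(length(hull) - 1L)) {
      i0 <- hull[i - 1L]; i1 <- hull[i]; i2 <- hull[i + 1L]
      s1 <- (f[i1] - f[i0]) / (c_[i1] - c_[i0])
      s2 <- (f[i2] - f[i1]) / (c_[i2] - c_[i1])
      if (s1 <= s2) { hull <- hull[-i]; dropped <- TRUE; break }
    }
    if (!dropped) break
  }
  if (length(hull) < 3L) {
    warning("fewer than 3 hull points: falling back to the largest ",
            "fit gain per free parameter")
    if (length(f) < 2L) {
      sel <- q[1]
      return(.selection_result("chull", NA_character_, sel,
                               list(q = q, hull = hull, st = NA_real_)))
    }
    gain <- diff(f) / diff(c_)
    sel <- q[which.max(gain) + 1L]
    return(.selection_result("chull", NA_character_, sel,
                             list(q = q, hull = hull, st = NA_real_)))
  }
  st <- rep(NA_real_, length(hull))
  for (i in 2:(length(hull) - 1L)) {
    i0 <- hull[i - 1L]; i1 <- hull[i]; i2 <- hull[i + 1L]
    num <- (f[i1] - f[i0]) / (c_[i1] - c_[i0])
    den <- (f[i2] - f[i1]) / (c_[i2] - c_[i1])
    st[i] <- num / den
  }
  sel <- q[hull[which.max(st)]]
  .selection_result("chull", NA_character_, sel,
                    list(q = q[hull], st = st))
}

#' CAF-based CHull selection from EFA solutions
#'
#' Computes `CAF_q = 1 - KMO(residual_q)` for every candidate solution
#' (q = 0 uses the observed correlation matrix) and applies
#' [chull_select()] with the free-parameter count as the complexity axis.
#'
#' @param solutions List of `efa_solution` objects including q = 0.
#' @return A `selection_result`.
#' @export
chull_caf <- function(solutions) {
  qs <- vapply(solutions, `[[`, integer(1), "q")
  conv <- vapply(solutions, `[[`, logical(1), "converged")
  cafs <- rep(NA_real_, length(solutions))
  cafs[conv] <- vapply(solutions[conv],
                       function(s) caf(NULL, residual_correlation(s)),
                       numeric(1))
  fps <- vapply(solutions, `[[`, integer(1), "fp")
  res <- chull_select(cafs, fps, qs)
  res$method <- solutions[[1]]$method
  res$scores$caf <- stats::setNames(cafs, paste0("q", qs))
  res
}

#' Assess dimensionality of an ordinal dataset
#'
#' End-to-end wrapper: estimates the requested correlation matrix, fits ML
#' EFA for `q = 0..q_max`, and applies BIC, parallel analysis and
#' CHull-CAF.
#'
#' @param data An `ordinal_dataset` or integer matrix coded `0..C-1`.
#' @param N Sample size (inferred from the data when `NULL`).
#' @param method `"pearson"` or `"polychoric"`.
#' @param q_max Largest candidate factor count.
#' @param criteria Subset of `c("bic", "pa", "chull")`.
#' @param n_sets,percentile Parallel-analysis settings.
#' @param seed Optional integer seed (used by parallel analysis).
#' @return Named list of `selection_result` objects.
#' @export
assess_dimensionality <- function(data, q_max, N = NULL,
                                  method = c("pearson", "polychoric"),
                                  criteria = c("bic", "pa", "chull"),
                                  n_sets = 20L, percentile = 95,
                                  seed = NULL) {
  method <- match.arg(method)
  criteria <- match.arg(criteria, several.ok = TRUE)
  x <- if (inherits(data, "ordinal_dataset")) data$responses else as.matrix(data)
  if (is.null(N)) N <- nrow(x)
  R <- if (method == "pearson") pearson_matrix(data)
       else polychoric_matrix(data)
  out <- list()
  if (any(c("bic", "chull") %in% criteria)) {
    sols <- fit_efa_range(R, q_max, N)
    if ("bic" %in% criteria) out$bic <- select_bic(sols)
    if ("chull" %in% criteria) out$chull <- chull_caf(sols)
  }
  if ("pa" %in% criteria)
    out$pa <- parallel_analysis(data, method = method, n_sets = n_sets,
                                percentile = percentile, seed = seed,
                                q_max = q_max)
  out
}
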