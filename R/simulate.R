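#' Draw censored-normal ARS factor scores
#'
#' Samples `n` scores from a normal distribution with the configuration's
#' mean and SD and replaces sub-zero draws by exactly 0, producing the mass
#' point at zero that represents respondents without an agreeing tendency.
#'
#' @param n Number of scores.
#' @param config An [ars_config()].
#' @param seed Optional integer seed (local to this draw).
#' @return Nonnegative numeric vector of length `n`.
#' @export
sample_ars_scores <- function(n, config = ars_config(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pmax(stats::rnorm(n, mean = config$mu, sd = config$sigma), 0)
}

#' Draw multivariate-normal content factor scores
#'
#' @param n Number of rows.
#' @param Q Number of content factors.
#' @param phi `Q x Q` covariance matrix (identity by default).
#' @param seed Optional integer seed.
#' @return `n x Q` matrix of scores with zero mean and covariance `phi`.
#' @export
sample_content_scores <- function(n, Q, phi = diag(Q), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- as.matrix(phi)
  stopifnot(nrow(phi) == Q, ncol(phi) == Q)
  ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("phi is not positive semidefinite")
  Z <- matrix(stats::rnorm(n * Q), n, Q)
  if (Q == 1L && phi[1, 1] == 1) return(Z)
  Z %*% chol(phi)
}

# Discretize latent responses through ascending thresholds: x = number of
# thresholds strictly below x*.
.discretize <- function(xstar, tau) {
  J <- ncol(xstar)
  x <- matrix(0L, nrow(xstar), J)
  for (j in seq_len(J))
    x[, j] <- as.integer(rowSums(outer(xstar[, j], tau[j, ], `>`)))
  x
}

#' Generate one ordinal dataset from a population model
#'
#' Draws content factor scores, censored-normal ARS scores and normal
#' residuals, forms latent responses `x* = Lambda eta + eps` and discretizes
#' them through the model thresholds. Datasets in which some item never
#' shows some category are rejected and regenerated from fresh draws, so
#' every accepted dataset exhibits full category coverage.
#'
#' @param model A [population_model()].
#' @param N Sample size.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param max_rejections Cap on full-dataset regenerations before erroring.
#' @return An object of class `ordinal_dataset` with fields `responses`
#'   (`N x J` integer matrix, values `0..C-1`), `C`, `N`, `seed`,
#'   `n_rejections` and `model`.
#' @export
generate_dataset <- function(model, N, seed = NULL, max_rejections = 1000L) {
  stopifnot(inherits(model, "population_model"), N >= 2)
  if (!is.null(seed)) set.seed(seed)
  J <- model$J; Q <- model$Q; C <- model$C
  sd_eps <- sqrt(model$uniquenesses)
  rejections <- 0L
  repeat {
    eta <- sample_content_scores(N, Q, model$phi)
    ars <- sample_ars_scores(N, model$ars)
    scores <- cbind(eta, ars)
    eps <- matrix(stats::rnorm(N * J), N, J) %*% diag(sd_eps, J)
    xstar <- matrix(model$nu, N, J, byrow = TRUE) +
      scores %*% t(model$loadings) + eps
    x <- .discretize(xstar, model$thresholds)
    if (all(apply(x, 2, function(col) length(unique(col))) == C)) break
    rejections <- rejections + 1L
    if (rejections > max_rejections)
      stop("category coverage not achieved after ", max_rejections,
           " regenerations; the design is infeasible at this sample size")
  }
  colnames(x) <- paste0("X", seq_len(J))
  structure(list(responses = x, C = C, N = N, seed = seed,
                 n_rejections = rejections, model = model),
            class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("ordinal_dataset: %d x %d responses in 0..%d (%d regenerations)\n",
              x$N, ncol(x$responses), x$C - 1L, x$n_rejections))
  invisible(x)
}

#' Read / write ordinal response matrices as CSV
#'
#' Plain CSV with a header row of item labels and integer cells. `base`
#' selects the coding dialect: responses are stored as `base .. base+C-1`
#' (internally the package codes categories `0..C-1`).
#'
#' @param data An `ordinal_dataset` or integer matrix.
#' @param file File path.
#' @param base First category code on disk (0 or 1).
#' @param C Number of categories; inferred from the data when `NULL`.
#' @return `read_ordinal_csv()` returns an `ordinal_dataset` (without a
#'   generating model).
#' @export
write_ordinal_csv <- function(data, file, base = 0L) {
  x <- if (inherits(data, "ordinal_dataset")) data$responses else as.matrix(data)
  utils::write.csv(x + base, file, row.names = FALSE)
  invisible(data)
}

#' @rdname write_ordinal_csv
#' @export
read_ordinal_csv <- function(file, base = 0L, C = NULL) {
  x <- as.matrix(utils::read.csv(file))
  storage.mode(x) <- "integer"
  x <- x - as.integer(base)
  if (any(x < 0)) stop("negative category codes after removing base ", base)
  if (is.null(C)) C <- max(x) + 1L
  structure(list(responses = x, C = as.integer(C), N = nrow(x), seed = NULL,
                 n_rejections = NA_integer_, model = NULL),
            class = "ordinal_dataset")
}
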