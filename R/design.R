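#' Scale design for a simulation cell
#'
#' Describes one cell of the factorial design: number of content factors,
#' total scale length, response categories, scale balance, ARS strength and
#' sample size. `J` is the *total* number of items; with two content
#' factors each factor gets `J/2` items (the published 12-item layouts have
#' 6 items per factor). In replication mode every field must come from the
#' design's enumerated levels; with `replication = FALSE` any sane value is
#' accepted (useful for toy examples and oracle tests).
#'
#' @param Q Number of content factors (replication mode: 1 or 2).
#' @param J Total number of items, divisible by `Q` (replication mode: 12
#'   or 24).
#' @param C Number of response categories (replication mode: 3, 5 or 7).
#' @param balanced Logical; `TRUE` for balanced scales (half the items
#'   contra-indicative), `FALSE` for unbalanced (all items indicative).
#' @param ars_strength One of `"none"`, `"small"`, `"medium"`, `"large"`.
#' @param N Sample size (replication mode: 250 or 500).
#' @param replication Logical; enforce the enumerated design levels.
#' @return An object of class `scale_design`.
#' @export
scale_design <- function(Q = 2L, J = 12L, C = 5L, balanced = TRUE,
                         ars_strength = "large", N = 250L,
                         replication = TRUE) {
  Q <- as.integer(Q); J <- as.integer(J); C <- as.integer(C)
  N <- as.integer(N)
  ars_strength <- match.arg(ars_strength, c("none", "small", "medium", "large"))
  stopifnot(is.logical(balanced), length(balanced) == 1L)
  if (J %% Q != 0L)
    stop("total item count J must be divisible by the number of factors Q")
  if (replication) {
    if (!Q %in% c(1L, 2L))
      stop("replication-mode designs have 1 or 2 content factors; got Q = ",
           Q, " (use replication = FALSE for free designs)")
    if (!J %in% c(12L, 24L))
      stop("replication-mode designs have 12 or 24 items in total")
    if (!C %in% c(3L, 5L, 7L))
      stop("replication-mode designs have 3, 5 or 7 categories")
    if (!N %in% c(250L, 500L))
      stop("replication-mode designs have N = 250 or 500")
  } else {
    stopifnot(Q >= 1L, J >= 2L * Q, C >= 2L, N >= 2L)
  }
  structure(
    list(Q = Q, J = J, J_pf = J %/% Q, C = C, balanced = balanced,
         ars_strength = ars_strength, N = N, replication = replication),
    class = "scale_design")
}

#' @export
print.scale_design <- function(x, ...) {
  cat(sprintf(
    "scale_design: Q = %d, J = %d (%d per factor), C = %d, %s, ARS %s, N = %d%s\n",
    x$Q, x$J, x$J_pf, x$C, if (x$balanced) "balanced" else "unbalanced",
    x$ars_strength, x$N, if (x$replication) "" else " [free mode]"))
  invisible(x)
}

#' ARS factor configuration
#'
#' Maps a strength label to the generating ARS loading and fixes the
#' censoring rule for the ARS factor scores. Scores are drawn from a normal
#' distribution with mean `mu` and standard deviation `sigma`, and draws
#' below the censor point 0 are set to exactly 0, so a mass point at zero
#' represents respondents without any agreeing tendency. The default is a
#' censored *standard* normal, whose scores have variance
#' 1/2 - 1/(2*pi) (about 0.34); the realized standardized ARS loadings are
#' therefore attenuated relative to the nominal values by about 0.58.
#' Setting `sigma = 1/sqrt(1/2 - 1/(2*pi))` instead gives censored scores
#' of exactly unit variance (used by the worked example, where the
#' generating loadings are meant to be recovered on their own scale).
#'
#' @param strength One of `"none"`, `"small"`, `"medium"`, `"large"`, or a
#'   numeric loading in `[0, 1)`.
#' @param mu,sigma Mean and SD of the pre-censoring normal.
#' @return An object of class `ars_config` with fields `strength`,
#'   `loading`, `censor`, `mu`, `sigma`.
#' @export
ars_config <- function(strength = "large", mu = 0, sigma = 1) {
  if (is.numeric(strength)) {
    loading <- strength
    strength <- "custom"
  } else {
    strength <- match.arg(strength, c("none", "small", "medium", "large"))
    loading <- c(none = 0, small = 0.218, medium = 0.343, large = 0.506)[[strength]]
  }
  stopifnot(loading >= 0, loading < 1, sigma > 0)
  structure(list(strength = strength, loading = loading, censor = 0,
                 mu = mu, sigma = sigma),
            class = "ars_config")
}

#' @export
print.ars_config <- function(x, ...) {
  cat(sprintf(
    "ars_config: strength %s (loading %.3f), N(%.2f, %.3f^2) censored below 0\n",
    x$strength, x$loading, x$mu, x$sigma))
  invisible(x)
}

# Base threshold row (easiest item, ascending) on the latent-response SD
# scale: C-1 cut points equally spaced in [-1, 1], lowered by 1. Remaining
# items are shifted upward on a 2-SD difficulty grid, so across the scale
# the thresholds span [-2, 2] for every C and the boundary categories keep
# probabilities of at least Phi(-2), which keeps the category-coverage
# rejection rule a rare event at the study's sample sizes.
.threshold_base <- function(C) {
  if (C == 2L) return(-1)
  seq(-1, 1, length.out = C - 1L) - 1
}

#' Threshold grid across items
#'
#' Builds a J x (C-1) matrix of strictly ascending latent-response
#' thresholds. Row 1 holds the base set for the easiest item; row `j` adds a
#' difficulty shift of `2 * (j - 1) / (J - 1)` SD so the first thresholds of
#' the easiest and the hardest item differ by exactly 2 SD.
#'
#' @param J Number of items (>= 2).
#' @param C Number of response categories (>= 2).
#' @return Numeric matrix `J x (C-1)`, rows strictly ascending.
#' @export
build_thresholds <- function(J, C) {
  J <- as.integer(J); C <- as.integer(C)
  stopifnot(J >= 2L, C >= 2L)
  base <- .threshold_base(C)
  shift <- 2 * (seq_len(J) - 1) / (J - 1)
  tau <- outer(shift, base, `+`)
  dimnames(tau) <- list(paste0("X", seq_len(J)),
                        paste0("tau", seq_len(C - 1L)))
  tau
}

# Signed content-loading pattern for one cell. Items are assigned to factors
# cyclically (item j -> factor ((j-1) mod Q) + 1). Balanced scales follow the
# canonical 12-item sign layout, recycled for longer scales: one factor gets
# the second half of its items contra-indicative; two factors alternate the
# sign within each factor.
.content_pattern <- function(Q, J_pf, balanced, value = 0.506) {
  J <- Q * J_pf
  L <- matrix(0, J, Q)
  for (j in seq_len(J)) {
    q <- ((j - 1L) %% Q) + 1L
    k <- ((j - 1L) %/% Q) + 1L            # position of item j within factor q
    sgn <- 1
    if (balanced) {
      if (Q == 1L) {
        # block pattern: items 7..12 of each 12-item stretch are negative
        sgn <- if (((k - 1L) %% 12L) < 6L) 1 else -1
      } else {
        sgn <- if (k %% 2L == 1L) 1 else -1
      }
    }
    L[j, q] <- sgn * value
  }
  L
}

#' Generating loading pattern for a design cell
#'
#' Constructs the population loading matrix (content columns plus a final
#' ARS column) for a design cell. In replication mode every nonzero content
#' loading has magnitude 0.506 and the ARS column is constant at the
#' configured ARS loading.
#'
#' @param design A [scale_design()].
#' @param ars An [ars_config()]; defaults to the design's `ars_strength`.
#' @param value Magnitude of the content loadings.
#' @return Numeric matrix `J x (Q + 1)` with column names
#'   `F1..FQ, ARS` and row names `X1..XJ`.
#' @export
build_loading_pattern <- function(design, ars = ars_config(design$ars_strength),
                                  value = 0.506) {
  stopifnot(inherits(design, "scale_design"), inherits(ars, "ars_config"))
  L <- .content_pattern(design$Q, design$J_pf, design$balanced, value)
  L <- cbind(L, ars$loading)
  dimnames(L) <- list(paste0("X", seq_len(nrow(L))),
                      c(paste0("F", seq_len(design$Q)), "ARS"))
  L
}

#' Population model (data-generating truth)
#'
#' Bundles loadings, thresholds, uniquenesses and the content-factor
#' covariance into the generating model. Uniquenesses default to
#' `1 - rowSums(loadings^2)`, the standardized categorical-CFA
#' parameterization in which every latent item response has unit variance
#' (the ARS scores are generated with unit variance, see [ars_config()]).
#'
#' @param loadings `J x (Q + 1)` matrix, last column the ARS loadings.
#' @param thresholds `J x (C - 1)` matrix, rows strictly ascending.
#' @param phi Content-factor covariance (`Q x Q`, unit diagonal); identity
#'   by default.
#' @param uniquenesses Optional `J`-vector; computed from the loadings when
#'   missing.
#' @param ars An [ars_config()] describing the ARS score distribution.
#' @return An object of class `population_model`.
#' @export
population_model <- function(loadings, thresholds, phi = NULL,
                             uniquenesses = NULL, ars = ars_config("none")) {
  loadings <- as.matrix(loadings)
  thresholds <- as.matrix(thresholds)
  J <- nrow(loadings)
  Q <- ncol(loadings) - 1L
  stopifnot(J == nrow(thresholds), Q >= 1L)
  if (is.null(phi)) phi <- diag(Q)
  phi <- as.matrix(phi)
  if (is.null(uniquenesses)) uniquenesses <- 1 - rowSums(loadings^2)
  if (any(uniquenesses < 0))
    stop("communalities exceed 1: uniquenesses must be nonnegative")
  if (any(diff(t(thresholds)) <= 0) && ncol(thresholds) > 1L)
    stop("threshold rows must be strictly ascending")
  if (!isTRUE(all.equal(phi, t(phi))) || any(diag(phi) != 1) ||
      any(eigen(phi, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("phi must be symmetric positive definite with unit diagonal")
  structure(
    list(loadings = loadings, thresholds = thresholds, phi = phi,
         uniquenesses = uniquenesses, nu = rep(0, J), ars = ars,
         J = J, Q = Q, C = ncol(thresholds) + 1L),
    class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "population_model: %d items, %d content factor(s) + ARS (loading %.3f), C = %d\n",
    x$J, x$Q, x$ars$loading, x$C))
  invisible(x)
}

#' Population model for a design cell
#'
#' Convenience constructor combining [build_loading_pattern()] and
#' [build_thresholds()] for a design cell.
#'
#' @inheritParams build_loading_pattern
#' @return A [population_model()].
#' @export
build_population_model <- function(design,
                                   ars = ars_config(design$ars_strength)) {
  population_model(
    loadings = build_loading_pattern(design, ars),
    thresholds = build_thresholds(design$J, design$C),
    ars = ars)
}

#' Worked-example population model
#'
#' The 12-item, two-content-factor illustration: content loadings of
#' magnitude 0.506 in the alternating balanced pattern, an ARS loading of
#' 0.295 on every item, uncorrelated factors, and the 5-category threshold
#' grid. Unlike the simulation cells, the illustration scales the censored
#' ARS distribution to unit variance so that a large-sample analysis
#' recovers the generating +/-0.506 / 0.295 values directly.
#'
#' @return A [population_model()].
#' @export
build_worked_example <- function() {
  L <- .content_pattern(2L, 6L, balanced = TRUE)
  ars <- ars_config(0.295, sigma = 1 / sqrt(0.5 - 1 / (2 * pi)))
  L <- cbind(L, ars$loading)
  dimnames(L) <- list(paste0("X", 1:12), c("F1", "F2", "ARS"))
  population_model(L, build_thresholds(12L, 5L), ars = ars)
}

#' Write / read population-model matrices as CSV
#'
#' Serializes the loadings and thresholds of a population model to two CSV
#' files with `X1..XJ` item labels, and reads them back.
#'
#' @param model A [population_model()].
#' @param loadings_file,thresholds_file File paths.
#' @return `write_population_model()` returns the model invisibly;
#'   `read_population_model()` returns a [population_model()] (the ARS
#'   loading is recovered from the last loading column).
#' @export
write_population_model <- function(model, loadings_file, thresholds_file) {
  stopifnot(inherits(model, "population_model"))
  utils::write.csv(as.data.frame(model$loadings), loadings_file)
  utils::write.csv(as.data.frame(model$thresholds), thresholds_file)
  invisible(model)
}

#' @rdname write_population_model
#' @export
read_population_model <- function(loadings_file, thresholds_file) {
  L <- as.matrix(utils::read.csv(loadings_file, row.names = 1))
  tau <- as.matrix(utils::read.csv(thresholds_file, row.names = 1))
  population_model(L, tau, ars = ars_config(unname(L[1, ncol(L)])))
}
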