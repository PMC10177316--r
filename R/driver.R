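#' Deterministic sub-seed for a simulation component
#'
#' Hashes a master seed together with arbitrary string/numeric tags
#' (design-cell id, replicate id, purpose) into an integer below 2^31, so
#' every stochastic component of a study is independently reproducible.
#'
#' @param master Integer master seed.
#' @param ... Tags (coerced to character).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "|")
  h <- 0
  m <- 2147483647                       # 2^31 - 1 (prime)
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Identifier string for a design cell
#'
#' @param design A [scale_design()].
#' @return Character id such as `"Q2_J12_C5_bal_large_N250"`.
#' @export
cell_id <- function(design) {
  sprintf("Q%d_J%d_C%d_%s_%s_N%d", design$Q, design$J, design$C,
          if (design$balanced) "bal" else "unbal", design$ars_strength,
          design$N)
}

# Rotation methods applicable to one analysis variant.
.applicable_rotations <- function(Q, ars_extracted) {
  if (Q == 1L) {
    if (ars_extracted) c("oblimin", "fst") else "none"
  } else {
    c("oblimin", "fst", "sst")
  }
}

# Rotate one EFA solution with one method and score it against the truth.
.rotate_and_score <- function(sol, rotation, design, model, ars_extracted,
                              seed) {
  q <- sol$q
  rot <- switch(rotation,
    none = {
      L <- sol$loadings
      s <- if (tucker_congruence(L[, 1], model$loadings[, 1]) < 0) -1 else 1
      .rotated_solution(L * s, diag(1), "none", 0, 0L)
    },
    oblimin = oblimin_rotate(sol, n_starts = 10L, seed = seed),
    fst = procrustes_oblique(sol, build_target(design, ars_extracted, "fst")),
    sst = procrustes_oblique(sol, build_target(design, ars_extracted, "sst")))
  aligned <- align_solution(rot, model, ars_extracted = ars_extracted)
  out <- data.frame(
    rotation = rotation,
    ars_extracted = ars_extracted,
    rmse_content = rmse_loadings(aligned, model, "content"),
    rmse_ars = if (ars_extracted) rmse_loadings(aligned, model, "ars")
               else NA_real_,
    mmab_zero = if (design$Q >= 2L) max_abs_bias_zero(aligned, model)
                else NA_real_,
    rmse_factor_corr = if (design$Q == 2L) rmse_factor_corr(aligned, model)
                       else NA_real_,
    stringsAsFactors = FALSE)
  out
}

#' Run every analysis variant on the replicates of one design cell
#'
#' Per replicate: generate a dataset, estimate Pearson and polychoric
#' correlation matrices, fit ML EFA for all candidate factor counts, apply
#' BIC, parallel analysis and CHull-CAF under both correlation types, then
#' — irrespective of the selection outcomes — rotate the `Q`-factor
#' (ARS ignored) and `(Q+1)`-factor (ARS extracted) solutions with every
#' applicable rotation and score recovery against the generating model.
#' Everything is reproducible from `(master_seed, cell id, replicate id)`.
#'
#' @param design A [scale_design()].
#' @param reps Number of replicates.
#' @param master_seed Integer master seed.
#' @param correlations Correlation types to analyze.
#' @param criteria Model-selection criteria to run (empty vector to skip).
#' @param rotate Run the rotation/recovery stage?
#' @param pa_sets,pa_percentile Parallel-analysis settings.
#' @param q_max Candidate cap; default 3 for unidimensional designs and 4
#'   for multidimensional ones.
#' @return List with data.frames `selection` (one row per replicate x
#'   correlation x criterion) and `recovery` (one row per replicate x
#'   correlation x rotation x ARS-extraction), plus `n_failed`.
#' @export
run_cell <- function(design, reps = 100L, master_seed = 1L,
                     correlations = c("pearson", "polychoric"),
                     criteria = c("bic", "pa", "chull"),
                     rotate = TRUE, pa_sets = 20L, pa_percentile = 95,
                     q_max = NULL) {
  stopifnot(inherits(design, "scale_design"), reps >= 1L)
  correlations <- match.arg(correlations, several.ok = TRUE)
  if (length(criteria))
    criteria <- match.arg(criteria, c("bic", "pa", "chull"),
                          several.ok = TRUE)
  if (is.null(q_max)) q_max <- if (design$Q == 1L) 3L else 4L
  id <- cell_id(design)
  model <- build_population_model(design)
  sel_rows <- list(); rec_rows <- list()
  n_failed <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      .run_replicate(design, model, id, r, master_seed, correlations,
                     criteria, rotate, pa_sets, pa_percentile, q_max),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      warning("replicate ", r, " of cell ", id, " failed: ",
              conditionMessage(res))
      next
    }
    sel_rows[[length(sel_rows) + 1L]] <- res$selection
    rec_rows[[length(rec_rows) + 1L]] <- res$recovery
  }
  if (n_failed > reps / 2)
    stop("more than half of the replicates failed in cell ", id)
  list(selection = do.call(rbind, sel_rows),
       recovery = do.call(rbind, rec_rows),
       n_failed = n_failed, cell = id, design = design)
}

.run_replicate <- function(design, model, id, r, master_seed, correlations,
                           criteria, rotate, pa_sets, pa_percentile, q_max) {
  dat <- generate_dataset(model, design$N,
                          seed = derive_seed(master_seed, id, r, "data"))
  base <- data.frame(cell = id, N = design$N, C = design$C, Q = design$Q,
                     J = design$J, balanced = design$balanced,
                     ars = design$ars_strength, replicate = r,
                     stringsAsFactors = FALSE)
  sel <- list(); rec <- list()
  for (m in correlations) {
    R <- if (m == "pearson") pearson_matrix(dat) else polychoric_matrix(dat)
    sols <- NULL
    if (any(c("bic", "chull") %in% criteria) || rotate)
      sols <- fit_efa_range(R, q_max, design$N)
    if ("bic" %in% criteria) {
      s <- select_bic(sols)
      sel[[length(sel) + 1L]] <- cbind(base, correlation = m,
                                       criterion = "bic",
                                       selected = s$selected)
    }
    if ("chull" %in% criteria) {
      s <- chull_caf(sols)
      sel[[length(sel) + 1L]] <- cbind(base, correlation = m,
                                       criterion = "chull",
                                       selected = s$selected)
    }
    if ("pa" %in% criteria) {
      s <- parallel_analysis(dat, method = m, n_sets = pa_sets,
                             percentile = pa_percentile,
                             seed = derive_seed(master_seed, id, r, "pa", m),
                             q_max = q_max)
      sel[[length(sel) + 1L]] <- cbind(base, correlation = m,
                                       criterion = "pa",
                                       selected = s$selected)
    }
    if (rotate) {
      for (extracted in c(FALSE, TRUE)) {
        q <- design$Q + as.integer(extracted)
        sol <- sols[[q + 1L]]          # sols indexed from q = 0
        if (!isTRUE(sol$converged)) next
        for (rot in .applicable_rotations(design$Q, extracted)) {
          # informed rotation toward an all-ones ARS column is not
          # identified on unbalanced scales; skip unobtainable variants
          sc <- tryCatch(
            .rotate_and_score(
              sol, rot, design, model, extracted,
              seed = derive_seed(master_seed, id, r, "rot", m, rot,
                                 extracted)),
            error = function(e) NULL)
          if (!is.null(sc))
            rec[[length(rec) + 1L]] <- cbind(base, correlation = m, sc)
        }
      }
    }
  }
  list(selection = if (length(sel)) do.call(rbind, sel) else NULL,
       recovery = if (length(rec)) do.call(rbind, rec) else NULL)
}

#' Run several design cells
#'
#' @param designs List of [scale_design()] objects.
#' @param ... Passed to [run_cell()].
#' @return List with row-bound `selection` and `recovery` data.frames.
#' @export
run_cells <- function(designs, ...) {
  out <- lapply(designs, run_cell, ...)
  list(selection = do.call(rbind, lapply(out, `[[`, "selection")),
       recovery = do.call(rbind, lapply(out, `[[`, "recovery")),
       n_failed = sum(vapply(out, `[[`, integer(1), "n_failed")))
}

#' Retention-rate summary of selection records
#'
#' Computes, per group, the proportion of replicates selecting the target
#' dimensionality: `Q + 1` when `sense = "additional"` (the extra ARS
#' factor retained), `Q` when `sense = "correct"` (null-scenario reading).
#'
#' @param selection Selection data.frame from [run_cell()].
#' @param by Grouping columns.
#' @param sense `"additional"` or `"correct"`.
#' @return Data.frame with one `tpr` row per group.
#' @export
summarize_tpr <- function(selection,
                          by = c("correlation", "criterion"),
                          sense = c("additional", "correct")) {
  sense <- match.arg(sense)
  target <- selection$Q + if (sense == "additional") 1L else 0L
  hit <- as.integer(selection$selected == target)
  agg <- stats::aggregate(hit, by = selection[by], FUN = mean)
  names(agg)[ncol(agg)] <- "tpr"
  agg
}

#' Main-effect summary of recovery metrics
#'
#' Averages a recovery metric within each level of one design factor
#' (margin), crossed with correlation type and rotation — the layout of the
#' study's main-effect tables.
#'
#' @param recovery Recovery data.frame from [run_cell()].
#' @param metric Metric column name.
#' @param margin Design-factor column (`"N"`, `"C"`, `"J"`, ...).
#' @param by Additional grouping columns.
#' @return Data.frame of margin means.
#' @export
summarize_metric <- function(recovery, metric = "rmse_content",
                             margin = "N",
                             by = c("correlation", "rotation",
                                    "ars_extracted")) {
  stopifnot(metric %in% names(recovery))
  agg <- stats::aggregate(recovery[[metric]],
                          by = recovery[c(margin, by)], FUN = mean,
                          na.rm = TRUE)
  names(agg)[ncol(agg)] <- metric
  agg
}

#' Worked example: one large-sample dataset, every rotation
#'
#' Generates a single large dataset from the worked-example population
#' model (12 items, two content factors with +/-0.506 loadings, ARS
#' loading 0.295, 5 response categories), fits a 3-factor ML EFA on the
#' requested correlation type, and rotates it by oblimin, fully specified
#' targets holding the generating values and the 0/1 structure, and the
#' semi-specified target.
#'
#' @param seed Integer seed.
#' @param n Sample size.
#' @param method Correlation type.
#' @return List of class `worked_example`: `model`, the four
#'   `rotated_solution`s (`oblimin`, `fst_original`, `fst`, `sst`) and the
#'   EFA solution.
#' @export
worked_example <- function(seed = 1L, n = 10000L,
                           method = c("polychoric", "pearson")) {
  method <- match.arg(method)
  model <- build_worked_example()
  dat <- generate_dataset(model, n, seed = derive_seed(seed, "worked", "data"))
  R <- if (method == "pearson") pearson_matrix(dat) else polychoric_matrix(dat)
  sol <- fit_efa(R, 3L, n)
  design <- scale_design(Q = 2L, J = 12L, C = 5L, balanced = TRUE,
                         ars_strength = "none", N = 250L,
                         replication = FALSE)
  orig <- target_spec(model$loadings, kind = "fst")
  out <- list(
    model = model,
    efa = sol,
    oblimin = oblimin_rotate(sol, seed = derive_seed(seed, "worked", "obl")),
    fst_original = procrustes_oblique(sol, orig),
    fst = procrustes_oblique(sol, build_target(design, TRUE, "fst")),
    sst = procrustes_oblique(sol, build_target(design, TRUE, "sst")))
  class(out) <- "worked_example"
  out
}

#' @export
print.worked_example <- function(x, digits = 3, ...) {
  blocks <- c("oblimin", "fst_original", "fst", "sst")
  labels <- c("Oblimin", "Target (original values)", "Target (0/1)",
              "Semi-specified target")
  for (i in seq_along(blocks)) {
    cat("==", labels[i], "==\nPattern loadings:\n")
    print(round(x[[blocks[i]]]$loadings, digits))
    cat("Factor correlations:\n")
    print(round(x[[blocks[i]]]$Phi, digits))
    cat("\n")
  }
  invisible(x)
}
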