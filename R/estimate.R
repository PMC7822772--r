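#' Default SD offset grid
#'
#' Uniform sweep of the generative model at 0.5-SD steps over ±2 SD: 9
#' offsets per tissue (81 combinations for two tissues).
#'
#' @param step grid step in SD units (default 0.5).
#' @param limit sweep limit (default 2).
#' @return numeric offset vector.
#' @export
offset_grid <- function(step = 0.5, limit = 2) {
  seq(-limit, limit, by = step)
}

# sample the task posterior at offset s, fit the requested meta-model and
# return the FEM material (NULL if no stable fit is possible)
candidate_material <- function(gp, task_id, grid, s, family, nu = 0.49) {
  curve <- sample_offset(gp, task_id, grid, s)
  fit <- fit_metamodel(curve, meta_fit_config(family))
  if (is.null(fit$params) || !fit$stability$stable) return(NULL)
  mat <- material_from_meta(fit$family, fit$params, nu = nu)
  mat$fit <- fit
  mat
}

#' Single-tissue parameter recovery on a phantom
#'
#' The inverse pipeline: sample candidate energy curves from the task's
#' GP posterior at each SD offset, fit each to a (neo-Hookean by default)
#' meta-model, deform the phantom to equilibrium with the candidate
#' material, and score the deformed state against the reference state by
#' surface-node RMSE. An optional refinement pass re-evaluates at half
#' the offset step around the incumbent best.
#'
#' @param gp a `trained_gp`.
#' @param task_id GP task to sample (1..12).
#' @param mesh a phantom [tet_mesh()].
#' @param reference_state the reference `sim_state` (converged).
#' @param offsets SD offsets in `[-2, 2]` (default 9 at step 0.5).
#' @param family meta-model family for the candidates (default `"NH"`).
#' @param refine run one half-step refinement pass (default `TRUE`).
#' @param cfg [solver_config()] for the equilibrium solves.
#' @param total_force compression load magnitude (N).
#' @param n_query points of the sampling grid over the task's stretch
#'   range.
#' @return a `recovery_result`: data.frame `rows` (offset, mu, rmse_mm,
#'   converged), `best_row` index, and the evaluation node subset.
#' @export
single_tissue_recovery <- function(gp, task_id, mesh, reference_state,
                                   offsets = offset_grid(), family = "NH",
                                   refine = TRUE, cfg = recovery_solver_config(),
                                   total_force = 10, n_query = 80L) {
  stopifnot(all(offsets >= -2 - 1e-9), all(offsets <= 2 + 1e-9))
  if (!isTRUE(attr(reference_state, "converged")))
    warning("reference state is not flagged as converged")
  grid <- query_grid(gp, task_id, n_query)
  eval_nodes <- surface_nodes(mesh, free_only = TRUE)
  f <- apply_compression_load(mesh, total_force)
  ref_pos <- node_positions(mesh, reference_state)
  # every candidate relaxes from the reference (observed) state: all
  # candidates share one deterministic protocol, the self-recovery
  # candidate is an exact fixed point, and solves converge quickly
  init <- sim_state(mesh, u = reference_state$u)
  eval_one <- function(s) {
    mat <- candidate_material(gp, task_id, grid, s, family)
    if (is.null(mat)) return(NULL)
    st <- simulate_to_equilibrium(mesh, mat, f, cfg, mode = "quasistatic",
                                  state = init)
    data.frame(offset = s, mu = mat$mu, rmse_mm = rmse_nodes(
      node_positions(mesh, st), ref_pos, eval_nodes),
      converged = isTRUE(attr(st, "converged")))
  }
  rows <- do.call(rbind, lapply(sort(offsets), eval_one))
  if (is.null(rows)) stop("no offset produced a stable meta-model fit")
  if (refine && nrow(rows) > 1) {
    step <- min(diff(sort(unique(rows$offset)))) / 2
    s_best <- rows$offset[which.min(rows$rmse_mm)]
    for (s in c(s_best - step, s_best + step)) {
      if (s < -2 || s > 2 || any(abs(rows$offset - s) < 1e-9)) next
      r <- eval_one(s)
      if (!is.null(r)) rows <- rbind(rows, r)
    }
  }
  rows <- rows[order(rows$offset), ]
  rownames(rows) <- NULL
  best <- best_converged_row(rows)
  structure(list(rows = rows, best_row = best, eval_nodes = eval_nodes,
                 reference = "phantom reference state", kind = "single"),
            class = "recovery_result")
}

query_grid <- function(gp, task_id, n_query) {
  xs <- gp$x[gp$t == task_id]
  if (!length(xs)) xs <- gp$x
  seq(min(xs), max(xs), length.out = n_query)
}

best_converged_row <- function(rows) {
  ok <- which(rows$converged)
  if (!length(ok)) ok <- seq_len(nrow(rows))
  ok[which.min(rows$rmse_mm[ok])]
}

#' Two-tissue parameter recovery on a phantom
#'
#' Exhaustive grid over (grey offset, white offset): 9 x 9 = 81
#' equilibrium solves at the default offsets, plus an optional half-step
#' refinement around the best cell. The RMSE surface over the grid is the
#' object in which the grey/white covariance valley appears.
#'
#' @inheritParams single_tissue_recovery
#' @param task_gm,task_wm GP tasks for grey and white matter.
#' @return a `recovery_result` with rows (offset_gm, offset_wm, mu_gm,
#'   mu_wm, rmse_mm, converged).
#' @export
multi_tissue_recovery <- function(gp, task_gm, task_wm, mesh, reference_state,
                                  offsets = offset_grid(), refine = TRUE,
                                  family = "NH", cfg = recovery_solver_config(),
                                  total_force = 10, n_query = 80L) {
  stopifnot(all(c("grey", "white") %in% mesh$tissue))
  grid_gm <- query_grid(gp, task_gm, n_query)
  grid_wm <- query_grid(gp, task_wm, n_query)
  eval_nodes <- surface_nodes(mesh, free_only = TRUE)
  f <- apply_compression_load(mesh, total_force)
  ref_pos <- node_positions(mesh, reference_state)
  offsets <- sort(offsets)
  # meta-model fits are per-offset, reusable across the grid
  mats_gm <- lapply(offsets, function(s)
    candidate_material(gp, task_gm, grid_gm, s, family))
  mats_wm <- lapply(offsets, function(s)
    candidate_material(gp, task_wm, grid_wm, s, family))
  names(mats_gm) <- names(mats_wm) <- sprintf("%.6g", offsets)
  # every cell relaxes from the reference state (see single_tissue_recovery)
  init <- sim_state(mesh, u = reference_state$u)
  eval_cell <- function(s_gm, s_wm, m_gm = NULL, m_wm = NULL) {
    if (is.null(m_gm)) m_gm <- candidate_material(gp, task_gm, grid_gm, s_gm, family)
    if (is.null(m_wm)) m_wm <- candidate_material(gp, task_wm, grid_wm, s_wm, family)
    if (is.null(m_gm) || is.null(m_wm)) return(NULL)
    st <- simulate_to_equilibrium(mesh, list(grey = m_gm, white = m_wm), f,
                                  cfg, mode = "quasistatic", state = init)
    data.frame(offset_gm = s_gm, offset_wm = s_wm, mu_gm = m_gm$mu,
               mu_wm = m_wm$mu,
               rmse_mm = rmse_nodes(node_positions(mesh, st), ref_pos,
                                    eval_nodes),
               converged = isTRUE(attr(st, "converged")))
  }
  rows <- list(); k <- 0L
  for (i in seq_along(offsets)) for (j in seq_along(offsets)) {
    r <- eval_cell(offsets[i], offsets[j], mats_gm[[i]], mats_wm[[j]])
    if (!is.null(r)) { k <- k + 1L; rows[[k]] <- r }
  }
  if (!k) stop("no offset pair produced stable meta-model fits")
  rows <- do.call(rbind, rows)
  if (refine) {
    step <- min(diff(offsets)) / 2
    b <- rows[which.min(rows$rmse_mm), ]
    for (ds in c(-step, 0, step)) for (dw in c(-step, 0, step)) {
      s_gm <- b$offset_gm + ds; s_wm <- b$offset_wm + dw
      if (ds == 0 && dw == 0) next
      if (abs(s_gm) > 2 || abs(s_wm) > 2) next
      if (any(abs(rows$offset_gm - s_gm) < 1e-9 &
                abs(rows$offset_wm - s_wm) < 1e-9)) next
      r <- eval_cell(s_gm, s_wm)
      if (!is.null(r)) rows <- rbind(rows, r)
    }
  }
  rownames(rows) <- NULL
  structure(list(rows = rows, best_row = best_converged_row(rows),
                 eval_nodes = eval_nodes,
                 reference = "two-tissue phantom reference state",
                 kind = "multi", offsets = offsets),
            class = "recovery_result")
}

#' @exportS3Method base::print
print.recovery_result <- function(x, ...) {
  b <- x$rows[x$best_row, ]
  cat(sprintf("recovery (%s tissue): %d candidates, best RMSE %.4f mm\n",
              x$kind, nrow(x$rows), b$rmse_mm))
  print(b, row.names = FALSE)
  invisible(x)
}

#' Minimum RMSE of a recovery result
#' @param result a `recovery_result`.
#' @return best (converged) RMSE in mm.
#' @export
best_rmse <- function(result) result$rows$rmse_mm[result$best_row]

#' Export a recovery result as CSV
#'
#' One row per candidate with a unique `best` flag; re-export is
#' idempotent.
#'
#' @param result a `recovery_result`.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
report_table <- function(result, path = NULL) {
  df <- result$rows
  df$best <- seq_len(nrow(df)) == result$best_row
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Extract the RMSE surface of a two-tissue recovery
#'
#' @param result a multi-tissue `recovery_result`.
#' @param base_only keep only the uniform base grid (drop refinement
#'   cells).
#' @return data.frame (offset_gm, offset_wm, rmse_mm).
#' @export
rmse_surface <- function(result, base_only = TRUE) {
  stopifnot(result$kind == "multi")
  df <- result$rows[, c("offset_gm", "offset_wm", "rmse_mm")]
  if (base_only) {
    keep <- df$offset_gm %in% result$offsets & df$offset_wm %in% result$offsets
    df <- df[keep, ]
  }
  df
}
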