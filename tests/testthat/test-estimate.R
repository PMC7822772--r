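# Recovery unit tests run on a coarse phantom with a gentle load so every
# equilibrium solve stays in the smooth-deformation regime and finishes
# quickly; the study-scale experiment lives in the acceptance suite.

recovery_fixture <- function() {
  fixture("recovery_fixture", function() {
    mesh <- generate_phantom(resolution = 8L)
    gp <- tiny_gp()
    ref <- make_reference_state(mesh, fem_material(333.28), total_force = 0.3)
    list(mesh = mesh, gp = gp, ref = ref)
  })
}

test_that("single-tissue recovery sweeps 9 offsets and the best row is the argmin", {
  fx <- recovery_fixture()
  res <- single_tissue_recovery(fx$gp, 11L, fx$mesh, fx$ref, refine = FALSE,
                                total_force = 0.3)
  expect_equal(nrow(res$rows), 9L)
  expect_true(all(res$rows$converged))
  # grid-argmin oracle
  expect_equal(res$best_row, which.min(res$rows$rmse_mm))
  expect_true(all(res$rows$rmse_mm[res$best_row] <= res$rows$rmse_mm))
  # recovered modulus is the candidate closest to the known reference
  mu_best <- res$rows$mu[res$best_row]
  expect_equal(which.min(abs(res$rows$mu - 333.28)),
               res$best_row)
  # with a corpus centred at the reference, recovery lands within the
  # spread of one offset step around the truth
  steps <- abs(diff(log(sort(res$rows$mu))))
  expect_lt(abs(log(mu_best / 333.28)), max(steps) + 1e-9)
})

test_that("refinement adds half-step candidates and never worsens the best RMSE", {
  fx <- recovery_fixture()
  base <- single_tissue_recovery(fx$gp, 11L, fx$mesh, fx$ref, refine = FALSE,
                                 total_force = 0.3)
  ref <- single_tissue_recovery(fx$gp, 11L, fx$mesh, fx$ref, refine = TRUE,
                                total_force = 0.3)
  expect_gte(nrow(ref$rows), nrow(base$rows))
  expect_lte(best_rmse(ref), best_rmse(base) + 1e-12)
  extra <- setdiff(ref$rows$offset, base$rows$offset)
  expect_true(all(abs(extra * 4 - round(extra * 4)) < 1e-9)) # quarter steps
})

test_that("self-recovery: a reference built from a candidate's modulus gives ~0 RMSE", {
  fx <- recovery_fixture()
  base <- single_tissue_recovery(fx$gp, 11L, fx$mesh, fx$ref, refine = FALSE,
                                 total_force = 0.3)
  mu_c <- base$rows$mu[5] # the s = 0 candidate
  ref2 <- make_reference_state(fx$mesh, fem_material(mu_c), total_force = 0.3)
  res <- single_tissue_recovery(fx$gp, 11L, fx$mesh, ref2, refine = FALSE,
                                total_force = 0.3)
  row <- which(abs(res$rows$mu - mu_c) < 1e-9)
  expect_length(row, 1L)
  expect_lt(res$rows$rmse_mm[row], 1e-3)
  expect_equal(res$best_row, row)
})

test_that("two-tissue recovery grids all offset pairs with a symmetric surface", {
  fx <- recovery_fixture()
  mesh2 <- label_two_tissues(fx$mesh)
  mats <- list(grey = fem_material(1370), white = fem_material(990))
  ref <- make_reference_state(mesh2, mats, total_force = 0.3)
  offs <- seq(-2, 2, by = 1)
  res <- multi_tissue_recovery(fx$gp, 9L, 10L, mesh2, ref, offsets = offs,
                               refine = FALSE, total_force = 0.3)
  expect_equal(nrow(res$rows), 25L)
  expect_equal(res$best_row, which.min(res$rows$rmse_mm))
  surf <- rmse_surface(res)
  expect_equal(nrow(surf), 25L)
  # swapping the grey/white labels and tasks transposes the RMSE surface:
  # per-element materials are unchanged, so cell (a, b) maps to (b, a)
  mesh_sw <- tet_mesh(mesh2$nodes, mesh2$tets, fixed_nodes = mesh2$fixed_nodes,
                      load_nodes = mesh2$load_nodes,
                      tissue = ifelse(mesh2$tissue == "grey", "white", "grey"),
                      density = mesh2$density)
  ref_sw <- make_reference_state(mesh_sw,
                                 list(grey = fem_material(990),
                                      white = fem_material(1370)),
                                 total_force = 0.3)
  res_sw <- multi_tissue_recovery(fx$gp, 10L, 9L, mesh_sw, ref_sw,
                                  offsets = offs, refine = FALSE,
                                  total_force = 0.3)
  a <- res$rows[order(res$rows$offset_gm, res$rows$offset_wm), ]
  b <- res_sw$rows[order(res_sw$rows$offset_wm, res_sw$rows$offset_gm), ]
  expect_equal(a$rmse_mm, b$rmse_mm, tolerance = 1e-4)
  expect_equal(a$offset_gm, b$offset_wm)
})

test_that("report tables round-trip with a unique best flag", {
  fx <- recovery_fixture()
  res <- single_tissue_recovery(fx$gp, 11L, fx$mesh, fx$ref, refine = FALSE,
                                total_force = 0.3)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- report_table(res, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(res$rows))
  expect_equal(sum(back$best), 1L)
  expect_equal(back$rmse_mm, df$rmse_mm, tolerance = 1e-12)
  report_table(res, path) # idempotent re-export
  expect_equal(utils::read.csv(path), back)
})
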