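# Kuhn 6-tet subdivision of a cube (conforming across neighbours: every
# face diagonal runs from the cube's minimal to maximal corner).
KUHN_TETS <- matrix(c(0, 1, 3, 7,  0, 1, 5, 7,  0, 2, 3, 7,
                      0, 2, 6, 7,  0, 4, 5, 7,  0, 4, 6, 7),
                    ncol = 4, byrow = TRUE) + 1L

#' Generate a half-ellipsoid brain phantom mesh
#'
#' A desk-scale stand-in for a template brain mesh: the upper half of an
#' ellipsoid with half-axes `half_axes` (default 60 x 45 x 40 mm, i.e. a
#' 120 x 90 x 80 mm brain-sized solid), meshed by a structured cube grid
#' with a Kuhn tetrahedral split. The grid is generated for `x >= 0` and
#' mirrored, so the mesh is exactly symmetric about the mid-sagittal
#' plane. Boundary conditions mirror a supine surgical setup: the base
#' plane (`z = 0`) is fixed, plus a mid-sagittal band of superior nodes
#' standing in for the falx cerebri; the load set is the superior surface
#' cap.
#'
#' @param resolution number of grid cells across the full x extent
#'   (default 16, about 3000 tets); refining increases node count.
#' @param seed kept for interface symmetry; generation is deterministic.
#' @param half_axes ellipsoid half-axes (m).
#' @param cap_frac load nodes are surface nodes with `z >= cap_frac * max z`.
#' @param falx_tol half-width of the fixed mid-sagittal band (m).
#' @param density mass density (kg/m^3).
#' @return a [tet_mesh()] with tissue label `"single"` everywhere.
#' @export
generate_phantom <- function(resolution = 16L, seed = 1L,
                             half_axes = c(0.060, 0.045, 0.040),
                             cap_frac = 0.55, falx_tol = 0.002,
                             density = 1000) {
  stopifnot(resolution >= 4L)
  a <- half_axes[1]; b <- half_axes[2]; cc <- half_axes[3]
  h <- 2 * a / resolution
  nx <- ceiling(a / h); ny <- ceiling(b / h); nz <- ceiling(cc / h)
  # grid nodes for the x >= 0 half
  xs <- h * (0:nx); ys <- h * (-ny:ny); zs <- h * (0:nz)
  nid <- array(0L, dim = c(nx + 1, 2 * ny + 1, nz + 1))
  nodes <- vector("list", (nx + 1) * (2 * ny + 1) * (nz + 1))
  k <- 0L
  for (i in seq_along(xs)) for (j in seq_along(ys)) for (l in seq_along(zs)) {
    k <- k + 1L
    nid[i, j, l] <- k
    nodes[[k]] <- c(xs[i], ys[j], zs[l])
  }
  nodes <- do.call(rbind, nodes[seq_len(k)])
  inside <- function(p) sum((p / c(a, b, cc))^2) <= 1
  tets <- list(); tk <- 0L
  for (i in seq_len(nx)) for (j in seq_len(2 * ny)) for (l in seq_len(nz)) {
    corners <- c(nid[i, j, l], nid[i + 1, j, l], nid[i, j + 1, l],
                 nid[i + 1, j + 1, l], nid[i, j, l + 1], nid[i + 1, j, l + 1],
                 nid[i, j + 1, l + 1], nid[i + 1, j + 1, l + 1])
    for (r in seq_len(nrow(KUHN_TETS))) {
      tet <- corners[KUHN_TETS[r, ]]
      cen <- colMeans(nodes[tet, , drop = FALSE])
      if (inside(cen)) { tk <- tk + 1L; tets[[tk]] <- tet }
    }
  }
  if (tk == 0L) stop("resolution too coarse: no elements inside the ellipsoid")
  tets <- do.call(rbind, tets)
  # drop unused nodes, then mirror about x = 0 and weld the plane nodes
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4)
  n0 <- nrow(nodes)
  on_plane <- abs(nodes[, 1]) < 1e-12
  mirror_id <- integer(n0)
  extra <- which(!on_plane)
  mirror_id[on_plane] <- which(on_plane)
  mirror_id[extra] <- n0 + seq_along(extra)
  nodes <- rbind(nodes, cbind(-nodes[extra, 1], nodes[extra, 2], nodes[extra, 3]))
  tets_m <- matrix(mirror_id[tets], ncol = 4)[, c(1, 3, 2, 4), drop = FALSE]
  tets <- rbind(tets, tets_m)
  # enforce positive orientation
  for (e in seq_len(nrow(tets))) {
    d <- t(nodes[tets[e, 2:4], , drop = FALSE]) - nodes[tets[e, 1], ]
    if (det(d) < 0) tets[e, 3:4] <- tets[e, c(4, 3)]
  }
  zmax <- max(nodes[, 3])
  fixed <- which(nodes[, 3] < 1e-12 |
                   (abs(nodes[, 1]) <= falx_tol & nodes[, 3] >= cc / 2))
  mesh0 <- tet_mesh(nodes, tets, fixed_nodes = fixed, density = density)
  surf <- surface_nodes(mesh0)
  load <- setdiff(intersect(surf, which(nodes[, 3] >= cap_frac * zmax)), fixed)
  if (!length(load) || !length(fixed))
    stop("resolution too coarse: empty fixed or load node set")
  tet_mesh(nodes, tets, fixed_nodes = fixed, load_nodes = load,
           density = density)
}

#' Label an outer grey-matter shell and a white-matter core
#'
#' Elements whose centroid lies within `shell_thickness` of the ellipsoid
#' surface (measured radially) are labelled `"grey"`, the interior
#' `"white"`.
#'
#' @param mesh a phantom [tet_mesh()].
#' @param shell_thickness shell depth in metres (default 0.010).
#' @param half_axes the ellipsoid half-axes used to generate the mesh.
#' @return the mesh with a two-valued tissue labelling.
#' @export
label_two_tissues <- function(mesh, shell_thickness = 0.010,
                              half_axes = c(0.060, 0.045, 0.040)) {
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
            mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  rho <- sqrt(rowSums((cen / rep(half_axes, each = nrow(cen)))^2))
  rad <- sqrt(rowSums(cen^2))
  dist_surf <- ifelse(rho > 0, rad * (1 / rho - 1), max(half_axes))
  tissue <- ifelse(dist_surf <= shell_thickness, "grey", "white")
  tet_mesh(mesh$nodes, mesh$tets, fixed_nodes = mesh$fixed_nodes,
           load_nodes = mesh$load_nodes, tissue = tissue,
           density = mesh$density)
}

#' Distribute a compressive load over the superior cap
#'
#' The total force (default 10 N) is split equally over the mesh's load
#' nodes and directed inferiorly (-z).
#'
#' @param mesh a phantom [tet_mesh()].
#' @param total_force total compressive force magnitude (N).
#' @return length-3n external force vector.
#' @export
apply_compression_load <- function(mesh, total_force = 10) {
  if (!length(mesh$load_nodes)) stop("mesh has an empty load node set")
  f <- numeric(3L * nrow(mesh$nodes))
  f[(mesh$load_nodes - 1L) * 3L + 3L] <- -total_force / length(mesh$load_nodes)
  f
}

#' Reference deformation state under known tissue parameters
#'
#' Deforms the phantom to equilibrium under the compression load with the
#' reference shear moduli: 333.28 Pa for single tissue, or grey 1370 Pa
#' (basal ganglia) / white 990 Pa (corpus callosum) for two-tissue
#' phantoms.
#'
#' @param mesh a phantom [tet_mesh()].
#' @param materials a `fem_material` or named list per tissue label; the
#'   defaults above are used when `NULL`.
#' @param cfg a [solver_config()]; a quasi-static-friendly default is used
#'   when `NULL`.
#' @param total_force compression magnitude (N).
#' @return equilibrium `sim_state` (attributes `converged`, `steps`).
#' @export
make_reference_state <- function(mesh, materials = NULL, cfg = NULL,
                                 total_force = 10) {
  if (is.null(materials)) {
    labs <- unique(mesh$tissue)
    materials <- if (identical(labs, "single")) fem_material(333.28) else
      list(grey = fem_material(1370), white = fem_material(990))
  }
  if (is.null(cfg)) cfg <- recovery_solver_config()
  f <- apply_compression_load(mesh, total_force)
  simulate_to_equilibrium(mesh, materials, f, cfg, mode = "quasistatic")
}

#' Solver configuration tuned for quasi-static equilibrium runs
#'
#' Larger step and heavier mass damping than the dynamic default; the
#' equilibrium state itself is step-size independent.
#'
#' @inheritParams solver_config
#' @return a `solver_config`.
#' @export
recovery_solver_config <- function(h = 0.3, rayleigh_alpha = 2,
                                   rayleigh_beta = 0.005, cg_tol = 1e-6,
                                   cg_max_iter = 20000L,
                                   equilibrium_tol = 1e-5, max_steps = 300L,
                                   max_incr = NULL) {
  solver_config(h, rayleigh_alpha, rayleigh_beta, cg_tol, cg_max_iter,
                equilibrium_tol, max_steps, max_incr)
}
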