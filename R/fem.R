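#' Construct a tetrahedral simulation mesh
#'
#' Validates positive orientation of every element at rest and the
#' disjointness of the Dirichlet (fixed) and load node sets, and
#' precomputes the shape matrices and sparse stiffness layout used by the
#' solver.
#'
#' @param nodes n x 3 matrix of rest positions (metres).
#' @param tets m x 4 integer matrix of 1-based node indices.
#' @param fixed_nodes integer indices of Dirichlet nodes (displacement 0).
#' @param load_nodes integer indices of loaded nodes.
#' @param tissue per-element labels (character), e.g. `"single"`,
#'   `"grey"`, `"white"`.
#' @param density mass density in kg/m^3 (default 1000).
#' @return a `tet_mesh` object.
#' @export
tet_mesh <- function(nodes, tets, fixed_nodes = integer(0),
                     load_nodes = integer(0), tissue = NULL, density = 1000) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L,
            min(tets) >= 1L, max(tets) <= nrow(nodes), density > 0)
  fixed_nodes <- sort(unique(as.integer(fixed_nodes)))
  load_nodes <- sort(unique(as.integer(load_nodes)))
  if (length(intersect(fixed_nodes, load_nodes)))
    stop("fixed and load node sets must be disjoint")
  if (is.null(tissue)) tissue <- rep("single", nrow(tets))
  stopifnot(length(tissue) == nrow(tets))
  setup <- fem_setup_cpp(nodes, tets) # errors on non-positive orientation
  structure(list(nodes = nodes, tets = tets, fixed_nodes = fixed_nodes,
                 load_nodes = load_nodes, tissue = as.character(tissue),
                 density = density, setup = setup),
            class = "tet_mesh")
}

#' @exportS3Method base::print
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet mesh: %d nodes, %d tets, %d fixed, %d loaded, tissues: %s\n",
              nrow(x$nodes), nrow(x$tets), length(x$fixed_nodes),
              length(x$load_nodes), paste(unique(x$tissue), collapse = "/")))
  invisible(x)
}

#' FEM material from Lame-style parameters
#'
#' Compressible neo-Hookean material
#' \eqn{\Psi = \mu/2(\lambda_1^2+\lambda_2^2+\lambda_3^2-3) - \mu \ln J +
#' \lambda/2 (\ln J)^2} plus a compression-resistance term
#' \eqn{k (1-J)^3} active only under volume loss (`J < 1`),
#' C2-continuous at `J = 1`.
#'
#' @param mu shear modulus (Pa), > 0.
#' @param lam first Lame coefficient (Pa); default from `nu`.
#' @param compression_k compression-resistance scale (Pa); default
#'   `10 * mu`.
#' @param nu Poisson ratio used when `lam` is omitted (default 0.49, near-incompressible brain tissue).
#' @return a `fem_material`.
#' @export
fem_material <- function(mu, lam = NULL, compression_k = NULL, nu = 0.49) {
  stopifnot(mu > 0)
  if (is.null(lam)) lam <- 2 * mu * nu / (1 - 2 * nu)
  if (is.null(compression_k)) compression_k <- 10 * mu
  stopifnot(lam >= 0, compression_k >= 0)
  structure(list(family = "NH", p1 = mu, p2 = 0, mu_v = mu, lam = lam,
                 compression_k = compression_k, mu = mu),
            class = "fem_material")
}

#' FEM material from meta-model parameters
#'
#' Maps a fitted meta-model into the compressible FEM: the family's
#' principal-stretch energy provides the isochoric part (through its
#' gradient and Hessian in the SVD stress path), the volumetric
#' \eqn{-\mu_v \ln J} coefficient is the family's principal stress at the
#' identity (so the rest state is stress free: \eqn{\mu}, \eqn{2C_1+4C_2},
#' \eqn{\mu_1}), and the Lame \eqn{\lambda} comes from the equivalent
#' small-strain shear modulus \eqn{\mu_{eff} = \Psi''_{uni}(1)/3}
#' (\eqn{\mu}, \eqn{2(C_1+C_2)}, \eqn{\mu_1\alpha_1/2}) at Poisson ratio
#' `nu`.
#'
#' @param family `"NH"`, `"MR"`, or `"O1"` (the meta-model Ogden variants
#'   map to `"O1"`).
#' @param params named list of family parameters.
#' @param nu Poisson ratio (default 0.49).
#' @param compression_k optional override of the resistance scale.
#' @return a `fem_material`.
#' @export
material_from_meta <- function(family, params, nu = 0.49,
                               compression_k = NULL) {
  if (family %in% c("O_hi", "O_lo")) family <- "O1"
  family <- match.arg(family, c("NH", "MR", "O1"))
  p <- check_params(family, params)
  spec <- switch(family,
    NH = list(p1 = p$mu, p2 = 0, mu_v = p$mu, mu_eff = p$mu),
    MR = list(p1 = p$c1, p2 = p$c2, mu_v = 2 * p$c1 + 4 * p$c2,
              mu_eff = 2 * (p$c1 + p$c2)),
    O1 = list(p1 = p$mu1, p2 = p$alpha1, mu_v = p$mu1,
              mu_eff = p$mu1 * p$alpha1 / 2))
  stopifnot(spec$mu_eff > 0)
  if (is.null(compression_k)) compression_k <- 10 * spec$mu_eff
  structure(list(family = family, p1 = spec$p1, p2 = spec$p2,
                 mu_v = spec$mu_v, lam = 2 * spec$mu_eff * nu / (1 - 2 * nu),
                 compression_k = compression_k, mu = spec$mu_eff),
            class = "fem_material")
}

mat_code <- function(family) match(family, c("NH", "MR", "O1")) - 1L

# per-element material arrays for the C++ assembly
material_arrays <- function(mesh, materials) {
  if (inherits(materials, "fem_material")) {
    materials <- setNames(rep(list(materials), length(unique(mesh$tissue))),
                          unique(mesh$tissue))
  }
  m <- nrow(mesh$tets)
  code <- integer(m); pars <- matrix(0, m, 5)
  for (lab in unique(mesh$tissue)) {
    mt <- materials[[lab]]
    if (is.null(mt)) stop("no material supplied for tissue '", lab, "'")
    sel <- mesh$tissue == lab
    code[sel] <- mat_code(mt$family)
    pars[sel, ] <- matrix(c(mt$p1, mt$p2, mt$mu_v, mt$lam, mt$compression_k),
                          sum(sel), 5, byrow = TRUE)
  }
  list(code = code, pars = pars)
}

#' Deformation gradient of one element
#'
#' Linear-tetrahedron deformation gradient \eqn{F = D_s D_m^{-1}} (deformed
#' versus rest edge matrices); the identity when `u = 0`.
#'
#' @param mesh a [tet_mesh()].
#' @param u displacement vector of length `3 n` (metres), xyz-interleaved.
#' @param element element index.
#' @return 3 x 3 matrix F.
#' @export
deformation_gradient <- function(mesh, u, element) {
  idx <- mesh$tets[element, ]
  X <- mesh$nodes[idx, , drop = FALSE] +
    matrix(u, ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
  Ds <- t(X[2:4, ]) - X[1, ]
  Bm <- matrix(mesh$setup$Bm[element, ], 3, 3, byrow = TRUE)
  Ds %*% Bm
}

#' Rotation-invariant SVD of a deformation gradient
#'
#' \eqn{F = U \hat F V^T} with proper rotations
#' (\eqn{\det U = \det V = +1}) and at most one negative entry of
#' \eqn{\hat F}, placed last — the convention that keeps the principal
#' stresses meaningful through element inversion.
#'
#' @param F 3 x 3 matrix.
#' @return list with `U`, `d` (signed stretches), `V`.
#' @export
rotation_invariant_svd <- function(F) {
  out <- svd_rv_cpp(as.matrix(F))
  list(U = out$U, d = drop(out$d), V = out$V)
}

#' Energy density of a material at a deformation gradient
#'
#' @param material a `fem_material`.
#' @param F 3 x 3 deformation gradient.
#' @return scalar energy density (Pa = J/m^3).
#' @export
element_energy <- function(material, F) {
  s <- rotation_invariant_svd(F)
  psi_principal_cpp(mat_code(material$family), material$p1, material$p2,
                    material$mu_v, material$lam, material$compression_k,
                    s$d)$psi
}

#' First Piola-Kirchhoff stress
#'
#' \eqn{P = U\, diag(\partial\Psi/\partial\lambda_i)\, V^T} computed from
#' the rotation-invariant SVD; zero at the identity, rotation-equivariant
#' (\eqn{P(RF) = R P(F)}).
#'
#' @inheritParams element_energy
#' @return 3 x 3 stress matrix (Pa).
#' @export
first_pk_stress <- function(material, F) {
  first_pk_cpp(mat_code(material$family), material$p1, material$p2,
               material$mu_v, material$lam, material$compression_k,
               as.matrix(F))
}

#' Internal elastic forces
#'
#' \eqn{R(u) = \nabla_u E_{elastic}(u)}; zero at rest and under rigid
#' translation; equilibrium states satisfy `R(u) = f`.
#'
#' @param mesh a [tet_mesh()].
#' @param materials a single `fem_material` or a named list keyed by the
#'   mesh's tissue labels.
#' @param u displacement vector (3n).
#' @return length-3n force vector (N).
#' @export
internal_forces <- function(mesh, materials, u) {
  ma <- material_arrays(mesh, materials)
  fem_assemble_cpp(mesh$setup, mesh$nodes, mesh$tets, u, ma$code, ma$pars,
                   clamp = FALSE, want_K = FALSE)$grad
}

#' Total elastic energy of a displaced mesh
#' @inheritParams internal_forces
#' @return scalar energy (J).
#' @export
elastic_energy <- function(mesh, materials, u) {
  ma <- material_arrays(mesh, materials)
  fem_assemble_cpp(mesh$setup, mesh$nodes, mesh$tets, u, ma$code, ma$pars,
                   clamp = FALSE, want_K = FALSE)$energy
}

#' Tangent stiffness matrix
#'
#' \eqn{K(u) = \partial R/\partial u}, assembled from the per-element
#' gradient and Hessian of \eqn{\Psi} in the diagonal SVD frame. With
#' `clamp = TRUE` indefinite element blocks are projected to positive
#' semidefinite (eigenvalue clamping at 0), the standard invertible-FEM
#' treatment that keeps the CG system solvable.
#'
#' @inheritParams internal_forces
#' @param clamp project element Hessians to PSD (default `FALSE` for the
#'   exact Jacobian).
#' @param constrained zero out rows/columns of fixed nodes (unit
#'   diagonal).
#' @return sparse `dgCMatrix` of size 3n x 3n.
#' @export
stiffness <- function(mesh, materials, u, clamp = FALSE, constrained = FALSE) {
  ma <- material_arrays(mesh, materials)
  out <- fem_assemble_cpp(mesh$setup, mesh$nodes, mesh$tets, u, ma$code,
                          ma$pars, clamp = clamp, want_K = TRUE)
  su <- mesh$setup
  vals <- out$Kvals
  if (constrained) {
    fd <- fixed_dofs(mesh)
    mask <- (su$row_of + 1L) %in% fd | (su$col_ind + 1L) %in% fd
    vals[mask] <- 0
    di <- su$diag_idx[fd] + 1L
    vals[di] <- 1
  }
  Matrix::sparseMatrix(i = su$row_of + 1L, j = su$col_ind + 1L, x = vals,
                       dims = c(3L * su$n, 3L * su$n))
}

min_edge_length <- function(mesh) {
  tt <- mesh$tets; nd <- mesh$nodes
  pairs <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
                 tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  min(sqrt(rowSums((nd[pairs[, 1], , drop = FALSE] -
                      nd[pairs[, 2], , drop = FALSE])^2)))
}

fixed_dofs <- function(mesh) {
  if (!length(mesh$fixed_nodes)) return(integer(0))
  as.integer(outer(1:3, (mesh$fixed_nodes - 1L) * 3L, "+"))
}

#' Solver configuration
#'
#' @param h time step in seconds.
#' @param rayleigh_alpha mass-proportional damping (1/s).
#' @param rayleigh_beta stiffness-proportional damping (s).
#' @param cg_tol relative CG tolerance.
#' @param cg_max_iter CG iteration cap.
#' @param equilibrium_tol settle threshold on the velocity max-norm (m/s).
#' @param max_steps step cap for [simulate_to_equilibrium()].
#' @param max_incr trust-region cap on the per-step displacement increment
#'   (m) in quasi-static mode; `NULL` selects the shortest rest
#'   edge, keeping every intermediate state physical.
#' @return a `solver_config` list.
#' @export
solver_config <- function(h = 0.01, rayleigh_alpha = 1, rayleigh_beta = 0.001,
                          cg_tol = 1e-8, cg_max_iter = 5000L,
                          equilibrium_tol = 1e-6, max_steps = 2000L,
                          max_incr = NULL) {
  stopifnot(h > 0, cg_tol > 0, equilibrium_tol > 0)
  structure(list(h = h, rayleigh_alpha = rayleigh_alpha,
                 rayleigh_beta = rayleigh_beta, cg_tol = cg_tol,
                 cg_max_iter = as.integer(cg_max_iter),
                 equilibrium_tol = equilibrium_tol,
                 max_steps = as.integer(max_steps), max_incr = max_incr),
            class = "solver_config")
}

#' Simulation state
#'
#' @param mesh a [tet_mesh()].
#' @param u,v displacement / velocity vectors (3n); fixed-node entries are
#'   forced to zero.
#' @param t simulation time (s).
#' @return a `sim_state`.
#' @export
sim_state <- function(mesh, u = NULL, v = NULL, t = 0) {
  N <- 3L * nrow(mesh$nodes)
  if (is.null(u)) u <- numeric(N)
  if (is.null(v)) v <- numeric(N)
  stopifnot(length(u) == N, length(v) == N)
  fd <- fixed_dofs(mesh)
  u[fd] <- 0; v[fd] <- 0
  structure(list(u = u, v = v, t = t), class = "sim_state")
}

mass_diag <- function(mesh) {
  md <- numeric(3L * nrow(mesh$nodes))
  per <- mesh$density * mesh$setup$vol / 4
  for (a in 1:4) {
    base <- (mesh$tets[, a] - 1L) * 3L
    for (b in 1:3) {
      acc <- rowsum(per, base + b)
      md[as.integer(rownames(acc))] <- md[as.integer(rownames(acc))] + acc[, 1]
    }
  }
  md
}

# assemble the backward-Euler system values on the shared CSR pattern and
# solve (M + hD + h^2 K) dv = rhs with Dirichlet projection
be_solve <- function(mesh, ma, state, f_ext, cfg, md, v0) {
  su <- mesh$setup
  out <- fem_assemble_cpp(su, mesh$nodes, mesh$tets, state$u, ma$code,
                          ma$pars, clamp = TRUE, want_K = TRUE)
  h <- cfg$h; al <- cfg$rayleigh_alpha; be <- cfg$rayleigh_beta
  kv <- out$Kvals
  avals <- (h * be + h * h) * kv
  di <- su$diag_idx + 1L
  avals[di] <- avals[di] + (1 + h * al) * md
  Kv0 <- csr_matvec_cpp(su$row_ptr, su$col_ind, kv, v0)
  rhs <- h * (f_ext - out$grad - al * md * v0 - be * Kv0) - h * h * Kv0
  fd <- fixed_dofs(mesh)
  if (length(fd)) {
    mask <- (su$row_of + 1L) %in% fd | (su$col_ind + 1L) %in% fd
    avals[mask] <- 0
    avals[di[fd]] <- 1
    rhs[fd] <- 0
  }
  sol <- pcg_cpp(su$row_ptr, su$col_ind, avals, rhs, numeric(length(rhs)),
                 cfg$cg_tol, cfg$cg_max_iter)
  if (!sol$converged)
    stop(sprintf("CG failed to converge within %d iterations (residual %.3g)",
                 cfg$cg_max_iter, sol$resid))
  list(dv = sol$x, grad = out$grad, energy = out$energy)
}

#' One implicit backward Euler step
#'
#' Solves \eqn{(M + h D + h^2 K)\,\Delta \dot u = h(f - R(u) - D \dot u_0)
#' - h^2 K \dot u_0} with lumped mass, Rayleigh damping
#' \eqn{D = \alpha M + \beta K}, PSD-clamped stiffness, Dirichlet rows
#' projected out, and a Jacobi-preconditioned conjugate gradient; then
#' updates \eqn{u \leftarrow u + h(\dot u_0 + \Delta\dot u)}.
#'
#' @inheritParams internal_forces
#' @param state a [sim_state()].
#' @param external_f external force vector (3n, N).
#' @param cfg a [solver_config()].
#' @return the advanced `sim_state`.
#' @export
backward_euler_step <- function(mesh, materials, state, external_f, cfg) {
  ma <- material_arrays(mesh, materials)
  md <- mass_diag(mesh)
  sol <- be_solve(mesh, ma, state, external_f, cfg, md, state$v)
  v1 <- state$v + sol$dv
  fd <- fixed_dofs(mesh)
  v1[fd] <- 0
  sim_state(mesh, u = state$u + cfg$h * v1, v = v1, t = state$t + cfg$h)
}

#' Run the solver until quasi-static equilibrium
#'
#' Steps the implicit integrator until the velocity max-norm falls below
#' `equilibrium_tol` or `max_steps` is reached. Two modes:
#' `"dynamic"` performs plain backward Euler steps (physical transient,
#' dissipative under Rayleigh damping); `"quasistatic"` resets the
#' velocity each step and backtracks on the total potential
#' \eqn{E(u) - f^T u}, which converges to the same equilibrium (the
#' settled state is independent of `h` and of the damping coefficients)
#' in far fewer steps.
#'
#' @inheritParams backward_euler_step
#' @param mode `"quasistatic"` (default) or `"dynamic"`.
#' @param state optional initial [sim_state()] (warm start).
#' @return a `sim_state` with attributes `converged` and `steps`.
#' @export
simulate_to_equilibrium <- function(mesh, materials, external_f, cfg = solver_config(),
                                    mode = c("quasistatic", "dynamic"),
                                    state = NULL) {
  mode <- match.arg(mode)
  ma <- material_arrays(mesh, materials)
  md <- mass_diag(mesh)
  fd <- fixed_dofs(mesh)
  if (is.null(state)) state <- sim_state(mesh)
  free <- setdiff(seq_along(state$u), fd)
  pot <- function(u) {
    e <- fem_assemble_cpp(mesh$setup, mesh$nodes, mesh$tets, u, ma$code,
                          ma$pars, clamp = FALSE, want_K = FALSE)$energy
    e - sum(external_f * u)
  }
  converged <- FALSE; steps <- 0L
  p0 <- if (mode == "quasistatic") pot(state$u) else NA_real_
  du_cap <- cfg$max_incr
  if (is.null(du_cap)) du_cap <- min_edge_length(mesh)
  for (k in seq_len(cfg$max_steps)) {
    steps <- k
    v0 <- if (mode == "quasistatic") numeric(length(state$v)) else state$v
    st0 <- state; st0$v <- v0
    sol <- be_solve(mesh, ma, st0, external_f, cfg, md, v0)
    v1 <- v0 + sol$dv
    v1[fd] <- 0
    if (mode == "quasistatic") {
      du <- cfg$h * v1
      mx <- max(abs(du))
      if (mx > du_cap) du <- du * (du_cap / mx)
      scale <- 1
      repeat {
        p1 <- pot(state$u + scale * du)
        if ((is.finite(p1) && p1 <= p0 + 1e-10 * (abs(p0) + 1)) ||
              scale < 1 / 64) break
        scale <- scale / 2
      }
      state <- sim_state(mesh, u = state$u + scale * du, v = v1,
                         t = state$t + cfg$h)
      p0 <- pot(state$u)
      vmax <- max(abs(scale * du[free])) / cfg$h
    } else {
      state <- sim_state(mesh, u = state$u + cfg$h * v1, v = v1,
                         t = state$t + cfg$h)
      vmax <- max(abs(v1[free]), 0)
    }
    if (vmax < cfg$equilibrium_tol) { converged <- TRUE; break }
  }
  attr(state, "converged") <- converged
  attr(state, "steps") <- steps
  state
}

#' Root-mean-square node distance between two states
#'
#' \eqn{RMSE = \sqrt{\sum_{i\in S} \|x_i^a - x_i^b\|^2 / S}} over the node
#' subset S, reported in millimetres.
#'
#' @param pos_a,pos_b n x 3 matrices of node positions in metres (or
#'   `sim_state`s together with `mesh`).
#' @param node_subset integer node indices (default all).
#' @param mesh optional [tet_mesh()] enabling `sim_state` inputs.
#' @return RMSE in mm.
#' @export
rmse_nodes <- function(pos_a, pos_b, node_subset = NULL, mesh = NULL) {
  to_pos <- function(p) {
    if (inherits(p, "sim_state")) {
      stopifnot(!is.null(mesh))
      mesh$nodes + matrix(p$u, ncol = 3, byrow = TRUE)
    } else as.matrix(p)
  }
  a <- to_pos(pos_a); b <- to_pos(pos_b)
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(node_subset)) node_subset <- seq_len(nrow(a))
  d <- a[node_subset, , drop = FALSE] - b[node_subset, , drop = FALSE]
  sqrt(sum(d^2) / length(node_subset)) * 1000
}

#' Node positions of a state
#' @param mesh a [tet_mesh()].
#' @param state a [sim_state()].
#' @return n x 3 matrix of positions (m).
#' @export
node_positions <- function(mesh, state) {
  mesh$nodes + matrix(state$u, ncol = 3, byrow = TRUE)
}

#' Surface nodes of a mesh
#'
#' Nodes incident to boundary faces (faces belonging to exactly one
#' element).
#'
#' @param mesh a [tet_mesh()].
#' @param free_only drop fixed nodes (default `FALSE`).
#' @return integer node indices.
#' @export
surface_nodes <- function(mesh, free_only = FALSE) {
  tt <- mesh$tets
  faces <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)],
                 tt[, c(1, 3, 4)], tt[, c(2, 3, 4)])
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  once <- names(which(table(key) == 1L))
  idx <- sort(unique(as.integer(unlist(strsplit(once, "-")))))
  if (free_only) idx <- setdiff(idx, mesh$fixed_nodes)
  idx
}
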