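random_F <- function() {
  repeat {
    F <- diag(3) + matrix(rnorm(9, 0, 0.15), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

test_that("deformation gradient reproduces affine maps exactly", {
  mesh <- two_tet_mesh()
  n <- nrow(mesh$nodes)
  expect_equal(deformation_gradient(mesh, numeric(3 * n), 1), diag(3))
  # uniform scaling of positions by c gives F = c I
  c0 <- 1.3
  u <- as.vector(t((c0 - 1) * mesh$nodes))
  expect_equal(deformation_gradient(mesh, u, 2), diag(c0, 3))
  # arbitrary affine map
  set.seed(51)
  A <- random_F()
  u <- as.vector(t(mesh$nodes %*% t(A) - mesh$nodes))
  for (e in 1:2) expect_equal(deformation_gradient(mesh, u, e), A)
})

test_that("rotation-invariant SVD returns proper rotations with inversion handled", {
  expect_equal(rotation_invariant_svd(diag(3))$d, rep(1, 3))
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s <- rotation_invariant_svd(R)
  expect_equal(s$d, rep(1, 3))
  expect_equal(s$U %*% diag(s$d) %*% t(s$V), R)
  expect_equal(det(s$U), 1)
  expect_equal(det(s$V), 1)
  set.seed(52)
  for (i in 1:20) {
    F <- random_F()
    if (i > 10) F[, 1] <- -F[, 1] # reflection-containing cases
    s <- rotation_invariant_svd(F)
    expect_lt(max(abs(s$U %*% diag(s$d) %*% t(s$V) - F)), 1e-10 * max(abs(F)))
    expect_equal(det(s$U), 1, tolerance = 1e-10)
    expect_equal(det(s$V), 1, tolerance = 1e-10)
    expect_lte(sum(s$d < 0), 1L)
    if (any(s$d < 0)) expect_lt(s$d[3], 0) # negative stretch placed last
    # brute-force sign-assignment oracle agrees on the stretch magnitudes
    orc <- oracle_svd_signs(F)
    expect_equal(sort(abs(s$d)), sort(abs(orc$d)), tolerance = 1e-8)
    expect_equal(sum(s$d < 0) %% 2, sum(orc$d < 0) %% 2)
  }
})

test_that("element energy matches the compressible neo-Hookean closed form", {
  mat <- fem_material(1000, lam = 1000, compression_k = 0)
  expect_equal(element_energy(mat, diag(3)), 0)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  expect_equal(element_energy(mat, R), 0, tolerance = 1e-10)
  # F = diag(0.9, 1, 1): Psi = mu/2 (0.81 - 1) - mu ln 0.9 + lam/2 (ln 0.9)^2
  val <- 1000 / 2 * (0.9^2 - 1) - 1000 * log(0.9) + 1000 / 2 * log(0.9)^2
  expect_equal(element_energy(mat, diag(c(0.9, 1, 1))), val, tolerance = 1e-10)
  # compression resistance adds k (1-J)^3 only below J = 1
  matk <- fem_material(1000, lam = 1000, compression_k = 500)
  expect_equal(element_energy(matk, diag(c(0.9, 1, 1))) -
                 element_energy(mat, diag(c(0.9, 1, 1))),
               500 * (1 - 0.9)^3)
  expect_equal(element_energy(matk, diag(c(1.2, 1, 1))),
               element_energy(mat, diag(c(1.2, 1, 1))))
})

test_that("first PK stress is the energy gradient and rotation equivariant", {
  set.seed(53)
  mats <- list(fem_material(800),
               material_from_meta("MR", list(c1 = 200, c2 = 80)),
               material_from_meta("O1", list(mu1 = -500, alpha1 = -4)))
  for (mat in mats) {
    expect_equal(first_pk_stress(mat, diag(3)), matrix(0, 3, 3),
                 tolerance = 1e-9 * mat$mu)
    for (rep in 1:34) {
      F <- random_F()
      P <- first_pk_stress(mat, F)
      Pfd <- matrix(0, 3, 3)
      h <- 1e-7
      for (r in 1:3) for (c in 1:3) {
        E <- matrix(0, 3, 3); E[r, c] <- h
        Pfd[r, c] <- (element_energy(mat, F + E) -
                        element_energy(mat, F - E)) / (2 * h)
      }
      expect_equal(P, Pfd, tolerance = 1e-5)
    }
    th <- 0.8
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    F <- random_F()
    expect_equal(first_pk_stress(mat, R %*% F),
                 R %*% first_pk_stress(mat, F), tolerance = 1e-9)
  }
})

test_that("internal forces are the energy gradient; rigid motions are force free", {
  mesh <- two_tet_mesh()
  mat <- fem_material(1200)
  N <- 3 * nrow(mesh$nodes)
  expect_equal(internal_forces(mesh, mat, numeric(N)), numeric(N))
  u_tr <- rep(c(2e-3, -1e-3, 3e-3), nrow(mesh$nodes))
  expect_equal(max(abs(internal_forces(mesh, mat, u_tr))), 0, tolerance = 1e-10)
  expect_equal(elastic_energy(mesh, mat, u_tr), 0, tolerance = 1e-14)
  set.seed(54)
  u <- rnorm(N, 0, 1e-3)
  R <- internal_forces(mesh, mat, u)
  h <- 1e-8
  Rfd <- vapply(seq_len(N), function(i) {
    e <- numeric(N); e[i] <- h
    (elastic_energy(mesh, mat, u + e) - elastic_energy(mesh, mat, u - e)) /
      (2 * h)
  }, 1.0)
  expect_equal(R, Rfd, tolerance = 1e-6)
})

test_that("stiffness is the symmetric force Jacobian with constrained rows projected", {
  mesh <- two_tet_mesh(fixed = 1L)
  mat <- fem_material(900)
  N <- 3 * nrow(mesh$nodes)
  set.seed(55)
  u <- rnorm(N, 0, 1e-3); u[1:3] <- 0
  K <- as.matrix(stiffness(mesh, mat, u))
  expect_equal(K, t(K), tolerance = 1e-8)
  h <- 1e-7
  Kfd <- vapply(seq_len(N), function(i) {
    e <- numeric(N); e[i] <- h
    (internal_forces(mesh, mat, u + e) - internal_forces(mesh, mat, u - e)) /
      (2 * h)
  }, numeric(N))
  expect_equal(K, Kfd, tolerance = 1e-5)
  Kc <- as.matrix(stiffness(mesh, mat, u, constrained = TRUE))
  expect_equal(Kc[1:3, -(1:3)], matrix(0, 3, N - 3))
  expect_equal(Kc[-(1:3), 1:3], matrix(0, N - 3, 3))
  expect_equal(diag(Kc)[1:3], rep(1, 3))
})

test_that("a loaded single tet settles to the independent static solution", {
  mesh <- unit_tet_mesh(fixed = 1:3)
  mat <- fem_material(1000)
  f <- numeric(12); f[10:12] <- c(1e-4, 5e-5, -5e-4)
  st <- simulate_to_equilibrium(mesh, mat, f, recovery_solver_config(),
                                "quasistatic")
  expect_true(attr(st, "converged"))
  # independent oracle: derivative-free minimisation of the total potential
  obj <- function(x) {
    u <- numeric(12); u[10:12] <- x
    elastic_energy(mesh, mat, u) - sum(f[10:12] * x)
  }
  opt <- optim(rep(1e-4, 3), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000,
                              parscale = rep(1e-4, 3)))
  expect_equal(st$u[10:12], opt$par, tolerance = 1e-3)
  # equilibrium satisfies R(u) = f on free dofs
  expect_equal(internal_forces(mesh, mat, st$u)[10:12], f[10:12],
               tolerance = 2e-3)
  # equilibrium is independent of the step size and damping
  st2 <- simulate_to_equilibrium(mesh, mat, f,
                                 recovery_solver_config(h = 0.023,
                                                        rayleigh_alpha = 7),
                                 "quasistatic")
  expect_lt(max(abs(st$u - st2$u)), 1e-8)
})

test_that("backward Euler dynamics dissipate energy and respect constraints", {
  mesh <- two_tet_mesh(fixed = 1L)
  mat <- fem_material(2000)
  N <- 3 * nrow(mesh$nodes)
  cfg <- solver_config(h = 0.004)
  # zero force, zero state: nothing moves
  st <- backward_euler_step(mesh, mat, sim_state(mesh), numeric(N), cfg)
  expect_equal(st$u, numeric(N))
  # all nodes fixed: any force leaves the state unchanged
  allfix <- two_tet_mesh(fixed = 1:5)
  stf <- backward_euler_step(allfix, mat, sim_state(allfix), rep(1, N), cfg)
  expect_equal(stf$u, numeric(N))
  expect_equal(stf$v, numeric(N))
  # free oscillation decays monotonically in total energy
  set.seed(56)
  u0 <- rnorm(N, 0, 5e-4); u0[1:3] <- 0
  st <- sim_state(mesh, u = u0)
  md <- elastogen:::mass_diag(mesh)
  etot <- function(s) 0.5 * sum(md * s$v^2) + elastic_energy(mesh, mat, s$u)
  e_prev <- etot(st)
  for (k in 1:30) {
    st <- backward_euler_step(mesh, mat, st, numeric(N), cfg)
    e_now <- etot(st)
    expect_lte(e_now, e_prev + 1e-12)
    e_prev <- e_now
    expect_equal(st$u[1:3], numeric(3))
    expect_equal(st$v[1:3], numeric(3))
  }
})

test_that("stiffer material deforms less under the same load", {
  mesh <- two_tet_mesh(fixed = 1:3)
  f <- numeric(3 * nrow(mesh$nodes))
  f[seq(12, length(f), by = 3)] <- -2e-4
  norms <- vapply(c(500, 1000, 2000), function(mu) {
    st <- simulate_to_equilibrium(mesh, fem_material(mu), f,
                                  recovery_solver_config(), "quasistatic")
    sqrt(sum(st$u^2))
  }, 1.0)
  expect_true(all(diff(norms) < 0))
})

test_that("RMSE metric follows the root-mean-square node distance in mm", {
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmse_nodes(a, a), 0)
  b <- a
  b[4, ] <- b[4, ] + c(3e-3, 4e-3, 0) # 5 mm offset on one node
  expect_equal(rmse_nodes(a, b, node_subset = 4L), 5)
  expect_equal(rmse_nodes(a, b), 5 / sqrt(10))
  sub <- c(2L, 4L, 7L)
  expect_equal(rmse_nodes(a, b, sub), rmse_nodes(a, b, rev(sub)))
})

test_that("CG solver failure is reported with its residual", {
  mesh <- unit_tet_mesh(fixed = 1:3)
  mat <- fem_material(1000)
  f <- numeric(12); f[12] <- -1e-3
  cfg <- solver_config(cg_max_iter = 0L, cg_tol = 1e-14)
  expect_error(backward_euler_step(mesh, mat, sim_state(mesh), f, cfg),
               "CG failed")
})
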