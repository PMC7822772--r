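# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a single regular tetrahedron mesh, 1 cm scale
unit_tet_mesh <- function(fixed = integer(0)) {
  tet_mesh(rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0), c(0, 0, 0.01)),
           matrix(1:4, 1), fixed_nodes = fixed)
}

# two-tet mesh sharing a face
two_tet_mesh <- function(fixed = integer(0)) {
  nodes <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0), c(0, 0, 0.01),
                 c(0.01, 0.01, 0.011))
  tet_mesh(nodes, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), fixed_nodes = fixed)
}

random_stretch <- function(n = 1) {
  matrix(runif(3 * n, 0.7, 1.4), ncol = 3)
}

# small but non-trivial corpus for GP tests (seeded, low spread)
tiny_corpus <- function(seed = 7, sigma_log = 0.2) {
  counts <- c(MRE.grey = 1L, MRE.white = 1L, MRE.healthy = 1L, MRE.abnormal = 1L,
              linear.grey = 1L, linear.white = 1L, linear.healthy = 2L,
              linear.abnormal = 1L,
              hyperelastic.grey = 2L, hyperelastic.white = 2L,
              hyperelastic.healthy = 3L, hyperelastic.abnormal = 1L)
  generate_synthetic_corpus(seed = seed, counts = counts,
                            sigma_log = sigma_log,
                            family_mix = c(NH = 1, MR = 0, O1 = 0))
}

tiny_gp <- function() {
  fixture("tiny_gp", function() {
    tasks <- assemble_tasks(tiny_corpus(), n_points = 25L)
    fit_gp(tasks, seed = 3, restarts = 2, max_points = 220L, maxit = 120L)
  })
}

# brute-force independent check used against rotation_invariant_svd:
# enumerate sign assignments of a plain SVD and keep the proper-rotation
# one reproducing F
oracle_svd_signs <- function(F) {
  sv <- svd(F)
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    S <- diag(c(s1, s2, s3))
    U <- sv$u %*% S
    d <- c(s1, s2, s3) * sv$d
    if (abs(det(U) - 1) < 1e-8 && abs(det(sv$v) - 1) < 1e-8) {
      err <- max(abs(U %*% diag(d) %*% t(sv$v) - F))
      if (err < 1e-8 && (is.null(best) || sum(d < 0) < sum(best$d < 0)))
        best <- list(U = U, d = d, V = sv$v)
    }
    V <- sv$v %*% S
    if (abs(det(sv$u) - 1) < 1e-8 && abs(det(V) - 1) < 1e-8) {
      err <- max(abs(sv$u %*% diag(d) %*% t(V) - F))
      if (err < 1e-8 && (is.null(best) || sum(d < 0) < sum(best$d < 0)))
        best <- list(U = sv$u, d = d, V = V)
    }
  }
  best
}
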