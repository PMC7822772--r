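test_that("Matern 3/2 kernel matches its closed form", {
  expect_equal(matern32(0, 0, 0.3, 2.5)[1, 1], 2.5)
  # frozen closed-form value at r = lengthscale
  expect_equal(matern32(0, 0.1, 0.1, 1)[1, 1], (1 + sqrt(3)) * exp(-sqrt(3)))
  expect_equal(matern32(0, 0.1, 0.1, 1)[1, 1], 0.4833578, tolerance = 1e-6)
  r <- seq(0, 5, by = 0.1)
  k <- matern32(0, r, 0.2, 1)[1, ]
  expect_true(all(diff(k) < 0))
  expect_lt(k[length(k)], 1e-8)
})

test_that("coregionalisation matrix is PSD, rank-1 + diagonal", {
  W <- rnorm(12); kap <- runif(12)
  B <- coregionalisation_matrix(W, kap)
  expect_equal(B, t(B))
  expect_true(all(eigen(B, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  expect_equal(coregionalisation_matrix(rep(0, 4), c(1, 2, 3, 4)),
               diag(c(1, 2, 3, 4)))
  expect_equal(sum(svd(outer(W, W))$d > 1e-10), 1L)
})

test_that("fitting exposes 38 hyperparameters for 12 tasks and is seed-deterministic", {
  gp <- tiny_gp()
  expect_equal(count_hyperparameters(gp), 38L)
  expect_equal(count_hyperparameters(gp$hyper), 2L + 3L * 12L)
  tasks <- assemble_tasks(tiny_corpus(), n_points = 25L)
  gp2 <- fit_gp(tasks, seed = 3, restarts = 2, max_points = 220L, maxit = 120L)
  expect_identical(gp$hyper, gp2$hyper)
  expect_equal(gp$lml, gp2$lml)
})

test_that("posterior interpolates low-noise synthetic tasks near the data", {
  gp <- tiny_gp()
  for (tid in c(9L, 11L)) {
    xs <- gp$x[gp$t == tid]
    ys <- gp$y[gp$t == tid] + gp$centers[tid]
    po <- posterior(gp, tid, xs)
    noise_sd <- sqrt(gp$hyper$noise_var[tid])
    expect_true(all(abs(po$mean - ys) < 2 * (noise_sd + 0.25)))
    expect_true(all(po$sd >= 0))
  }
})

test_that("exact GP conditioning on a noise-free toy task reproduces targets", {
  # 1 task, smooth low-noise data: compare against hand-rolled
  # single-task GP conditioning algebra
  x <- seq(0.8, 1.2, length.out = 9)
  y <- sin(4 * x)
  tk <- list(structure(list(task_id = 1L, study_type = "MRE", region = "grey",
                            x = x, y = y, model_id = rep("a", 9)),
                       class = "task_dataset"))
  gp <- fit_gp(tk, seed = 1, restarts = 3, maxit = 300L, center = FALSE)
  po <- posterior(gp, 1L, x)
  expect_equal(po$mean, y, tolerance = 0.05)
  # independent conditioning oracle with the fitted hyperparameters
  h <- gp$hyper
  B11 <- h$W[1]^2 + h$kappa[1]
  K <- B11 * matern32(x, x, h$lengthscale, h$variance) +
    diag(h$noise_var[1], length(x))
  xq <- seq(0.85, 1.15, length.out = 7)
  ks <- B11 * matern32(xq, x, h$lengthscale, h$variance)
  oracle_mean <- drop(ks %*% solve(K, y))
  po_q <- posterior(gp, 1L, xq)
  expect_equal(po_q$mean, oracle_mean, tolerance = 1e-5)
  oracle_var <- B11 * h$variance - diag(ks %*% solve(K, t(ks)))
  expect_equal(po_q$sd^2, pmax(oracle_var, 0), tolerance = 1e-5)
  # posterior SD shrinks at the data vs far extrapolation
  far <- posterior(gp, 1L, 3.0)
  expect_gt(far$sd[1], max(po$sd))
})

test_that("offset sampling is the exponentiated envelope, monotone in s", {
  gp <- tiny_gp()
  grid <- seq(0.8, 1.3, length.out = 40)
  c0 <- sample_offset(gp, 11L, grid, 0)
  po <- posterior(gp, 11L, grid)
  expect_equal(c0$energies, pmax(exp(po$mean) - gp$log_offset, 0))
  cm <- sample_offset(gp, 11L, grid, -2)
  cp <- sample_offset(gp, 11L, grid, 2)
  expect_true(all(cp$energies >= c0$energies))
  expect_true(all(c0$energies >= cm$energies))
  expect_length(offset_grid(), 9L)
  curves <- lapply(offset_grid(), function(s) sample_offset(gp, 11L, grid, s))
  expect_length(curves, 9L)
})

test_that("cross-task coupling borrows strength for a sparse task", {
  # two strongly correlated tasks; the sparse one must have lower posterior
  # SD at stretches covered only by the dense one than an isolated task
  set.seed(21)
  xd <- seq(0.8, 1.2, length.out = 30)
  f <- function(x) 2 * (x - 1)
  dense <- structure(list(task_id = 1L, study_type = "MRE", region = "grey",
                          x = xd, y = f(xd) + rnorm(30, 0, 0.01),
                          model_id = rep("d", 30)), class = "task_dataset")
  sparse <- structure(list(task_id = 2L, study_type = "MRE", region = "white",
                           x = c(0.8, 1.2), y = f(c(0.8, 1.2)),
                           model_id = rep("s", 2)), class = "task_dataset")
  gp2 <- fit_gp(list(dense, sparse), seed = 2, restarts = 3, center = FALSE)
  sparse1 <- sparse; sparse1$task_id <- 1L
  lone <- fit_gp(list(sparse1), seed = 2, restarts = 3, center = FALSE)
  sd_coupled <- posterior(gp2, 2L, 1.0)$sd
  sd_alone <- posterior(lone, 1L, 1.0)$sd
  expect_lt(sd_coupled, sd_alone)
})

test_that("joint covariance admits a Cholesky with bounded jitter", {
  gp <- tiny_gp()
  K <- elastogen:::gp_cov_train(gp$hyper, gp$x, gp$t)
  expect_equal(K, t(K), tolerance = 1e-12)
  ch <- elastogen:::chol_jitter(K)
  expect_lte(ch$jitter, 1e-6 * mean(diag(K)))
})

test_that("GP serialisation round-trips posterior predictions", {
  gp <- tiny_gp()
  path <- withr::local_tempfile(fileext = ".json")
  write_gp_json(gp, path)
  gp2 <- read_gp_json(path)
  grid <- seq(0.9, 1.2, length.out = 11)
  po1 <- posterior(gp, 11L, grid)
  po2 <- posterior(gp2, 11L, grid)
  expect_equal(po1$mean, po2$mean, tolerance = 1e-6)
  expect_equal(po1$sd, po2$sd, tolerance = 1e-5)
})
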