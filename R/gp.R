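#' Matern 3/2 covariance
#'
#' \eqn{k(x, x') = \sigma^2 (1 + \sqrt{3} r / \ell) \exp(-\sqrt{3} r /
#' \ell)} with \eqn{r = |x - x'|}; once-differentiable sample paths, which
#' suits energy curves that bend sharply near the rest configuration.
#'
#' @param x,xp numeric vectors of inputs (stretch units).
#' @param lengthscale kernel length scale, > 0.
#' @param variance kernel variance, > 0 ((ln Psi)^2 units here).
#' @return `length(x)` x `length(xp)` covariance matrix.
#' @export
matern32 <- function(x, xp, lengthscale, variance) {
  stopifnot(lengthscale > 0, variance > 0)
  r <- abs(outer(x, xp, "-")) * (sqrt(3) / lengthscale)
  variance * (1 + r) * exp(-r)
}

#' Intrinsic coregionalisation matrix
#'
#' \eqn{B = W W^T + diag(\kappa)} with rank-1 task coefficients `W`;
#' symmetric positive semidefinite by construction.
#'
#' @param W numeric task-coefficient vector (one entry per task).
#' @param kappa non-negative per-task variance vector, same length.
#' @return T x T matrix B.
#' @export
coregionalisation_matrix <- function(W, kappa) {
  stopifnot(length(W) == length(kappa), all(kappa >= 0))
  outer(W, W) + diag(kappa, length(kappa))
}

# pack/unpack the 38 hyperparameters (T = 12):
# log lengthscale, log kernel variance, W (T), log kappa (T), log noise (T)
gp_pack <- function(h) {
  c(log(h$lengthscale), log(h$variance), h$W, log(h$kappa), log(h$noise_var))
}

gp_unpack <- function(theta, T) {
  list(lengthscale = exp(theta[1]), variance = exp(theta[2]),
       W = theta[2 + seq_len(T)],
       kappa = exp(theta[2 + T + seq_len(T)]),
       noise_var = exp(theta[2 + 2 * T + seq_len(T)]))
}

#' Number of free hyperparameters of a trained GP
#'
#' Kernel length scale and variance plus three per-task vectors (task
#' coefficients W, task variances kappa, noise variances): `2 + 3 T`,
#' i.e. 38 for the 12-task model.
#'
#' @param gp a `trained_gp` or an hyperparameter list.
#' @return integer count.
#' @export
count_hyperparameters <- function(gp) {
  h <- if (inherits(gp, "trained_gp")) gp$hyper else gp
  2L + length(h$W) + length(h$kappa) + length(h$noise_var)
}

gp_cov_train <- function(h, x, t) {
  B <- coregionalisation_matrix(h$W, h$kappa)
  K <- matern32(x, x, h$lengthscale, h$variance) * B[t, t, drop = FALSE]
  diag(K) <- diag(K) + h$noise_var[t]
  K
}

chol_jitter <- function(K) {
  scale <- mean(diag(K))
  for (j in c(0, 1e-10, 1e-8, 1e-6)) {
    L <- tryCatch(chol(K + diag(j * scale, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j * scale))
  }
  stop("joint covariance is singular even after maximal jitter")
}

gp_nll <- function(theta, x, y, t, T) {
  h <- gp_unpack(theta, T)
  K <- gp_cov_train(h, x, t)
  ch <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  val <- 0.5 * sum(y * a) + sum(log(diag(ch$L))) + 0.5 * length(y) * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

#' Fit the multi-task GP over log energy curves
#'
#' Maximises the log marginal likelihood of the intrinsic
#' coregionalisation model: the joint covariance over all task
#' observations is \eqn{B \otimes K + diag(\sigma_t^2)} restricted to the
#' observed (task, stretch) pairs, with a Matern 3/2 within-task kernel
#' and \eqn{B = W W^T + diag(\kappa)} across tasks. Targets are
#' `ln(Psi + 0.001)`, optionally recentred per task (the shift is stored
#' and undone at prediction). Gradient-based local optimisation with
#' random restarts; 38 free scalars for 12 tasks.
#'
#' @param tasks list of task datasets from [assemble_tasks()].
#' @param seed RNG seed controlling restart initialisation.
#' @param restarts number of optimiser restarts (best kept).
#' @param max_points cap on total training points; each task's points are
#'   thinned evenly to fit (dense Cholesky cost is cubic in this number).
#' @param center recentre targets per task before fitting.
#' @param maxit optimiser iteration cap per restart.
#' @return a `trained_gp` with hyperparameters, retained training data,
#'   Cholesky factors, and the best log marginal likelihood `lml`.
#' @export
fit_gp <- function(tasks, seed = 1L, restarts = 3L, max_points = 600L,
                   center = TRUE, maxit = 150L) {
  T <- length(tasks)
  n_all <- sum(vapply(tasks, function(tk) length(tk$x), 1L))
  if (n_all == 0L) stop("at least one task must contain data")
  frac <- min(1, max_points / n_all)
  x <- y <- numeric(0); t <- integer(0)
  for (tk in tasks) {
    n <- length(tk$x)
    if (n == 0L) next
    keep <- unique(round(seq(1L, n, length.out = max(2L, ceiling(n * frac)))))
    x <- c(x, tk$x[keep]); y <- c(y, tk$y[keep])
    t <- c(t, rep(tk$task_id, length(keep)))
  }
  centers <- rep(0, T)
  if (center) {
    for (ti in unique(t)) centers[ti] <- mean(y[t == ti])
    y <- y - centers[t]
  }
  xr <- max(diff(range(x)), 1e-3)
  lower <- c(log(1e-4), log(1e-8), rep(-10, T), rep(log(1e-8), 2 * T))
  upper <- c(log(10), log(1e4), rep(10, T), rep(log(1e4), 2 * T))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- list(lengthscale = xr * runif(1, 0.2, 1),
                 variance = stats::var(y) * runif(1, 0.5, 2) + 1e-3,
                 W = rnorm(T, 0, 0.5),
                 kappa = rep(stats::var(y) / 2 + 1e-3, T) * runif(T, 0.5, 2),
                 noise_var = rep(max(stats::var(y) / 10, 1e-4), T))
    theta0 <- pmin(pmax(gp_pack(init), lower), upper)
    opt <- tryCatch(
      optim(theta0, gp_nll, x = x, y = y, t = t, T = T,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("GP hyperparameter optimisation failed in all restarts")
  h <- gp_unpack(best$par, T)
  K <- gp_cov_train(h, x, t)
  ch <- chol_jitter(K)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  structure(list(hyper = h, x = x, y = y, t = t, centers = centers,
                 L = ch$L, alpha = alpha, lml = -best$value,
                 n_tasks = T, log_offset = LOG_OFFSET),
            class = "trained_gp")
}

#' @exportS3Method base::print
print.trained_gp <- function(x, ...) {
  cat(sprintf("trained ICM GP: %d tasks, %d training points, %d hyperparameters, lml = %.2f\n",
              x$n_tasks, length(x$x), count_hyperparameters(x), x$lml))
  invisible(x)
}

#' Posterior of a task's log energy function
#'
#' Standard GP conditioning of the joint normal on the training data:
#' returns the posterior mean and standard deviation of the latent task
#' function (excluding observation noise) at the query stretches.
#'
#' @param gp a `trained_gp`.
#' @param task_id integer task id (1..12).
#' @param query_stretches numeric vector of stretches.
#' @return list with `mean` and `sd` vectors (log-energy units).
#' @export
posterior <- function(gp, task_id, query_stretches) {
  stopifnot(inherits(gp, "trained_gp"),
            task_id >= 1, task_id <= gp$n_tasks)
  h <- gp$hyper
  B <- coregionalisation_matrix(h$W, h$kappa)
  ks <- matern32(query_stretches, gp$x, h$lengthscale, h$variance) *
    matrix(B[task_id, gp$t], nrow = length(query_stretches),
           ncol = length(gp$x), byrow = TRUE)
  mean <- drop(ks %*% gp$alpha) + gp$centers[task_id]
  v <- forwardsolve(t(gp$L), t(ks))
  var <- pmax(B[task_id, task_id] * h$variance - colSums(v^2), 0)
  list(mean = mean, sd = sqrt(var))
}

#' Sample an energy curve at a fixed SD offset
#'
#' The generative model's samples are envelope offsets of the posterior:
#' `Psi(lambda) = exp(mean + s * sd) - 0.001` (clamped at 0) on the query
#' grid, with `s` in SD units (the `+-2 SD` sweep of the recovery
#' pipeline). The SD is predictive (latent posterior variance plus the
#' task's observation-noise variance), so the `+-2 SD` band covers the
#' spread of the literature models feeding the task rather than only the
#' uncertainty of the posterior mean. `s = 0` returns the exponentiated
#' posterior mean.
#'
#' @inheritParams posterior
#' @param s SD offset, typically in `[-2, 2]`.
#' @param include_noise use the predictive SD (default `TRUE`); `FALSE`
#'   offsets by the latent posterior SD only.
#' @return an `energy_curve` on the query grid (energies in Pa, >= 0).
#' @export
sample_offset <- function(gp, task_id, query_stretches, s,
                          include_noise = TRUE) {
  stopifnot(length(s) == 1L, is.finite(s))
  po <- posterior(gp, task_id, query_stretches)
  sd <- if (include_noise)
    sqrt(po$sd^2 + gp$hyper$noise_var[task_id]) else po$sd
  e <- pmax(exp(po$mean + s * sd) - gp$log_offset, 0)
  energy_curve(query_stretches, e)
}

#' Draw correlated posterior sample curves
#'
#' Alternative to the envelope offsets of [sample_offset()]: full
#' correlated function draws from the task posterior.
#'
#' @inheritParams posterior
#' @param n number of draws.
#' @param seed RNG seed.
#' @return list of `energy_curve`s.
#' @export
sample_posterior_draws <- function(gp, task_id, query_stretches, n = 1L,
                                   seed = 1L) {
  h <- gp$hyper
  B <- coregionalisation_matrix(h$W, h$kappa)
  ks <- matern32(query_stretches, gp$x, h$lengthscale, h$variance) *
    matrix(B[task_id, gp$t], nrow = length(query_stretches),
           ncol = length(gp$x), byrow = TRUE)
  mean <- drop(ks %*% gp$alpha) + gp$centers[task_id]
  Kss <- matern32(query_stretches, query_stretches, h$lengthscale, h$variance) *
    B[task_id, task_id]
  v <- forwardsolve(t(gp$L), t(ks))
  Sig <- Kss - crossprod(v)
  Sig <- (Sig + t(Sig)) / 2
  ev <- eigen(Sig, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Sig))
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    f <- mean + drop(A %*% rnorm(length(query_stretches)))
    energy_curve(query_stretches, pmax(exp(f) - gp$log_offset, 0))
  })
}

#' Serialise / load a trained GP as JSON
#'
#' Stores the hyperparameters, retained training data and per-task
#' centres; the Cholesky factor is rebuilt on load.
#'
#' @param gp a `trained_gp`.
#' @param path JSON file path.
#' @return `write_gp_json` returns `path` invisibly; `read_gp_json` the
#'   reconstructed `trained_gp`.
#' @export
write_gp_json <- function(gp, path) {
  obj <- list(hyper = gp$hyper, x = gp$x, y = gp$y, t = gp$t,
              centers = gp$centers, lml = gp$lml, n_tasks = gp$n_tasks,
              log_offset = gp$log_offset)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_gp_json
#' @export
read_gp_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  h <- list(lengthscale = as.numeric(obj$hyper$lengthscale),
            variance = as.numeric(obj$hyper$variance),
            W = as.numeric(obj$hyper$W),
            kappa = as.numeric(obj$hyper$kappa),
            noise_var = as.numeric(obj$hyper$noise_var))
  x <- as.numeric(obj$x); y <- as.numeric(obj$y); t <- as.integer(obj$t)
  K <- gp_cov_train(h, x, t)
  ch <- chol_jitter(K)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  structure(list(hyper = h, x = x, y = y, t = t,
                 centers = as.numeric(obj$centers), L = ch$L, alpha = alpha,
                 lml = as.numeric(obj$lml), n_tasks = as.integer(obj$n_tasks),
                 log_offset = as.numeric(obj$log_offset)),
            class = "trained_gp")
}
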