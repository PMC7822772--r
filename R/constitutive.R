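#' @useDynLib elastogen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim runif rnorm median setNames kruskal.test pairwise.wilcox.test sd
#' @importFrom utils read.csv write.csv modifyList
NULL

FAMILIES <- c("NH", "MR", "O1", "O8")

as_stretch <- function(s) {
  if (is.null(dim(s))) {
    stopifnot(length(s) == 3L)
    s <- matrix(s, nrow = 1L)
  }
  if (ncol(s) != 3L) stop("a stretch triplet has exactly 3 components")
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("principal stretches must be finite and strictly positive")
  }
  s
}

check_params <- function(family, params) {
  family <- match.arg(family, FAMILIES)
  p <- as.list(params)
  switch(family,
    NH = stopifnot(is.finite(p$mu)),
    MR = stopifnot(is.finite(p$c1), is.finite(p$c2)),
    O1 = {
      stopifnot(is.finite(p$mu1), is.finite(p$alpha1))
      if (p$alpha1 == 0) stop("Ogden exponent alpha1 must be nonzero")
    },
    O8 = stopifnot(length(p$mu) == length(p$alpha), all(p$alpha != 0))
  )
  p
}

#' Neo-Hookean strain energy density
#'
#' \eqn{\Psi_{NH} = \mu/2 (\lambda_1^2 + \lambda_2^2 + \lambda_3^2 - 3)},
#' the one-parameter incompressible neo-Hookean potential. Zero at the
#' identity configuration.
#'
#' @param stretch principal stretch triplet (length-3 vector, all > 0) or an
#'   n x 3 matrix of triplets.
#' @param mu shear modulus in Pa.
#' @return energy density in Pa (J/m^3), one value per triplet.
#' @export
#' @examples
#' psi_nh(c(1.1, 1.1^-0.5, 1.1^-0.5), mu = 333.28)
psi_nh <- function(stretch, mu) {
  s <- as_stretch(stretch)
  drop(mu / 2 * (rowSums(s^2) - 3))
}

#' Mooney-Rivlin strain energy density
#'
#' \eqn{\Psi_{MR} = C_1(I_1 - 3) + C_2(I_2 - 3)} with the principal
#' invariants \eqn{I_1 = \sum \lambda_i^2} and
#' \eqn{I_2 = \sum_{i<j} \lambda_i^2 \lambda_j^2}. Reduces to neo-Hookean with
#' \eqn{\mu = 2 C_1} when \eqn{C_2 = 0}.
#'
#' @inheritParams psi_nh
#' @param c1,c2 Mooney-Rivlin coefficients in Pa.
#' @return energy density in Pa.
#' @export
psi_mr <- function(stretch, c1, c2) {
  s <- as_stretch(stretch)^2
  i1 <- rowSums(s)
  i2 <- s[, 1] * s[, 2] + s[, 2] * s[, 3] + s[, 3] * s[, 1]
  unname(drop(c1 * (i1 - 3) + c2 * (i2 - 3)))
}

#' One-term Ogden strain energy density
#'
#' \eqn{\Psi_{O_1} = \mu_1/\alpha_1 (\lambda_1^{\alpha_1} +
#' \lambda_2^{\alpha_1} + \lambda_3^{\alpha_1} - 3)}. Drucker stability
#' requires \eqn{\mu_1 \alpha_1 > 0}; brain-tissue literature typically
#' reports negative exponents (with negative \eqn{\mu_1}).
#'
#' @inheritParams psi_nh
#' @param mu1 Ogden modulus in Pa.
#' @param alpha1 dimensionless exponent, nonzero.
#' @return energy density in Pa.
#' @export
psi_ogden1 <- function(stretch, mu1, alpha1) {
  if (alpha1 == 0) stop("Ogden exponent alpha1 must be nonzero")
  s <- as_stretch(stretch)
  drop(mu1 / alpha1 * (rowSums(s^alpha1) - 3))
}

psi_ogden_multi <- function(stretch, mu, alpha) {
  s <- as_stretch(stretch)
  out <- 0
  for (p in seq_along(mu)) {
    out <- out + mu[p] / alpha[p] * (rowSums(s^alpha[p]) - 3)
  }
  drop(out)
}

#' Evaluate a strain energy density family
#'
#' Dispatcher over the supported families: `"NH"` (`mu`), `"MR"` (`c1`,
#' `c2`), `"O1"` (`mu1`, `alpha1`) and the multi-term `"O8"` (`mu`, `alpha`
#' vectors; used only as a hard test-data family, never fitted).
#'
#' @param family one of `"NH"`, `"MR"`, `"O1"`, `"O8"`.
#' @param params named list of the family's parameters (Pa / dimensionless).
#' @inheritParams psi_nh
#' @return energy density in Pa.
#' @export
psi <- function(family, params, stretch) {
  p <- check_params(family, params)
  switch(match.arg(family, FAMILIES),
    NH = psi_nh(stretch, p$mu),
    MR = psi_mr(stretch, p$c1, p$c2),
    O1 = psi_ogden1(stretch, p$mu1, p$alpha1),
    O8 = psi_ogden_multi(stretch, p$mu, p$alpha)
  )
}

#' Gradient of the energy density w.r.t. the principal stretches
#'
#' Analytic \eqn{\partial\Psi/\partial\lambda_i}; used by the SVD-based
#' first Piola-Kirchhoff stress in the FEM and checkable against central
#' finite differences.
#'
#' @inheritParams psi
#' @param stretch a single length-3 stretch triplet.
#' @return numeric length-3 gradient in Pa.
#' @export
psi_gradient <- function(family, params, stretch) {
  p <- check_params(family, params)
  l <- drop(as_stretch(stretch))
  switch(match.arg(family, FAMILIES),
    NH = p$mu * l,
    MR = {
      l2 <- l^2
      other <- sum(l2) - l2
      2 * p$c1 * l + 2 * p$c2 * l * other
    },
    O1 = p$mu1 * l^(p$alpha1 - 1),
    O8 = {
      g <- numeric(3)
      for (k in seq_along(p$mu)) g <- g + p$mu[k] * l^(p$alpha[k] - 1)
      g
    }
  )
}

#' Hessian of the energy density w.r.t. the principal stretches
#'
#' @inheritParams psi_gradient
#' @return symmetric 3 x 3 matrix in Pa.
#' @export
psi_hessian <- function(family, params, stretch) {
  p <- check_params(family, params)
  l <- drop(as_stretch(stretch))
  switch(match.arg(family, FAMILIES),
    NH = diag(p$mu, 3),
    MR = {
      l2 <- l^2
      other <- sum(l2) - l2
      h <- 4 * p$c2 * outer(l, l)
      diag(h) <- 2 * p$c1 + 2 * p$c2 * other
      h
    },
    O1 = diag(p$mu1 * (p$alpha1 - 1) * l^(p$alpha1 - 2), 3),
    O8 = {
      d <- numeric(3)
      for (k in seq_along(p$mu)) {
        d <- d + p$mu[k] * (p$alpha[k] - 1) * l^(p$alpha[k] - 2)
      }
      diag(d, 3)
    }
  )
}

#' Uniaxial stretch triplet under incompressibility
#'
#' For a uniaxial tension/compression test at stretch \eqn{\lambda} the
#' lateral stretches of an incompressible material are
#' \eqn{\lambda^{-1/2}}, so the triplet is
#' \eqn{(\lambda, \lambda^{-1/2}, \lambda^{-1/2})} (isochoric by
#' construction).
#'
#' @param l scalar or vector of axial stretches, > 0.
#' @return an n x 3 matrix of stretch triplets (n = length(l)).
#' @export
uniaxial_stretch <- function(l) {
  if (any(!is.finite(l)) || any(l <= 0)) stop("stretch must be positive")
  cbind(l1 = l, l2 = l^(-0.5), l3 = l^(-0.5))
}

#' Uniaxial energy of a family at axial stretches
#'
#' Convenience wrapper: `psi(family, params, uniaxial_stretch(l))`.
#'
#' @inheritParams psi
#' @param l axial stretch(es), > 0.
#' @return energy densities in Pa.
#' @export
uniaxial_psi <- function(family, params, l) {
  psi(family, params, uniaxial_stretch(l))
}

#' Convert linear-elastic constants to a neo-Hookean shear modulus
#'
#' Small-strain identification \eqn{\mu = E / (2(1 + \nu))}; used to
#' reformulate linear-study records as hyperelastic models.
#'
#' @param youngs_E Young's modulus in Pa, > 0.
#' @param poisson_nu Poisson ratio in (-1, 0.5).
#' @return list with element `mu` (Pa).
#' @export
linear_to_nh <- function(youngs_E, poisson_nu) {
  stopifnot(youngs_E > 0, poisson_nu > -1, poisson_nu < 0.5)
  list(mu = youngs_E / (2 * (1 + poisson_nu)))
}

#' Convert an MRE storage modulus to a neo-Hookean shear modulus
#'
#' Magnetic resonance elastography reports the shear storage modulus G';
#' at small strain this is identified directly with \eqn{\mu}.
#'
#' @param storage_modulus G' in Pa, > 0.
#' @return list with element `mu` (Pa).
#' @export
mre_to_nh <- function(storage_modulus) {
  stopifnot(is.finite(storage_modulus), storage_modulus > 0)
  list(mu = storage_modulus)
}

#' Check convexity and Drucker stability of a constitutive model
#'
#' Two layers: the family's algebraic convexity conditions
#' (NH: \eqn{\mu>0}; MR: \eqn{C_1>0, C_2\ge 0}; Ogden:
#' \eqn{\mu_1\alpha_1>0}) and a numerical Drucker criterion — the uniaxial
#' energy must be non-decreasing in \eqn{|\lambda - 1|} on a dense grid over
#' the window. Never raises for unstable parameters; returns a report.
#'
#' @inheritParams psi
#' @param window stretch interval containing 1.0 (default `c(0.5, 1.5)`).
#' @param n_grid grid points for the Drucker scan (default 201).
#' @return a `stability_report` list: `convex_ok`, `drucker_ok`, `stable`
#'   (both), and `violations` (data.frame of offending stretches).
#' @export
check_stability <- function(family, params, window = c(0.5, 1.5), n_grid = 201L) {
  family <- match.arg(family, FAMILIES)
  p <- check_params(family, params)
  stopifnot(window[1] < 1, window[2] > 1)
  convex_ok <- switch(family,
    NH = p$mu > 0,
    MR = p$c1 > 0 && p$c2 >= 0,
    O1 = p$mu1 * p$alpha1 > 0,
    O8 = all(p$mu * p$alpha > 0)
  )
  grid <- sort(unique(c(seq(window[1], window[2], length.out = n_grid), 1)))
  e <- uniaxial_psi(family, p, grid)
  viol <- data.frame(stretch = numeric(0), description = character(0))
  # energy must grow (weakly) moving away from lambda = 1 in either direction
  comp <- rev(grid[grid <= 1]); comp_e <- rev(e[grid <= 1])
  tens <- grid[grid >= 1];      tens_e <- e[grid >= 1]
  tol <- 1e-10 * max(1, max(abs(e)))
  bad_c <- which(diff(comp_e) < -tol)
  bad_t <- which(diff(tens_e) < -tol)
  if (length(bad_c)) {
    viol <- rbind(viol, data.frame(
      stretch = comp[bad_c + 1L],
      description = "energy decreases with increasing compression"))
  }
  if (length(bad_t)) {
    viol <- rbind(viol, data.frame(
      stretch = tens[bad_t + 1L],
      description = "energy decreases with increasing tension"))
  }
  drucker_ok <- nrow(viol) == 0L
  structure(list(convex_ok = convex_ok, drucker_ok = drucker_ok,
                 stable = convex_ok && drucker_ok, violations = viol,
                 window = window),
            class = "stability_report")
}

#' @exportS3Method base::print
print.stability_report <- function(x, ...) {
  cat(sprintf("stability report on [%g, %g]: convex=%s drucker=%s (%d violations)\n",
              x$window[1], x$window[2], x$convex_ok, x$drucker_ok,
              nrow(x$violations)))
  invisible(x)
}
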