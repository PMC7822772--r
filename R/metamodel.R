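META_FAMILIES <- c("NH", "MR", "O_hi", "O_lo")
OGDEN_SPLIT <- -5.0 # alpha1 partition between the two Ogden meta-models

#' Default meta-model fit configuration
#'
#' Bounds enforce each family's stability conditions: NH mu in [1, 1e5]
#' Pa; MR C1 in [0.5, 5e4], C2 in [0, 5e4] Pa; Ogden with high exponent
#' (alpha1 >= -5) mu1 in [1, 1e5] with alpha1 in (0, 30] or mu1 in
#' [-1e5, -1] with alpha1 in [-5, 0) (two stable branches so that
#' mu1*alpha1 > 0 always holds); Ogden with low exponent mu1 in
#' [-1e5, -1], alpha1 in [-30, -5). The spanned moduli cover reported
#' brain stiffness from tens of Pa to tens of kPa.
#'
#' @param family one of `"NH"`, `"MR"`, `"O_hi"`, `"O_lo"`.
#' @param log_offset offset inside the log residual (Pa, default 0.001).
#' @param max_iter,tolerance optimiser controls.
#' @return a `meta_fit_config` list (with a `branches` element holding one
#'   or two boxed parameter spaces).
#' @export
meta_fit_config <- function(family, log_offset = 0.001, max_iter = 200L,
                            tolerance = 1e-12) {
  family <- match.arg(family, META_FAMILIES)
  stopifnot(log_offset > 0)
  branches <- switch(family,
    NH = list(list(lower = c(mu = 1), upper = c(mu = 1e5))),
    MR = list(list(lower = c(c1 = 0.5, c2 = 0), upper = c(c1 = 5e4, c2 = 5e4))),
    O_hi = list(
      list(lower = c(mu1 = 1, alpha1 = 0.05), upper = c(mu1 = 1e5, alpha1 = 30)),
      list(lower = c(mu1 = -1e5, alpha1 = OGDEN_SPLIT),
           upper = c(mu1 = -1, alpha1 = -0.05))),
    O_lo = list(list(lower = c(mu1 = -1e5, alpha1 = -30),
                     upper = c(mu1 = -1, alpha1 = OGDEN_SPLIT - 1e-6))))
  structure(list(family = family, branches = branches,
                 log_offset = log_offset, max_iter = as.integer(max_iter),
                 tolerance = tolerance),
            class = "meta_fit_config")
}

meta_psi <- function(family, par, l3) {
  switch(family,
    NH = psi_nh(l3, par[["mu"]]),
    MR = psi_mr(l3, par[["c1"]], par[["c2"]]),
    psi_ogden1(l3, par[["mu1"]], par[["alpha1"]]))
}

# d Psi / d theta, one column per parameter, rows = curve points
meta_psi_jac <- function(family, par, l3) {
  switch(family,
    NH = cbind(mu = (rowSums(l3^2) - 3) / 2),
    MR = {
      s <- l3^2
      cbind(c1 = rowSums(s) - 3,
            c2 = s[, 1] * s[, 2] + s[, 2] * s[, 3] + s[, 3] * s[, 1] - 3)
    },
    {
      a <- par[["alpha1"]]; m <- par[["mu1"]]
      S <- rowSums(l3^a) - 3
      dS <- rowSums(l3^a * log(l3))
      cbind(mu1 = S / a, alpha1 = m * dS / a - m * S / a^2)
    })
}

#' Fit a stable hyperelastic meta-model to an energy curve
#'
#' Bounded least squares on the log residuals
#' \eqn{r_i = \ln(\Psi_{model}(\lambda_i) + 0.001) - \ln(\Psi_i + 0.001)}
#' with the analytic Jacobian, multi-start (box midpoint plus log-spaced
#' extremes) to avoid the narrow-valley pathology of hyperelastic
#' calibration. The returned parameters always satisfy the family's
#' stability bounds and are additionally scanned with [check_stability()]
#' on the wider `[0.5, 1.5]` window, so predictions remain valid beyond
#' the sampled strain range.
#'
#' @param curve an `energy_curve` (energies > -log_offset everywhere).
#' @param cfg a [meta_fit_config()] or a family name.
#' @return a `meta_fit_result`: `family`, `params` (named list), `cost`
#'   (sum of squared log residuals), `converged`, `stability`.
#' @export
fit_metamodel <- function(curve, cfg) {
  if (is.character(cfg)) cfg <- meta_fit_config(cfg)
  stopifnot(inherits(curve, "energy_curve"), inherits(cfg, "meta_fit_config"))
  off <- cfg$log_offset
  if (any(curve$energies <= -off)) stop("curve energies must exceed -log_offset")
  l3 <- uniaxial_stretch(curve$stretches)
  zi <- log(curve$energies + off)
  fam <- cfg$family
  resid_fn <- function(par) {
    r <- log(pmax(meta_psi(fam, par, l3) + off, 1e-300)) - zi
    if (any(!is.finite(r))) stop("non-finite residuals in meta-model fit")
    r
  }
  jac_fn <- function(par) {
    meta_psi_jac(fam, par, l3) / pmax(meta_psi(fam, par, l3) + off, 1e-300)
  }
  starts_for <- function(lo, hi) {
    # geometric interior points of the box, sign-aware
    mk <- function(f) mapply(function(l, h, fr) {
      if (l > 0) exp(log(l) + fr * (log(h) - log(l)))
      else if (h < 0) -exp(log(-h) + fr * (log(-l) - log(-h)))
      else l + fr * (h - l)
    }, lo, hi, MoreArgs = list(fr = f))
    list(mk(0.5), mk(0.15), mk(0.85))
  }
  best <- NULL
  for (br in cfg$branches) {
    for (p0 in starts_for(br$lower, br$upper)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p0, lower = br$lower, upper = br$upper,
                           fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = cfg$max_iter, ftol = cfg$tolerance,
                             ptol = cfg$tolerance)),
        error = function(e) NULL)
      if (is.null(fit)) next
      cost <- sum(resid_fn(fit$par)^2)
      if (is.null(best) || cost < best$cost) {
        best <- list(par = fit$par, cost = cost, info = fit$info)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(family = fam, params = NULL, cost = Inf,
                          converged = FALSE, stability = NULL),
                     class = "meta_fit_result"))
  }
  params <- as.list(best$par)
  cfamily <- if (fam %in% c("O_hi", "O_lo")) "O1" else fam
  stab <- check_stability(cfamily, params, window = c(0.5, 1.5))
  structure(list(family = fam, params = params, cost = best$cost,
                 converged = best$info %in% c(1L, 2L, 3L, 4L), stability = stab),
            class = "meta_fit_result")
}

#' @exportS3Method base::print
print.meta_fit_result <- function(x, ...) {
  cat(sprintf("meta-model %s: cost %.3g, converged %s, params (%s)\n",
              x$family, x$cost, x$converged,
              paste(sprintf("%s=%.4g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Fit all four meta-model families to a curve
#'
#' Neo-Hookean, Mooney-Rivlin and the two one-term Ogden meta-models
#' (exponent above/below -5). Ranking by final cost; ties broken by
#' preferring the family with fewer parameters.
#'
#' @inheritParams fit_metamodel
#' @param families subset of families to fit (default all four).
#' @param log_offset log-residual offset (Pa).
#' @return list with `fits` (per family), `ranking` (family names, best
#'   first), and `costs`.
#' @export
fit_all_families <- function(curve, families = META_FAMILIES,
                             log_offset = 0.001) {
  fits <- lapply(families, function(f)
    fit_metamodel(curve, meta_fit_config(f, log_offset = log_offset)))
  names(fits) <- families
  costs <- vapply(fits, function(f) f$cost, 1.0)
  npar <- vapply(fits, function(f) length(f$params), 1L)
  ranking <- families[order(costs, npar)]
  list(fits = fits, ranking = ranking, costs = costs)
}

#' Compare meta-model families across a corpus of curves
#'
#' Fits every family to every curve, then tests whether fit costs differ
#' across families with a Kruskal-Wallis rank test and
#' Bonferroni-corrected pairwise Wilcoxon comparisons.
#'
#' @param curves list of `energy_curve`s.
#' @param families families to compare.
#' @return list with the cost matrix (`curves` x `families`), the
#'   Kruskal-Wallis `H` statistic and `p` value, and the pairwise
#'   Bonferroni-adjusted p-value matrix.
#' @export
compare_costs <- function(curves, families = META_FAMILIES) {
  costs <- vapply(curves, function(cv)
    fit_all_families(cv, families)$costs, numeric(length(families)))
  costs <- t(matrix(costs, nrow = length(families),
                    dimnames = list(families, NULL)))
  long <- data.frame(cost = as.vector(costs),
                     family = factor(rep(families, each = nrow(costs)),
                                     levels = families))
  kw <- kruskal.test(cost ~ family, data = long)
  pw <- suppressWarnings(
    pairwise.wilcox.test(long$cost, long$family, p.adjust.method = "bonferroni"))
  list(costs = costs, H = unname(kw$statistic), p = kw$p.value,
       pairwise_p = pw$p.value)
}

#' Export meta-model fits as CSV rows
#'
#' @param fits list of `meta_fit_result`s.
#' @param path output CSV path.
#' @return path, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    data.frame(family = f$family,
               params_json = as.character(jsonlite::toJSON(f$params, digits = NA)),
               cost = f$cost, converged = f$converged,
               stable = if (is.null(f$stability)) NA else f$stability$stable)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
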