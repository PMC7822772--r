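STUDY_TYPES <- c("MRE", "linear", "hyperelastic")
REGIONS <- c("grey", "white", "healthy", "abnormal")
LOG_OFFSET <- 0.001 # Pa, offset used throughout for log-energy targets

#' Construct a literature-style constitutive model record
#'
#' One record of the characterisation corpus: which kind of study produced
#' it (MRE, linear, or hyperelastic mechanical testing), the tissue region,
#' the constitutive family with its parameters, and the stretch range over
#' which the study observed the tissue. MRE and linear records are stored
#' already reformulated as neo-Hookean models (see [mre_to_nh()],
#' [linear_to_nh()]).
#'
#' @param id character identifier.
#' @param study_type one of `"MRE"`, `"linear"`, `"hyperelastic"`.
#' @param region one of `"grey"`, `"white"`, `"healthy"`, `"abnormal"`.
#' @param family one of `"NH"`, `"MR"`, `"O1"`, `"O8"`.
#' @param params named list of family parameters.
#' @param stretch_range length-2 numeric, min < max, straddling/touching 1.
#' @param params_tension optional second parameter set used for the tension
#'   side (`stretch > 1`) when a study reports separate
#'   compression/tension fits.
#' @return a `literature_model` list.
#' @export
literature_model <- function(id, study_type, region, family, params,
                             stretch_range, params_tension = NULL) {
  study_type <- match.arg(study_type, STUDY_TYPES)
  region <- match.arg(region, REGIONS)
  family <- match.arg(family, FAMILIES)
  check_params(family, params)
  if (!is.null(params_tension)) check_params(family, params_tension)
  stopifnot(length(stretch_range) == 2L,
            stretch_range[1] < stretch_range[2],
            stretch_range[1] <= 1, stretch_range[2] >= 1,
            stretch_range[1] > 0)
  structure(list(id = as.character(id), study_type = study_type,
                 region = region, family = family, params = params,
                 stretch_range = as.numeric(stretch_range),
                 params_tension = params_tension),
            class = "literature_model")
}

#' Discretise a constitutive model into an energy curve
#'
#' Evaluates the model's uniaxial energy on a uniform stretch grid over its
#' reported stretch range. When the record carries a separate tension
#' parameter set, compression points (`stretch < 1`) use `params` and
#' tension points use `params_tension`.
#'
#' @param m a [literature_model()].
#' @param n_points number of interpolation points (default 100).
#' @return an `energy_curve`: list with `stretches` (increasing) and
#'   `energies` (Pa).
#' @export
discretise <- function(m, n_points = 100L) {
  stopifnot(inherits(m, "literature_model"), n_points >= 2L)
  grid <- seq(m$stretch_range[1], m$stretch_range[2], length.out = n_points)
  e <- uniaxial_psi(m$family, m$params, grid)
  if (!is.null(m$params_tension)) {
    tens <- grid > 1
    if (any(tens)) e[tens] <- uniaxial_psi(m$family, m$params_tension, grid[tens])
  }
  if (any(e <= -LOG_OFFSET)) {
    stop("model '", m$id, "' has energy <= -", LOG_OFFSET,
         " on its stretch range; log transform undefined downstream")
  }
  energy_curve(grid, e)
}

#' Construct an energy curve
#'
#' Discretised (stretch, energy density) samples: strictly increasing
#' stretches with finite energies in Pa.
#'
#' @param stretches numeric vector, strictly increasing.
#' @param energies numeric vector of the same length (Pa).
#' @return an `energy_curve`.
#' @export
energy_curve <- function(stretches, energies) {
  stopifnot(length(stretches) == length(energies),
            all(diff(stretches) > 0), all(is.finite(energies)))
  structure(list(stretches = as.numeric(stretches),
                 energies = as.numeric(energies)),
            class = "energy_curve")
}

#' @exportS3Method base::print
print.energy_curve <- function(x, ...) {
  cat(sprintf("energy curve: %d points, stretch [%.4g, %.4g], Psi [%.4g, %.4g] Pa\n",
              length(x$stretches), min(x$stretches), max(x$stretches),
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Default number of corpus models per task
#'
#' 3 study types x 4 regions, summing to 73 models, with the
#' hyperelastic-healthy task the largest (literature availability is
#' heaviest for ex-vivo hyperelastic testing of unspecified healthy
#' tissue).
#'
#' @return named integer vector of length 12 (names `study.region`).
#' @export
default_task_counts <- function() {
  counts <- c(MRE.grey = 2L, MRE.white = 2L, MRE.healthy = 4L, MRE.abnormal = 2L,
              linear.grey = 3L, linear.white = 3L, linear.healthy = 6L,
              linear.abnormal = 3L,
              hyperelastic.grey = 12L, hyperelastic.white = 12L,
              hyperelastic.healthy = 18L, hyperelastic.abnormal = 6L)
  stopifnot(sum(counts) == 73L)
  counts
}

default_stretch_ranges <- function() {
  list(MRE = c(0.995, 1.005), linear = c(0.95, 1.05),
       hyperelastic = c(0.7, 1.4))
}

#' Generate a synthetic literature corpus
#'
#' Emulates a corpus of constitutive models for brain tissue gathered from
#' MRE, linear and hyperelastic characterisation studies: 73 models over 12
#' (study type x region) tasks, with shear moduli drawn log-normally around
#' per-region medians, heterotopic stretch ranges per study type (MRE
#' observes tiny strains, linear small, hyperelastic large), and energies
#' consequently spanning orders of magnitude. All generated models satisfy
#' the stability conditions by construction.
#'
#' @param seed integer RNG seed; identical seeds yield identical corpora.
#' @param counts per-task model counts (see [default_task_counts()]).
#' @param region_medians named numeric, median shear modulus (Pa) per
#'   region. Defaults: grey 1370, white 990, healthy 333.28, abnormal 2000.
#' @param sigma_log log-normal scale of moduli around the median
#'   (default 0.5); doubled for abnormal tissue, whose studies vary most.
#' @param family_mix probabilities of NH/MR/O1 for hyperelastic-study
#'   models.
#' @param ogden_alpha_range range of the (negative) Ogden exponent.
#' @param range_jitter relative jitter applied to each study-type stretch
#'   window's half-widths (heterotopic inputs).
#' @return list of [literature_model()] records.
#' @export
generate_synthetic_corpus <- function(seed = 1L,
                                      counts = default_task_counts(),
                                      region_medians = c(grey = 1370, white = 990,
                                                         healthy = 333.28,
                                                         abnormal = 2000),
                                      sigma_log = 0.5,
                                      family_mix = c(NH = 0.4, MR = 0.3, O1 = 0.3),
                                      ogden_alpha_range = c(-9, -3),
                                      range_jitter = 0.2) {
  stopifnot(all(counts >= 0L), all(REGIONS %in% names(region_medians)))
  ranges <- default_stretch_ranges()
  set.seed(as.integer(seed))
  corpus <- list()
  k <- 0L
  for (st in STUDY_TYPES) {
    for (rg in REGIONS) {
      key <- paste(st, rg, sep = ".")
      n <- if (key %in% names(counts)) counts[[key]] else 0L
      if (n == 0L) next
      sig <- if (rg == "abnormal") 2 * sigma_log else sigma_log
      for (i in seq_len(n)) {
        k <- k + 1L
        mu_s <- region_medians[[rg]] * exp(rnorm(1, 0, sig))
        base <- ranges[[st]]
        jit <- runif(2, 1 - range_jitter, 1 + range_jitter)
        rng <- c(1 - (1 - base[1]) * jit[1], 1 + (base[2] - 1) * jit[2])
        if (st == "hyperelastic") {
          fam <- sample(names(family_mix), 1, prob = family_mix)
          params <- switch(fam,
            NH = list(mu = mu_s),
            MR = {
              r <- runif(1, 0.6, 0.9) # share of mu carried by C1
              list(c1 = r * mu_s / 2, c2 = (1 - r) * mu_s / 2)
            },
            O1 = {
              a <- runif(1, ogden_alpha_range[1], ogden_alpha_range[2])
              list(mu1 = 2 * mu_s / a, alpha1 = a)
            })
        } else {
          fam <- "NH"
          params <- if (st == "MRE") mre_to_nh(mu_s) else {
            nu <- runif(1, 0.45, 0.49)
            linear_to_nh(2 * (1 + nu) * mu_s, nu)
          }
        }
        corpus[[k]] <- literature_model(
          id = sprintf("%s-%s-%02d", st, rg, i), study_type = st, region = rg,
          family = fam, params = params, stretch_range = rng)
      }
    }
  }
  corpus
}

task_index <- function(study_type, region) {
  (match(study_type, STUDY_TYPES) - 1L) * 4L + match(region, REGIONS)
}

#' Assemble per-task datasets from a corpus
#'
#' Discretises every model (100 interpolation points by default) and groups
#' the resulting `(stretch, ln(Psi + 0.001))` pairs into the 12 tasks of
#' the multi-task regression: 3 study types x 4 tissue regions. Empty
#' tasks are permitted and reported via the `n_points` attribute.
#'
#' @param corpus list of [literature_model()] records.
#' @param n_points interpolation points per model.
#' @return list of 12 `task_dataset`s, each with `task_id`, `study_type`,
#'   `region`, `x` (stretches), `y` (log energies), `model_id`.
#' @export
assemble_tasks <- function(corpus, n_points = 100L) {
  tasks <- vector("list", 12L)
  t_id <- 0L
  for (st in STUDY_TYPES) {
    for (rg in REGIONS) {
      t_id <- t_id + 1L
      tasks[[t_id]] <- structure(
        list(task_id = t_id, study_type = st, region = rg,
             x = numeric(0), y = numeric(0), model_id = character(0)),
        class = "task_dataset")
    }
  }
  for (m in corpus) {
    cv <- discretise(m, n_points)
    t_id <- task_index(m$study_type, m$region)
    tk <- tasks[[t_id]]
    tk$x <- c(tk$x, cv$stretches)
    tk$y <- c(tk$y, log(cv$energies + LOG_OFFSET))
    tk$model_id <- c(tk$model_id, rep(m$id, length(cv$stretches)))
    tasks[[t_id]] <- tk
  }
  tasks
}

#' Find a task id by study type and region
#' @param tasks output of [assemble_tasks()].
#' @param study_type,region task labels.
#' @return integer task id in 1..12.
#' @export
find_task <- function(tasks, study_type, region) {
  id <- task_index(match.arg(study_type, STUDY_TYPES),
                   match.arg(region, REGIONS))
  stopifnot(tasks[[id]]$study_type == study_type,
            tasks[[id]]$region == region)
  id
}

#' Write / read a corpus as CSV
#'
#' Schema: one row per model with columns `id`, `study_type`, `region`,
#' `family`, `params_json` (JSON-encoded parameter blob), `stretch_min`,
#' `stretch_max`, `split_ct` (JSON tension parameters or empty). Round
#' trips losslessly.
#'
#' @param corpus list of [literature_model()] records.
#' @param path CSV file path.
#' @return `write_corpus_csv` returns `path` invisibly; `read_corpus_csv`
#'   returns the corpus list.
#' @export
write_corpus_csv <- function(corpus, path) {
  df <- do.call(rbind, lapply(corpus, function(m) {
    data.frame(id = m$id, study_type = m$study_type, region = m$region,
               family = m$family,
               params_json = as.character(jsonlite::toJSON(m$params, digits = NA)),
               stretch_min = m$stretch_range[1],
               stretch_max = m$stretch_range[2],
               split_ct = if (is.null(m$params_tension)) "" else
                 as.character(jsonlite::toJSON(m$params_tension, digits = NA)),
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_corpus_csv
#' @export
read_corpus_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "study_type", "region", "family", "params_json",
            "stretch_min", "stretch_max")
  if (!all(need %in% names(df))) {
    stop("corpus CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(is.na(df$stretch_min)) || any(is.na(df$stretch_max))) {
    stop("corpus CSV has missing stretch_range entries")
  }
  lapply(seq_len(nrow(df)), function(i) {
    pt <- df$split_ct[i]
    literature_model(
      id = df$id[i], study_type = df$study_type[i], region = df$region[i],
      family = df$family[i],
      params = lapply(jsonlite::fromJSON(df$params_json[i]), as.numeric),
      stretch_range = c(df$stretch_min[i], df$stretch_max[i]),
      params_tension = if (is.null(pt) || is.na(pt) || !nzchar(pt)) NULL else
        lapply(jsonlite::fromJSON(pt), as.numeric))
  })
}
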