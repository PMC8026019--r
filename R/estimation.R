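#' Parameter estimation against concentration-time datasets
#'
#' Multi-experiment weighted least squares: one parameter vector is fitted
#' simultaneously to any number of datasets (e.g. an oral and an intravenous
#' study), with per-curve mean-square weighting to balance tissues whose
#' concentrations span four orders of magnitude. Optimization is multistart
#' bounded Levenberg-Marquardt in log-parameter space, reproducible from a
#' seed.
#'
#' @name estimation
NULL

#' Map dataset tissue labels to model compartments
#'
#' Observed "intestine" and "kidney" homogenate concentrations are matched to
#' the enterocyte and kidney-tissue sub-compartments; "plasma" is venous
#' plasma (sampling site); urine and feces are cumulative amounts.
#'
#' @return data.frame with columns `tissue`, `compartment`, `measure`
#' @export
tissue_compartment_map <- function() {
  data.frame(
    tissue = c("plasma", "portal_vein", "intestine", "liver", "kidney",
               "heart", "muscle", "adipose", "brain", "stomach", "lungs",
               "rbc", "urine", "feces"),
    compartment = c("venous_plasma", "portal_vein", "enterocytes", "liver",
                    "kidney_tissue", "heart", "muscle", "adipose", "brain",
                    "stomach", "lungs", "rbc", "urine", "feces"),
    measure = c(rep("conc", 12), "amount", "amount"),
    stringsAsFactors = FALSE)
}

#' Undo the inulin-space correction of tissue concentrations
#'
#' Published mouse tissue concentrations corrected for extracellular (inulin)
#' space are converted back to whole-tissue concentrations by dividing by the
#' organ's intracellular fraction FI. The direction is exposed because the
#' correction is applied in the literature in both conventions.
#'
#' @param c_reported reported concentration (umol/kg tissue, numerically
#'   nmol/mL at unit density)
#' @param fi intracellular fraction of the organ, in (0, 1]
#' @param direction `"divide"` (default, recover whole-tissue concentration)
#'   or `"multiply"` (its inverse)
#' @return corrected concentration, nmol/mL
#' @export
inulin_correction <- function(c_reported, fi, direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  if (any(fi <= 0) || any(fi > 1)) stop("FI must lie in (0, 1]", call. = FALSE)
  if (direction == "divide") c_reported / fi else c_reported * fi
}

#' Create an experiment dataset
#'
#' @param label dataset label
#' @param species `"mouse"` or `"human"`
#' @param schedule the [dose_schedule()] administered
#' @param observations data.frame with columns `tissue`, `time_h`, `value`
#'   (nmol/mL for concentrations, nmol for cumulative urine/feces amounts),
#'   and optionally `sd`, `n`, `excluded`
#' @param fi optional named intracellular fractions used when the values were
#'   inulin-corrected
#' @return a `pbpk_dataset`
#' @export
experiment_dataset <- function(label, species, schedule, observations, fi = NULL) {
  stopifnot(inherits(schedule, "pbpk_schedule"),
            all(c("tissue", "time_h", "value") %in% names(observations)))
  known <- tissue_compartment_map()$tissue
  bad <- setdiff(unique(observations$tissue), known)
  if (length(bad)) {
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(observations$value < 0)) stop("observed values must be >= 0", call. = FALSE)
  if (is.null(observations$sd)) observations$sd <- NA_real_
  if (is.null(observations$n)) observations$n <- NA_integer_
  if (is.null(observations$excluded)) observations$excluded <- FALSE
  structure(list(label = label, species = match.arg(species, c("mouse", "human")),
                 schedule = schedule, observations = observations, fi = fi),
            class = "pbpk_dataset")
}

#' Apply the mouse oral-dose exclusion rules
#'
#' For a mouse PO dataset: the whole stomach curve is flagged (lumenal
#' content inflates the measurement) and the 2 h point in venous plasma,
#' portal vein and brain is flagged (second-peak artefact). Points are
#' flagged, never deleted, and flagged points never enter the objective.
#' Intravenous and human datasets are returned unchanged.
#'
#' @param dataset a `pbpk_dataset`
#' @return the dataset with updated `excluded` flags
#' @export
apply_exclusions <- function(dataset) {
  stopifnot(inherits(dataset, "pbpk_dataset"))
  if (dataset$species != "mouse" || !all(dataset$schedule$route == "PO")) {
    return(dataset)
  }
  obs <- dataset$observations
  obs$excluded <- obs$excluded | obs$tissue == "stomach"
  obs$excluded <- obs$excluded |
    (obs$tissue %in% c("plasma", "portal_vein", "brain") & obs$time_h == 2)
  dataset$observations <- obs
  dataset
}

# Predictions at the observation times of one dataset.
predict_dataset <- function(model, dataset, opts) {
  obs <- dataset$observations
  duration <- max(obs$time_h, dataset$schedule$time + 0.5)
  sim <- simulate_pbpk(model, dataset$schedule, duration, opts)
  map <- tissue_compartment_map()
  pred <- numeric(nrow(obs))
  for (tis in unique(obs$tissue)) {
    m <- map[map$tissue == tis, ]
    series <- if (m$measure == "conc") sim$conc[, m$compartment] else sim$amounts[, m$compartment]
    rows <- obs$tissue == tis
    pred[rows] <- stats::approx(sim$time, series, xout = obs$time_h[rows], rule = 2)$y
  }
  pred
}

# Weighted residual vector over all datasets; weight 1/mean(curve)^2 balances
# curves across scales (urine amounts form their own curves and are thereby
# weighted separately from concentrations).
dataset_residuals <- function(models, datasets, opts) {
  res <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    model <- if (inherits(models, "pbpk_model")) models else models[[ds$label]]
    if (is.null(model)) stop(sprintf("no model for dataset '%s'", ds$label), call. = FALSE)
    obs <- ds$observations
    keep <- !obs$excluded
    pred <- predict_dataset(model, ds, opts)
    for (tis in unique(obs$tissue[keep])) {
      rows <- keep & obs$tissue == tis
      w <- 1 / mean(obs$value[rows])^2
      res[[paste(ds$label, tis)]] <- sqrt(w) * (pred[rows] - obs$value[rows])
    }
  }
  unlist(res, use.names = FALSE)
}

#' Weighted least-squares objective
#'
#' Sum over non-excluded observations of `w * (simulated - observed)^2` with
#' per-curve weight `1/mean(observed)^2`. A failed simulation contributes a
#' large finite penalty so the optimizer can retreat.
#'
#' @param params named parameter vector
#' @param builder function taking `params` and returning a `pbpk_model`
#'   (used for every dataset) or a named list of models keyed by dataset label
#' @param datasets list of `pbpk_dataset`
#' @param opts solver options used during fitting (coarser than the
#'   simulation defaults for speed)
#' @return scalar objective value
#' @export
pbpk_objective <- function(params, builder, datasets,
                           opts = fit_solver_options()) {
  r <- tryCatch(dataset_residuals(builder(params), datasets, opts),
                error = function(e) {
                  warning("simulation failed during objective: ",
                          conditionMessage(e), call. = FALSE)
                  NULL
                })
  if (is.null(r)) return(1e10)
  sum(r^2)
}

#' Solver options used inside parameter estimation
#'
#' Coarser output grid and tolerances than the reporting defaults: residuals
#' only need the solution at the observation times, and the fitted optimum
#' moves by far less than the fit's confidence region at these settings.
#'
#' @inheritParams solver_options
#' @return a `pbpk_solver_options` list
#' @export
fit_solver_options <- function(rel_tol = 1e-6, abs_tol = 1e-8,
                               output_resolution = 8) {
  solver_options(rel_tol = rel_tol, abs_tol = abs_tol,
                 output_resolution = output_resolution)
}

#' Specify a fit
#'
#' @param parameters data.frame with columns `name`, `start`, `lower`,
#'   `upper` (bounds must be finite and positive: parameters are fitted in
#'   log space) and optionally `transform` (`"log"`, the default, or
#'   `"linear"`)
#' @param datasets list of `pbpk_dataset`
#' @param builder function mapping a named parameter vector to model(s), see
#'   [pbpk_objective()]
#' @param n_starts number of multistart points (log-space Latin hypercube;
#'   the first start is always `start`)
#' @param seed RNG seed making the fit reproducible
#' @param opts solver options for fitting
#' @return a `pbpk_fit_spec`
#' @export
fit_spec <- function(parameters, datasets, builder, n_starts = 32, seed = 1,
                     opts = fit_solver_options()) {
  stopifnot(is.data.frame(parameters),
            all(c("name", "start", "lower", "upper") %in% names(parameters)))
  if (!nrow(parameters)) stop("at least one free parameter required", call. = FALSE)
  if (is.null(parameters$transform)) parameters$transform <- "log"
  if (any(parameters$lower <= 0 & parameters$transform == "log") ||
      any(!is.finite(parameters$lower)) || any(!is.finite(parameters$upper))) {
    stop("bounds must be finite, and positive for log-transformed parameters",
         call. = FALSE)
  }
  if (any(parameters$start < parameters$lower | parameters$start > parameters$upper)) {
    stop("start values must lie within the bounds", call. = FALSE)
  }
  structure(list(parameters = parameters, datasets = datasets, builder = builder,
                 n_starts = n_starts, seed = seed, opts = opts),
            class = "pbpk_fit_spec")
}

to_internal <- function(x, pars) ifelse(pars$transform == "log", log(x), x)
from_internal <- function(z, pars) {
  stats::setNames(ifelse(pars$transform == "log", exp(z), z), pars$name)
}

#' Run a multistart fit
#'
#' Latin-hypercube starts in (log-transformed) parameter space, a bounded
#' Levenberg-Marquardt least-squares run from each start, and the best final
#' objective wins. Deterministic given the spec's seed; the best objective is
#' never worse than any start's final objective.
#'
#' @param spec a [fit_spec()]
#' @return a `pbpk_fit` with elements `par` (best parameters), `objective`,
#'   `starts` (per-start summary data.frame), `spec`
#' @export
fit_pbpk <- function(spec) {
  stopifnot(inherits(spec, "pbpk_fit_spec"))
  pars <- spec$parameters
  np <- nrow(pars)
  lo <- to_internal(pars$lower, pars)
  hi <- to_internal(pars$upper, pars)

  set.seed(spec$seed)
  starts <- matrix(to_internal(pars$start, pars), nrow = 1)
  if (spec$n_starts > 1) {
    u <- lhs::randomLHS(spec$n_starts - 1, np)
    starts <- rbind(starts, sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  }

  resid_fn <- function(z) {
    p <- from_internal(z, pars)
    r <- tryCatch(dataset_residuals(spec$builder(p), spec$datasets, spec$opts),
                  error = function(e) NULL)
    if (is.null(r)) rep(1e5, max(np + 1, 2)) else r
  }

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fitted <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi, fn = resid_fn,
                         # epsfcn keeps finite-difference steps well above the
                         # ODE-solver noise floor, or the Jacobian is noise
                         control = minpack.lm::nls.lm.control(maxiter = 200,
                                                              epsfcn = 1e-6)),
      error = function(e) NULL)
    runs[[i]] <- if (is.null(fitted)) {
      list(par = starts[i, ], objective = Inf, converged = FALSE)
    } else {
      list(par = fitted$par, objective = sum(fitted$fvec^2),
           converged = fitted$info %in% 1:4)
    }
  }
  objs <- vapply(runs, `[[`, 0, "objective")
  best <- which.min(objs)
  start_tab <- data.frame(
    start = seq_along(runs), objective = objs,
    converged = vapply(runs, `[[`, TRUE, "converged"))
  structure(list(par = from_internal(runs[[best]]$par, pars),
                 objective = objs[best], starts = start_tab, spec = spec),
            class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("<pbpk_fit> objective %.6g over %d start(s)\n", x$objective,
              nrow(x$starts)))
  print(round(x$par, 5))
  invisible(x)
}

#' Compare estimated and calculated partition coefficients
#'
#' Percent difference `100 * (estimated - calculated) / calculated` per
#' tissue; tissues missing from either map are reported as `NA`.
#'
#' @param estimated named vector of fitted K_t:p values
#' @param calculated named vector of tissue-composition predictions
#'   (default [calculated_ktp()])
#' @return data.frame with columns `tissue`, `calculated`, `estimated`,
#'   `pct_difference`
#' @export
compare_partition_coefficients <- function(estimated, calculated = calculated_ktp()) {
  tissues <- union(names(calculated), names(estimated))
  est <- estimated[tissues]; calc <- calculated[tissues]
  data.frame(tissue = tissues,
             calculated = unname(calc), estimated = unname(est),
             pct_difference = unname(100 * (est - calc) / calc),
             stringsAsFactors = FALSE)
}
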