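#' Synthetic concentration-time data with known ground truth
#'
#' Emulates the sparse tissue-sampling designs of the source studies (mouse
#' organ harvests at 0.5-24 h; human plasma/RBC sampling with timed urine
#' collections) on top of any model and regimen, with multiplicative
#' lognormal measurement noise. Ground-truth parameters are recorded
#' alongside so estimation can be validated by parameter recovery.
#'
#' @name synthetic_data
NULL

#' Measurement-noise model
#'
#' Multiplicative lognormal noise `exp(N(0, sigma))` with
#' `sigma = sqrt(log(1 + cv^2))`, so the coefficient of variation of the
#' noisy observation equals `cv` exactly. Default 10% CV, typical of
#' bioanalytical assay precision.
#'
#' @param kind `"none"` or `"lognormal_cv"`
#' @param cv coefficient of variation (fraction, >= 0)
#' @param seed RNG seed
#' @return a `pbpk_noise` list
#' @export
noise_model <- function(kind = c("lognormal_cv", "none"), cv = 0.1, seed = 1) {
  kind <- match.arg(kind)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(kind = kind, cv = cv, seed = seed), class = "pbpk_noise")
}

#' Tissue-sampling scheme
#'
#' @param tissues tissue labels measured as concentrations (see
#'   [tissue_compartment_map()])
#' @param times sampling times, h (strictly increasing, > 0)
#' @param urine_times urine collection times, h (cumulative amounts)
#' @param feces_times feces collection times, h (cumulative amounts)
#' @return a `pbpk_scheme` list
#' @export
sampling_scheme <- function(tissues, times, urine_times = numeric(0),
                            feces_times = numeric(0)) {
  for (tv in list(times, urine_times, feces_times)) {
    if (length(tv) && (is.unsorted(tv, strictly = TRUE) || any(tv <= 0))) {
      stop("sampling times must be positive and strictly increasing", call. = FALSE)
    }
  }
  structure(list(tissues = tissues, times = times, urine_times = urine_times,
                 feces_times = feces_times), class = "pbpk_scheme")
}

#' Mouse oral-dose tissue-harvest scheme
#'
#' Nine tissues and fluids sampled at 0.5, 1, 2, 4, 8 and 24 h, with
#' cumulative urine and feces at 24 h.
#' @return a `pbpk_scheme`
#' @export
preset_wilcock_po <- function() {
  sampling_scheme(
    tissues = c("plasma", "portal_vein", "intestine", "liver", "kidney",
                "heart", "muscle", "adipose", "brain"),
    times = c(0.5, 1, 2, 4, 8, 24),
    urine_times = 24, feces_times = 24)
}

#' Mouse intravenous-dose scheme
#'
#' Plasma, intestine, stomach and liver at 0.5, 1, 2 and 4 h; all drug is
#' excreted in urine after an IV dose.
#' @return a `pbpk_scheme`
#' @export
preset_wilcock_iv <- function() {
  sampling_scheme(
    tissues = c("plasma", "intestine", "stomach", "liver"),
    times = c(0.5, 1, 2, 4),
    urine_times = 24)
}

#' Human single-dose plasma/RBC/urine scheme
#'
#' Plasma and red blood cells at 1, 2, 3, 4, 6, 10 and 24 h; urine collected
#' at 4, 6, 10 and 24 h.
#' @return a `pbpk_scheme`
#' @export
preset_zaharenko <- function() {
  sampling_scheme(
    tissues = c("plasma", "rbc"),
    times = c(1, 2, 3, 4, 6, 10, 24),
    urine_times = c(4, 6, 10, 24))
}

#' Human pre-dosed plasma sampling design
#'
#' Two oral doses 12 h apart with blood sampling over the 12 h after the
#' second dose (0.5-12 h), as used for the 1000 mg (1000 mg pre-dose) and
#' 250 mg (375 mg pre-dose) regimens. Returns both the sampling scheme and
#' the matching dose schedule (pre-dose at 0 h, main dose at 12 h).
#'
#' @param dose_mg_hcl main dose, mg metformin hydrochloride (250 or 1000 in
#'   the source design; any positive dose accepted)
#' @return list with `scheme` (`pbpk_scheme`, times relative to the first
#'   dose) and `schedule` (`pbpk_schedule`)
#' @export
preset_chung <- function(dose_mg_hcl) {
  pre <- if (dose_mg_hcl <= 250) 375 else 1000
  offsets <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 10, 12)
  list(scheme = sampling_scheme("plasma", 12 + offsets),
       schedule = dose_schedule(c(0, 12), c(pre, dose_mg_hcl), "PO"))
}

#' Human twice-daily multiple-dose design
#'
#' Six 500 mg pre-doses at 12 h intervals followed by a final 500 mg dose,
#' with plasma sampling over the 10 h after the final dose.
#' @return list with `scheme` and `schedule` as in [preset_chung()]
#' @export
preset_el_messaoudi <- function() {
  t_last <- 72
  offsets <- c(1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 8, 10)
  list(scheme = sampling_scheme("plasma", t_last + offsets),
       schedule = dose_schedule(seq(0, t_last, by = 12), 500, "PO"))
}

#' All-tissue recovery scheme
#'
#' Every measurable tissue (including lungs and stomach) on the mouse
#' harvest grid plus urine/feces; used for parameter-recovery experiments,
#' where each partition coefficient needs its tissue observed.
#' @return a `pbpk_scheme`
#' @export
preset_recovery <- function() {
  sampling_scheme(
    tissues = c("plasma", "portal_vein", "intestine", "liver", "kidney",
                "heart", "muscle", "adipose", "brain", "lungs", "stomach"),
    times = c(0.5, 1, 2, 4, 8, 24),
    urine_times = c(8, 24), feces_times = 24)
}

#' Generate a synthetic dataset
#'
#' Simulates the model under the schedule, samples the mapped compartments at
#' the scheme's times, and applies multiplicative lognormal noise. The
#' generating parameter values travel with the dataset as the
#' `ground_truth` attribute.
#'
#' @param model a `pbpk_model`
#' @param schedule a [dose_schedule()]
#' @param scheme a [sampling_scheme()]
#' @param noise a [noise_model()]
#' @param label dataset label
#' @param ground_truth named vector recorded alongside (defaults to the
#'   model's partition coefficients)
#' @param opts solver options
#' @return a `pbpk_dataset` with attribute `ground_truth`
#' @export
generate_dataset <- function(model, schedule, scheme, noise = noise_model(),
                             label = "synthetic",
                             ground_truth = NULL,
                             opts = solver_options(rel_tol = 1e-8,
                                                   output_resolution = 20)) {
  stopifnot(inherits(scheme, "pbpk_scheme"), inherits(noise, "pbpk_noise"))
  duration <- max(scheme$times, scheme$urine_times, scheme$feces_times,
                  schedule$time + 1)
  sim <- simulate_pbpk(model, schedule, duration, opts)
  map <- tissue_compartment_map()

  grab <- function(tissue, times) {
    m <- map[map$tissue == tissue, ]
    series <- if (m$measure == "conc") sim$conc[, m$compartment] else sim$amounts[, m$compartment]
    data.frame(tissue = tissue, time_h = times,
               value = stats::approx(sim$time, series, xout = times)$y,
               stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, c(
    lapply(scheme$tissues, grab, times = scheme$times),
    if (length(scheme$urine_times)) list(grab("urine", scheme$urine_times)),
    if (length(scheme$feces_times)) list(grab("feces", scheme$feces_times))))

  if (noise$kind == "lognormal_cv" && noise$cv > 0) {
    set.seed(noise$seed)
    sigma <- sqrt(log(1 + noise$cv^2))
    obs$value <- obs$value * exp(stats::rnorm(nrow(obs), 0, sigma))
  }
  obs$sd <- obs$value * noise$cv
  obs$n <- 1L
  obs$excluded <- FALSE

  if (is.null(ground_truth)) {
    comp <- model$compartments
    ws <- comp$kind == "tissue_well_stirred"
    ground_truth <- stats::setNames(comp$ktp[ws], comp$name[ws])
  }
  ds <- experiment_dataset(label, model$species, schedule, obs)
  attr(ds, "ground_truth") <- ground_truth
  ds
}

#' Write a dataset as tidy CSV (with ground-truth sidecar)
#'
#' Columns follow the tidy dialect `dataset_label, tissue, time_h,
#' conc_nmol_per_mL, sd, n, excluded, measure`; urine/feces rows carry
#' cumulative amounts (nmol) in the value column with `measure = "amount"`.
#' If the dataset has a `ground_truth` attribute it is written next to the
#' CSV as JSON.
#'
#' @param dataset a `pbpk_dataset`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_dataset_csv <- function(dataset, path) {
  obs <- dataset$observations
  map <- tissue_compartment_map()
  out <- data.frame(dataset_label = dataset$label, tissue = obs$tissue,
                    time_h = obs$time_h, conc_nmol_per_mL = obs$value,
                    sd = obs$sd, n = obs$n, excluded = obs$excluded,
                    measure = map$measure[match(obs$tissue, map$tissue)],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  gt <- attr(dataset, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(as.list(gt), sub("\\.csv$", "_truth.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a tidy dataset CSV
#'
#' @param path CSV path in the [write_dataset_csv()] dialect
#' @param species dataset species
#' @param schedule the administered [dose_schedule()]
#' @return a `pbpk_dataset`
#' @export
read_dataset_csv <- function(path, species, schedule) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  obs <- data.frame(tissue = d$tissue, time_h = d$time_h,
                    value = d$conc_nmol_per_mL, sd = d$sd, n = d$n,
                    excluded = as.logical(d$excluded), stringsAsFactors = FALSE)
  experiment_dataset(d$dataset_label[1], species, schedule, obs)
}
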