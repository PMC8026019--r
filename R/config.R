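#' Model configuration round-trip
#'
#' Models are specified by four blocks — `physiology`,
#' `partition_coefficients`, `kinetics`, `scale_up` — serialized to YAML, or
#' by a two-column `parameter,value` CSV laid out like a supplementary
#' parameter table (dotted parameter paths, e.g. `physiology.volumes.muscle`).
#'
#' @name model_config
NULL

phys_from_list <- function(x) {
  phys <- default_physiology(x$species)
  for (nm in c("body_weight", "cardiac_output", "q_gfr", "q_urine",
               "k_gastric", "k_transit", "hematocrit", "intestinal_area_cm2",
               "protein_per_area")) {
    if (!is.null(x[[nm]])) phys[[nm]] <- x[[nm]]
  }
  if (!is.null(x$volumes)) phys$volumes[names(x$volumes)] <- unlist(x$volumes)
  if (!is.null(x$flows)) phys$flows[names(x$flows)] <- unlist(x$flows)
  if (is.null(x$k_gastric) && x$species == "mouse") {
    # gut motility governs oral Tmax; refuse to guess silently
    message("note: mouse gastric/transit rates not in config; using package defaults")
  }
  phys
}

#' Write a model configuration as YAML
#'
#' @param path output path
#' @param species `"mouse"` or `"human"`
#' @param phys a [default_physiology()] list
#' @param kinetics a [default_kinetics()] list
#' @param ktp named partition coefficients
#' @param coefs [scale_up_coefficients()] (human only, may be `NULL`)
#' @return `path`, invisibly
#' @export
write_model_config <- function(path, species, phys = default_physiology(species),
                               kinetics = default_kinetics(), ktp = default_ktp(),
                               coefs = if (species == "human") scale_up_coefficients()) {
  cfg <- list(
    species = species,
    physiology = list(
      body_weight = phys$body_weight, cardiac_output = phys$cardiac_output,
      volumes = as.list(phys$volumes), flows = as.list(phys$flows),
      q_gfr = phys$q_gfr, q_urine = phys$q_urine,
      k_gastric = phys$k_gastric, k_transit = phys$k_transit,
      hematocrit = phys$hematocrit,
      intestinal_area_cm2 = phys$intestinal_area_cm2,
      protein_per_area = phys$protein_per_area),
    partition_coefficients = as.list(ktp),
    kinetics = list(proctor = as.list(kinetics$proctor),
                    kidney = as.list(kinetics$kidney),
                    ps_intestine = as.list(kinetics$ps_intestine),
                    ps_kidney = as.list(kinetics$ps_kidney),
                    rbc = as.list(kinetics$rbc),
                    proctor_coefficient_human = kinetics$proctor_coefficient_human),
    scale_up = if (!is.null(coefs)) list(absorption = coefs$absorption,
                                         elimination = coefs$elimination))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load a model from a YAML configuration
#'
#' @param path YAML file written by [write_model_config()] (or hand-edited in
#'   the same layout; omitted entries fall back to package defaults)
#' @return a `pbpk_model`
#' @export
load_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  species <- match.arg(cfg$species, c("mouse", "human"))
  phys <- phys_from_list(c(list(species = species), cfg$physiology))
  kin <- default_kinetics()
  if (!is.null(cfg$kinetics)) {
    for (blk in c("proctor", "kidney", "ps_intestine", "ps_kidney", "rbc")) {
      if (!is.null(cfg$kinetics[[blk]])) {
        v <- unlist(cfg$kinetics[[blk]])
        kin[[blk]][names(v)] <- v
      }
    }
    if (!is.null(cfg$kinetics$proctor_coefficient_human)) {
      kin$proctor_coefficient_human <- cfg$kinetics$proctor_coefficient_human
    }
  }
  ktp <- default_ktp()
  if (!is.null(cfg$partition_coefficients)) {
    v <- unlist(cfg$partition_coefficients)
    ktp[names(v)] <- v
  }
  if (species == "mouse") {
    build_mouse_model(phys, kin, ktp)
  } else {
    coefs <- if (is.null(cfg$scale_up)) scale_up_coefficients() else
      scale_up_coefficients(cfg$scale_up$absorption, cfg$scale_up$elimination)
    build_human_model(phys, kin, ktp, coefs, body_weight = phys$body_weight)
  }
}

#' Load parameter overrides from a supplementary-style CSV
#'
#' Two/three-column CSV (`parameter`, `value`, optional `unit`) with dotted
#' parameter paths: `physiology.volumes.muscle`, `physiology.q_gfr`,
#' `partition_coefficients.liver`, `kinetics.kidney.vmax_oct2`,
#' `scale_up.elimination`, `species`. Returns the nested list that
#' [load_model_config()] consumes.
#'
#' @param path CSV path
#' @return nested configuration list
#' @export
load_params_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("parameter", "value") %in% names(d))) {
    stop("parameter CSV needs 'parameter' and 'value' columns", call. = FALSE)
  }
  assign_path <- function(lst, keys, val) {
    if (length(keys) == 1) {
      lst[[keys]] <- val
    } else {
      if (is.null(lst[[keys[1]]])) lst[[keys[1]]] <- list()
      lst[[keys[1]]] <- assign_path(lst[[keys[1]]], keys[-1], val)
    }
    lst
  }
  cfg <- list()
  for (i in seq_len(nrow(d))) {
    keys <- strsplit(d$parameter[i], ".", fixed = TRUE)[[1]]
    val <- d$value[i]
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    cfg <- assign_path(cfg, keys, val)
  }
  cfg
}

#' Build a model from a parameter CSV
#'
#' @param path CSV in the [load_params_csv()] layout; must contain a
#'   `species` row
#' @return a `pbpk_model`
#' @export
load_model_csv <- function(path) {
  cfg <- load_params_csv(path)
  if (is.null(cfg$species)) stop("parameter CSV must set 'species'", call. = FALSE)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  load_model_config(tmp)
}

#' Standard parameter builder for estimation
#'
#' Maps a named parameter vector onto the stock model of one species:
#' `ktp.<tissue>` entries override partition coefficients,
#' `coef.absorption` / `coef.elimination` override the human scale-up
#' coefficients, and `kinetics.kidney.<name>` / `kinetics.proctor.<name>`
#' override kinetic constants. Everything else stays at the supplied
#' baseline, so a fit over `ktp.*` recovers partition coefficients and a fit
#' over `coef.*` recovers the scale-up.
#'
#' @param species `"mouse"` or `"human"`
#' @param phys baseline physiology
#' @param kinetics baseline kinetics
#' @param ktp baseline partition coefficients
#' @param coefs baseline scale-up (human)
#' @return function mapping a named parameter vector to a `pbpk_model`
#' @export
standard_fit_builder <- function(species, phys = default_physiology(species),
                                 kinetics = default_kinetics(),
                                 ktp = default_ktp(),
                                 coefs = scale_up_coefficients()) {
  force(phys); force(kinetics); force(ktp); force(coefs)
  function(params) {
    k <- ktp; kin <- kinetics; cf <- coefs
    for (nm in names(params)) {
      v <- params[[nm]]
      if (startsWith(nm, "ktp.")) {
        k[[sub("^ktp\\.", "", nm)]] <- v
      } else if (nm == "coef.absorption") {
        cf$absorption <- v
      } else if (nm == "coef.elimination") {
        cf$elimination <- v
      } else if (startsWith(nm, "kinetics.")) {
        keys <- strsplit(nm, ".", fixed = TRUE)[[1]][-1]
        kin[[keys[1]]][[keys[2]]] <- v
      } else {
        stop(sprintf("unknown fit parameter '%s'", nm), call. = FALSE)
      }
    }
    if (species == "mouse") build_mouse_model(phys, kin, k)
    else build_human_model(phys, kin, k, cf, body_weight = phys$body_weight)
  }
}
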