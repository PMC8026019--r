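#' Model domain types
#'
#' A `pbpk_model` is a self-contained description of one species' whole-body
#' model: a compartment table (name, volume, kind, partition coefficient), a
#' reaction list (rate laws with parameters wired between compartments), and a
#' plasma-flow topology map used to check cardiac-output consistency.
#'
#' @name model_types
NULL

COMPARTMENT_KINDS <- c("tissue_well_stirred", "vascular", "lumen", "excreta")
RATE_FORMS <- c("clearance", "michaelis_menten", "first_order",
                "partition_exchange", "gfr_filtration")

#' Create a compartment
#'
#' @param name compartment identifier
#' @param volume volume in mL (> 0 for all non-excreta compartments; excreta
#'   compartments are pure amount sinks and carry `NA`)
#' @param kind one of `"tissue_well_stirred"`, `"vascular"`, `"lumen"`,
#'   `"excreta"`
#' @param ktp tissue:plasma partition coefficient; required (> 0) iff
#'   `kind == "tissue_well_stirred"`
#' @return a one-row data.frame
#' @export
compartment <- function(name, volume, kind, ktp = NA_real_) {
  kind <- match.arg(kind, COMPARTMENT_KINDS)
  if (kind != "excreta" && (!is.finite(volume) || volume <= 0)) {
    stop(sprintf("compartment '%s': volume must be > 0", name), call. = FALSE)
  }
  if (kind == "tissue_well_stirred" && (!is.finite(ktp) || ktp <= 0)) {
    stop(sprintf("compartment '%s': K_t:p must be > 0 for well-stirred tissue", name),
         call. = FALSE)
  }
  data.frame(name = name, volume = if (kind == "excreta") NA_real_ else volume,
             kind = kind, ktp = ktp, stringsAsFactors = FALSE)
}

#' Create a rate law (one reaction)
#'
#' Supported forms and their parameters (units):
#' * `clearance`: `CL` (mL/h), rate `CL * C_source`. Used for plasma flows,
#'   flow-limited tissue efflux (`Q/Ktp`), linear transport (`Kd`), urine flow.
#' * `gfr_filtration`: `CL` (mL/h), same law; kept as a distinct form so the
#'   glomerular-filtration reaction is identifiable.
#' * `michaelis_menten`: `Vmax` (nmol/h), `Km` (nmol/mL), rate
#'   `Vmax*C/(Km+C)`.
#' * `first_order`: `k` (1/h), rate `k * A_source` (amount-based; gut transit).
#' * `partition_exchange`: `PS` (mL/h), `Ktp`, net rate
#'   `PS * (C_source - C_sink/Ktp)` (bidirectional passive exchange).
#'
#' @param id stable reaction identifier (e.g. `"03.2"`)
#' @param form rate-law form, see Details
#' @param params named numeric vector of kinetic parameters (all >= 0)
#' @param source source compartment name
#' @param sink sink compartment name (must differ from `source`)
#' @param name human-readable label
#' @param scale_group `"absorption"`, `"elimination"` or `NA`; marks the
#'   reactions whose kinetic constants the mouse-to-human scale-up multiplies
#' @return a `pbpk_reaction` list
#' @export
rate_law <- function(id, form, params, source, sink, name = id,
                     scale_group = NA_character_) {
  form <- match.arg(form, RATE_FORMS)
  if (identical(source, sink)) {
    stop(sprintf("reaction '%s': source and sink must differ", id), call. = FALSE)
  }
  if (any(!is.finite(params)) || any(params < 0)) {
    stop(sprintf("reaction '%s': kinetic parameters must be finite and >= 0", id),
         call. = FALSE)
  }
  needed <- switch(form,
    clearance = "CL", gfr_filtration = "CL",
    michaelis_menten = c("Vmax", "Km"),
    first_order = "k",
    partition_exchange = c("PS", "Ktp"))
  if (!all(needed %in% names(params))) {
    stop(sprintf("reaction '%s': form '%s' needs parameters %s", id, form,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  structure(list(id = id, form = form, params = params, source = source,
                 sink = sink, name = name, scale_group = scale_group),
            class = "pbpk_reaction")
}

#' Create a dose schedule
#'
#' Doses are given in mg of metformin hydrochloride (the clinical unit) and
#' converted internally to nmol of free base via the fixed salt factor.
#'
#' @param time dose times, h (>= 0, non-decreasing)
#' @param amount_mg_hcl dose amounts, mg metformin hydrochloride (>= 0)
#' @param route `"PO"` or `"IV"` (recycled)
#' @return a `pbpk_schedule` data.frame with columns `time`, `amount_mg_hcl`,
#'   `route`, `amount_nmol`
#' @export
#' @examples
#' dose_schedule(0, 500, "PO")
#' dose_schedule(seq(0, 84, by = 12), 500, "PO") # 500 mg BID x 8
dose_schedule <- function(time, amount_mg_hcl, route = "PO") {
  route <- toupper(route)
  if (!all(route %in% c("PO", "IV"))) stop("route must be 'PO' or 'IV'", call. = FALSE)
  if (any(time < 0)) stop("dose times must be >= 0", call. = FALSE)
  if (is.unsorted(time)) stop("dose times must be non-decreasing", call. = FALSE)
  if (any(amount_mg_hcl < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  out <- data.frame(time = time, amount_mg_hcl = amount_mg_hcl,
                    route = rep_len(route, length(time)),
                    stringsAsFactors = FALSE)
  out$amount_nmol <- dose_hcl_mg_to_nmol(out$amount_mg_hcl)
  class(out) <- c("pbpk_schedule", "data.frame")
  out
}

#' Assemble and validate a model definition
#'
#' @param species `"mouse"` or `"human"`
#' @param body_weight body weight, kg
#' @param compartments data.frame of [compartment()] rows
#' @param reactions list of [rate_law()] objects
#' @param flows data.frame with columns `from`, `to`, `q` (mL/h) describing the
#'   plasma-flow wiring, used only for topology validation and scenario edits
#' @param inputs the raw inputs (physiology, kinetics, partition coefficients,
#'   scale-up) the model was built from; retained so scenario and estimation
#'   code can rebuild consistently
#' @return a validated `pbpk_model`
#' @export
pbpk_model <- function(species, body_weight, compartments, reactions, flows,
                       inputs = list()) {
  species <- match.arg(species, c("mouse", "human"))
  model <- structure(list(species = species, body_weight = body_weight,
                          compartments = compartments, reactions = reactions,
                          flows = flows, inputs = inputs),
                     class = "pbpk_model")
  validate_model(model)
  model
}

#' Validate model topology and parameter invariants
#'
#' Checks compartment invariants (positive volumes, positive partition
#' coefficients), reaction wiring (known compartments, source != sink),
#' and plasma-flow consistency: at the arterial, venous and portal nodes
#' inflow equals outflow; lung flow equals total cardiac output; liver inflow
#' equals hepatic artery plus portal vein flow.
#'
#' @param model a `pbpk_model`
#' @return invisibly `TRUE`; stops with a named error otherwise
#' @export
validate_model <- function(model) {
  comp <- model$compartments
  stopifnot(is.data.frame(comp), all(c("name", "volume", "kind", "ktp") %in% names(comp)))
  if (anyDuplicated(comp$name)) stop("duplicate compartment names", call. = FALSE)
  bad <- comp$kind != "excreta" & (!is.finite(comp$volume) | comp$volume <= 0)
  if (any(bad)) {
    stop("non-positive volume in compartment(s): ",
         paste(comp$name[bad], collapse = ", "), call. = FALSE)
  }
  ws <- comp$kind == "tissue_well_stirred"
  if (any(ws & (!is.finite(comp$ktp) | comp$ktp <= 0))) {
    stop("well-stirred tissues must have K_t:p > 0", call. = FALSE)
  }
  for (r in model$reactions) {
    if (!all(c(r$source, r$sink) %in% comp$name)) {
      stop(sprintf("reaction '%s' references unknown compartment", r$id), call. = FALSE)
    }
  }
  fl <- model$flows
  if (!is.null(fl) && nrow(fl)) {
    node_balance <- function(node) {
      sum(fl$q[fl$to == node]) - sum(fl$q[fl$from == node])
    }
    co <- sum(fl$q[fl$from == "venous_plasma"]) # cardiac output (plasma)
    for (node in intersect(c("arterial_plasma", "venous_plasma", "portal_vein", "lungs"),
                           unique(c(fl$from, fl$to)))) {
      if (abs(node_balance(node)) > 1e-8 * co) {
        stop(sprintf("flow imbalance at vascular node '%s'", node), call. = FALSE)
      }
    }
    q_lung <- sum(fl$q[fl$to == "lungs"])
    if (abs(q_lung - co) > 1e-8 * co) {
      stop("lung flow must equal total cardiac output", call. = FALSE)
    }
    q_liver_in <- sum(fl$q[fl$to == "liver"])
    q_ha <- sum(fl$q[fl$from == "arterial_plasma" & fl$to == "liver"])
    q_pv <- sum(fl$q[fl$from == "portal_vein" & fl$to == "liver"])
    if (abs(q_liver_in - (q_ha + q_pv)) > 1e-8 * co) {
      stop("liver inflow must equal hepatic artery + portal vein flow", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Replace saturable reactions by their linear limits
#'
#' Every Michaelis-Menten reaction is replaced by a linear clearance
#' `CL = Vmax/Km` (the low-concentration limit). The resulting model is fully
#' linear, so superposition holds and tissue-to-plasma AUC ratios equal the
#' partition coefficients for flow-limited tissues.
#'
#' @param model a `pbpk_model`
#' @return the linearized model
#' @export
linearize_model <- function(model) {
  model$reactions <- lapply(model$reactions, function(r) {
    if (r$form == "michaelis_menten") {
      rate_law(r$id, "clearance", c(CL = unname(r$params["Vmax"] / r$params["Km"])),
               r$source, r$sink, name = paste0(r$name, " (linearized)"),
               scale_group = r$scale_group)
    } else r
  })
  model
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s, body weight %.3g kg\n", x$species, x$body_weight))
  cat(sprintf("  %d compartments (%d well-stirred, %d vascular, %d lumen, %d excreta)\n",
              nrow(x$compartments),
              sum(x$compartments$kind == "tissue_well_stirred"),
              sum(x$compartments$kind == "vascular"),
              sum(x$compartments$kind == "lumen"),
              sum(x$compartments$kind == "excreta")))
  cat(sprintf("  %d reactions\n", length(x$reactions)))
  invisible(x)
}

#' Look up a reaction by id
#' @param model a `pbpk_model`
#' @param id reaction id
#' @return the `pbpk_reaction`, or error if absent
#' @export
get_reaction <- function(model, id) {
  for (r in model$reactions) if (r$id == id) return(r)
  stop(sprintf("no reaction with id '%s'", id), call. = FALSE)
}
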