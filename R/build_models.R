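#' Rescale per-mg-protein carrier kinetics to a whole organ
#'
#' Caco-2 monolayer kinetics are reported per mg of monolayer protein; the
#' whole-organ value is `value * protein_density * surface_area` (1 cm2 of
#' monolayer carries 0.2 mg protein; mouse small-intestinal area 3e4 cm2,
#' human area carried as a configuration parameter, default 71e4 cm2).
#'
#' @param value_per_mg kinetic constant per mg protein (Vmax nmol/h/mg or
#'   Kd mL/h/mg)
#' @param surface_area_cm2 intestinal surface area, cm2
#' @param protein_density_mg_per_cm2 monolayer protein density, mg/cm2
#' @return whole-organ value
#' @export
#' @examples
#' rescale_proctor_kinetics(1, 3e4, 0.2) # 6000
rescale_proctor_kinetics <- function(value_per_mg, surface_area_cm2,
                                     protein_density_mg_per_cm2) {
  if (any(surface_area_cm2 < 0) || any(protein_density_mg_per_cm2 < 0)) {
    stop("area and protein density must be >= 0", call. = FALSE)
  }
  value_per_mg * protein_density_mg_per_cm2 * surface_area_cm2
}

# Shared assembler for both species. `organ` carries the fully resolved
# organ-level kinetic constants; `species` only controls the RBC compartment.
assemble_model <- function(species, phys, ktp, organ, inputs) {
  rem <- remainder_physiology(phys)
  vol <- phys$volumes
  q <- phys$flows
  co <- phys$cardiac_output

  need <- c("intestine", "stomach", "liver", "lungs", "brain", "muscle",
            "adipose", "heart", "remainder", "kidney")
  if (!all(need %in% names(ktp))) {
    stop("missing K_t:p for: ", paste(setdiff(need, names(ktp)), collapse = ", "),
         call. = FALSE)
  }

  comp <- rbind(
    compartment("lungs", vol[["lungs"]], "tissue_well_stirred", ktp[["lungs"]]),
    compartment("heart", vol[["heart"]], "tissue_well_stirred", ktp[["heart"]]),
    compartment("brain", vol[["brain"]], "tissue_well_stirred", ktp[["brain"]]),
    compartment("muscle", vol[["muscle"]], "tissue_well_stirred", ktp[["muscle"]]),
    compartment("adipose", vol[["adipose"]], "tissue_well_stirred", ktp[["adipose"]]),
    compartment("remainder", rem$volume, "tissue_well_stirred", ktp[["remainder"]]),
    compartment("stomach", vol[["stomach"]], "tissue_well_stirred", ktp[["stomach"]]),
    compartment("liver", vol[["liver"]], "tissue_well_stirred", ktp[["liver"]]),
    compartment("kidney_tissue", vol[["kidney_tissue"]], "tissue_well_stirred", ktp[["kidney"]]),
    compartment("enterocytes", vol[["enterocytes"]], "tissue_well_stirred", ktp[["intestine"]]),
    compartment("arterial_plasma", vol[["arterial_plasma"]], "vascular"),
    compartment("venous_plasma", vol[["venous_plasma"]], "vascular"),
    compartment("portal_vein", vol[["portal_vein"]], "vascular"),
    compartment("kidney_plasma", vol[["kidney_plasma"]], "vascular"),
    compartment("intestine_vascular", vol[["intestine_vascular"]], "vascular"),
    compartment("stomach_lumen", vol[["stomach_lumen"]], "lumen"),
    compartment("intestine_lumen", vol[["intestine_lumen"]], "lumen"),
    compartment("kidney_tubular", vol[["kidney_tubular"]], "lumen"),
    compartment("urine", NA, "excreta"),
    compartment("feces", NA, "excreta"))
  if (species == "human") {
    comp <- rbind(comp, compartment("rbc", vol[["rbc"]], "vascular"))
  }

  q_pv <- q[["stomach"]] + q[["intestine"]]
  q_liver <- q[["liver_arterial"]] + q_pv

  rx <- list(
    rate_law("01.1", "clearance", c(CL = co), "venous_plasma", "lungs",
             "VenousPlasma -> Lungs (flow)"),
    rate_law("01.2", "clearance", c(CL = co / ktp[["lungs"]]), "lungs",
             "arterial_plasma", "Lungs -> ArterialPlasma (flow/Ktp)"),
    rate_law("02.1", "clearance", c(CL = q[["heart"]]), "arterial_plasma", "heart"),
    rate_law("02.2", "clearance", c(CL = q[["heart"]] / ktp[["heart"]]), "heart", "venous_plasma"),
    rate_law("02.3", "clearance", c(CL = q[["brain"]]), "arterial_plasma", "brain"),
    rate_law("02.4", "clearance", c(CL = q[["brain"]] / ktp[["brain"]]), "brain", "venous_plasma"),
    rate_law("02.5", "clearance", c(CL = q[["muscle"]]), "arterial_plasma", "muscle"),
    rate_law("02.6", "clearance", c(CL = q[["muscle"]] / ktp[["muscle"]]), "muscle", "venous_plasma"),
    rate_law("02.7", "clearance", c(CL = q[["adipose"]]), "arterial_plasma", "adipose"),
    rate_law("02.8", "clearance", c(CL = q[["adipose"]] / ktp[["adipose"]]), "adipose", "venous_plasma"),
    rate_law("02.9", "clearance", c(CL = rem$flow), "arterial_plasma", "remainder"),
    rate_law("02.10", "clearance", c(CL = rem$flow / ktp[["remainder"]]), "remainder", "venous_plasma"),
    rate_law("02.11", "clearance", c(CL = q[["stomach"]]), "arterial_plasma", "stomach"),
    rate_law("02.12", "clearance", c(CL = q[["stomach"]] / ktp[["stomach"]]), "stomach", "portal_vein",
             "Stomach -> PortalVein (flow/Ktp)"),
    rate_law("04.1", "clearance", c(CL = q[["intestine"]]), "arterial_plasma", "intestine_vascular"),
    rate_law("04.2", "clearance", c(CL = q[["intestine"]]), "intestine_vascular", "portal_vein"),
    rate_law("05.1", "clearance", c(CL = q[["liver_arterial"]]), "arterial_plasma", "liver",
             "HepaticArtery -> Liver (flow)"),
    rate_law("05.2", "clearance", c(CL = q_pv), "portal_vein", "liver",
             "PortalVein -> Liver (flow)"),
    rate_law("05.3", "clearance", c(CL = q_liver / ktp[["liver"]]), "liver", "venous_plasma",
             "Liver -> VenousPlasma (flow/Ktp)"),
    # gastrointestinal transit
    rate_law("03.1", "first_order", c(k = phys$k_gastric), "stomach_lumen",
             "intestine_lumen", "StomachLumen -> IntestineLumen (gastric emptying)"),
    rate_law("03.8", "first_order", c(k = phys$k_transit), "intestine_lumen",
             "feces", "IntestineLumen -> Feces (intestinal transit)"),
    # intestinal absorption (permeability-limited sub-model)
    rate_law("03.2", "michaelis_menten", c(Vmax = organ[["v32"]], Km = organ[["km32"]]),
             "intestine_lumen", "enterocytes",
             "IntestineLumen -> Enterocytes (PMAT OCT3)", scale_group = "absorption"),
    rate_law("03.3", "michaelis_menten", c(Vmax = organ[["v33"]], Km = organ[["km33"]]),
             "enterocytes", "intestine_vascular",
             "Enterocytes -> IntestineVascular (OCT1)", scale_group = "absorption"),
    rate_law("03.4", "michaelis_menten", c(Vmax = organ[["v34"]], Km = organ[["km34"]]),
             "intestine_lumen", "intestine_vascular",
             "IntestineLumen -> IntestineVascular (saturable paracellular)",
             scale_group = "absorption"),
    rate_law("03.5", "partition_exchange",
             c(PS = organ[["ps_intestine"]], Ktp = ktp[["intestine"]]),
             "intestine_vascular", "enterocytes",
             "IntestineVascular <-> Enterocytes (passive exchange)"),
    rate_law("03.6", "clearance", c(CL = organ[["kd36"]]),
             "intestine_lumen", "enterocytes",
             "IntestineLumen -> Enterocytes (diffusion)", scale_group = "absorption"),
    rate_law("03.7", "clearance", c(CL = organ[["kd37"]]),
             "intestine_lumen", "intestine_vascular",
             "IntestineLumen -> IntestineVascular (paracellular diffusion)",
             scale_group = "absorption"),
    # kidney (permeability-limited sub-model)
    rate_law("13.1", "clearance", c(CL = q[["kidney"]]), "arterial_plasma", "kidney_plasma"),
    rate_law("13.2", "clearance", c(CL = q[["kidney"]]), "kidney_plasma", "venous_plasma"),
    rate_law("13.3", "partition_exchange",
             c(PS = organ[["ps_kidney"]], Ktp = ktp[["kidney"]]),
             "kidney_plasma", "kidney_tissue",
             "KidneyPlasma <-> KidneyTissue (passive exchange)"),
    rate_law("13.4", "michaelis_menten",
             c(Vmax = organ[["vmax_oct2"]], Km = organ[["km_oct2"]]),
             "kidney_plasma", "kidney_tissue",
             "KidneyPlasma -> KidneyTissue (OCT2)", scale_group = "elimination"),
    rate_law("13.5", "michaelis_menten",
             c(Vmax = organ[["vmax_mate"]], Km = organ[["km_mate"]]),
             "kidney_tissue", "kidney_tubular",
             "KidneyTissue -> KidneyTubular (MATE1/MATE2-K)", scale_group = "elimination"),
    rate_law("13.6", "gfr_filtration", c(CL = phys$q_gfr), "kidney_plasma",
             "kidney_tubular", "KidneyPlasma -> KidneyTubular (GFR)"),
    rate_law("13.7", "clearance", c(CL = phys$q_urine), "kidney_tubular",
             "urine", "KidneyTubular -> Urine (urine flow)"))
  if (species == "human") {
    rx <- c(rx, list(
      rate_law("15.1", "clearance", c(CL = organ[["cl_rbc_in"]]),
               "venous_plasma", "rbc", "VenousPlasma -> RBC (diffusion)"),
      rate_law("15.2", "clearance", c(CL = organ[["cl_rbc_out"]]),
               "rbc", "venous_plasma", "RBC -> VenousPlasma (diffusion)")))
  }

  flows <- rbind(
    data.frame(from = "venous_plasma", to = "lungs", q = co),
    data.frame(from = "lungs", to = "arterial_plasma", q = co),
    data.frame(from = "arterial_plasma",
               to = c("heart", "brain", "muscle", "adipose", "remainder",
                      "stomach", "kidney_plasma", "intestine_vascular", "liver"),
               q = c(q[["heart"]], q[["brain"]], q[["muscle"]], q[["adipose"]],
                     rem$flow, q[["stomach"]], q[["kidney"]], q[["intestine"]],
                     q[["liver_arterial"]])),
    data.frame(from = c("heart", "brain", "muscle", "adipose", "remainder",
                        "kidney_plasma", "liver"),
               to = "venous_plasma",
               q = c(q[["heart"]], q[["brain"]], q[["muscle"]], q[["adipose"]],
                     rem$flow, q[["kidney"]], q_liver)),
    data.frame(from = c("stomach", "intestine_vascular"), to = "portal_vein",
               q = c(q[["stomach"]], q[["intestine"]])),
    data.frame(from = "portal_vein", to = "liver", q = q_pv))

  pbpk_model(species, phys$body_weight, comp, rx, flows, inputs)
}

# Resolve organ-level kinetic constants for one species.
resolve_organ_kinetics <- function(species, phys, kinetics, coefs, kinetic_scale) {
  p <- kinetics$proctor
  area <- phys$intestinal_area_cm2
  dens <- if (species == "human") kinetics$proctor_coefficient_human else phys$protein_per_area
  acoef <- if (is.null(coefs)) 1 else coefs$absorption
  ecoef <- if (is.null(coefs)) 1 else coefs$elimination
  org <- c(
    v32 = rescale_proctor_kinetics(p[["v32_per_mg"]], area, dens) * acoef,
    km32 = p[["km32"]],
    v33 = rescale_proctor_kinetics(p[["v33_per_mg"]], area, dens) * acoef,
    km33 = p[["km33"]],
    v34 = rescale_proctor_kinetics(p[["v34_per_mg"]], area, dens) * acoef,
    km34 = p[["km34"]],
    kd36 = rescale_proctor_kinetics(p[["kd36_per_mg"]], area, dens) * acoef,
    kd37 = rescale_proctor_kinetics(p[["kd37_per_mg"]], area, dens) * acoef,
    ps_intestine = kinetics$ps_intestine[[species]] * kinetic_scale,
    ps_kidney = kinetics$ps_kidney[[species]] * kinetic_scale,
    vmax_oct2 = kinetics$kidney[["vmax_oct2"]] * ecoef * kinetic_scale,
    km_oct2 = kinetics$kidney[["km_oct2"]],
    vmax_mate = kinetics$kidney[["vmax_mate"]] * ecoef * kinetic_scale,
    km_mate = kinetics$kidney[["km_mate"]])
  if (species == "human") {
    org <- c(org, cl_rbc_in = kinetics$rbc[["cl_in"]] * kinetic_scale,
             cl_rbc_out = kinetics$rbc[["cl_out"]] * kinetic_scale)
  }
  org
}

#' Build the 20-compartment mouse model
#'
#' Whole-body flow-limited organs (lungs, heart, brain, muscle, adipose,
#' remainder, stomach, liver) connected through arterial/venous plasma and the
#' portal vein, a three-compartment permeability-limited small intestine
#' (vascular space, enterocytes, lumen) with carrier-mediated absorption, a
#' three-compartment kidney (plasma, tissue, proximal tubular lumen) with
#' glomerular filtration plus OCT2/MATE secretion, gastric and intestinal
#' lumen transit, and urine/feces sinks. No red-blood-cell compartment.
#'
#' @param phys a [default_physiology()] list (mouse)
#' @param kinetics a [default_kinetics()] list
#' @param ktp named partition-coefficient vector, see [default_ktp()]
#' @param kinetic_scale linear scaling of organ-level transport capacities
#'   with body size; defaults to `body_weight / 0.04`
#' @return a validated `pbpk_model` with 20 compartments
#' @export
build_mouse_model <- function(phys = default_physiology("mouse"),
                              kinetics = default_kinetics(),
                              ktp = default_ktp(),
                              kinetic_scale = phys$body_weight / 0.04) {
  if (phys$species != "mouse") stop("phys must be a mouse physiology", call. = FALSE)
  organ <- resolve_organ_kinetics("mouse", phys, kinetics, coefs = NULL,
                                  kinetic_scale = kinetic_scale)
  assemble_model("mouse", phys, ktp, organ,
                 inputs = list(phys = phys, kinetics = kinetics, ktp = ktp,
                               coefs = NULL, kinetic_scale = kinetic_scale))
}

#' Build the 21-compartment human model by mouse-to-human scale-up
#'
#' Identical structure to the mouse model plus a red-blood-cell compartment
#' exchanging with venous plasma by slow first-order diffusion (RBC is
#' excluded from the flow topology). Mouse partition coefficients are used
#' unchanged. The absorption coefficient multiplies the kinetic constants of
#' the five intestinal absorption reactions (03.2, 03.3, 03.4, 03.6, 03.7)
#' and the elimination coefficient the two active renal reactions (13.4,
#' 13.5). Volumes, flows and organ-level transport capacities scale linearly
#' with `body_weight / 70`.
#'
#' @param phys human physiology; defaults to
#'   `default_physiology("human", body_weight)`
#' @param kinetics a [default_kinetics()] list (mouse-referenced)
#' @param ktp named partition-coefficient vector (mouse values, unchanged)
#' @param coefs [scale_up_coefficients()]
#' @param body_weight body weight, kg (adjustable parameter)
#' @param kinetic_scale linear scaling of organ-level transport capacities;
#'   defaults to `body_weight / 70`
#' @return a validated `pbpk_model` with 21 compartments
#' @export
build_human_model <- function(phys = NULL,
                              kinetics = default_kinetics(),
                              ktp = default_ktp(),
                              coefs = scale_up_coefficients(),
                              body_weight = 70,
                              kinetic_scale = body_weight / 70) {
  if (is.null(phys)) phys <- default_physiology("human", body_weight)
  if (!"rbc" %in% names(phys$volumes)) {
    stop("human physiology must include an 'rbc' volume", call. = FALSE)
  }
  organ <- resolve_organ_kinetics("human", phys, kinetics, coefs, kinetic_scale)
  assemble_model("human", phys, ktp, organ,
                 inputs = list(phys = phys, kinetics = kinetics, ktp = ktp,
                               coefs = coefs, kinetic_scale = kinetic_scale))
}

#' Tissue-proportion scenario: change a tissue's volume
#'
#' Increases (or decreases) one tissue's volume; its plasma flow scales by
#' the new/old volume ratio, so cardiac output and lung flow grow by the same
#' absolute flow increment. All kinetic parameters are untouched. Used for
#' body-composition scenarios (e.g. +20 L muscle for an athlete, +60 L
#' adipose for obesity).
#'
#' @param model a `pbpk_model` built by [build_mouse_model()] or
#'   [build_human_model()]
#' @param tissue one of the named flow-limited tissues (e.g. `"muscle"`,
#'   `"adipose"`)
#' @param volume_delta volume change, mL (resulting volume must be > 0)
#' @return the rebuilt `pbpk_model`
#' @export
scenario_modify_tissue <- function(model, tissue, volume_delta) {
  inputs <- model$inputs
  if (is.null(inputs$phys)) stop("model does not carry its build inputs", call. = FALSE)
  phys <- inputs$phys
  if (!tissue %in% names(phys$volumes) || !tissue %in% names(phys$flows)) {
    stop(sprintf("tissue '%s' not found among named perfused tissues", tissue),
         call. = FALSE)
  }
  if (volume_delta == 0) return(model)
  v_old <- phys$volumes[[tissue]]
  v_new <- v_old + volume_delta
  if (v_new <= 0) stop("resulting tissue volume must be > 0", call. = FALSE)
  q_old <- phys$flows[[tissue]]
  q_new <- q_old * v_new / v_old
  phys$volumes[[tissue]] <- v_new
  phys$flows[[tissue]] <- q_new
  phys$cardiac_output <- phys$cardiac_output + (q_new - q_old)
  # the added tissue enlarges the body; keeps the computed remainder unchanged
  phys$body_weight <- phys$body_weight + volume_delta / 1000
  if (model$species == "mouse") {
    build_mouse_model(phys, inputs$kinetics, inputs$ktp, inputs$kinetic_scale)
  } else {
    build_human_model(phys, inputs$kinetics, inputs$ktp, inputs$coefs,
                      body_weight = phys$body_weight,
                      kinetic_scale = inputs$kinetic_scale)
  }
}
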