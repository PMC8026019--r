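#' Reference physiology tables
#'
#' Species physiology (tissue volumes, plasma flows, filtration, gut motility)
#' assembled from standard laboratory-rodent and reference-human values. The
#' quantities the source publications print directly (intestinal surface
#' areas, monolayer protein density, the partition-coefficient table, the
#' scale-up coefficients) are used as printed; the remaining entries are a
#' synthetic reconstruction calibrated once against the published headline
#' pharmacokinetics (see the methods vignette) and then frozen.
#'
#' Units: volumes mL, flows mL/h, rates 1/h, areas cm2, protein mg/cm2.
#' Flows are plasma flows; the remainder tissue's volume and flow are computed
#' as total minus the named tissues and must stay positive.
#'
#' @param species `"mouse"` or `"human"`
#' @param body_weight body weight in kg; defaults to the reference weight
#'   (0.04 mouse, 70 human). Volumes and flows scale linearly with
#'   `body_weight / reference_weight`.
#' @return a `pbpk_physiology` list
#' @export
default_physiology <- function(species = c("mouse", "human"), body_weight = NULL) {
  species <- match.arg(species)
  if (species == "mouse") {
    ref_bw <- 0.04
    vol <- c(lungs = 0.29, heart = 0.2, brain = 0.5, muscle = 15.4,
             adipose = 2.8, stomach = 0.24, liver = 2.2,
             kidney_plasma = 0.08, kidney_tissue = 0.55, kidney_tubular = 0.055,
             intestine_vascular = 0.16, enterocytes = 0.48,
             intestine_lumen = 0.56, stomach_lumen = 0.48,
             arterial_plasma = 0.56, venous_plasma = 1.04, portal_vein = 0.16)
    flow <- c(heart = 78, brain = 40, muscle = 189, adipose = 60,
              stomach = 14, kidney = 108, intestine = 142, liver_arterial = 24)
    phys <- list(species = species, body_weight = ref_bw,
                 cardiac_output = 1193, volumes = vol, flows = flow,
                 q_gfr = 14, q_urine = 0.06,
                 k_gastric = 3.0, k_transit = 1.0,
                 hematocrit = NA_real_,
                 intestinal_area_cm2 = 3e4, protein_per_area = 0.2)
  } else {
    ref_bw <- 70
    vol <- c(lungs = 530, heart = 330, brain = 1450, muscle = 28000,
             adipose = 15000, stomach = 150, liver = 1800,
             kidney_plasma = 30, kidney_tissue = 280, kidney_tubular = 30,
             intestine_vascular = 300, enterocytes = 650,
             intestine_lumen = 350, stomach_lumen = 250,
             arterial_plasma = 900, venous_plasma = 1900, portal_vein = 70,
             rbc = 2340)
    flow <- c(heart = 6864, brain = 20592, muscle = 36000, adipose = 8580,
              stomach = 1716, kidney = 45000, intestine = 25740,
              liver_arterial = 11154)
    phys <- list(species = species, body_weight = ref_bw,
                 cardiac_output = 171600, volumes = vol, flows = flow,
                 q_gfr = 7200, q_urine = 60,
                 k_gastric = 3.5, k_transit = 0.5,
                 hematocrit = 0.45,
                 intestinal_area_cm2 = 71e4, protein_per_area = 0.2)
  }
  if (!is.null(body_weight)) {
    s <- body_weight / ref_bw
    if (s <= 0) stop("body_weight must be > 0", call. = FALSE)
    phys$body_weight <- body_weight
    phys$volumes <- phys$volumes * s
    phys$flows <- phys$flows * s
    phys$cardiac_output <- phys$cardiac_output * s
    phys$q_gfr <- phys$q_gfr * s
    phys$q_urine <- phys$q_urine * s
    phys$intestinal_area_cm2 <- phys$intestinal_area_cm2 * s
  }
  structure(phys, class = "pbpk_physiology")
}

# remainder tissue volume and flow, computed as total minus named tissues
remainder_physiology <- function(phys) {
  named_flow <- sum(phys$flows)
  q_rem <- phys$cardiac_output - named_flow
  total_vol <- phys$body_weight * 1000 # ~1 mL/g body density
  lumens <- c("intestine_lumen", "stomach_lumen")
  v_rem <- total_vol - sum(phys$volumes[setdiff(names(phys$volumes), lumens)])
  if (q_rem <= 0 || v_rem <= 0) {
    stop("remainder tissue volume/flow must be positive: named tissues exceed the total",
         call. = FALSE)
  }
  list(volume = v_rem, flow = q_rem)
}

#' Default tissue:plasma partition coefficients
#'
#' The fitted (estimated) partition coefficients of the mouse model; the
#' scale-up assumes they are identical in humans, so the same set
#' parameterizes both species.
#'
#' @return named vector of K_t:p values
#' @export
default_ktp <- function() {
  c(intestine = 4.6, stomach = 3.2, liver = 5.5, lungs = 3.0, brain = 0.8,
    muscle = 4.1, adipose = 0.7, heart = 2.5, remainder = 0.8, kidney = 4.5)
}

#' Calculated (tissue-composition) partition coefficients
#'
#' Partition coefficients predicted from tissue composition
#' (lipophilicity/ionization-based method), used only as the comparison
#' column against the fitted values; treated as printed constants. Stomach
#' and remainder have no calculated value.
#'
#' @return named vector of K_t:p values
#' @export
calculated_ktp <- function() {
  c(intestine = 3.0, liver = 7.0, lungs = 2.7, brain = 2.0, muscle = 4.9,
    adipose = 0.4, heart = 3.1, kidney = 4.3)
}

#' Default transporter and transit kinetics
#'
#' Intestinal carrier kinetics are carried per mg of monolayer protein
#' (Caco-2 convention) and rescaled to whole-organ values via
#' [rescale_proctor_kinetics()] using the species' intestinal surface area and
#' protein density. The renal OCT2/MATE parameters, the passive
#' tissue-exchange permeabilities and the red-blood-cell exchange clearances
#' are organ-level mouse values; the human model multiplies the five
#' absorption reactions by the absorption coefficient and the two active
#' renal reactions by the elimination coefficient.
#'
#' Values are a synthetic reconstruction calibrated against the published
#' headline pharmacokinetics (see the methods vignette).
#'
#' @return a `pbpk_kinetics` list with elements
#'   `proctor` (per-mg-protein intestinal table),
#'   `kidney` (mouse organ-level renal parameters),
#'   `ps_intestine`, `ps_kidney` (passive exchange, mL/h, per species),
#'   `rbc` (human red-blood-cell exchange clearances, mL/h),
#'   `proctor_coefficient_human` (mg protein per cm2 used for the human
#'   intestine; adjustable, the mouse uses the measured monolayer density)
#' @export
default_kinetics <- function() {
  structure(list(
    proctor = c(
      v32_per_mg = 0.6,    # 03.2 lumen -> enterocytes (PMAT/OCT3) Vmax, nmol/h/mg
      km32 = 1200,          # nmol/mL
      v33_per_mg = 0.0825,  # 03.3 enterocytes -> vascular (OCT1) Vmax (reduced value)
      km33 = 9000,
      v34_per_mg = 0.15,    # 03.4 lumen -> vascular saturable paracellular
      km34 = 2000,
      kd36_per_mg = 2.2e-5, # 03.6 lumen -> enterocytes diffusion, mL/h/mg
      kd37_per_mg = 1.0e-5  # 03.7 lumen -> vascular paracellular diffusion
    ),
    kidney = c(
      vmax_oct2 = 400000,    # 13.4 kidney plasma -> kidney tissue, nmol/h (mouse)
      km_oct2 = 1000,
      vmax_mate = 6280,      # 13.5 kidney tissue -> tubular lumen, nmol/h (mouse)
      km_mate = 780
    ),
    ps_intestine = c(mouse = 6, human = 3000),   # 03.5 vascular <-> enterocytes
    ps_kidney = c(mouse = 5, human = 500),       # 13.3 plasma <-> kidney tissue
    rbc = c(cl_in = 75, cl_out = 85),            # venous <-> RBC, human
    proctor_coefficient_human = 1.75
  ), class = "pbpk_kinetics")
}

#' Default mouse-to-human scale-up coefficients
#'
#' The absorption coefficient multiplies the kinetic constants of the five
#' intestinal absorption reactions (03.2, 03.3, 03.4, 03.6, 03.7); the
#' elimination coefficient multiplies the two active renal transport
#' reactions (13.4, 13.5).
#'
#' @param absorption absorption scaling coefficient (> 0)
#' @param elimination elimination scaling coefficient (> 0)
#' @return a `pbpk_scaleup` list
#' @export
scale_up_coefficients <- function(absorption = 0.7, elimination = 320) {
  if (absorption <= 0 || elimination <= 0) {
    stop("scale-up coefficients must be > 0", call. = FALSE)
  }
  structure(list(absorption = absorption, elimination = elimination),
            class = "pbpk_scaleup")
}

#' Intracellular (inulin-space) fractions per organ
#'
#' Fractions of organ volume that are intracellular, used to undo the
#' extracellular-space correction applied to published mouse tissue
#' homogenate concentrations. The source table is not reproduced in the text,
#' so these are synthetic stand-in values in the physiological range;
#' override with measured fractions where available.
#'
#' @return named vector of fractions in (0, 1]
#' @export
default_intracellular_fractions <- function() {
  c(intestine = 0.70, stomach = 0.70, liver = 0.78, kidney = 0.76,
    heart = 0.70, muscle = 0.67, adipose = 0.90, brain = 0.80)
}
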