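# Lazily built, cached models and simulations shared across test files.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

mouse_model <- function() cached("mouse", build_mouse_model())
human_model <- function() cached("human", build_human_model())

mouse_po_schedule <- function() dose_schedule(0, 50 * 0.04, "PO") # 50 mg/kg HCl
mouse_iv_schedule <- function() dose_schedule(0, 50 * 0.04, "IV")

mouse_po_sim <- function() cached("mouse_po_sim",
  simulate_pbpk(mouse_model(), mouse_po_schedule(), 24))
mouse_iv_sim <- function() cached("mouse_iv_sim",
  simulate_pbpk(mouse_model(), mouse_iv_schedule(), 24))
human_po_sim <- function() cached("human_po_sim",
  simulate_pbpk(human_model(), dose_schedule(0, 500, "PO"), 48))

# one-compartment degenerate model: volume V, linear clearance CL into urine
one_compartment_model <- function(V = 10, CL = 2) {
  comp <- rbind(
    compartment("venous_plasma", V, "vascular"),
    compartment("urine", NA, "excreta"))
  rx <- list(rate_law("cl", "clearance", c(CL = CL), "venous_plasma", "urine"))
  pbpk_model("mouse", 1, comp, rx, flows = data.frame())
}

# noiseless synthetic mouse recovery datasets (all tissues observed)
recovery_datasets <- function() cached("recovery_ds", {
  m <- mouse_model()
  list(
    po = generate_dataset(m, mouse_po_schedule(), preset_recovery(),
                          noise_model("none"), label = "po"),
    iv = generate_dataset(m, mouse_iv_schedule(), preset_wilcock_iv(),
                          noise_model("none"), label = "iv"))
})
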