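test_that("mouse and human models have 20 and 21 compartments", {
  m <- mouse_model(); h <- human_model()
  expect_equal(nrow(m$compartments), 20)
  expect_equal(nrow(h$compartments), 21)
  expect_false("rbc" %in% m$compartments$name)
  expect_true("rbc" %in% h$compartments$name)
  expect_setequal(setdiff(h$compartments$name, m$compartments$name), "rbc")
  # the remainder tissue is computed as total minus named and must be positive
  rem <- m$compartments[m$compartments$name == "remainder", ]
  expect_gt(rem$volume, 0)
})

test_that("tissue flows sum to cardiac output at the venous node", {
  for (model in list(mouse_model(), human_model())) {
    fl <- model$flows
    co <- sum(fl$q[fl$from == "venous_plasma"])
    expect_equal(sum(fl$q[fl$to == "venous_plasma"]), co)
    expect_equal(sum(fl$q[fl$to == "lungs"]), co)
  }
})

test_that("no absorption path exists from the stomach lumen into stomach tissue", {
  m <- mouse_model()
  from_stomach_lumen <- vapply(m$reactions, function(r)
    r$source == "stomach_lumen", TRUE)
  sinks <- vapply(m$reactions[from_stomach_lumen], `[[`, "", "sink")
  expect_setequal(sinks, "intestine_lumen") # gastric emptying only
})

test_that("with all transport reactions zeroed the dose stays in the lumen", {
  m <- mouse_model()
  m$reactions <- lapply(m$reactions, function(r) {
    # zero capacities but keep Km/Ktp positive (they sit in denominators)
    for (p in intersect(names(r$params), c("CL", "Vmax", "PS"))) r$params[[p]] <- 0
    r
  })
  sim <- simulate_pbpk(m, dose_schedule(0, 2, "PO"), 24)
  lumen <- c("stomach_lumen", "intestine_lumen", "feces")
  body <- setdiff(colnames(sim$amounts), lumen)
  expect_true(all(sim$amounts[, body] == 0))
  expect_equal(sum(sim$amounts[nrow(sim$amounts), lumen]),
               sum(sim$schedule$amount_nmol), tolerance = 1e-8)
})

test_that("intestinal kinetics rescale per protein density and surface area", {
  expect_equal(rescale_proctor_kinetics(1, 3e4, 0.2), 6e3)
  expect_equal(rescale_proctor_kinetics(5, 100, 0), 0)
  # organ-level ratio equals the area ratio at equal density
  expect_equal(rescale_proctor_kinetics(2, 71e4, 0.2) /
               rescale_proctor_kinetics(2, 3e4, 0.2), 71e4 / 3e4)
})

test_that("the scale-up multiplies exactly the five absorption and two renal reactions", {
  base <- build_human_model(coefs = scale_up_coefficients(1, 1))
  scaled <- build_human_model(coefs = scale_up_coefficients(0.7, 320))
  for (id in c("03.2", "03.3", "03.4")) {
    expect_equal(get_reaction(scaled, id)$params[["Vmax"]],
                 0.7 * get_reaction(base, id)$params[["Vmax"]])
    expect_equal(get_reaction(scaled, id)$params[["Km"]],
                 get_reaction(base, id)$params[["Km"]])
  }
  for (id in c("03.6", "03.7")) {
    expect_equal(get_reaction(scaled, id)$params[["CL"]],
                 0.7 * get_reaction(base, id)$params[["CL"]])
  }
  for (id in c("13.4", "13.5")) {
    expect_equal(get_reaction(scaled, id)$params[["Vmax"]],
                 320 * get_reaction(base, id)$params[["Vmax"]])
  }
  # everything else untouched (e.g. passive exchange, GFR, flows)
  for (id in c("03.5", "13.3", "13.6", "01.1")) {
    expect_equal(get_reaction(scaled, id)$params, get_reaction(base, id)$params)
  }
})

test_that("human model with unit coefficients and mouse physiology matches the mouse model", {
  mph <- default_physiology("mouse")
  mph$volumes <- c(mph$volumes, rbc = 1e-8) # inert, negligible-volume RBC
  kin <- default_kinetics()
  kin$ps_intestine[["human"]] <- kin$ps_intestine[["mouse"]]
  kin$ps_kidney[["human"]] <- kin$ps_kidney[["mouse"]]
  kin$rbc[] <- 0
  kin$proctor_coefficient_human <- mph$protein_per_area
  h <- build_human_model(phys = mph, kinetics = kin,
                         coefs = scale_up_coefficients(1, 1),
                         body_weight = mph$body_weight, kinetic_scale = 1)
  expect_equal(nrow(h$compartments), 21)
  sh <- simulate_pbpk(h, dose_schedule(0, 2, "PO"), 12)
  sm <- simulate_pbpk(mouse_model(), dose_schedule(0, 2, "PO"), 12)
  shared <- colnames(sm$amounts)
  expect_equal(sh$amounts[, shared], sm$amounts[, shared], tolerance = 1e-8)
  expect_true(all(sh$amounts[, "rbc"] == 0))
})

test_that("doubling body weight with dose-per-kg leaves the linear variant invariant", {
  a <- linearize_model(build_human_model(body_weight = 70))
  b <- linearize_model(build_human_model(body_weight = 140))
  sa <- simulate_pbpk(a, dose_schedule(0, 500, "PO"), 24)
  sb <- simulate_pbpk(b, dose_schedule(0, 1000, "PO"), 24)
  expect_equal(sb$conc[, "venous_plasma"], sa$conc[, "venous_plasma"],
               tolerance = 1e-6)
  expect_equal(sb$conc[, "muscle"], sa$conc[, "muscle"], tolerance = 1e-6)
})

test_that("tissue-proportion scenarios scale volume, flow and cardiac output together", {
  h <- human_model()
  expect_identical(scenario_modify_tissue(h, "muscle", 0), h)
  athlete <- scenario_modify_tissue(h, "muscle", 20e3)
  vm <- function(m, x) m$compartments$volume[m$compartments$name == x]
  expect_equal(vm(athlete, "muscle"), 48e3)
  q0 <- h$inputs$phys$flows[["muscle"]]
  q1 <- athlete$inputs$phys$flows[["muscle"]]
  expect_equal(q1 / q0, 48 / 28)
  # cardiac output and lung flow rise by the same absolute increment
  co0 <- h$inputs$phys$cardiac_output; co1 <- athlete$inputs$phys$cardiac_output
  expect_equal(co1 - co0, q1 - q0)
  fl <- athlete$flows
  expect_equal(sum(fl$q[fl$to == "lungs"]), co1)
  # the remainder tissue is untouched by the scenario
  expect_equal(vm(athlete, "remainder"), vm(h, "remainder"))

  obese <- scenario_modify_tissue(h, "adipose", 60e3)
  expect_equal(vm(obese, "adipose"), 75e3)
  expect_equal(obese$inputs$phys$flows[["adipose"]] / h$inputs$phys$flows[["adipose"]], 5)
  expect_error(scenario_modify_tissue(h, "spleen", 10), "not found")
  expect_error(scenario_modify_tissue(h, "adipose", -20e3), "> 0")
})

test_that("the mouse oral dose reproduces the ~61% urinary excretion study condition", {
  sim <- mouse_po_sim()
  frac <- utils::tail(cumulative_urine(sim)$amount, 1) / sum(sim$schedule$amount_nmol)
  expect_gt(frac, 0.55)
  expect_lt(frac, 0.67)
})
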