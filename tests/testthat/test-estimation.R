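test_that("inulin correction divides by FI and round-trips", {
  expect_equal(inulin_correction(50, 1), 50)
  expect_equal(inulin_correction(50, 0.5), 100)
  x <- c(3.2, 18, 440)
  expect_equal(inulin_correction(inulin_correction(x, 0.7), 0.7, "multiply"), x)
  expect_error(inulin_correction(1, 0), "FI")
  expect_error(inulin_correction(1, 1.2), "FI")
})

test_that("mouse oral exclusion rules flag the stomach curve and the 2 h artefact points", {
  m <- mouse_model()
  ds <- generate_dataset(m, mouse_po_schedule(), preset_recovery(), noise_model("none"))
  ds <- apply_exclusions(ds)
  obs <- ds$observations
  expect_true(all(obs$excluded[obs$tissue == "stomach"])) # whole curve
  point_flags <- obs$excluded & obs$tissue != "stomach"
  expect_equal(sum(point_flags), 3)
  expect_setequal(obs$tissue[point_flags], c("plasma", "portal_vein", "brain"))
  expect_true(all(obs$time_h[point_flags] == 2))
  expect_equal(nrow(obs), nrow(ds$observations)) # flagged, never deleted

  # IV and human datasets are untouched
  iv <- apply_exclusions(recovery_datasets()$iv)
  expect_false(any(iv$observations$excluded))
  h <- generate_dataset(human_model(), dose_schedule(0, 500, "PO"),
                        preset_zaharenko(), noise_model("none"))
  expect_false(any(apply_exclusions(h)$observations$excluded))
})

test_that("the objective equals a brute-force weighted sum of squares", {
  V <- 10; CL <- 2
  builder <- function(p) one_compartment_model(V, p[["cl"]])
  obs <- data.frame(tissue = "plasma", time_h = c(0.5, 1, 2, 4, 8),
                    value = c(70, 60, 40, 20, 5))
  ds <- experiment_dataset("toy", "mouse", dose_schedule(0, 1, "IV"), obs)
  p <- c(cl = 3)
  got <- pbpk_objective(p, builder, list(ds))
  # brute force: dense simulation, pointwise interpolation, per-curve weight
  sim <- simulate_pbpk(builder(p), ds$schedule, 8.5, fit_solver_options())
  pred <- approx(sim$time, sim$conc[, "venous_plasma"], xout = obs$time_h)$y
  w <- 1 / mean(obs$value)^2
  expect_equal(got, sum(w * (pred - obs$value)^2), tolerance = 1e-12)
  # a perfect model gives (numerically) zero
  obs2 <- obs
  obs2$value <- dose_hcl_mg_to_nmol(1) / V * exp(-CL * obs$time_h / V)
  ds2 <- experiment_dataset("toy2", "mouse", dose_schedule(0, 1, "IV"), obs2)
  expect_lt(pbpk_objective(c(cl = CL), builder, list(ds2)), 1e-8)
})

test_that("the objective ignores excluded points and dataset row order", {
  ds <- apply_exclusions(generate_dataset(mouse_model(), mouse_po_schedule(),
                                          preset_recovery(), noise_model("none")))
  builder <- standard_fit_builder("mouse")
  p <- c(ktp.liver = 4.0)
  o1 <- pbpk_objective(p, builder, list(ds))
  shuffled <- ds
  set.seed(7)
  shuffled$observations <- ds$observations[sample(nrow(ds$observations)), ]
  expect_equal(pbpk_objective(p, builder, list(shuffled)), o1, tolerance = 1e-12)
  # perturbing only excluded values changes nothing
  tampered <- ds
  tampered$observations$value[tampered$observations$excluded] <- 999
  expect_equal(pbpk_objective(p, builder, list(tampered)), o1, tolerance = 1e-12)
})

test_that("fit specifications validate bounds and parameters", {
  ds <- recovery_datasets()$po
  b <- standard_fit_builder("mouse")
  expect_error(fit_spec(data.frame(name = "ktp.liver", start = 1, lower = 0,
                                   upper = 10), list(ds), b), "positive")
  expect_error(fit_spec(data.frame(name = "ktp.liver", start = 100, lower = 1,
                                   upper = 10), list(ds), b), "within the bounds")
  expect_error(fit_spec(data.frame(name = character(), start = numeric(),
                                   lower = numeric(), upper = numeric()),
                        list(ds), b), "at least one")
})

test_that("fits are reproducible from the seed and improve on their starts", {
  ds <- recovery_datasets()$po
  pars <- data.frame(name = c("ktp.muscle", "ktp.liver"), start = c(2, 2),
                     lower = 0.2, upper = 20)
  fs <- fit_spec(pars, list(ds), standard_fit_builder("mouse"),
                 n_starts = 3, seed = 11)
  f1 <- fit_pbpk(fs)
  f2 <- fit_pbpk(fs)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$starts, f2$starts)
  expect_true(all(f1$objective <= f1$starts$objective))
  expect_equal(unname(f1$par), c(4.1, 5.5), tolerance = 0.01)
})

test_that("partition-coefficient comparison reports percent differences per tissue", {
  tab <- compare_partition_coefficients(default_ktp())
  expect_equal(tab$pct_difference[tab$tissue == "intestine"], 53.3, tolerance = 1e-2)
  expect_equal(tab$pct_difference[tab$tissue == "adipose"], 75, tolerance = 1e-6)
  expect_equal(tab$pct_difference[tab$tissue == "liver"],
               100 * (5.5 - 7.0) / 7.0, tolerance = 1e-6)
  expect_true(is.na(tab$calculated[tab$tissue == "stomach"]))
  same <- compare_partition_coefficients(calculated_ktp())
  expect_true(all(same$pct_difference[!is.na(same$pct_difference)] == 0))
})
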