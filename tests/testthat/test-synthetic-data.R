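test_that("noiseless datasets equal the simulation at the sample times", {
  m <- mouse_model()
  ds <- generate_dataset(m, mouse_po_schedule(), preset_wilcock_po(),
                         noise_model("none"))
  sim <- simulate_pbpk(m, mouse_po_schedule(), 24,
                       solver_options(output_resolution = 20))
  obs <- ds$observations
  liver <- obs[obs$tissue == "liver", ]
  expect_equal(liver$value,
               approx(sim$time, sim$conc[, "liver"], xout = liver$time_h)$y,
               tolerance = 1e-6)
  urine <- obs[obs$tissue == "urine", ]
  expect_equal(urine$value,
               utils::tail(sim$amounts[, "urine"], 1), tolerance = 1e-6)
  expect_false(any(is.na(obs$value)))
})

test_that("the same seed reproduces the dataset bit for bit", {
  m <- mouse_model()
  d1 <- generate_dataset(m, mouse_po_schedule(), preset_wilcock_po(),
                         noise_model(cv = 0.1, seed = 99))
  d2 <- generate_dataset(m, mouse_po_schedule(), preset_wilcock_po(),
                         noise_model(cv = 0.1, seed = 99))
  d3 <- generate_dataset(m, mouse_po_schedule(), preset_wilcock_po(),
                         noise_model(cv = 0.1, seed = 100))
  expect_identical(d1$observations, d2$observations)
  expect_false(identical(d1$observations$value, d3$observations$value))
})

test_that("lognormal noise has the requested coefficient of variation", {
  # many samples of one curve: pointwise noisy/true ratios are iid lognormal
  m <- one_compartment_model(V = 10, CL = 1)
  times <- seq(0.1, 80, length.out = 1000)
  scheme <- sampling_scheme("plasma", times)
  truth <- generate_dataset(m, dose_schedule(0, 1, "IV"), scheme, noise_model("none"))
  noisy <- generate_dataset(m, dose_schedule(0, 1, "IV"), scheme,
                            noise_model(cv = 0.1, seed = 5))
  ratio <- noisy$observations$value / truth$observations$value
  expect_equal(sd(ratio) / mean(ratio), 0.1, tolerance = 0.012)
  expect_equal(mean(ratio), 1, tolerance = 0.02) # multiplicative, unbiased
})

test_that("sampling presets mirror the study designs", {
  po <- preset_wilcock_po()
  expect_setequal(po$tissues, c("plasma", "portal_vein", "intestine", "liver",
                                "kidney", "heart", "muscle", "adipose", "brain"))
  expect_equal(po$times, c(0.5, 1, 2, 4, 8, 24))
  iv <- preset_wilcock_iv()
  expect_setequal(iv$tissues, c("plasma", "intestine", "stomach", "liver"))
  expect_equal(iv$times, c(0.5, 1, 2, 4))
  z <- preset_zaharenko()
  expect_setequal(z$tissues, c("plasma", "rbc"))
  expect_equal(z$times, c(1, 2, 3, 4, 6, 10, 24))
  expect_equal(z$urine_times, c(4, 6, 10, 24))
  # pre-dose designs: 375 mg at -12 h before 250 mg; 1000 before 1000
  ch <- preset_chung(250)
  expect_equal(ch$schedule$amount_mg_hcl, c(375, 250))
  expect_equal(diff(ch$schedule$time), 12)
  expect_equal(preset_chung(1000)$schedule$amount_mg_hcl, c(1000, 1000))
  em <- preset_el_messaoudi()
  expect_equal(nrow(em$schedule), 7)
  expect_true(all(em$scheme$times > max(em$schedule$time)))
  # all schemes strictly increasing
  for (s in list(po, iv, z, ch$scheme, em$scheme, preset_recovery())) {
    expect_false(is.unsorted(s$times, strictly = TRUE))
  }
  expect_error(sampling_scheme("plasma", c(2, 1)), "increasing")
})

test_that("dataset CSV round-trips through the tidy dialect with ground truth sidecar", {
  m <- mouse_model()
  ds <- generate_dataset(m, mouse_po_schedule(), preset_wilcock_po(),
                         noise_model(cv = 0.1, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  d <- read.csv(path)
  expect_setequal(names(d), c("dataset_label", "tissue", "time_h",
                              "conc_nmol_per_mL", "sd", "n", "excluded", "measure"))
  expect_setequal(unique(d$measure[d$tissue == "urine"]), "amount")
  back <- read_dataset_csv(path, "mouse", mouse_po_schedule())
  expect_equal(back$observations$value, ds$observations$value)
  truth <- jsonlite::read_json(sub("\\.csv$", "_truth.json", path))
  expect_equal(truth$muscle, 4.1)
})
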