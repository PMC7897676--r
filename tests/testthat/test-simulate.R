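test_that("peak-table simulation is exact at zero jitter and bias", {
  sim <- simulate_peak_table(ms_sim_config(mass_jitter_ppm = 0,
                                           mass_bias_ppm = 0,
                                           envelope_noise = 0,
                                           n_decoys = 0, seed = 2))
  ref <- ref_table()
  for (i in seq_len(nrow(sim$truth))) {
    pat <- isotope_pattern(
      ion_species(parse_formula(sim$truth$mh_composition[i])))
    got <- sim$peaks$mz[sim$peaks$rt_min == sim$truth$rt_min[i]]
    expect_equal(sort(got), sort(pat$mz), tolerance = 1e-9)
  }
  expect_identical(nrow(sim$truth), nrow(ref))
})

test_that("simulation is deterministic given its seed", {
  a <- simulate_peak_table(ms_sim_config(seed = 123))
  b <- simulate_peak_table(ms_sim_config(seed = 123))
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_peak_table(ms_sim_config(seed = 124))
  expect_false(identical(a$peaks$mz, c_$peaks$mz))

  ia <- simulate_ir_library(ir_sim_config(seed = 7))
  ib <- simulate_ir_library(ir_sim_config(seed = 7))
  expect_identical(ia$library[["isomer_2"]]$absorbance,
                   ib$library[["isomer_2"]]$absorbance)
  expect_identical(ia$queries[["isomer_1"]]$absorbance,
                   ib$queries[["isomer_1"]]$absorbance)
})

test_that("metabolite retention times stay strictly below the parent's", {
  sim <- simulate_peak_table(ms_sim_config(seed = 21))
  met <- sim$truth[sim$truth$acronym != "3-MeO-PCP", ]
  expect_true(all(met$rt_min < 0.98 * 7.74))
  expect_true(all(met$rt_min > 0.4 * 7.74))
  expect_identical(sim$truth$rt_min[sim$truth$acronym == "3-MeO-PCP"], 7.74)
})

test_that("planted mass bias appears as the simulated ppm offset", {
  sim <- simulate_peak_table(ms_sim_config(mass_jitter_ppm = 0,
                                           mass_bias_ppm = 3,
                                           envelope_noise = 0,
                                           n_decoys = 0, seed = 2))
  for (i in seq_len(nrow(sim$truth))) {
    pat <- isotope_pattern(
      ion_species(parse_formula(sim$truth$mh_composition[i])))
    got <- sort(sim$peaks$mz[sim$peaks$rt_min == sim$truth$rt_min[i]])
    expect_equal(got / sort(pat$mz), rep(1 + 3e-6, 4), tolerance = 1e-9)
  }
})

test_that("noise-free IR queries match their library entry at QMF 100", {
  sim <- simulate_ir_library(ir_sim_config(noise_sd = 0,
                                           drift_amplitude = 0, seed = 5))
  q <- sim$queries[["isomer_1"]]
  expect_equal(as.numeric(qmf(preprocess_ir(q),
                              preprocess_ir(sim$library[["isomer_1"]]))),
               100, tolerance = 1e-9)
})

test_that("simulated IR spectra live on the standard acquisition grid", {
  sim <- simulate_ir_library(ir_sim_config(seed = 6))
  expect_identical(length(sim$library), 23L)  # 3 isomers + 20 decoys
  for (s in sim$library) expect_identical(s$wavenumber, default_ir_grid())
})
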