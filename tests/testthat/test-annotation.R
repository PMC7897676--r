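cands3 <- enumerate_candidates("C18H27NO", depth = 3)

test_that("the default rule set encodes the expected transformations", {
  rules <- default_rule_set()
  demeth <- subtract_formula(parse_formula("C18H27NO"), parse_formula("CH2"))
  expect_identical(format(demeth), "C17H25NO")
  gluc <- rules[["glucuronidation"]]
  expect_identical(gluc$phase, "II")
  expect_identical(format(gluc$add), "C6H8O6")
  expect_true(rules[["methylation-artifact"]]$artifact)
  expect_identical(rules[["hydroxylation"]]$max_n, 3L)
})

test_that("rule paths reach the named reference metabolites", {
  # O-demethyl (M1a)
  m1a <- cands3[cands3$mh_formula == "C17H26NO", ]
  expect_identical(m1a$formula, "C17H25NO")
  expect_true(any(vapply(m1a$paths[[1]], function(p)
    identical(p, "O-demethylation"), TRUE)))
  # O-demethyl glucuronide (M2a)
  m2a <- cands3[cands3$mh_formula == "C23H34NO7", ]
  expect_identical(m2a$formula, "C23H33NO7")
  expect_identical(m2a$phase, "II")
})

test_that("depth-limited enumeration behaves at the boundaries", {
  d0 <- enumerate_candidates("C18H27NO", depth = 0,
                             rules = default_rule_set()["hydroxylation"])
  expect_identical(d0$formula, "C18H27NO")
  d1 <- enumerate_candidates("C18H27NO", depth = 1,
                             rules = default_rule_set()["hydroxylation"])
  expect_setequal(d1$formula, c("C18H27NO", "C18H27NO2"))
})

test_that("depth-3 enumeration covers every distinct reference composition", {
  ref <- ref_table()
  expect_true(all(unique(ref$mh_composition) %in% cands3$mh_formula))
})

test_that("glucuronidation is terminal and applied at most once", {
  for (i in seq_len(nrow(cands3))) {
    for (p in cands3$paths[[i]]) {
      w <- which(p == "glucuronidation")
      expect_true(length(w) <= 1L)
      if (length(w)) expect_identical(w, length(p))
    }
  }
})

test_that("artifact flag marks methylation-only candidates", {
  m1m <- cands3[cands3$mh_formula == "C19H30NO3", ]
  expect_true(m1m$artifact)
  m1a <- cands3[cands3$mh_formula == "C17H26NO", ]
  expect_false(m1a$artifact)
})

test_that("zero-jitter annotation recovers every planted analyte exactly", {
  sim <- simulate_peak_table(ms_sim_config(mass_jitter_ppm = 0,
                                           envelope_noise = 0,
                                           n_decoys = 0, seed = 7))
  ann <- annotate(sim$peaks, cands3, parent_rt = 7.74)
  idd <- ann[!is.na(ann$feature_id) & ann$status == "identified", ]
  expect_true(all(sim$truth$feature_id %in% idd$feature_id))
  expect_equal(max(abs(idd$dm_ppm)), 0, tolerance = 1e-9)
})

test_that("a mass bias beyond tolerance defeats the mass criterion", {
  sim <- simulate_peak_table(ms_sim_config(mass_jitter_ppm = 0,
                                           mass_bias_ppm = 10,
                                           envelope_noise = 0,
                                           n_decoys = 0, seed = 7))
  ann <- annotate(sim$peaks, cands3, parent_rt = 7.74,
                  config = annotation_config(ppm_tol = 5))
  expect_false(any(ann$status == "identified"))
})

test_that("recovery is non-increasing in mass jitter", {
  recovery <- vapply(c(0, 2, 8, 30), function(sig) {
    sim <- simulate_peak_table(ms_sim_config(mass_jitter_ppm = sig,
                                             n_decoys = 0, seed = 5))
    ann <- annotate(sim$peaks, cands3, parent_rt = 7.74)
    idd <- ann[!is.na(ann$feature_id) & ann$status == "identified", ]
    mean(sim$truth$feature_id %in% idd$feature_id)
  }, 0)
  expect_identical(recovery[1], 1)
  expect_true(all(diff(recovery) <= 0))
})

test_that("isomeric features share a composition with one primary flag", {
  # two planted features with the same composition at distinct tR
  sim <- simulate_peak_table(ms_sim_config(
    include = c("3-MeO-PCP", "M1b", "M1c"), rt_model = "reference",
    mass_jitter_ppm = 0, envelope_noise = 0, n_decoys = 0, seed = 3))
  ann <- annotate(sim$peaks, cands3, parent_rt = 7.74)
  iso <- ann[ann$mh_formula == "C17H26NO2" & !is.na(ann$feature_id), ]
  expect_identical(nrow(iso), 2L)
  expect_identical(sum(iso$is_primary), 1L)
  expect_true(iso$is_primary[which.max(iso$intensity)])
  expect_true(all(iso$ambiguous))
})

test_that("panel selection honours intensity ranking, parent pinning and k", {
  sim <- simulate_peak_table(ms_sim_config(
    abundances = urine_screening_abundances(), seed = 11))
  ann <- annotate(sim$peaks, cands3, parent_rt = 7.74)
  panel <- select_panel(ann, 7)
  acr <- sim$truth$acronym[match(panel$feature_id, sim$truth$feature_id)]
  expect_identical(acr[1], "3-MeO-PCP")
  expect_setequal(acr[-1], c("M1a", "M1b", "M1g", "M1h", "M2a", "M2c"))

  p1 <- select_panel(ann, 1)
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$formula, "C18H27NO")
})

test_that("artifact candidates are excluded from panels", {
  ab <- urine_screening_abundances()
  ab["M1m"] <- 5e7
  sim <- simulate_peak_table(ms_sim_config(abundances = ab, seed = 11))
  ann <- annotate(sim$peaks, cands3, parent_rt = 7.74)
  panel <- select_panel(ann, 7)
  acr <- sim$truth$acronym[match(panel$feature_id, sim$truth$feature_id)]
  expect_false("M1m" %in% acr)
})

test_that("reports carry exact/accurate/ppm triplets that are consistent", {
  sim <- simulate_peak_table(ms_sim_config(n_decoys = 0, seed = 13))
  cfg <- annotation_config()
  ann <- annotate(sim$peaks, cands3, parent_rt = 7.74, config = cfg)
  rep_ <- build_report(ann, sim$peaks, config = cfg)
  expect_s3_class(rep_, "annotation_report")
  expect_true(nrow(rep_) >= 20)
  for (k in 0:3) {
    acc <- rep_[[paste0("accurate_m", k)]]
    ex <- rep_[[paste0("exact_m", k)]]
    dm <- rep_[[paste0("dm_m", k)]]
    ok <- !is.na(acc)
    expect_equal(dm[ok], round((acc[ok] - ex[ok]) / ex[ok] * 1e6, 2),
                 tolerance = 0.01)
  }
  # absent measurements render as "-"
  path <- tempfile(fileext = ".csv")
  write_report(rep_, path)
  expect_true(any(grepl(",-", readLines(path), fixed = TRUE)))
})
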