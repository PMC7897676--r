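test_that("formula parsing round-trips in Hill order and validates input", {
  cases <- list(
    c("C18H28NO", "C18H28NO"),
    c("C23H34NO7", "C23H34NO7"),
    c("C18H28NO3", "C18H28NO3"),
    c("OC18NH28", "C18H28NO")  # scrambled input canonicalises
  )
  for (cs in cases) expect_identical(format(parse_formula(cs[1])), cs[2])

  f <- parse_formula("C18H28NO")
  expect_identical(unclass(f)[c("C", "H", "N", "O")],
                   c(C = 18L, H = 28L, N = 1L, O = 1L))
  expect_error(parse_formula("C18H28XO"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C18h28NO"), "cannot parse|unknown element")
})

test_that("formula algebra adds and subtracts elementwise", {
  a <- parse_formula("C18H27NO")
  expect_identical(format(subtract_formula(a, parse_formula("CH2"))),
                   "C17H25NO")
  empty <- subtract_formula(a, a)
  expect_identical(format(add_formula(a, empty)), format(a))
  expect_error(subtract_formula(parse_formula("CH4"), parse_formula("C2H2")),
               "infeasible")
})

test_that("exact ionic masses reproduce reference MH+ values", {
  expect_identical(exact_mass(ion_species("C18H28NO"), digits = 4), 274.2165)
  expect_identical(exact_mass(ion_species("C11H16NO"), digits = 4), 178.1226)
  expect_identical(exact_mass(ion_species("C17H26NO"), digits = 4), 260.2009)
  expect_equal(exact_mass(parse_formula("H")), 1.00783, tolerance = 1e-5)
  expect_error(exact_mass(ion_species("C2H6", charge = 0L)), "charge")
})

test_that("exact mass is additive over formula addition", {
  set.seed(1)
  for (i in 1:20) {
    a <- new_chem_formula(c(C = sample(0:20, 1), H = sample(0:40, 1),
                            N = sample(0:3, 1), O = sample(1:5, 1)))
    b <- new_chem_formula(c(C = sample(1:10, 1), H = sample(0:20, 1)))
    expect_equal(exact_mass(add_formula(a, b)),
                 exact_mass(a) + exact_mass(b), tolerance = 1e-9)
  }
})

test_that("electron correction shifts a +1 ion by one electron mass", {
  on_ <- exact_mass(ion_species("C18H28NO", electron_correction = TRUE))
  off <- exact_mass(ion_species("C18H28NO", electron_correction = FALSE))
  expect_equal(off - on_, 0.000548579909065, tolerance = 1e-9)
})

test_that("ppm error reproduces reported mass accuracies", {
  expect_identical(ppm_error(274.2164, 274.2165), -0.36)
  expect_identical(ppm_error(292.1903, 292.1907), -1.37)
  expect_identical(ppm_error(100, 100), 0)
  expect_error(ppm_error(1, 0), "positive")
})

test_that("ppm error inverts a planted ppm perturbation", {
  m <- exact_mass(ion_species("C18H28NO"))
  for (p in c(-100, -7.5, -0.36, 0, 1.37, 42, 100)) {
    expect_equal(ppm_error(m * (1 + p * 1e-6), m, digits = NULL), p,
                 tolerance = 1e-6)
  }
})

test_that("RDBE matches the known values for the two seized drugs", {
  expect_identical(rdbe("C18H27NO"), 6)
  expect_identical(rdbe("C11H15NO"), 5)
})
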