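band_spec <- function(name = "s", seed = 1) {
  set.seed(seed)
  g <- default_ir_grid()
  y <- gaussian_sum(g, runif(10, 700, 3900), runif(10, 10, 40),
                    runif(10, 0.2, 1))
  ir_spectrum(g, y, name = name)
}

gaussian_sum <- function(g, c0, w, a) {
  Reduce(`+`, lapply(seq_along(c0), function(i)
    a[i] * exp(-0.5 * ((g - c0[i]) / w[i])^2)))
}

test_that("preprocessing resamples, truncates and normalises", {
  s <- band_spec()
  p <- preprocess_ir(s)
  expect_equal(range(p$absorbance), c(0, 1))
  expect_identical(p$wavenumber, default_ir_grid())

  # 2 cm-1 input onto the 4 cm-1 grid: same range, decimated
  g2 <- seq(650, 4000, by = 2)
  s2 <- ir_spectrum(g2, approx(s$wavenumber, s$absorbance, g2)$y)
  p2 <- preprocess_ir(s2)
  expect_identical(length(p2$wavenumber), length(default_ir_grid()))
  expect_equal(p2$absorbance, p$absorbance, tolerance = 1e-6)

  flat <- preprocess_ir(ir_spectrum(default_ir_grid(),
                                    rep(0.3, length(default_ir_grid()))))
  expect_true(attr(flat, "degenerate"))
  expect_true(all(flat$absorbance == 0))

  narrow <- ir_spectrum(seq(2000, 2500, by = 4), rep(1, 126))
  expect_error(preprocess_ir(narrow), "overlap")
})

test_that("QMF is 100 on self-match and 0 on anti-correlated input", {
  s <- preprocess_ir(band_spec())
  expect_equal(as.numeric(qmf(s, s)), 100)
  neg <- ir_spectrum(s$wavenumber, -s$absorbance)
  expect_equal(as.numeric(qmf(neg, s)), 0)
})

test_that("QMF is symmetric and invariant to positive affine rescaling", {
  a <- preprocess_ir(band_spec(seed = 2))
  b <- preprocess_ir(band_spec(seed = 3))
  expect_equal(as.numeric(qmf(a, b)), as.numeric(qmf(b, a)))
  for (tf in list(c(2, 0), c(0.3, 5), c(10, -1))) {
    b2 <- ir_spectrum(b$wavenumber, tf[1] * b$absorbance + tf[2])
    expect_equal(as.numeric(qmf(a, b2)), as.numeric(qmf(a, b)),
                 tolerance = 1e-9)
  }
})

test_that("zero-variance spectra score QMF 0 with a degenerate flag", {
  s <- preprocess_ir(band_spec())
  flat <- ir_spectrum(s$wavenumber, rep(0, length(s$wavenumber)))
  q <- qmf(flat, s)
  expect_identical(as.numeric(q), 0)
  expect_true(attr(q, "degenerate"))
})

test_that("library search ranks the query itself first at QMF 100", {
  sim <- simulate_ir_library(ir_sim_config(seed = 42))
  hits <- rank_library(sim$library[["isomer_1"]], sim$library)
  expect_identical(hits$name[1], "isomer_1")
  expect_equal(hits$qmf[1], 100)
  expect_identical(hits$rank, seq_len(nrow(hits)))
  expect_true(all(diff(hits$qmf) <= 0))
})

test_that("the fixed-seed isomer benchmark separates correct and wrong", {
  sim <- simulate_ir_library(ir_sim_config(seed = 42))
  for (nm in names(sim$queries)) {
    hits <- rank_library(sim$queries[[nm]], sim$library)
    expect_identical(hits$name[1], nm)
    wrong <- hits[grepl("^isomer", hits$name) & hits$name != nm, ]
    expect_gt(hits$qmf[1] - max(wrong$qmf), 30)
  }
})

test_that("fully shared bands make isomers indistinguishable (control)", {
  sim <- simulate_ir_library(ir_sim_config(shared_fraction = 1, seed = 9))
  q <- rank_library(sim$library[["isomer_1"]], sim$library)
  iso <- q[grepl("^isomer", q$name), ]
  expect_equal(diff(range(iso$qmf)), 0, tolerance = 1e-9)
})

test_that("co-addition sums spectra and accumulates deposition counts", {
  s <- band_spec()
  expect_equal(coadd(list(s))$absorbance, s$absorbance)
  c3 <- coadd(list(s, s, s))
  expect_equal(c3$absorbance, 3 * s$absorbance)
  expect_identical(c3$n_depositions, 3L)
  other <- ir_spectrum(seq(650, 4000, by = 8), rep(1, 419))
  expect_error(coadd(list(s, other)), "grid")
})

test_that("added noise never raises the median QMF against the clean truth", {
  ref <- preprocess_ir(band_spec(seed = 4))
  g <- ref$wavenumber
  meds <- vapply(c(0, 0.02, 0.1, 0.5), function(sig) {
    qs <- vapply(1:25, function(r) {
      set.seed(1000 + r)
      as.numeric(qmf(ir_spectrum(g, ref$absorbance +
                                   rnorm(length(g), sd = sig)), ref))
    }, 0)
    median(qs)
  }, 0)
  expect_true(all(diff(meds) <= 1e-9))
})

test_that("LOI is 1 for a noiseless query and unreachable thresholds stay NA", {
  ref <- band_spec(seed = 5)
  clean <- limit_of_identification(ref, qmf_threshold = 80, amplitude = 0.02,
                                   deposition_noise_sd = 0,
                                   readout_noise_sd = 0,
                                   drift_amplitude = 0,
                                   max_depositions = 2L, n_replicates = 3L)
  expect_identical(clean$loi, 1L)
  hard <- limit_of_identification(ref, qmf_threshold = 99.99,
                                  max_depositions = 3L, n_replicates = 5L)
  expect_true(is.na(hard$loi))
  expect_error(limit_of_identification(ref, qmf_threshold = 100), "0, 100")
})
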