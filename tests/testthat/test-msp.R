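grid100 <- spectral_grid(400, 700, 3)

make_scan <- function(sample_v, reference_v, grid = grid100,
                      type = "erythrophore", cell = "c1", fish = "f1") {
  msp_scan(spectrum(grid, sample_v, "counts"),
           spectrum(grid, reference_v, "counts"),
           cell_id = cell, fish_id = fish, chromatophore_type = type)
}

test_that("transmittance recovers the sample/reference ratio", {
  ref <- 5000 + 10 * (grid100 - 400)
  expect_equal(transmittance(make_scan(ref, ref))$value,
               rep(100, length(grid100)))
  expect_equal(transmittance(make_scan(0.5 * ref, ref))$value,
               rep(50, length(grid100)))
})

test_that("transmittance is invariant to common scaling of both scans", {
  set.seed(3)
  ref <- 4000 + 2000 * runif(length(grid100))
  smp <- ref * runif(length(grid100))
  t1 <- transmittance(make_scan(smp, ref))
  t2 <- transmittance(make_scan(7.3 * smp, 7.3 * ref))
  expect_equal(t1$value, t2$value, tolerance = 1e-12)
})

test_that("non-positive reference counts fail, naming the wavelength", {
  ref <- rep(1000, length(grid100))
  ref[grid100 == 502] <- 0
  expect_error(transmittance(make_scan(ref * 0.5, ref)), "502")
})

test_that("noiseless synthetic melanophore transmittance rises monotonically", {
  scans <- generate_scans(
    generator_config(n_fish = 1, cells_per_fish = 1, types = "melanophore",
                     cv = 0, jitter_sd = 0))
  tv <- transmittance(scans[[1]])$value
  expect_true(all(diff(tv) > 0))
})

test_that("averaging reproduces single-scan and two-scan arithmetic", {
  ref <- rep(1000, length(grid100))
  one <- average_by_type(list(make_scan(0.37 * ref, ref)), grid = grid100)
  expect_equal(one$mean_T$value, rep(37, length(grid100)))
  expect_equal(one$sem_T$value, rep(0, length(grid100)))
  expect_equal(one$n_cells, 1)

  two <- average_by_type(list(make_scan(0.4 * ref, ref),
                              make_scan(0.6 * ref, ref, cell = "c2")),
                         grid = grid100)
  expect_equal(two$mean_T$value, rep(50, length(grid100)))
  expect_equal(two$sem_T$value, rep(10, length(grid100)))
  expect_equal(two$n_cells, 2)
  expect_error(average_by_type(list()), "no scans")
})

test_that("transition estimator matches the logistic closed form m - 2s", {
  g <- default_msp_grid()
  cases <- list(c(m = 560, s = 10), c(m = 520, s = 15), c(m = 600, s = 8))
  for (cs in cases) {
    est <- transition_wavelength(logistic_T(g, cs["m"], cs["s"]))
    expect_lt(abs(est - (cs[["m"]] - 2 * cs[["s"]])), 0.5)
  }
})

test_that("slow uniform rises are reported as having no transition", {
  g <- default_msp_grid()
  mel <- spectrum(g, 9 + 0.03 * (g - 400), "transmittance_percent")
  expect_true(is.na(transition_wavelength(mel)))
})

test_that("transition estimation enforces its grid contract", {
  g <- default_msp_grid()
  irregular <- spectrum(sort(c(400, 401, runif(60, 402, 700))),
                        runif(62, 0, 100), "transmittance_percent")
  expect_error(transition_wavelength(irregular), "uniform")
  short <- logistic_T(seq(400, 700, by = 10), 560, 10)
  expect_error(transition_wavelength(short), "at least 50")
})

test_that("attenuation endpoints: full transmission gives 0, full blocking gives 1", {
  g <- default_msp_grid()
  tmpl <- a1_template(415, g[g <= 520])
  expect_equal(sws1_attenuation(flat_T(g, 100), tmpl), 0, tolerance = 1e-12)
  expect_equal(sws1_attenuation(flat_T(g, 0), tmpl), 1, tolerance = 1e-12)
})

test_that("attenuation rejects a zero-weight window", {
  g <- default_msp_grid()
  zero_tmpl <- spectrum(g, rep(0, length(g)), "sensitivity")
  expect_error(sws1_attenuation(flat_T(g, 50), zero_tmpl),
               "integrates to zero")
})

test_that("attenuation responds to a tabulated illuminant", {
  g <- default_msp_grid()
  tmpl <- a1_template(415, g[g <= 520])
  # transmittance that blocks below 450 and passes above it
  tv <- ifelse(g < 450, 0, 100)
  tr <- spectrum(g, tv, "transmittance_percent")
  flat <- sws1_attenuation(tr, tmpl)
  # an illuminant weighted toward long wavelengths must lower attenuation
  ill <- spectrum(g, (g - 399)^2, "counts")
  skewed <- sws1_attenuation(tr, tmpl, illuminant = ill)
  expect_lt(skewed, flat)
})

test_that("summarize_types splits by type and fills summaries", {
  scans <- generate_scans(
    generator_config(n_fish = 1, cells_per_fish = 3, cv = 0, jitter_sd = 0))
  sm <- summarize_types(scans)
  tab <- summary_table(sm)
  expect_setequal(tab$type,
                  c("melanophore", "erythrophore", "xanthophore"))
  expect_equal(tab$n_cells, rep(3L, 3))
  expect_true(is.na(sm$melanophore$transition_nm))
  expect_false(anyNA(tab$attenuation_fraction))
})

test_that("scan directories round-trip through manifest and spectrum files", {
  scans <- generate_scans(
    generator_config(n_fish = 1, cells_per_fish = 2, types = "xanthophore",
                     seed = 5))
  dir <- withr::local_tempdir()
  write_scans(scans, dir)
  back <- read_scans(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$chromatophore_type, "xanthophore")
  expect_equal(back[[1]]$sample$value, scans[[1]]$sample$value,
               tolerance = 1e-12)
  expect_equal(transmittance(back[[2]])$value,
               transmittance(scans[[2]])$value, tolerance = 1e-10)
})
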