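small_cfg <- function(...) {
  generator_config(n_fish = 1, cells_per_fish = 3, ...)
}

test_that("the same master seed reproduces scans bit for bit", {
  a <- generate_scans(small_cfg(seed = 42))
  b <- generate_scans(small_cfg(seed = 42))
  expect_identical(a, b)
  c <- generate_scans(small_cfg(seed = 43))
  expect_false(identical(a, c))
})

test_that("per-cell streams make leading subsets reproducible", {
  full <- generate_scans(generator_config(n_fish = 1, cells_per_fish = 10,
                                          types = "erythrophore", seed = 9))
  head3 <- generate_scans(generator_config(n_fish = 1, cells_per_fish = 3,
                                           types = "erythrophore", seed = 9))
  expect_identical(full[1:3], head3)
})

test_that("defaults produce the study's replication: 180 scans, 60 per type", {
  scans <- generate_scans(generator_config(cv = 0, jitter_sd = 0))
  expect_length(scans, 180)
  types <- vapply(scans, `[[`, "", "chromatophore_type")
  expect_equal(as.integer(table(types)[c("melanophore", "erythrophore",
                                         "xanthophore")]),
               rep(60L, 3))
  fish <- vapply(scans, `[[`, "", "fish_id")
  expect_equal(length(unique(fish)), 3)
})

test_that("disabling noise and jitter recovers the pigment curve exactly", {
  for (ty in c("melanophore", "erythrophore", "xanthophore")) {
    scans <- generate_scans(small_cfg(types = ty, cv = 0, jitter_sd = 0))
    curve <- pigment_transmittance(pigment_model(ty),
                                   scans[[1]]$sample$wavelength_nm)
    expect_equal(transmittance(scans[[1]])$value, curve$value,
                 tolerance = 1e-12)
  }
})

test_that("poisson noise mode produces integer counts near the gaussian mean", {
  scans <- generate_scans(small_cfg(types = "xanthophore", noise = "poisson",
                                    seed = 2))
  expect_true(all(scans[[1]]$reference$value ==
                    round(scans[[1]]$reference$value)))
  tv <- transmittance(scans[[1]])$value
  curve <- pigment_transmittance(pigment_model("xanthophore"),
                                 scans[[1]]$sample$wavelength_nm)$value
  expect_lt(mean(abs(tv - curve)), 5)
})

test_that("standard error of the type mean scales roughly as 1/sqrt(n)", {
  mean_sem <- function(cells) {
    scans <- generate_scans(generator_config(
      n_fish = 3, cells_per_fish = cells, types = "erythrophore", seed = 21))
    mean(average_by_type(scans)$sem_T$value)
  }
  ratio <- mean_sem(5) / mean_sem(20)
  expect_lt(abs(ratio - 2) / 2, 0.2)
})

test_that("pigment models respect their structural constraints", {
  models <- default_pigment_models()
  expect_gt(models$erythrophore$m, models$xanthophore$m)
  g <- default_msp_grid()
  for (m in models) {
    tv <- pigment_transmittance(m, g)$value
    expect_true(all(tv >= 0 & tv <= 100))
  }
  expect_error(pigment_model("melanophore", m = 550), "unknown parameter")
  expect_error(generate_scans(small_cfg(types = "melanophore"),
                              models = list()), "no pigment model")
})

test_that("an empty substitution spec yields an identical fixture pair", {
  fx <- generate_fixture_sequences(character(0))
  expect_identical(as.character(fx[[1]]), as.character(fx[[2]]))
})

test_that("fixture generation validates its substitution spec", {
  expect_error(generate_fixture_sequences("S999C"), "outside the reference")
  expect_error(generate_fixture_sequences("A97C"), "mismatch")
  expect_error(generate_fixture_sequences("97SC"), "malformed")
})
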