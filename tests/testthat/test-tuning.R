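bovine <- as.character(bovine_rhodopsin()[[1]])

test_that("the reference maps onto itself with identity numbering", {
  ns <- map_to_bovine(bovine)
  expect_equal(ns$bovine_pos, seq_len(nchar(bovine)))
  expect_equal(ns$residue, strsplit(bovine, "")[[1]])
})

test_that("an extra N-terminal residue leaves bovine numbering intact", {
  ns <- map_to_bovine(paste0("M", bovine))
  expect_equal(sum(is.na(ns$bovine_pos)), 1)
  expect_equal(sort(ns$bovine_pos[!is.na(ns$bovine_pos)]),
               seq_len(nchar(bovine)))
  # every mapped residue still matches the reference residue it maps to
  ref_res <- strsplit(bovine, "")[[1]]
  mapped <- !is.na(ns$bovine_pos)
  expect_equal(ns$residue[mapped], ref_res[ns$bovine_pos[mapped]])
})

test_that("non-amino-acid characters are rejected with the offending symbols", {
  expect_error(map_to_bovine("MNGTB2G"), "B, 2")
  expect_error(map_to_bovine(""), "non-empty")
})

test_that("fixture pair carries S/C at site 97 and M/V at site 116", {
  fx <- generate_fixture_sequences()
  a <- map_to_bovine(fx[1])
  b <- map_to_bovine(fx[2])
  expect_identical(residue_at(a, 97), "S")
  expect_identical(residue_at(b, 97), "C")
  expect_identical(residue_at(a, 116), "M")
  expect_identical(residue_at(b, 116), "V")

  subs <- compare_tuning_sites(a, b)
  expect_setequal(subs$notation, c("S97C", "M116V"))
  expect_length(attr(subs, "uncallable"), 0)
})

test_that("identical sequences yield no substitutions", {
  a <- map_to_bovine(bovine)
  subs <- compare_tuning_sites(a, a)
  expect_equal(nrow(subs), 0)
})

test_that("substitution calling is antisymmetric in its arguments", {
  fx <- generate_fixture_sequences(c("S97C", "M116V", "F46L"))
  a <- map_to_bovine(fx[1])
  b <- map_to_bovine(fx[2])
  ab <- compare_tuning_sites(a, b)
  ba <- compare_tuning_sites(b, a)
  expect_equal(ab$site, ba$site)
  expect_equal(ab$ref, ba$alt)
  expect_equal(ab$alt, ba$ref)
})

test_that("a deletion spanning a tuning site is uncallable, not substituted", {
  res <- strsplit(bovine, "")[[1]]
  gapped <- paste(res[-(110:125)], collapse = "")
  a <- map_to_bovine(bovine)
  g <- map_to_bovine(gapped)
  subs <- compare_tuning_sites(a, g)
  expect_true(all(c(113, 114, 116, 118) %in% attr(subs, "uncallable")))
  expect_false(116 %in% subs$site)
})

test_that("a substitution at a non-tuning position is invisible to site calling", {
  fx <- generate_fixture_sequences(c("S97C", "A164S"))
  a <- map_to_bovine(fx[1])
  b <- map_to_bovine(fx[2])
  subs <- compare_tuning_sites(a, b)
  expect_identical(subs$notation, "S97C")
  # but the full-sequence diff sees both
  ra <- strsplit(as.character(fx[[1]]), "")[[1]]
  rb <- strsplit(as.character(fx[[2]]), "")[[1]]
  expect_equal(which(ra != rb), c(97, 164))
})

test_that("specified substitution sets round-trip through the full pipeline", {
  base <- map_to_bovine(generate_fixture_sequences(character(0))[1])
  sites <- sws1_tuning_sites()
  set.seed(11)
  for (rep in 1:5) {
    chosen <- sort(sample(sites, sample(1:4, 1)))
    refs <- residue_at(base, chosen)
    alts <- vapply(refs, function(r) sample(setdiff(c("A", "G", "L", "S", "T", "V"), r), 1), "")
    spec <- paste0(refs, chosen, alts)
    fx <- generate_fixture_sequences(spec)
    got <- compare_tuning_sites(map_to_bovine(fx[1]), map_to_bovine(fx[2]))
    expect_setequal(got$notation, spec)
  }
})

test_that("anchor-plus-shift estimate follows the centering rule", {
  est <- estimate_lambda_max(415, c("S97C", "M116V"))
  expect_equal(est$point_nm, 415)
  expect_equal(est$interval_nm, c(411, 415))
  expect_true(est$in_sws1_range)

  none <- estimate_lambda_max(415, character(0))
  expect_equal(none$point_nm, 415)
  expect_equal(none$interval_nm, c(415, 415))

  # a degenerate positive interval forces the midpoint rule
  tab <- data.frame(site = 97, from = "S", to = "A",
                    shift_low_nm = 5, shift_high_nm = 5)
  up <- estimate_lambda_max(400, "S97A", table = tab)
  expect_equal(up$point_nm, 405)
  expect_equal(up$interval_nm, c(405, 405))
})

test_that("unknown substitutions get a zero-centred default interval, with a note", {
  expect_message(est <- estimate_lambda_max(415, "T52A"), "low-confidence")
  expect_equal(est$interval_nm, c(412, 418))
  expect_equal(est$point_nm, 415)
})

test_that("the estimate is translation-equivariant in the anchor", {
  base <- estimate_lambda_max(400, c("S97C", "M116V"))
  for (shift in c(5, 17.5, 30)) {
    moved <- estimate_lambda_max(400 + shift, c("S97C", "M116V"))
    expect_equal(moved$point_nm, base$point_nm + shift)
    expect_equal(moved$interval_nm, base$interval_nm + shift)
  }
  expect_error(estimate_lambda_max(300, character(0)), "\\[330, 650\\]")
})

test_that("interval width equals the summed shift-interval width", {
  tab <- sws1_shift_table()
  est <- estimate_lambda_max(415, c("S97C", "M116V"), table = tab)
  expect_equal(diff(est$interval_nm),
               sum(tab$shift_high_nm - tab$shift_low_nm))
})

test_that("substitution reports carry shift intervals to disk", {
  fx <- generate_fixture_sequences()
  subs <- compare_tuning_sites(map_to_bovine(fx[1]), map_to_bovine(fx[2]))
  path <- withr::local_tempfile(fileext = ".tsv")
  rep <- write_substitution_report(subs, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$notation, c("S97C", "M116V"))
  expect_equal(back$shift_low_nm, c(-1, -3))
  expect_equal(back$shift_high_nm, c(0, 0))
})
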