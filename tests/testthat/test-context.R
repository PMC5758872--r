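test_that("maximal repeat runs are found exactly", {
  expect_length(find_repeats(transcript("g", "GGGGGG")), 0L)
  runs <- find_repeats(transcript("r", "UUCACACACACAUU"))
  expect_length(runs, 1L)
  expect_equal(unclass(runs[[1]]$interval), c(start = 2L, end = 12L))
  expect_equal(runs[[1]]$n_units, 5L)
  expect_error(find_repeats(transcript("x", "ACGU"), unit = "CX"), "non-ACGU")
})

test_that("repeat finder equals a brute-force offset scanner on planted runs", {
  set.seed(3)
  for (i in 1:60) {
    n_runs <- sample(0:3, 1)
    parts <- random_rna(sample(20:60, 1), gc = 0.3)
    for (k in seq_len(n_runs)) {
      parts <- paste0(parts, strrep("CA", sample(4:9, 1)),
                      random_rna(sample(10:40, 1), gc = 0.3))
    }
    got <- find_repeats(transcript("p", parts), "CA", 4L)
    want <- oracle_repeats(normalize_rna(parts), "CA", 4L)
    expect_equal(length(got), length(want))
    if (length(got) > 0L) {
      expect_equal(vapply(got, function(r) r$interval[[1L]], 0L),
                   vapply(want, function(r) unname(r["start"]), 0))
      expect_equal(vapply(got, `[[`, 0L, "n_units"),
                   vapply(want, function(r) unname(r["n_units"]), 0))
    }
  }
})

test_that("interval deletion is exact and bounds-checked", {
  t <- transcript("d", "UUCACACACACAUU")
  expect_equal(delete_interval(t, iv(0, 0))$seq, t$seq)
  expect_equal(delete_interval(t, iv(2, 12))$seq, "UUUU")
  expect_error(delete_interval(t, iv(5, 99)), "out of bounds")
  set.seed(5)
  for (i in 1:30) {
    s <- random_rna(sample(20:80, 1))
    a <- sample(0:(nchar(s) - 1), 1); b <- sample(a:nchar(s), 1)
    out <- delete_interval(transcript("r", s, utr_start = sample(0:nchar(s), 1)),
                           iv(a, b))
    expect_equal(nchar(out$seq), nchar(s) - (b - a))
  }
})

test_that("masking analysis quantifies repeat competition against the oracle", {
  m <- energy_model()
  pm <- plant_masked_dle(8)
  h <- match_dle(pm$masked, pm$descriptor,
                 region = iv(0, nchar(pm$masked$seq)))[[1]]
  rep <- masking_analysis(pm$masked, h, pm$deletion, pm$descriptor, m, 25:28)
  expect_true(all(rep$fold_change > 1))

  # verify both endpoints against restricted enumeration at 26 C
  m26 <- energy_model(temperature = 26 + 273.15)
  e_before <- enum_partition_function(pm$masked$seq, m26, h$pairs)
  h2 <- match_dle(pm$unmasked, pm$descriptor,
                  region = iv(0, nchar(pm$unmasked$seq)))[[1]]
  e_after <- enum_partition_function(pm$unmasked$seq, m26, h2$pairs)
  fc_oracle <- e_after$p_substructure / e_before$p_substructure
  expect_lt(abs(rep$fold_change[rep$T_grid == 26] - fc_oracle), 1e-9)

  # empty deletion -> fold change exactly 1
  rep0 <- masking_analysis(pm$unmasked, h2, iv(0, 0), pm$descriptor, m, 25:26)
  expect_equal(rep0$fold_change, c(1, 1))

  # deleting an interval overlapping the motif is refused
  expect_error(
    masking_analysis(pm$masked, h, iv(h$loop[[1L]], h$loop[[2L]]),
                     pm$descriptor, m),
    "overlaps")
})

test_that("pairing-inert context deletions leave the probability unchanged", {
  m <- energy_model()
  pi <- plant_masked_dle(8, inert = TRUE)
  h <- match_dle(pi$masked, pi$descriptor,
                 region = iv(0, nchar(pi$masked$seq)))[[1]]
  rep <- masking_analysis(pi$masked, h, pi$deletion, pi$descriptor, m, 25:28)
  expect_true(all(abs(log(rep$fold_change)) < 1e-9))
})

test_that("fold change is invariant to prepended pairing-inert context", {
  # construct uses no U, so a 5' poly-A extension cannot pair anything
  m <- energy_model()
  pm <- plant_masked_dle(6)
  shifted <- transcript("shifted", paste0(strrep("A", 15), pm$masked$seq))
  h0 <- match_dle(pm$masked, pm$descriptor,
                  region = iv(0, nchar(pm$masked$seq)))[[1]]
  h1 <- match_dle(shifted, pm$descriptor, region = iv(0, nchar(shifted$seq)))[[1]]
  del1 <- iv(pm$deletion[[1L]] + 15L, pm$deletion[[2L]] + 15L)
  r0 <- masking_analysis(pm$masked, h0, pm$deletion, pm$descriptor, m, 26)
  r1 <- masking_analysis(shifted, h1, del1, pm$descriptor, m, 26)
  expect_lt(abs(r0$fold_change - r1$fold_change), 1e-9)
})
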