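test_that("descriptor presets encode the published grammar variants", {
  r <- dle_preset("relaxed")
  s <- dle_preset("strict")
  expect_equal(r$spacer_min, 2L); expect_equal(r$spacer_max, 5L)
  expect_equal(r$spacer_alphabet, "any"); expect_equal(r$stem_min_bp, 3L)
  expect_equal(s$spacer_max, 3L); expect_equal(s$spacer_alphabet, "pyrimidine")
  expect_equal(s$loop_min, 5L); expect_equal(s$loop_max, 12L)
  expect_error(dle_descriptor("bad", loop_min = 2), "hairpin")
  expect_error(dle_descriptor("bad", spacer_min = 3, spacer_max = 2), "spacer")
})

test_that("the constructed minimal hairpin is parsed into the exact decomposition", {
  t <- transcript("x", "GCACUUGGGAAAAACCC")
  h <- match_dle(t, dle_preset("strict"))
  expect_length(h, 1L)
  expect_equal(unclass(h[[1]]$anchor), c(start = 0L, end = 4L))
  expect_equal(unclass(h[[1]]$spacer), c(start = 4L, end = 6L))
  expect_equal(unclass(h[[1]]$stem5), c(start = 6L, end = 9L))
  expect_equal(unclass(h[[1]]$loop), c(start = 9L, end = 14L))
  expect_equal(unclass(h[[1]]$stem3), c(start = 14L, end = 17L))
  expect_equal(h[[1]]$pairs, cbind(6:8, 16:14))
  expect_length(match_dle(transcript("a", "AAAAAAAAAAAA"), dle_preset("strict")), 0L)
})

test_that("scanner equals the exhaustive-decomposition oracle on random sequences", {
  set.seed(11)
  for (preset in c("strict", "relaxed")) {
    d <- dle_preset(preset)
    for (i in 1:25) {
      seq <- random_rna(200)
      t <- transcript(paste0("r", i), seq)
      got <- match_dle(t, d, enumerate_all = TRUE)
      want <- oracle_dle(seq, d)
      expect_setequal(vapply(got, decomp_key, ""),
                      vapply(want, oracle_key, ""))
    }
  }
})

test_that("every strict match has a relaxed match at the same anchor", {
  set.seed(12)
  strict <- dle_preset("strict"); relaxed <- dle_preset("relaxed")
  for (i in 1:20) {
    t <- transcript(paste0("n", i), random_rna(300))
    sh <- match_dle(t, strict)
    if (length(sh) == 0L) next
    rh <- match_dle(t, relaxed)
    expect_true(all(vapply(sh, function(h) h$anchor[1L], 0L) %in%
                    vapply(rh, function(h) h$anchor[1L], 0L)))
  }
})

test_that("require_preceding_A restricts anchors to AGCAC occurrences", {
  t <- transcript("x", "AGCACUUGGGAAAAACCCUUGCACUUGGGAAAAACCC")
  all_hits <- match_dle(t, dle_preset("strict"))
  a_hits <- match_dle(t, dle_preset("strict", require_preceding_A = TRUE))
  expect_setequal(vapply(all_hits, function(h) h$anchor[1L], 0L), c(1L, 20L))
  expect_equal(vapply(a_hits, function(h) h$anchor[1L], 0L), 1L)
})

test_that("mutant edits act on the located element as defined", {
  t <- transcript("wt", "GCACUUGGGAAAAACCC")
  d <- dle_preset("strict")
  h <- match_dle(t, d)[[1]]

  sr <- apply_mutant(t, h, "SR")
  expect_equal(sr$seq, "GCACUUCCCAAAAAGGG")
  h_sr <- match_dle(sr, d)
  expect_length(h_sr, 1L)                      # arms swapped, still paired
  expect_equal(h_sr[[1]]$pairs, h$pairs)

  sm <- apply_mutant(t, h, "SM", replacement = "AAA")
  expect_equal(sm$seq, "GCACUUAAAAAAAACCC")
  expect_length(match_dle(sm, d), 0L)          # pairing destroyed

  sm_auto <- apply_mutant(t, h, "SM")          # auto replacement also breaks it
  expect_length(match_dle(sm_auto, d), 0L)

  lm <- apply_mutant(t, h, "LM", replacement = "UCUCU")
  expect_equal(lm$seq, "GCACUUGGGUCUCUCCC")
  h_lm <- match_dle(lm, d)
  expect_true(any(vapply(h_lm, function(x) identical(x$pairs, h$pairs), NA)))

  expect_equal(apply_mutant(t, h, "dG")$seq, "UUGGGAAAAACCC")
  expect_equal(apply_mutant(t, h, "dSL")$seq, "GCACUU")
  expect_equal(apply_mutant(t, h, "dGSL")$seq, "UU")
})

test_that("out-of-bounds regions and broken descriptors are validation errors", {
  t <- transcript("x", "GCACUUGGGAAAAACCC")
  expect_error(match_dle(t, dle_preset("strict"), region = iv(0, 99)),
               "out of bounds")
})
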