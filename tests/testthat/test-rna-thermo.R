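test_that("partition function matches closed forms on degenerate sequences", {
  m <- energy_model()
  expect_equal(partition_function("AAAA", m), 1.0)     # open chain only
  RT <- 1.9872e-3 * 310.15
  expect_equal(partition_function("GAAAC", m), 1 + exp(3.0 / RT),
               tolerance = 1e-12)
  expect_error(partition_function("ACGT x", m), "non-ACGU")
})

test_that("DP equals exhaustive enumeration on all fixture sequences", {
  m <- energy_model()
  for (seq in fold_fixture_set()) {
    e <- enum_partition_function(seq, m)
    z <- partition_function(seq, m)
    expect_lt(abs(z - e$Z_total) / e$Z_total, 1e-10)
  }
})

test_that("constrained probabilities equal enumeration and obey the contract", {
  m <- energy_model()
  req <- rbind(c(0, 9), c(1, 8), c(2, 7))
  got <- constrained_probability("GGGAAAACCC", req, m)
  want <- enum_partition_function("GGGAAAACCC", m, req)
  expect_lt(abs(got$p_substructure - want$p_substructure), 1e-10)
  expect_lte(got$Z_constrained, got$Z_total)

  # empty constraint -> probability exactly 1
  expect_equal(constrained_probability("GGGAAAACCC", NULL, m)$p_substructure, 1.0)

  # impossible constraint is an error, not p = 0
  expect_error(constrained_probability("AAAAAAA", rbind(c(0, 6)), m),
               "not pairable")
  # crossing constraints are an error
  expect_error(
    constrained_probability("GGAAAACCAAAGC", rbind(c(0, 7), c(1, 12)), m),
    "cross")
  # steric minimum hairpin loop enforced
  expect_error(constrained_probability("GAAC", rbind(c(0, 3)), m), "loop")
})

test_that("ensemble probabilities are normalized and constraints are monotone", {
  m <- energy_model()
  set.seed(31)
  for (i in 1:5) {
    seq <- random_rna(12)
    e <- enum_partition_function(seq, m)
    z <- partition_function(seq, m)
    expect_lt(abs(e$Z_total / z - 1), 1e-10)  # sum of weights / Z = 1
  }
  # adding a required pair never increases the constrained weight
  seq <- "GGGCAAAAGCCC"
  p1 <- rbind(c(0, 11))
  p2 <- rbind(c(0, 11), c(1, 10))
  z1 <- constrained_probability(seq, p1, m)$Z_constrained
  z2 <- constrained_probability(seq, p2, m)$Z_constrained
  expect_lte(z2, z1 * (1 + 1e-12))
})

test_that("temperature grid wraps single-point calls consistently", {
  m <- energy_model()
  seq <- "GCACUUGGGAAAAACCC"
  req <- rbind(c(6, 16), c(7, 15), c(8, 14))
  grid <- probability_vs_temperature(seq, req, m, 25:28)
  expect_equal(nrow(grid), 4L)
  expect_true(all(grid$p >= 0 & grid$p <= 1))
  single <- constrained_probability(
    seq, req, energy_model(temperature = 26 + 273.15))$p_substructure
  expect_equal(grid$p[grid$T_celsius == 26], single)
  # grid point equals enumeration at that temperature
  e <- enum_partition_function(seq, energy_model(temperature = 25 + 273.15), req)
  expect_lt(abs(grid$p[grid$T_celsius == 25] - e$p_substructure), 1e-10)
  expect_error(probability_vs_temperature(seq, req, m, numeric(0)))
})

test_that("base-pair probability matrix agrees with both independent routes", {
  m <- energy_model()
  set.seed(41)
  for (i in 1:4) {
    seq <- random_rna(12)
    P <- bp_probability_matrix(seq, m)
    E <- dletools:::enum_bp_matrix(seq, m)
    expect_lt(max(abs(P - E)), 1e-10)
  }
  # dual route: p(i,j) equals constrained-over-total ratio
  seq <- "GGCAAAAGCC"
  P <- bp_probability_matrix(seq, m)
  for (ij in list(c(0, 9), c(1, 8))) {
    r <- constrained_probability(seq, rbind(ij), m)$p_substructure
    expect_lt(abs(P[ij[1] + 1, ij[2] + 1] - r), 1e-10)
  }
})

test_that("turner backend reproduces the qualitative masking order", {
  expect_true(rnafold_available())
  # construct whose (CA)k repeat forms a contiguous helix against the
  # GU-rich stem arm, so both energy models see the competition
  t <- transcript("turner_demo",
                  paste0("GCAC", "UU", "GUGUG", "AAAAA", "CACAC", "AA",
                         strrep("CA", 8)))
  d <- dle_preset("strict")
  hits <- match_dle(t, d, region = iv(0, nchar(t$seq)))
  h <- hits[[which.max(vapply(hits, function(x) nrow(x$pairs), 0L))]]
  run <- find_repeats(t, "CA", 4L)[[1]]
  for (backend in c("turner", "simple")) {
    m <- energy_model(backend, temperature = 301.15)
    rep <- masking_analysis(t, h, run$interval, d, m, 25:28)
    expect_true(all(rep$p_before >= 0 & rep$p_before <= 1))
    expect_true(all(rep$p_after >= 0 & rep$p_after <= 1))
    expect_true(all(rep$fold_change > 1))  # masked < unmasked on both backends
  }
})
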