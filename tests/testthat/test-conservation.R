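test_that("orthologue scan annotates species and respects CDS context", {
  fam <- gen_orthologue_family(4, 0.1, TRUE, seed = 17)
  hits <- scan_orthologues(fam$transcripts, cds_context = 0)
  expect_true(all(vapply(hits, function(h) !is.null(h$species), NA)))
  expect_setequal(unique(vapply(hits, `[[`, "", "species")), paste0("sp", 1:4))

  # short CDS context is used as available, with a message
  t <- transcript("shortcds", paste0("AUG", "GCACUUGGGAAAAACCC", strrep("A", 10)),
                  utr_start = 3L)
  expect_message(hits2 <- scan_orthologues(list(t), cds_context = 100L),
                 "only 3 nt")
  expect_length(hits2, 1L)
})

test_that("pairwise alignment matches the Needleman-Wunsch oracle scores", {
  a <- "GCACUUGGGAAAAACCC"
  b <- "GCACUUGGGAAAAAAACCC"   # 2-nt insertion in the loop
  A <- matrix(strsplit(a, "")[[1]], nrow = 1)
  B <- matrix(strsplit(b, "")[[1]], nrow = 1)
  prof <- dletools:::align_profiles(A, B)
  aligned <- apply(prof, 1, paste, collapse = "")
  # exactly one 2-column gap run in the shorter sequence
  gaps <- gregexpr("-+", aligned[1])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 2L)
  expect_false(grepl("-", aligned[2]))

  # score agrees with an independent affine NW implementation
  score_cols <- function(x, y) {
    s <- 0; open <- 4; ext <- 1
    in_gap <- FALSE
    for (k in seq_along(x)) {
      if (x[k] == "-" || y[k] == "-") {
        s <- s - ext - (!in_gap) * open; in_gap <- TRUE
      } else {
        s <- s + ifelse(x[k] == y[k], 2, -1); in_gap <- FALSE
      }
    }
    s
  }
  my_score <- score_cols(strsplit(aligned[1], "")[[1]],
                         strsplit(aligned[2], "")[[1]])
  pa <- Biostrings::pairwiseAlignment(
    chartr("U", "T", a), chartr("U", "T", b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  expect_equal(my_score, Biostrings::score(pa))

  # identical sequences align gaplessly
  prof2 <- dletools:::align_profiles(A, A)
  expect_false(any(prof2 == "-"))
})

test_that("alignment IO round-trips and validates row lengths", {
  rows <- c(sp1 = "GCAC--UU", sp2 = "GCACGGUU")
  aln <- dletools:::new_alignment_set(rows)
  path <- tempfile(fileext = ".fa")
  write_alignment(aln, path)
  back <- read_alignment(path)
  expect_equal(back$rows, rows)
  expect_error(dletools:::new_alignment_set(c(a = "ACG", b = "AC")), "unequal")
})

test_that("consensus reduces to per-sequence probabilities for trivial alignments", {
  m <- energy_model()
  seq <- "GGCAAAAGCC"
  aln1 <- dletools:::new_alignment_set(c(s1 = seq))
  cons1 <- consensus_structure(aln1, m)
  P <- bp_probability_matrix(seq, m)
  expect_equal(cons1$pair_reliability, P, tolerance = 1e-12)
  # two identical rows: averaging is idempotent
  aln2 <- dletools:::new_alignment_set(c(s1 = seq, s2 = seq))
  cons2 <- consensus_structure(aln2, m)
  expect_equal(cons2$pair_reliability, cons1$pair_reliability, tolerance = 1e-12)
  expect_equal(cons2$conservation, rep(1, nchar(seq)))
  expect_error(dletools:::new_alignment_set(character()), "empty")
})

test_that("consensus reliabilities are probabilities and the dot-bracket is nested", {
  m <- energy_model()
  fam <- gen_orthologue_family(5, 0.2, TRUE, seed = 2)
  tl <- stats::setNames(fam$transcripts, vapply(fam$transcripts, `[[`, "", "id"))
  hits <- top_hit_per_species(scan_orthologues(fam$transcripts, cds_context = 0))
  aln <- align_motif_regions(hits, tl, flank = 10)
  cons <- consensus_structure(aln, m)
  expect_true(all(cons$pair_reliability >= 0 & cons$pair_reliability <= 1))
  expect_true(all(cons$single_reliability >= -1e-9 &
                  cons$single_reliability <= 1 + 1e-9))
  db <- strsplit(cons$dot_bracket, "")[[1]]
  expect_equal(sum(db == "("), sum(db == ")"))
  depth <- cumsum((db == "(") - (db == ")"))
  expect_true(all(depth >= 0))
  block <- format_consensus_block(cons, aln)
  expect_length(block, length(aln$rows) + 3L)
})

test_that("compensatory families out-score pairing-breaking families on planted stems", {
  m <- energy_model()
  rel_of <- function(compensatory, seed) {
    fam <- gen_orthologue_family(6, 0.2, compensatory, seed = seed)
    tl <- stats::setNames(fam$transcripts, vapply(fam$transcripts, `[[`, "", "id"))
    # score the planted columns directly on the truth alignment (identity)
    tp <- fam$truth$pairs
    lo <- max(0, fam$truth$anchor_start - 10)
    hi <- min(nchar(tl$sp1$seq), fam$truth$motif_end + 10)
    rel <- 0
    for (t in tl) {
      P <- bp_probability_matrix(substr(t$seq, lo + 1, hi), m)
      rel <- rel + mean(P[cbind(tp[, 1] - lo + 1, tp[, 2] - lo + 1)])
    }
    rel / length(tl)
  }
  expect_gt(rel_of(TRUE, 17), rel_of(FALSE, 17))
  expect_gt(rel_of(TRUE, 3), rel_of(FALSE, 3))
})
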