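#' @name synthetic-data
#' @title Synthetic inputs with known ground truth
#' @description Generators for every input class the pipeline consumes:
#' UTR-like sequences with planted DLE motifs, masked-DLE constructs with a
#' competing dinucleotide repeat, orthologue families with compensatory
#' stem substitutions, and two-channel embryo-like image cohorts. All are
#' deterministic under a seed and return their ground truth alongside the
#' data.
NULL

WC_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")
WC_PAIRS <- c("GC", "CG", "AU", "UA")

sample_bases <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# one random strict-grammar DLE instance (Watson-Crick stem); stem length
# and alphabet are tunable so callers can plant grammar-only motifs (any
# composition) or thermodynamically dominant hairpins (G/C stems)
sample_dle_instance <- function(d = dle_preset("strict"), stem_min = NULL,
                                stem_max = 6L,
                                stem_alphabet = c("A", "C", "G", "U"),
                                loop_alphabet = c("A", "C", "G", "U"),
                                spacer_alphabet = c("U", "C")) {
  if (is.null(stem_min)) stem_min <- d$stem_min_bp
  pick <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)
  spacer <- paste(sample(spacer_alphabet, pick(d$spacer_min, d$spacer_max),
                         replace = TRUE), collapse = "")
  b <- pick(stem_min, min(stem_max, d$stem_max_bp))
  stem5 <- paste(sample(stem_alphabet, b, replace = TRUE), collapse = "")
  loop_len <- pick(d$loop_min, d$loop_max)
  loop <- paste(sample(loop_alphabet, loop_len, replace = TRUE),
                collapse = "")
  stem3 <- paste(rev(WC_COMPLEMENT[strsplit(stem5, "")[[1]]]), collapse = "")
  list(motif = paste0(d$anchor, spacer, stem5, loop, stem3),
       spacer = spacer, stem5 = stem5, loop = loop, stem3 = stem3)
}

#' Generate UTR-like sequences with one planted strict DLE each
#'
#' Backgrounds are i.i.d. at the given GC content; one random
#' strict-grammar DLE instance is planted per sequence at a random (or
#' given) position. Each sequence is rejection-screened so that the strict
#' scan reports hits at the planted anchor only, making recall and
#' precision on the cohort exact by construction (the screened backgrounds
#' are therefore slightly non-i.i.d.).
#'
#' @param n number of sequences.
#' @param utr_length sequence length (all-UTR; `utr_start = 0`).
#' @param gc_content background GC fraction in `[0, 1]`.
#' @param descriptor planting/screening descriptor
#'   (default `dle_preset("strict")`).
#' @param plant_positions optional integer vector of 0-based motif start
#'   offsets, recycled; default random.
#' @param seed RNG seed (identical seed and arguments reproduce the output
#'   exactly).
#' @param max_retries rejection retries per sequence before erroring with
#'   advice (a permissive descriptor on long sequences may be unplantable
#'   cleanly).
#' @param stem_min,stem_max planted stem length bounds in bp (defaults:
#'   the descriptor minimum to 6).
#' @param stem_alphabet bases the planted 5' stem arm is drawn from;
#'   restrict to `c("G", "C")` to plant thermodynamically dominant stems.
#' @return list: `transcripts` (list of [transcript()]), `truth`
#'   (data.frame: id, anchor_start, motif_start, motif_end, spacer_len,
#'   stem_bp, loop_len -- the planted decomposition).
#' @export
gen_planted_utrs <- function(n = 200L, utr_length = 200L, gc_content = 0.5,
                             descriptor = dle_preset("strict"),
                             plant_positions = NULL, seed = 1L,
                             max_retries = 200L, stem_min = NULL,
                             stem_max = 6L,
                             stem_alphabet = c("A", "C", "G", "U"),
                             loop_alphabet = c("A", "C", "G", "U"),
                             spacer_alphabet = c("U", "C")) {
  stopifnot(n >= 1L, utr_length >= 30L, gc_content >= 0, gc_content <= 1)
  set.seed(seed)
  transcripts <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(max_retries)) {
      inst <- sample_dle_instance(descriptor, stem_min, stem_max,
                                  stem_alphabet, loop_alphabet,
                                  spacer_alphabet)
      ml <- nchar(inst$motif)
      if (ml > utr_length) next
      pos <- if (!is.null(plant_positions)) {
        plant_positions[(i - 1L) %% length(plant_positions) + 1L]
      } else sample(0L:(utr_length - ml), 1L)
      bg <- sample_bases(utr_length - ml, gc_content)
      seq <- paste0(substr(bg, 1L, pos), inst$motif,
                    substr(bg, pos + 1L, nchar(bg)))
      t <- transcript(sprintf("synth_utr_%03d", i), seq)
      hits <- match_dle(t, descriptor)
      anchors <- unique(vapply(hits, function(h) h$anchor[1L], 0L))
      if (identical(anchors, pos)) {
        transcripts[[i]] <- t
        truth[[i]] <- data.frame(id = t$id, anchor_start = pos,
                                 motif_start = pos, motif_end = pos + ml,
                                 spacer_len = nchar(inst$spacer),
                                 stem_bp = nchar(inst$stem5),
                                 loop_len = nchar(inst$loop),
                                 stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("could not plant a clean motif in sequence ", i, " after ",
           max_retries, " tries; the descriptor is too permissive for ",
           "length ", utr_length, " -- shorten the sequences or tighten it")
    }
  }
  list(transcripts = transcripts, truth = do.call(rbind, truth))
}

#' Paired masked/unmasked DLE constructs
#'
#' Builds a short construct in which a planted strict DLE (G/C stem,
#' pyrimidine spacer, A-only loop) is followed by a (CA)k repeat whose C
#' residues can pair the G-rich 5' stem arm, competing with stem formation
#' -- the sequence-level mechanism by which a CA repeat masks a DLE. The
#' unmasked partner has the repeat deleted. With `inert = TRUE` the repeat
#' is replaced by a poly-A tract of the same length, which cannot pair
#' anything in the (U-free) construct, giving a structurally inert
#' deletion control.
#'
#' The construct is deterministic; it is kept short enough for the
#' exhaustive enumeration oracle.
#'
#' @param ca_units number of repeat units (>= 4).
#' @param inert use a non-pairing poly-A tract instead of the CA repeat.
#' @return list: `masked`, `unmasked` ([transcript()]s), `deletion`
#'   ([iv()] of the repeat in the masked construct), `descriptor`.
#' @export
plant_masked_dle <- function(ca_units = 8L, inert = FALSE) {
  stopifnot(ca_units >= 4L)
  core <- paste0("GCAC", "CC", "GGG", "AAAAA", "CCC", "AA")
  rep_seq <- if (inert) strrep("A", 2L * ca_units) else strrep("CA", ca_units)
  masked <- transcript(if (inert) "construct_inert" else "construct_masked",
                       paste0(core, rep_seq))
  deletion <- iv(nchar(core), nchar(core) + nchar(rep_seq))
  unmasked <- delete_interval(masked, deletion)
  unmasked$id <- paste0(masked$id, "_del")
  list(masked = masked, unmasked = unmasked, deletion = deletion,
       descriptor = dle_preset("strict"))
}

#' Simulated orthologue family with a conserved DLE
#'
#' Builds an ancestor UTR with one planted strict DLE (screened to be the
#' only strict hit), then derives `family_size - 1` descendants by per-site
#' substitution at the given divergence. Anchor and spacer positions are
#' held fixed (the functional constraint); loop and background positions
#' mutate freely. Stem positions mutate as compensatory double
#' substitutions that preserve Watson-Crick pairing when
#' `compensatory = TRUE`, and independently (pairing-breaking) otherwise.
#' No indels, so the ground-truth alignment is the identity.
#'
#' The benchmark is constructed so that the planted helix is the dominant
#' local fold of its region: the stem is 6 bp of Watson-Crick G-C pairs
#' with the 5' arm starting in C, the loop is poly-A, the spacer is UU,
#' and the background is an inert poly-A tract by default
#' (`gc_content = 0`; positive values give a random background at that
#' GC, at the cost of incidental background structure). Under the
#' base-pair energy model, helices enjoy no stacking cooperativity, so a
#' planted stem is only recoverable from consensus pair reliabilities if
#' its bases have essentially no alternative partners. The G/C stem has
#' no partners in an A-only background; the spacer U's pair distant
#' background A's in arrangements that cross (and thereby exclude) every
#' competing pairing of the anchor G against the stem arms, leaving the
#' planted register dominant. The ancestor is additionally
#' rejection-screened so that every planted pair has probability at
#' least 0.6 and every other pair at most 0.5 in its motif region.
#' Divergence then reintroduces realistic noise in the descendants.
#'
#' @param family_size number of sequences including the ancestor (>= 2).
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param compensatory preserve stem pairing under substitution.
#' @param utr_length sequence length.
#' @param gc_content background GC (default 0: A/U-only background).
#' @param seed RNG seed.
#' @param flank context width (nt) used by the ancestor dominance screen,
#'   matching the downstream alignment flank.
#' @param max_retries rejection retries for the ancestor construction.
#' @return list: `transcripts` (ancestor first, ids `sp1..spN`), `truth`
#'   (list: `anchor_start`, `pairs` -- 0-based stem pair coordinates,
#'   identical across rows -- `motif_start`, `motif_end`).
#' @export
gen_orthologue_family <- function(family_size = 7L, divergence = 0.2,
                                  compensatory = TRUE, utr_length = 120L,
                                  gc_content = 0, seed = 17L, flank = 10L,
                                  max_retries = 100L) {
  stopifnot(family_size >= 2L, divergence >= 0, divergence <= 1,
            utr_length >= 80L)
  set.seed(seed)
  d <- dle_preset("strict")
  rc <- function(s) paste(rev(WC_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  b <- 6L
  model <- energy_model()
  t0 <- NULL
  for (try in seq_len(max_retries)) {
    stem5 <- paste(c("C", sample(c("G", "C"), b - 1L, replace = TRUE)),
                   collapse = "")
    loop_len <- sample(d$loop_min:d$loop_max, 1L)
    motif <- paste0(d$anchor, "UU", stem5, strrep("A", loop_len), rc(stem5))
    ml <- nchar(motif)
    pos <- sample(seq(flank + 2L, utr_length - ml - flank - 2L), 1L)
    bg <- if (gc_content == 0) strrep("A", utr_length - ml)
          else sample_bases(utr_length - ml, gc_content)
    seqq <- paste0(substr(bg, 1L, pos), motif,
                   substr(bg, pos + 1L, nchar(bg)))
    cand <- transcript("sp1", seqq, gene = "nodal_like")
    hits <- match_dle(cand, d)
    anchors <- unique(vapply(hits, function(h) h$anchor[1L], 0L))
    if (!identical(anchors, pos)) next
    s5s <- pos + nchar(d$anchor) + 2L
    pairs <- cbind(s5s + 0L:(b - 1L),
                   s5s + 2L * b + loop_len - 1L - 0L:(b - 1L))
    lo <- max(0L, pos - flank); hi <- min(nchar(seqq), pos + ml + flank)
    P <- bp_probability_matrix(substr(seqq, lo + 1L, hi), model)
    pcm <- cbind(pairs[, 1L] - lo + 1L, pairs[, 2L] - lo + 1L)
    unplanted <- P; unplanted[pcm] <- 0
    if (min(P[pcm]) >= 0.6 && max(unplanted) <= 0.5) {
      t0 <- cand
      anchor_start <- pos; motif_end <- pos + ml
      break
    }
  }
  if (is.null(t0)) {
    stop("could not construct a dominant-fold ancestor in ", max_retries,
         " tries; lower gc_content or shorten the sequence")
  }
  anchor_cols <- seq(anchor_start, s5s - 1L)  # anchor + spacer
  stem_cols <- c(pairs[, 1L], pairs[, 2L])
  free_cols <- setdiff(0L:(nchar(t0$seq) - 1L), c(anchor_cols, stem_cols))

  mutate_one <- function(ch) {
    # substitutions at free sites: any other base uniformly
    for (p in free_cols) {
      if (stats::runif(1) < divergence) {
        ch[p + 1L] <- sample(setdiff(c("A", "C", "G", "U"), ch[p + 1L]), 1L)
      }
    }
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L] + 1L; j <- pairs[r, 2L] + 1L
      if (compensatory) {
        if (stats::runif(1) < divergence) {
          new <- sample(setdiff(WC_PAIRS, paste0(ch[i], ch[j])), 1L)
          ch[i] <- substr(new, 1L, 1L); ch[j] <- substr(new, 2L, 2L)
        }
      } else {
        for (p in c(i, j)) {
          if (stats::runif(1) < divergence) {
            ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
          }
        }
      }
    }
    ch
  }

  anc_ch <- strsplit(t0$seq, "")[[1]]
  transcripts <- vector("list", family_size)
  transcripts[[1L]] <- transcript("sp1", t0$seq, gene = "nodal_like")
  for (k in 2L:family_size) {
    transcripts[[k]] <- transcript(paste0("sp", k),
                                   paste(mutate_one(anc_ch), collapse = ""),
                                   gene = "nodal_like")
  }
  list(transcripts = transcripts,
       truth = list(anchor_start = anchor_start, pairs = pairs,
                    motif_start = anchor_start, motif_end = motif_end))
}

## ---- embryo image cohorts ----

render_disc <- function(dim_yx, center, radius, amplitude, background) {
  y <- matrix(seq_len(dim_yx[1L]), dim_yx[1L], dim_yx[2L])
  x <- matrix(seq_len(dim_yx[2L]), dim_yx[1L], dim_yx[2L], byrow = TRUE)
  inside <- (y - center[1L])^2 + (x - center[2L])^2 <= radius^2
  plane <- matrix(background, dim_yx[1L], dim_yx[2L])
  plane[inside] <- amplitude + background
  list(plane = plane, mask = inside)
}

render_stack <- function(dim_yx, n_slices, focus_start, focus_len, center,
                         radius, amplitude, background, noise_cv,
                         out_of_focus_frac = 0.15) {
  stack <- array(0, dim = c(dim_yx, n_slices))
  for (z in seq_len(n_slices)) {
    amp <- if (z >= focus_start && z < focus_start + focus_len) amplitude
           else amplitude * out_of_focus_frac
    stack[, , z] <- render_disc(dim_yx, center, radius, amp, background)$plane
  }
  if (noise_cv > 0) {
    stack <- stack * (1 + noise_cv * array(stats::rnorm(length(stack)),
                                           dim = dim(stack)))
    stack[stack < 0] <- 0
  }
  pmin(stack, 65535)
}

#' Simulated two-channel embryo imaging cohort
#'
#' Per embryo: 15-slice (by default) two-channel 16-bit stacks with a
#' bright disc ("blastoderm") in a known in-focus block; the rhodamine
#' (RFP) disc amplitude is fixed and GFP amplitude is `ratio * rfp_amp`,
#' over a common autofluorescence background, with multiplicative Gaussian
#' noise at `noise_cv`. Un-injected controls carry background only. Ground
#' truth records the planted ratio, ROI area and focus block per embryo.
#'
#' @param groups character vector of group labels.
#' @param stages character vector of stage labels.
#' @param n_per_cell embryos per group x stage cell.
#' @param ratio_per_group named numeric, planted GFP/RFP ratio per group.
#' @param dim_yx image shape (default 64 x 64).
#' @param n_slices z planes (default 15).
#' @param focus_len in-focus block length (default 4).
#' @param disc_radius ROI disc radius in pixels.
#' @param rfp_amp RFP disc amplitude above background (counts).
#' @param background_level background counts in both channels.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param n_controls number of un-injected control embryos.
#' @param seed RNG seed.
#' @return list: `embryos` (list of stacks for [measure()]), `controls`,
#'   `truth` (data.frame: embryo_id, group, stage, ratio, roi_area,
#'   focus_start).
#' @export
gen_embryo_cohort <- function(groups = c("Mybx1", "control"),
                              stages = c("1K", "sphere", "epiboly30"),
                              n_per_cell = 2L,
                              ratio_per_group = c(Mybx1 = 1.5, control = 1.0),
                              dim_yx = c(64L, 64L), n_slices = 15L,
                              focus_len = 4L, disc_radius = 12L,
                              rfp_amp = 20000, background_level = 400,
                              noise_cv = 0, n_controls = 2L, seed = 23L) {
  stopifnot(all(groups %in% names(ratio_per_group)), n_slices >= focus_len)
  set.seed(seed)
  embryos <- list(); truth <- list()
  margin <- disc_radius + 4L
  for (g in groups) for (st in stages) for (i in seq_len(n_per_cell)) {
    id <- sprintf("%s_%s_%02d", g, st, i)
    center <- c(sample(margin:(dim_yx[1L] - margin), 1L),
                sample(margin:(dim_yx[2L] - margin), 1L))
    focus_start <- sample(seq_len(n_slices - focus_len + 1L), 1L)
    ratio <- ratio_per_group[[g]]
    rfp <- render_stack(dim_yx, n_slices, focus_start, focus_len, center,
                        disc_radius, rfp_amp, background_level, noise_cv)
    gfp <- render_stack(dim_yx, n_slices, focus_start, focus_len, center,
                        disc_radius, ratio * rfp_amp, background_level,
                        noise_cv)
    embryos[[length(embryos) + 1L]] <-
      list(embryo_id = id, group = g, stage = st, gfp = gfp, rfp = rfp)
    disc <- render_disc(dim_yx, center, disc_radius, 1, 0)
    truth[[length(truth) + 1L]] <-
      data.frame(embryo_id = id, group = g, stage = st, ratio = ratio,
                 roi_area = sum(disc$mask), focus_start = focus_start,
                 stringsAsFactors = FALSE)
  }
  controls <- lapply(seq_len(n_controls), function(i) {
    bg <- array(background_level, dim = c(dim_yx, n_slices))
    if (noise_cv > 0) {
      bg <- bg * (1 + noise_cv * array(stats::rnorm(length(bg)),
                                       dim = dim(bg)))
      bg[bg < 0] <- 0
    }
    list(embryo_id = sprintf("uninjected_%02d", i), group = "uninjected",
         stage = NA_character_, gfp = bg, rfp = bg)
  })
  list(embryos = embryos, controls = controls, truth = do.call(rbind, truth))
}

#' Write an embryo cohort as TIFF stacks plus a sample sheet
#'
#' Serializes a cohort from [gen_embryo_cohort()] into per-channel
#' multi-page 16-bit TIFFs, a `samples.tsv` sheet consumable by
#' [quantify_cohort()], and a `truth.tsv`.
#'
#' @param cohort output of [gen_embryo_cohort()].
#' @param dir output directory (created if needed).
#' @return the sample sheet path, invisibly.
#' @export
write_embryo_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(stack, path) {
    planes <- lapply(seq_len(dim(stack)[3L]),
                     function(z) stack[, , z] / 65535)
    tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  }
  rows <- lapply(c(cohort$embryos, cohort$controls), function(e) {
    gfp_path <- paste0(e$embryo_id, "_gfp.tif")
    rfp_path <- paste0(e$embryo_id, "_rfp.tif")
    write_one(e$gfp, file.path(dir, gfp_path))
    write_one(e$rfp, file.path(dir, rfp_path))
    data.frame(embryo_id = e$embryo_id, group = e$group, stage = e$stage,
               gfp_path = gfp_path, rfp_path = rfp_path,
               is_control = e$group == "uninjected", stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, rows)
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sheet_path)
}

#' Simulated measurement-level reporter cohort
#'
#' Draws per-embryo GFP/RFP ratios directly (Gaussian, sd = cv x mean) for
#' statistical simulations of [compare_groups()] -- null calibration and
#' power -- without rendering images.
#'
#' @param group_means named numeric, true mean ratio per group.
#' @param stages stage labels.
#' @param n_per_cell embryos per group x stage cell (default 34, the
#'   cohort size of the quantitative reporter comparison).
#' @param cv coefficient of variation of the ratio.
#' @param stage_effects optional named numeric added per stage (default 0).
#' @param seed RNG seed.
#' @return measurements data.frame for [compare_groups()].
#' @export
gen_ratio_cohort <- function(group_means, stages = c("1K", "sphere", "epiboly30"),
                             n_per_cell = 34L, cv = 0.2,
                             stage_effects = NULL, seed = 29L) {
  set.seed(seed)
  if (is.null(stage_effects)) {
    stage_effects <- stats::setNames(rep(0, length(stages)), stages)
  }
  rows <- list()
  for (g in names(group_means)) for (st in stages) {
    mu <- group_means[[g]] + stage_effects[[st]]
    rows[[length(rows) + 1L]] <- data.frame(
      embryo_id = sprintf("%s_%s_%02d", g, st, seq_len(n_per_cell)),
      group = g, stage = st,
      ratio = stats::rnorm(n_per_cell, mu, cv * mu),
      valid = TRUE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
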