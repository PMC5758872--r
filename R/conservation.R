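#' Scan orthologue transcripts for strict DLE motifs
#'
#' Runs the strict descriptor over each transcript's 3'UTR plus up to
#' `cds_context` trailing CDS nucleotides (the scan window used for the
#' orthologue screen). Transcripts whose annotated CDS context is shorter
#' than requested are scanned with what is available, with a message.
#'
#' @param transcripts list of [transcript()]s, one per species (typically
#'   after [select_longest_utr()]).
#' @param d descriptor, default `dle_preset("strict")`.
#' @param cds_context CDS nucleotides to include 5' of the UTR (default 100).
#' @return list of matches, each annotated with `species` (the transcript
#'   id); species without a match are absent (reported via `message()`).
#' @export
scan_orthologues <- function(transcripts, d = dle_preset("strict"),
                             cds_context = 100L) {
  out <- list()
  for (t in transcripts) {
    ctx <- min(cds_context, t$utr_start)
    if (ctx < cds_context) {
      message("transcript '", t$id, "': only ", ctx,
              " nt of CDS context available (requested ", cds_context, ")")
    }
    hits <- match_dle(t, d, region = iv(t$utr_start - ctx, nchar(t$seq)))
    if (length(hits) == 0L) {
      message("transcript '", t$id, "': no ", d$name, " DLE match")
      next
    }
    for (h in hits) {
      h$species <- t$id
      out[[length(out) + 1L]] <- h
    }
  }
  out
}

#' Keep one best match per species
#'
#' A single anchor can admit several collapsed decompositions (different
#' loop starts); for downstream alignment one representative per species is
#' wanted. Keeps, per species, the match with the most stem pairs, breaking
#' ties by leftmost anchor then smallest loop.
#'
#' @param hits matches from [scan_orthologues()].
#' @return filtered list, one match per species, in first-seen species
#'   order.
#' @export
top_hit_per_species <- function(hits) {
  if (length(hits) == 0L) return(hits)
  sp <- vapply(hits, function(h) {
    if (!is.null(h$species)) h$species else h$transcript_id
  }, "")
  nb <- vapply(hits, function(h) nrow(h$pairs), 0L)
  a <- vapply(hits, function(h) h$anchor[1L], 0L)
  ll <- vapply(hits, function(h) iv_len(h$loop), 0L)
  keep <- vapply(unique(sp), function(s) {
    ix <- which(sp == s)
    ix[order(-nb[ix], a[ix], ll[ix])][1L]
  }, 0L)
  hits[keep]
}

## ---- progressive profile alignment (affine gaps) ----

ALN_MATCH <- 2; ALN_MISMATCH <- -1; ALN_GAP_OPEN <- 4; ALN_GAP_EXT <- 1

sub_score <- function(a, b) {
  if (a == "-" || b == "-") return(0)
  if (a == b) ALN_MATCH else ALN_MISMATCH
}

# column-vs-column sum-of-pairs score, averaged over row pairs
profile_col_score <- function(colA, colB) {
  s <- 0
  for (a in colA) for (b in colB) s <- s + sub_score(a, b)
  s / (length(colA) * length(colB))
}

# global affine-gap alignment of two profiles (character matrices,
# rows = sequences, cols = alignment columns); returns merged profile
align_profiles <- function(A, B) {
  m <- ncol(A); n <- ncol(B)
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)   # A col aligned to B col
  X <- matrix(NEG, m + 1L, n + 1L)   # A col aligned to gap
  Y <- matrix(NEG, m + 1L, n + 1L)   # gap aligned to B col
  tb <- array("", dim = c(m + 1L, n + 1L, 3L))  # traceback per state
  M[1L, 1L] <- 0
  for (i in seq_len(m)) {
    X[i + 1L, 1L] <- -(ALN_GAP_OPEN + ALN_GAP_EXT * i)
    tb[i + 1L, 1L, 2L] <- if (i == 1L) "M" else "X"
  }
  for (j in seq_len(n)) {
    Y[1L, j + 1L] <- -(ALN_GAP_OPEN + ALN_GAP_EXT * j)
    tb[1L, j + 1L, 3L] <- if (j == 1L) "M" else "Y"
  }
  S <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    S[i, j] <- profile_col_score(A[, i], B[, j])
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1L, j + 1L] <- best + S[i, j]
      tb[i + 1L, j + 1L, 1L] <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
      xo <- M[i, j + 1L] - (ALN_GAP_OPEN + ALN_GAP_EXT)
      xe <- X[i, j + 1L] - ALN_GAP_EXT
      X[i + 1L, j + 1L] <- max(xo, xe)
      tb[i + 1L, j + 1L, 2L] <- if (xo >= xe) "M" else "X"
      yo <- M[i + 1L, j] - (ALN_GAP_OPEN + ALN_GAP_EXT)
      ye <- Y[i + 1L, j] - ALN_GAP_EXT
      Y[i + 1L, j + 1L] <- max(yo, ye)
      tb[i + 1L, j + 1L, 3L] <- if (yo >= ye) "M" else "Y"
    }
  }
  state <- c("M", "X", "Y")[which.max(c(M[m + 1L, n + 1L], X[m + 1L, n + 1L],
                                        Y[m + 1L, n + 1L]))]
  i <- m; j <- n
  colsA <- integer(); colsB <- integer()  # 0 = gap column
  while (i > 0L || j > 0L) {
    prev <- tb[i + 1L, j + 1L, match(state, c("M", "X", "Y"))]
    if (state == "M") { colsA <- c(i, colsA); colsB <- c(j, colsB); i <- i - 1L; j <- j - 1L }
    else if (state == "X") { colsA <- c(i, colsA); colsB <- c(0L, colsB); i <- i - 1L }
    else { colsA <- c(0L, colsA); colsB <- c(j, colsB); j <- j - 1L }
    state <- prev
  }
  gapA <- matrix("-", nrow(A), 1L); gapB <- matrix("-", nrow(B), 1L)
  outA <- vapply(colsA, function(c) if (c == 0L) gapA else A[, c, drop = FALSE],
                 matrix("", nrow(A), 1L))
  outB <- vapply(colsB, function(c) if (c == 0L) gapB else B[, c, drop = FALSE],
                 matrix("", nrow(B), 1L))
  rbind(matrix(outA, nrow = nrow(A)), matrix(outB, nrow = nrow(B)))
}

#' Multiple alignment of DLE motif regions
#'
#' Progressive global alignment (match +2, mismatch -1, gap open -4, gap
#' extend -1; guide order = input order, so the result is deterministic) of
#' the motif regions of a set of matches, each extended by `flank`
#' nucleotides of context. A curated alignment can be supplied instead via
#' [read_alignment()] wherever an `alignment_set` is accepted.
#'
#' @param matches list of matches (from [scan_orthologues()] or
#'   [match_dle()]), each carrying `species` or `transcript_id`.
#' @param transcripts named list of [transcript()]s keyed by id.
#' @param flank context nucleotides on each side (default 10).
#' @return object of class `alignment_set`: `rows` (named character vector
#'   of equal-length gapped sequences) and `column_count`.
#' @export
align_motif_regions <- function(matches, transcripts, flank = 10L) {
  if (length(matches) == 0L) stop("no matches to align")
  ids <- vapply(matches, function(h) {
    if (!is.null(h$species)) h$species else h$transcript_id
  }, "")
  seqs <- vapply(seq_along(matches), function(i) {
    h <- matches[[i]]
    t <- transcripts[[ids[i]]]
    if (is.null(t)) stop("no transcript supplied for '", ids[i], "'")
    lo <- max(0L, h$anchor[1L] - flank)
    hi <- min(nchar(t$seq), h$stem3[2L] + flank)
    iv_seq(t$seq, iv(lo, hi))
  }, "")
  profiles <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1L))
  prof <- Reduce(align_profiles, profiles)
  rows <- apply(prof, 1L, paste, collapse = "")
  names(rows) <- ids
  new_alignment_set(rows)
}

new_alignment_set <- function(rows) {
  if (length(rows) == 0L) stop("empty alignment")
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("alignment rows have unequal lengths")
  structure(list(rows = rows, column_count = unname(lens[1L])),
            class = "alignment_set")
}

#' Read an aligned FASTA into an alignment set
#' @param path aligned FASTA path (rows of equal gapped length).
#' @return an `alignment_set`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(chartr("Tt", "Uu", as.character(set)))
  names(rows) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  new_alignment_set(rows)
}

#' Write an alignment set as aligned FASTA
#' @param aln an `alignment_set`.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

## ---- consensus structure surrogate ----

# pair-probability matrix by exhaustive enumeration (reference route for
# short sequences)
enum_bp_matrix <- function(seq, model) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  RT <- model$R * model$temperature
  e <- model$pair_energies
  pe <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) e[["GC"]] else if (p %in% c("AU", "UA")) e[["AU"]] else e[["GU"]]
  }
  structs <- enumerate_structures(seq, allow_GU = model$allow_GU)
  P <- matrix(0, n, n); Z <- 0
  for (s in structs) {
    w <- if (nrow(s) == 0L) 1.0 else {
      exp(-sum(vapply(seq_len(nrow(s)),
                      function(r) pe(ch[s[r, 1L] + 1L], ch[s[r, 2L] + 1L]), 0.0)) / RT)
    }
    Z <- Z + w
    if (nrow(s) > 0L) for (r in seq_len(nrow(s))) {
      P[s[r, 1L] + 1L, s[r, 2L] + 1L] <- P[s[r, 1L] + 1L, s[r, 2L] + 1L] + w
    }
  }
  P / Z
}

#' Consensus structure reliability from an alignment
#'
#' A thermodynamic consensus surrogate: each row's exact base-pair
#' probabilities (simple backend; enumeration for rows up to 25 nt,
#' inside-outside dynamic programming otherwise) are mapped through the
#' alignment columns and averaged over rows -- a row contributes 0 to a
#' column pair where it has a gap. The consensus dot-bracket is the greedy
#' maximum-weight nested matching over column pairs with average
#' reliability at or above `threshold`. This is a surrogate for
#' tree-weighted consensus folding (it uses no phylogeny), documented as
#' such.
#'
#' @param aln an `alignment_set`.
#' @param model simple-backend [energy_model()].
#' @param threshold reliability cutoff for consensus pairs (default 0.5).
#' @return object of class `consensus_structure`: `columns`,
#'   `pair_reliability` (columns x columns matrix), `single_reliability`,
#'   `conservation`, `dot_bracket`.
#' @export
consensus_structure <- function(aln, model = energy_model(), threshold = 0.5) {
  stopifnot(inherits(aln, "alignment_set"))
  if (length(aln$rows) == 0L) stop("empty alignment")
  nc <- aln$column_count
  nr <- length(aln$rows)
  rel <- matrix(0, nc, nc)
  unpaired <- matrix(0, nr, nc)  # per row, per column: P(unpaired), gap -> 0
  chars <- do.call(rbind, strsplit(unname(aln$rows), ""))
  for (r in seq_len(nr)) {
    row_ch <- chars[r, ]
    pos <- which(row_ch != "-")        # columns carrying residues
    seq_r <- paste(row_ch[pos], collapse = "")
    if (nchar(seq_r) == 0L) next
    P <- if (nchar(seq_r) <= 25L) enum_bp_matrix(seq_r, model)
         else bp_probability_matrix(seq_r, model)
    for (i in seq_len(nchar(seq_r))) {
      js <- which(P[i, ] > 0)
      for (j in js) rel[pos[i], pos[j]] <- rel[pos[i], pos[j]] + P[i, j]
    }
    pr <- rowSums(P) + colSums(P)
    unpaired[r, pos] <- 1 - pr[seq_len(nchar(seq_r))]
  }
  rel <- rel / nr
  single <- colSums(unpaired) / nr
  conservation <- vapply(seq_len(nc), function(ci) {
    res <- chars[, ci]; res <- res[res != "-"]
    if (length(res) == 0L) 0 else max(table(res)) / nr
  }, 0.0)

  cand <- which(rel >= threshold, arr.ind = TRUE)
  db <- rep(".", nc)
  chosen <- matrix(integer(), 0L, 2L)
  if (nrow(cand) > 0L) {
    ord <- order(-rel[cand], cand[, 1L], cand[, 2L])
    used <- logical(nc)
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (used[i] || used[j]) next
      crossing <- FALSE
      if (nrow(chosen) > 0L) {
        for (r in seq_len(nrow(chosen))) {
          a <- chosen[r, 1L]; b <- chosen[r, 2L]
          if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
            crossing <- TRUE; break
          }
        }
      }
      if (crossing) next
      chosen <- rbind(chosen, c(i, j))
      used[i] <- used[j] <- TRUE
      db[i] <- "("; db[j] <- ")"
    }
  }
  structure(list(columns = nc, pair_reliability = rel,
                 single_reliability = single, conservation = conservation,
                 dot_bracket = paste(db, collapse = ""),
                 consensus_pairs = chosen, threshold = threshold),
            class = "consensus_structure")
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat("<consensus_structure> ", x$columns, " columns, ",
      nrow(x$consensus_pairs), " consensus pairs\n", x$dot_bracket, "\n",
      sep = "")
  invisible(x)
}

#' Render an alignment with its consensus tracks
#'
#' Text block in the style of consensus-structure figures: aligned rows,
#' the dot-bracket consensus, a per-column sequence conservation track and
#' a per-column paired-reliability track (0-9 deciles).
#'
#' @param cons a `consensus_structure`.
#' @param aln the `alignment_set` it was computed from.
#' @return character vector of lines (also printed invisibly-friendly).
#' @export
format_consensus_block <- function(cons, aln) {
  decile <- function(v) {
    paste(ifelse(v <= 0, "0", as.character(pmin(9L, floor(v * 10)))), collapse = "")
  }
  paired_rel <- vapply(seq_len(cons$columns), function(ci) {
    sum(cons$pair_reliability[ci, ]) + sum(cons$pair_reliability[, ci])
  }, 0.0)
  w <- max(nchar(names(aln$rows)), nchar("reliab_paired")) + 2L
  pad <- function(nm) formatC(nm, width = -w)
  c(vapply(seq_along(aln$rows),
           function(i) paste0(pad(names(aln$rows)[i]), aln$rows[[i]]), ""),
    paste0(pad("structure"), cons$dot_bracket),
    paste0(pad("conservation"), decile(cons$conservation)),
    paste0(pad("reliab_paired"), decile(paired_rel)))
}
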