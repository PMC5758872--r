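#' Define a composite DLE motif grammar
#'
#' The dorsal localization element (DLE) is a composite of a short anchor
#' sequence (GCAC, in some transcripts preceded by an A) followed, after a
#' short spacer, by a stem-loop. A descriptor parameterizes each part:
#' anchor string, spacer length range and alphabet, stem length range in
#' base pairs, and loop length range.
#'
#' @param name descriptor label carried into matches.
#' @param anchor anchor sequence over A/C/G/U (default `"GCAC"`).
#' @param require_preceding_A require an A immediately 5' of the anchor.
#' @param spacer_min,spacer_max spacer length bounds (nt).
#' @param spacer_alphabet `"any"` or `"pyrimidine"` (U/C only).
#' @param stem_min_bp,stem_max_bp stem length bounds in base pairs.
#' @param loop_min,loop_max loop length bounds (nt); `loop_min >= 3`
#'   (shorter hairpin loops are sterically disallowed).
#' @param allow_GU permit G.U wobble pairs in the stem (default TRUE).
#' @return object of class `dle_descriptor`.
#' @seealso [dle_preset()] for the two published parameterizations.
#' @export
dle_descriptor <- function(name, anchor = "GCAC", require_preceding_A = FALSE,
                           spacer_min = 2L, spacer_max = 5L,
                           spacer_alphabet = c("any", "pyrimidine"),
                           stem_min_bp = 3L, stem_max_bp = 20L,
                           loop_min = 3L, loop_max = 30L, allow_GU = TRUE) {
  spacer_alphabet <- match.arg(spacer_alphabet)
  anchor <- normalize_rna(anchor)
  d <- list(name = name, anchor = anchor,
            require_preceding_A = isTRUE(require_preceding_A),
            spacer_min = as.integer(spacer_min),
            spacer_max = as.integer(spacer_max),
            spacer_alphabet = spacer_alphabet,
            stem_min_bp = as.integer(stem_min_bp),
            stem_max_bp = as.integer(stem_max_bp),
            loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
            allow_GU = isTRUE(allow_GU))
  with(d, {
    if (!(0L <= spacer_min && spacer_min <= spacer_max)) {
      stop("need 0 <= spacer_min <= spacer_max")
    }
    if (!(1L <= stem_min_bp && stem_min_bp <= stem_max_bp)) {
      stop("need 1 <= stem_min_bp <= stem_max_bp")
    }
    if (!(3L <= loop_min && loop_min <= loop_max)) {
      stop("need 3 <= loop_min <= loop_max (hairpin steric limit)")
    }
  })
  structure(d, class = "dle_descriptor")
}

#' Published DLE descriptor presets
#'
#' `"relaxed"`: GCAC anchor, spacer of 2-5 nucleotides of any base, a stem
#' of at least 3 bp and a variable loop (3-30 nt here) -- the pattern used
#' to find DLE-like motifs in the cyc/lefty 3'UTRs. `"strict"`: GCAC anchor
#' followed by 2-3 pyrimidines (U/C), a 3-20 bp stem and a 5-12 nt loop --
#' the definition used for the orthologue screen.
#'
#' @param which `"relaxed"` or `"strict"`.
#' @param ... overrides forwarded to [dle_descriptor()] (e.g.
#'   `require_preceding_A = TRUE`, `allow_GU = FALSE`).
#' @return a `dle_descriptor`.
#' @export
dle_preset <- function(which = c("relaxed", "strict"), ...) {
  which <- match.arg(which)
  args <- switch(which,
    relaxed = list(name = "relaxed", spacer_min = 2L, spacer_max = 5L,
                   spacer_alphabet = "any", stem_min_bp = 3L,
                   stem_max_bp = 20L, loop_min = 3L, loop_max = 30L),
    strict = list(name = "strict", spacer_min = 2L, spacer_max = 3L,
                  spacer_alphabet = "pyrimidine", stem_min_bp = 3L,
                  stem_max_bp = 20L, loop_min = 5L, loop_max = 12L))
  do.call(dle_descriptor, utils::modifyList(args, list(...)))
}

spacer_ok <- function(s, alphabet) {
  if (alphabet == "any") return(TRUE)
  nchar(s) == 0L || all(strsplit(s, "")[[1]] %in% c("U", "C"))
}

#' Match the composite DLE grammar against a transcript
#'
#' Enumerates, for every anchor occurrence in the region, all
#' (spacer, stem, loop) decompositions satisfying the descriptor. By
#' default overlapping decompositions are collapsed to one representative
#' per (anchor position, loop start): the one with the maximal stem
#' (smallest loop on ties), giving a stable non-redundant hit set;
#' `enumerate_all = TRUE` returns every decomposition.
#'
#' @param t a [transcript()].
#' @param d a [dle_descriptor()].
#' @param region interval from [iv()] to scan (the whole motif must lie
#'   inside it); default the transcript's 3'UTR.
#' @param enumerate_all return all decompositions instead of collapsing.
#' @return list of matches, each a list with `transcript_id`, intervals
#'   `anchor`, `spacer`, `stem5`, `loop`, `stem3` (0-based half-open,
#'   adjacent and in order), `pairs` (2-column 0-based matrix, 5' index
#'   first) and `descriptor_name`; ordered left to right by anchor, then
#'   loop start.
#' @export
match_dle <- function(t, d, region = NULL, enumerate_all = FALSE) {
  stopifnot(inherits(t, "transcript"), inherits(d, "dle_descriptor"))
  n <- nchar(t$seq)
  if (is.null(region)) region <- iv(t$utr_start, n)
  check_iv_in(region, n, "scan region")
  ch <- strsplit(t$seq, "")[[1]]
  la <- nchar(d$anchor)

  anchors <- integer()
  if (iv_len(region) >= la) {
    hitpos <- gregexpr(d$anchor, iv_seq(t$seq, region), fixed = TRUE)[[1]]
    if (hitpos[1L] != -1L) anchors <- region[1L] + hitpos - 1L  # 0-based
  }
  if (d$require_preceding_A) {
    anchors <- anchors[anchors >= 1L & ch[anchors] == "A"]
  }

  cand <- list()
  for (a in anchors) {
    for (s in d$spacer_min:d$spacer_max) {
      sp_iv <- c(a + la, a + la + s)
      if (sp_iv[2L] > region[2L]) next
      if (!spacer_ok(substr(t$seq, sp_iv[1L] + 1L, sp_iv[2L]), d$spacer_alphabet)) next
      p0 <- sp_iv[2L]  # stem5 start
      for (b in d$stem_min_bp:d$stem_max_bp) {
        for (L in d$loop_min:d$loop_max) {
          e3 <- p0 + 2L * b + L
          if (e3 > region[2L]) next
          ok <- TRUE
          for (k in 0L:(b - 1L)) {
            if (!can_pair(ch[p0 + k + 1L], ch[p0 + b + L + (b - 1L - k) + 1L],
                          d$allow_GU)) { ok <- FALSE; break }
          }
          if (!ok) next
          pairs <- cbind(p0 + 0L:(b - 1L), p0 + 2L * b + L - 1L - 0L:(b - 1L))
          cand[[length(cand) + 1L]] <- list(
            transcript_id = t$id,
            anchor = iv(a, a + la), spacer = iv(sp_iv[1L], sp_iv[2L]),
            stem5 = iv(p0, p0 + b), loop = iv(p0 + b, p0 + b + L),
            stem3 = iv(p0 + b + L, e3), pairs = pairs,
            descriptor_name = d$name)
        }
      }
    }
  }
  if (length(cand) == 0L) return(list())
  key_a <- vapply(cand, function(h) h$anchor[1L], 0L)
  key_l <- vapply(cand, function(h) h$loop[1L], 0L)
  nb <- vapply(cand, function(h) nrow(h$pairs), 0L)
  ll <- vapply(cand, function(h) iv_len(h$loop), 0L)
  if (!enumerate_all) {
    keep <- !logical(length(cand))
    grp <- split(seq_along(cand), paste(key_a, key_l))
    sel <- vapply(grp, function(ix) ix[order(-nb[ix], ll[ix])][1L], 0L)
    keep <- seq_along(cand) %in% sel
    cand <- cand[keep]; key_a <- key_a[keep]; key_l <- key_l[keep]
    nb <- nb[keep]; ll <- ll[keep]
  }
  cand[order(key_a, key_l, -nb, ll)]
}

#' Apply a named DLE mutation to a transcript
#'
#' The six mutant classes used in the localization assays, defined against
#' a located DLE match: `dG` deletes the anchor; `dSL` deletes
#' stem5+loop+stem3; `dGSL` deletes both; `SM` substitutes the 5' stem arm
#' to abolish complementarity; `SR` swaps the two stem arms (compensatory:
#' pairing is preserved with different sequence); `LM` substitutes the loop
#' sequence (same length, structure-neutral at the grammar level).
#'
#' @param t a [transcript()].
#' @param match a DLE match from [match_dle()] located on `t`.
#' @param type one of `"dG"`, `"dSL"`, `"dGSL"`, `"SM"`, `"SR"`, `"LM"`.
#' @param replacement optional replacement sequence for `SM` (stem arm
#'   length) or `LM` (loop length); sensible defaults otherwise.
#' @return the edited [transcript()], id suffixed with the mutation name.
#' @export
apply_mutant <- function(t, match, type = c("dG", "dSL", "dGSL", "SM", "SR", "LM"),
                         replacement = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(t, "transcript"))
  n <- nchar(t$seq)
  for (part in c("anchor", "stem5", "loop", "stem3")) {
    check_iv_in(match[[part]], n, part)
  }
  if (iv_seq(t$seq, match$stem5) == "" || match$stem3[2L] > n) {
    stop("match does not lie on this transcript")
  }
  seq <- t$seq
  del <- function(seq, ivs) {
    # delete a list of disjoint intervals, rightmost first
    ivs <- ivs[order(-vapply(ivs, `[[`, 0L, 1L))]
    for (x in ivs) {
      seq <- paste0(substr(seq, 1L, x[1L]), substr(seq, x[2L] + 1L, nchar(seq)))
    }
    seq
  }
  sub_at <- function(seq, x, repl) {
    stopifnot(nchar(repl) == iv_len(x))
    paste0(substr(seq, 1L, x[1L]), repl, substr(seq, x[2L] + 1L, nchar(seq)))
  }
  sl <- iv(match$stem5[1L], match$stem3[2L])
  deleted <- 0L
  new_seq <- switch(type,
    dG = { deleted <- iv_len(match$anchor); del(seq, list(match$anchor)) },
    dSL = { deleted <- iv_len(sl); del(seq, list(sl)) },
    dGSL = { deleted <- iv_len(match$anchor) + iv_len(sl)
             del(seq, list(match$anchor, sl)) },
    SR = {
      s5 <- iv_seq(seq, match$stem5); s3 <- iv_seq(seq, match$stem3)
      sub_at(sub_at(seq, match$stem5, s3), match$stem3, s5)
    },
    SM = {
      repl <- if (!is.null(replacement)) normalize_rna(replacement) else {
        # per position, first base that pairs neither the partner nor keeps
        # wobble ambiguity: breaks every stem pair deterministically
        partner <- rev(strsplit(iv_seq(seq, match$stem3), "")[[1]])
        paste(vapply(partner, function(p) {
          for (cand in c("A", "C", "G", "U")) {
            if (!can_pair(cand, p, allow_GU = TRUE)) return(cand)
          }
          "A"
        }, ""), collapse = "")
      }
      sub_at(seq, match$stem5, repl)
    },
    LM = {
      repl <- if (!is.null(replacement)) normalize_rna(replacement) else {
        substr(strrep("UC", iv_len(match$loop)), 1L, iv_len(match$loop))
      }
      sub_at(seq, match$loop, repl)
    })
  new_utr <- if (deleted > 0L && match$anchor[1L] < t$utr_start) {
    max(0L, t$utr_start - deleted)
  } else t$utr_start
  transcript(paste0(t$id, "_", type), new_seq, utr_start = new_utr,
             source = t$source, gene = t$gene)
}
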