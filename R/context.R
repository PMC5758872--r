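#' Find maximal dinucleotide (or general unit) repeat runs
#'
#' Locates all maximal runs of a repeated unit (default `"CA"`) of at least
#' `min_units` copies, left to right. Runs are maximal in the sense that
#' they cannot be extended by another full unit on either side.
#'
#' @param t a [transcript()].
#' @param unit repeat unit over A/C/G/U (default `"CA"`).
#' @param min_units minimum number of unit copies (default 4; the cyc
#'   3'UTR run is much longer, but no threshold is prescribed).
#' @return list of repeat runs: `transcript_id`, `interval` ([iv()]),
#'   `unit`, `n_units`.
#' @export
find_repeats <- function(t, unit = "CA", min_units = 4L) {
  stopifnot(inherits(t, "transcript"), min_units >= 2L, nchar(unit) >= 1L)
  unit <- normalize_rna(unit)
  m <- gregexpr(paste0("(?:", unit, ")+"), t$seq)[[1]]
  if (m[1L] == -1L) return(list())
  lens <- attr(m, "match.length")
  out <- list()
  for (i in seq_along(m)) {
    nu <- lens[i] %/% nchar(unit)
    if (nu < min_units) next
    start <- m[i] - 1L  # 0-based
    out[[length(out) + 1L]] <- list(transcript_id = t$id,
                                    interval = iv(start, start + nu * nchar(unit)),
                                    unit = unit, n_units = nu)
  }
  out
}

#' Delete an interval from a transcript (in-silico deletion)
#'
#' Excises the interval; the UTR start is shifted by the number of deleted
#' positions 5' of it. Motif coordinates are not lifted -- re-scan the
#' edited transcript to re-locate matches.
#'
#' @param t a [transcript()].
#' @param interval [iv()] to excise (may be empty).
#' @return the edited [transcript()].
#' @export
delete_interval <- function(t, interval) {
  stopifnot(inherits(t, "transcript"))
  check_iv_in(interval, nchar(t$seq), "deletion")
  if (iv_len(interval) == 0L) return(t)
  new_seq <- paste0(substr(t$seq, 1L, interval[1L]),
                    substr(t$seq, interval[2L] + 1L, nchar(t$seq)))
  shift <- max(0L, min(interval[2L], t$utr_start) - interval[1L])
  transcript(t$id, new_seq, utr_start = t$utr_start - shift,
             source = t$source, gene = t$gene)
}

#' Quantify how a context deletion changes DLE stem-loop probability
#'
#' The CA-repeat masking analysis: computes the probability that the DLE
#' stem forms in the full sequence context before and after deleting a
#' context interval (which must not overlap the motif), across a
#' temperature grid, and reports the per-temperature fold change
#' `p_after / p_before`. The motif is re-located in the edited sequence by
#' re-scanning and matching the motif's local sequence, so deletions 5' of
#' the motif are handled without coordinate arithmetic.
#'
#' @param t a [transcript()].
#' @param dle a match from [match_dle()] on `t`.
#' @param deletion [iv()] to excise; empty interval gives fold change 1.
#' @param descriptor the [dle_descriptor()] used to find `dle` (needed for
#'   re-scanning).
#' @param model an [energy_model()].
#' @param t_grid_celsius temperature grid in C (default 25-28).
#' @param pairs_mode `"all"` requires every stem pair of the match;
#'   `"innermost"` requires only the `stem_min_bp` pairs closest to the
#'   loop.
#' @return object of class `masking_report`: per-temperature `p_before`,
#'   `p_after`, `fold_change`, plus `fold_change_min`/`_max` and inputs.
#' @export
masking_analysis <- function(t, dle, deletion, descriptor,
                             model = energy_model(),
                             t_grid_celsius = 25:28,
                             pairs_mode = c("all", "innermost")) {
  pairs_mode <- match.arg(pairs_mode)
  stopifnot(inherits(t, "transcript"), inherits(descriptor, "dle_descriptor"))
  check_iv_in(deletion, nchar(t$seq), "deletion")
  motif_span <- iv(dle$anchor[1L], dle$stem3[2L])
  if (iv_len(deletion) > 0L &&
      deletion[1L] < motif_span[2L] && deletion[2L] > motif_span[1L]) {
    stop("deletion [", deletion[1L], ",", deletion[2L],
         ") overlaps the DLE motif [", motif_span[1L], ",", motif_span[2L],
         "); the analysis requires the motif intact")
  }
  motif_seq <- iv_seq(t$seq, motif_span)

  pick_pairs <- function(m) {
    p <- m$pairs
    if (pairs_mode == "innermost") {
      p <- p[order(-p[, 1L]), , drop = FALSE][seq_len(descriptor$stem_min_bp), ,
                                              drop = FALSE]
    }
    p
  }

  t2 <- delete_interval(t, deletion)
  hits2 <- match_dle(t2, descriptor, region = iv(0L, nchar(t2$seq)))
  same <- Filter(function(h) {
    iv_seq(t2$seq, iv(h$anchor[1L], h$stem3[2L])) == motif_seq
  }, hits2)
  if (length(same) == 0L) {
    stop("could not re-locate the DLE motif after deletion; ",
         "the edit should leave the motif sequence intact")
  }
  dle2 <- same[[1L]]

  p_before <- probability_vs_temperature(t$seq, pick_pairs(dle), model,
                                         t_grid_celsius)$p
  p_after <- probability_vs_temperature(t2$seq, pick_pairs(dle2), model,
                                        t_grid_celsius)$p
  fc <- ifelse(p_before > 0, p_after / p_before, NA_real_)
  structure(list(transcript_id = t$id, dle = dle, deleted = deletion,
                 T_grid = as.numeric(t_grid_celsius),
                 p_before = p_before, p_after = p_after, fold_change = fc,
                 fold_change_min = min(fc, na.rm = TRUE),
                 fold_change_max = max(fc, na.rm = TRUE),
                 pairs_mode = pairs_mode, backend = model$backend),
            class = "masking_report")
}

#' @export
print.masking_report <- function(x, ...) {
  cat("<masking_report> ", x$transcript_id, ": fold change ",
      format(x$fold_change_min, digits = 3), "-",
      format(x$fold_change_max, digits = 3), " over ",
      min(x$T_grid), "-", max(x$T_grid), " C (", x$backend, " backend)\n",
      sep = "")
  invisible(x)
}

#' Tabulate a masking report
#' @param x a `masking_report`.
#' @param ... unused.
#' @return data.frame with one row per temperature.
#' @export
as.data.frame.masking_report <- function(x, ...) {
  data.frame(transcript_id = x$transcript_id, T_celsius = x$T_grid,
             p_before = x$p_before, p_after = x$p_after,
             fold_change = x$fold_change, stringsAsFactors = FALSE)
}
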