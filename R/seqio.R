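#' Read transcripts from a FASTA file
#'
#' Headers may carry whitespace-separated `key=value` tags after the record
#' id; recognized tags are `utr_start` (0-based UTR offset, default 0),
#' `gene` (grouping label for [select_longest_utr()]) and `source`.
#' Sequences are normalized to the RNA alphabet (T to U, uppercase).
#'
#' @param path FASTA file path.
#' @return list of [transcript()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    id <- fields[1L]
    tags <- parse_tags(fields[-1L])
    tryCatch(
      transcript(id, as.character(set[[i]]),
                 utr_start = if (!is.null(tags$utr_start)) as.integer(tags$utr_start) else 0L,
                 source = if (!is.null(tags$source)) tags$source else "",
                 gene = if (!is.null(tags$gene)) tags$gene else NA_character_),
      error = function(e) stop("record '", id, "': ", conditionMessage(e)))
  })
}

parse_tags <- function(fields) {
  kv <- grep("=", fields, fixed = TRUE, value = TRUE)
  if (length(kv) == 0L) return(list())
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) paste(p[-1L], collapse = "=")),
                  vapply(parts, `[[`, "", 1L))
}

#' Write transcripts to a FASTA file
#'
#' Inverse of [read_fasta()]: ids and the `utr_start`/`gene`/`source` tags
#' round-trip.
#'
#' @param transcripts list of [transcript()] objects.
#' @param path output path.
#' @export
write_fasta <- function(transcripts, path) {
  headers <- vapply(transcripts, function(t) {
    h <- paste0(t$id, " utr_start=", t$utr_start)
    if (!is.na(t$gene)) h <- paste0(h, " gene=", t$gene)
    if (nzchar(t$source)) h <- paste0(h, " source=", t$source)
    h
  }, "")
  seqs <- Biostrings::BStringSet(vapply(transcripts, `[[`, "", "seq"))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write DLE matches as GFF3
#'
#' Internal 0-based half-open intervals are converted to 1-based inclusive
#' GFF3 columns. One `DLE_motif` feature per match spans anchor through
#' stem3; the anchor/spacer/stem/loop sub-intervals and the pair count are
#' stored in the attributes column.
#'
#' @param hits list of DLE matches from [match_dle()].
#' @param path output path.
#' @export
write_hits_gff3 <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    span <- c(h$anchor[1L], h$stem3[2L])
    attrs <- paste0(
      "ID=dle", i,
      ";descriptor=", h$descriptor_name,
      ";anchor=", gff_iv(h$anchor), ";spacer=", gff_iv(h$spacer),
      ";stem5=", gff_iv(h$stem5), ";loop=", gff_iv(h$loop),
      ";stem3=", gff_iv(h$stem3), ";n_pairs=", nrow(h$pairs))
    writeLines(paste(h$transcript_id, "dletools", "DLE_motif",
                     span[1L] + 1L, span[2L], ".", "+", ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}

gff_iv <- function(x) paste0(x[1L] + 1L, "-", x[2L])

#' Read DLE match coordinates back from a GFF3 file
#'
#' Round-trip reader for [write_hits_gff3()]; restores internal 0-based
#' half-open sub-intervals from the attribute column.
#'
#' @param path GFF3 path written by [write_hits_gff3()].
#' @return list of match skeletons (intervals and descriptor name; base
#'   pairs are not serialized and can be recovered by re-scanning).
#' @export
read_hits_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    attrs <- parse_tags(strsplit(f[9L], ";", fixed = TRUE)[[1]])
    geti <- function(k) {
      se <- as.integer(strsplit(attrs[[k]], "-", fixed = TRUE)[[1]])
      iv(se[1L] - 1L, se[2L])  # back to 0-based half-open
    }
    list(transcript_id = f[1L], anchor = geti("anchor"),
         spacer = geti("spacer"), stem5 = geti("stem5"),
         loop = geti("loop"), stem3 = geti("stem3"),
         descriptor_name = attrs$descriptor)
  })
}

#' Select the longest 3'UTR per gene group
#'
#' Keeps exactly one transcript per gene group, the one with the longest
#' 3'UTR; ties are broken by the lexicographically smallest id so the
#' result is deterministic.
#'
#' @param transcripts list of [transcript()] objects with `gene` labels.
#' @return list of transcripts, one per non-empty group, in group order of
#'   first appearance.
#' @export
select_longest_utr <- function(transcripts) {
  if (length(transcripts) == 0L) return(list())
  genes <- vapply(transcripts, `[[`, "", "gene")
  if (anyNA(genes)) stop("all transcripts must carry a gene label")
  out <- list()
  for (g in unique(genes)) {
    grp <- transcripts[genes == g]
    lens <- vapply(grp, utr_length, 0L)
    ids <- vapply(grp, `[[`, "", "id")
    best <- order(-lens, ids)[1L]
    out[[length(out) + 1L]] <- grp[[best]]
  }
  out
}

#' Convert DLE matches to a data frame
#'
#' @param hits list of matches from [match_dle()].
#' @return data.frame with one row per match (0-based half-open columns).
#' @export
hits_to_df <- function(hits) {
  if (length(hits) == 0L) {
    return(data.frame(transcript_id = character(), descriptor = character(),
                      anchor_start = integer(), anchor_end = integer(),
                      stem5_start = integer(), loop_start = integer(),
                      loop_end = integer(), stem3_end = integer(),
                      n_pairs = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(hits, function(h) {
    data.frame(transcript_id = h$transcript_id,
               descriptor = h$descriptor_name,
               anchor_start = h$anchor[1L], anchor_end = h$anchor[2L],
               stem5_start = h$stem5[1L], loop_start = h$loop[1L],
               loop_end = h$loop[2L], stem3_end = h$stem3[2L],
               n_pairs = nrow(h$pairs), stringsAsFactors = FALSE)
  }))
}
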