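#!/usr/bin/env Rscript

# Orthologue conservation analysis: strict scan of the simulated family,
# progressive alignment of the motif regions, and the consensus base-pair
# reliability tracks with dot-bracket structure.

suppressMessages(library(dletools))

out <- "results/conservation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fam_fa <- "results/simulated/orthologue_family.fa"
transcripts <- if (file.exists(fam_fa)) read_fasta(fam_fa) else {
  gen_orthologue_family(7, 0.2, TRUE, seed = 17)$transcripts
}
tl <- stats::setNames(transcripts, vapply(transcripts, `[[`, "", "id"))

hits <- top_hit_per_species(scan_orthologues(transcripts, cds_context = 0))
message(length(hits), " species carry a strict DLE at the homologous anchor (",
        paste(vapply(hits, function(h) h$anchor[1L], 0L), collapse = ","), ")")

aln <- align_motif_regions(hits, tl, flank = 10)
write_alignment(aln, file.path(out, "motif_alignment.fa"))

cons <- consensus_structure(aln, energy_model())
block <- format_consensus_block(cons, aln)
writeLines(block, file.path(out, "consensus_block.txt"))
cat(block, sep = "\n")

rel <- cons$pair_reliability
pairs <- which(rel >= 0.5, arr.ind = TRUE)
tab <- data.frame(col_i = pairs[, 1], col_j = pairs[, 2],
                  reliability = rel[pairs])
write.table(tab[order(-tab$reliability), ],
            file.path(out, "consensus_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(cons$consensus_pairs),
        " consensus pairs at reliability >= 0.5; see ", out)
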