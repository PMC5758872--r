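#!/usr/bin/env Rscript

# Generates every synthetic input class used by the downstream analyses,
# with ground truth alongside: planted-DLE UTRs, masked/unmasked repeat
# constructs, a compensatory orthologue family, and a two-channel embryo
# imaging cohort.

suppressMessages(library(dletools))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Planted-DLE UTR cohort (200 sequences, strict grammar) ...")
utrs <- gen_planted_utrs(n = 200, utr_length = 200, seed = 11)
write_fasta(utrs$transcripts, file.path(out, "planted_utrs.fa"))
write.table(utrs$truth, file.path(out, "planted_utrs_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Masked-DLE constructs ((CA)8 repeat vs inert poly-A control) ...")
pm <- plant_masked_dle(8)
pi <- plant_masked_dle(8, inert = TRUE)
write_fasta(list(pm$masked, pm$unmasked, pi$masked, pi$unmasked),
            file.path(out, "masked_constructs.fa"))
writeLines(sprintf("masked deletion interval: [%d,%d)",
                   pm$deletion[[1]], pm$deletion[[2]]),
           file.path(out, "masked_deletion.txt"))

message("Orthologue family (7 species, divergence 0.2, compensatory) ...")
fam <- gen_orthologue_family(7, 0.2, TRUE, seed = 17)
write_fasta(fam$transcripts, file.path(out, "orthologue_family.fa"))
writeLines(c(sprintf("anchor_start\t%d", fam$truth$anchor_start),
             sprintf("stem_pair\t%d\t%d", fam$truth$pairs[, 1],
                     fam$truth$pairs[, 2])),
           file.path(out, "orthologue_truth.tsv"))

message("Embryo imaging cohort (2 groups x 3 stages, 16-bit TIFF stacks) ...")
co <- gen_embryo_cohort(n_per_cell = 2, noise_cv = 0.05, seed = 23)
write_embryo_cohort(co, file.path(out, "embryo_cohort"))

message("Done; inputs under ", out)
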