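#!/usr/bin/env Rscript
# The 20x20 substitution grid over the census missense variants,
# single-nucleotide reachability checks, and the Grantham distance
# distribution of the recorded substitutions.

suppressMessages(library(fxivar))
dir.create("results", showWarnings = FALSE)

cen <- fxi_census()
grid <- build_grid(cen)
write_grid(grid, "results/03_substitution_grid.tsv")
cat("Grid over", grid$n_missense, "recorded missense substitutions;",
    nrow(grid$suspect), "fall outside single-nucleotide reachability.\n")
tops <- sort(grid$row_totals, decreasing = TRUE)
cat("Most-substituted reference residues:",
    paste(names(tops)[1:3], tops[1:3], collapse = ", "), "\n")

G <- grantham_matrix()
write.table(G, "results/03_grantham_matrix.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
mis <- cen[cen$effect == "missense" & !is.na(cen$ref_aa), ]
scores <- grantham_distance(mis$ref_aa, mis$alt_aa, G)
write.table(data.frame(protein_change = mis$protein_change,
                       grantham = scores),
            "results/03_grantham_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Grantham matrix spans", min(G[upper.tri(G)]), "-", max(G),
    "; census substitutions span", min(scores), "-", max(scores),
    "(median", stats::median(scores), ").\n")
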