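#!/usr/bin/env Rscript
# Generate the synthetic dataset for the downstream analyses: per-gene
# haplotype alignments, gene-category table and FPKM expression matrices
# under the study-condition demographies (isolation with migration,
# post-split growth, two-class heterogeneous migration; rare categories
# dominated by the low-migration class).
#
# Scale note: gene counts follow the study design
# (freqA/rareA/freqX/rareX = 2009/1909/209/398); pass --scale 0.25 for a
# quick look.

suppressMessages(library(periflow))

args <- commandArgs(trailingOnly = TRUE)
arg_of <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
seed <- as.integer(arg_of("--seed", "1"))
scale <- as.numeric(arg_of("--scale", "1"))
out <- arg_of("--out", "results/data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  genes_per_category = pmax(round(
    scale * c(freqA = 2009, rareA = 1909, freqX = 209, rareX = 398)), 10),
  seed = seed)
cat("simulating", sum(cfg$genes_per_category), "genes",
    "(", cfg$n_codons, "codons each, 12 diploids/species )\n")
d <- simulate_dataset(cfg)

write_gene_alignments(d$alignments, file.path(out, "alignments.fasta"))
write_gene_categories(d$categories, file.path(out, "categories.tsv"))
write_expression(d$expression, file.path(out, "expression.tsv"))
write.table(alignment_species_map(d$alignments),
            file.path(out, "species_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(d$truth$genes, file.path(out, "truth_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(d$truth$expression, file.path(out, "truth_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(jsonlite::toJSON(list(seed = seed, scale = scale,
                                 theta = as.list(cfg$theta)),
                            auto_unbox = TRUE, digits = NA),
           file.path(out, "sim_meta.json"))
cat("wrote alignments, categories, expression and truth records to",
    out, "\n")
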