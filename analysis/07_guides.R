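#!/usr/bin/env Rscript
# CRISPR/Cas9 guide design against the toy gene: scan a target exon and its
# flanks for 23-mer protospacer+NGG sites on both strands, verify genome
# uniqueness by exact matching, and rank (unique first, then 5'-GG for T7).

suppressPackageStartupMessages(library(cronoscan))
dir.create("results", showWarnings = FALSE)

gene <- make_toy_gene(sim_config(seed = 1L))
tx <- gene$transcripts$main
target <- 2L                               # exon hit by the engineered lines
ex <- tx$exons[tx$exons$index == target, ]

cand <- scan_protospacers(gene$genome, ex$contig, ex$start - 20L, ex$end + 20L)
cand <- add_genome_matches(cand, gene$genome)
ranked <- rank_guides(cand)
write.table(ranked, "results/guides.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("exon %d +/- 20 bp: %d candidate sites, %d unique in genome, %d 5'-GG\n",
            target, nrow(ranked), sum(ranked$genome_matches == 1),
            sum(ranked$gg_start)))
cat("top guides:\n")
print(head(ranked, 5), row.names = FALSE)
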