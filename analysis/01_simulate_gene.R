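#!/usr/bin/env Rscript
# Build the miniature Titin-like gene every downstream analysis runs on, and
# write its fixtures (genome FASTA, gene models GFF3) under results/.
# The gene carries a designated internal-promoter intron with an in-frame
# initiator ATG upstream of one exon, and a Novex-3-role minor-isoform
# terminal exon.

suppressPackageStartupMessages(library(cronoscan))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
gene <- make_toy_gene(cfg)
tx <- gene$transcripts$main

write_genome_fasta(gene$genome, "results/toy_genome.fa")
write_gene_models_gff3(gene$transcripts, "results/toy_models.gff3")

cds <- spliced_cds(tx, gene$genome)
tr <- translate_cds(cds)
cat("mini-titin:", n_exons(tx), "exons,",
    nchar(cds), "nt CDS,", nchar(tr$protein), "aa protein\n")
cat("internal promoter intron upstream of exon", gene$promoter_exon,
    "| TSS at", gene$tss_position,
    "| in-frame ATG", gene$expected_aa_offset, "codons upstream\n")
cat("minor isoform:", n_exons(gene$transcripts$novex),
    "exons ending in its own terminal exon\n")
cat("wrote results/toy_genome.fa, results/toy_models.gff3\n")
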