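#!/usr/bin/env Rscript
# Step 2: reload the universe from disk, intersect the lineages, and
# annotate every shared variant with its coding consequence.
#
# Reading everything back through the package's own FASTA/GFF3/VCF readers
# exercises the full I/O path a real analysis would take.

suppressMessages(library(variantfunnel))

indir <- "results/synthetic"
genome <- read_genome(file.path(indir, "ref.fa"))
genes <- read_gene_models(file.path(indir, "genes.gff3"), genome)
vcfs <- list.files(indir, pattern = "\\.vcf$", full.names = TRUE)
sets <- lapply(vcfs, function(f)
  read_variants(f, sub("\\.vcf$", "", basename(f)), genome))

common <- intersect_lineages(sets)
cat("shared variants:", nrow(common),
    sprintf("(%d SNVs, %d DIPs)\n", sum(common$vclass == "SNV"),
            sum(common$vclass == "DIP")))

effects <- classify_variants(common, genes, genome)
cat("effects on genes:\n")
print(table(effects$eclass))

dir.create("results", showWarnings = FALSE)
write.table(effects, "results/effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/effects.tsv\n")
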