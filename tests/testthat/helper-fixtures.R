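# Deterministic toy fixtures built in code.

# Toy three-exon gene mirroring the splice-retention mechanism: intron 2
# sits 20 nt (= 2 mod 3) into the CDS and begins GTAAGT, so retaining it
# puts a TAA stop in frame. Returned with the gene placed on a plus- or
# minus-strand scaffold after a 10 bp pad.
toy_splice_gene <- function(strand = "+") {
  cds <- "ATGGCTCATTACGAAGCAAAAGGACCATGTTGA"  # 11 codons incl. stop
  e1 <- substr(cds, 1, 9)
  e2 <- substr(cds, 10, 20)
  e3 <- substr(cds, 21, 33)
  i1 <- "GTCTCTAG"
  i2 <- "GTAAGTCCACCTTCAG"
  region <- paste0(e1, i1, e2, i2, e3)
  pad <- "ACACACACAC"
  L <- nchar(region)
  if (strand == "+") {
    seqs <- paste0(pad, region, pad)
    starts <- 10 + c(1, 1 + 9 + 8, 1 + 9 + 8 + 11 + 16)
    ends <- starts + c(9, 11, 13) - 1
  } else {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(region, "")[[1]]),
                                       collapse = ""))
    seqs <- paste0(pad, rc, pad)
    # sense interval [a,b] of the region maps to genomic [10+L-b+1, 10+L-a+1]
    sense_starts <- c(1, 1 + 9 + 8, 1 + 9 + 8 + 11 + 16)
    sense_ends <- sense_starts + c(9, 11, 13) - 1
    starts <- rev(10 + L - sense_ends + 1)
    ends <- rev(10 + L - sense_starts + 1)
  }
  genome <- c(chr1 = seqs)
  gene <- gene_model("toy1", "chr1", strand, starts, ends, genome = genome)
  # genomic position of the donor +1 base of intron 2 (sense base G)
  i2_sense_start <- 9 + 8 + 11 + 1
  donor_pos <- if (strand == "+") 10 + i2_sense_start else
    10 + L - i2_sense_start + 1
  list(genome = genome, gene = gene, donor_pos = donor_pos,
       cds = cds, protein = "MAHYEAKGPC")
}

# Intronless toy gene with planted codons for each substitution class:
# codon 2 AAA (K), codon 3 GCT (A), codon 4 TGG (W), codon 5 CTT (L).
toy_coding_gene <- function() {
  cds <- "ATGAAAGCTTGGCTTCAGTGA"  # M K A W L Q *
  pad <- "GGATCCGGAT"
  genome <- c(chr1 = paste0(pad, cds, pad))
  gene <- gene_model("cod1", "chr1", "+", 11, 10 + nchar(cds),
                     genome = genome)
  list(genome = genome, gene = gene, cds = cds, protein = "MKAWLQ")
}

snv <- function(scaffold, pos, ref, alt) {
  list(scaffold = scaffold, pos = as.integer(pos), ref = ref, alt = alt)
}
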