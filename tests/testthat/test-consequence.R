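test_that("donor +1 G>T is classified as splice disruption with retained-intron truncation", {
  for (strand in c("+", "-")) {
    fix <- toy_splice_gene(strand)
    ref <- if (strand == "+") "G" else "C"
    alt <- if (strand == "+") "T" else "A"
    eff <- classify(snv("chr1", fix$donor_pos, ref, alt), fix$gene,
                    fix$genome)
    expect_identical(eff$eclass, "splice_donor_disrupted")
    expect_identical(eff$allele_disrupted, "inbred")
    expect_equal(eff$intron_index, 2L)
    # retained intron 2 with the variant applied: TAA stop right after the
    # codon that crosses into the intron -> 7 residues
    vdf <- data.frame(pos = fix$donor_pos, ref = ref, alt = alt)
    ret <- retained_intron_protein(fix$gene, fix$genome, 2L, vdf)
    expect_true(ret$truncated)
    expect_identical(ret$protein, "MAHYEAN")
    expect_equal(eff$truncated_length, 7L)
    # independent oracle translation of the retained transcript
    seg <- fix$gene$cds_segments
    seq <- fix$genome[["chr1"]]
    seq <- paste0(substr(seq, 1, fix$donor_pos - 1), alt,
                  substr(seq, fix$donor_pos + 1, nchar(seq)))
    intr <- gene_introns(fix$gene)
    keep <- intr[intr$index == 2L, ]
    pieces <- rbind(seg, data.frame(start = keep$start, end = keep$end))
    pieces <- pieces[order(pieces$start), ]
    oracle <- oracle_splice_translate(seq, pieces$start, pieces$end, strand)
    expect_identical(oracle$protein, ret$protein)
    expect_true(oracle$stopped)
  }
})

test_that("a variant restoring a broken reference donor is flagged as a reference lesion", {
  fix <- toy_splice_gene("+")
  # break the donor in the reference (the sterile-strain orientation) ...
  genome <- fix$genome
  substr(genome[["chr1"]], fix$donor_pos, fix$donor_pos) <- "T"
  # ... and let the shared inbred variant restore it
  eff <- classify(snv("chr1", fix$donor_pos, "T", "G"), fix$gene, genome)
  expect_identical(eff$eclass, "splice_donor_disrupted")
  expect_identical(eff$allele_disrupted, "reference")
  expect_equal(eff$truncated_length, 7L)  # the reference allele truncates
})

test_that("splice windows take priority over coding interpretation", {
  fix <- toy_splice_gene("+")
  intr <- gene_introns(fix$gene)
  i2 <- intr[intr$index == 2L, ]
  # donor +2 and acceptor -1/-2 of intron 2
  eff <- classify(snv("chr1", i2$start + 1L, "T", "C"), fix$gene, fix$genome)
  expect_identical(eff$eclass, "splice_donor_disrupted")
  expect_identical(eff$allele_disrupted, "inbred")
  eff <- classify(snv("chr1", i2$end, "G", "C"), fix$gene, fix$genome)
  expect_identical(eff$eclass, "splice_acceptor_disrupted")
  eff <- classify(snv("chr1", i2$end - 1L, "A", "C"), fix$gene, fix$genome)
  expect_identical(eff$eclass, "splice_acceptor_disrupted")
  # a deletion spanning the exon/intron junction is splice disruption
  del_pos <- i2$start - 2L
  ref <- substr(fix$genome[["chr1"]], del_pos, del_pos + 2L)
  eff <- classify(list(scaffold = "chr1", pos = del_pos, ref = ref,
                       alt = substr(ref, 1, 1)), fix$gene, fix$genome)
  expect_identical(eff$eclass, "splice_donor_disrupted")
})

test_that("coding SNVs classify by codon diff: silent, conservative, nonconservative, nonsense", {
  fix <- toy_coding_gene()
  # codon 3 GCT -> GTT: A>V, a conservative exchange
  eff <- classify(snv("chr1", 10 + 8, "C", "T"), fix$gene, fix$genome)
  expect_identical(eff$eclass, "missense_conservative")
  expect_identical(c(eff$aa_ref, eff$aa_alt), c("A", "V"))
  expect_equal(eff$aa_pos, 3L)
  # codon 4 TGG -> GGG: W>G, non-conservative
  eff <- classify(snv("chr1", 10 + 10, "T", "G"), fix$gene, fix$genome)
  expect_identical(eff$eclass, "missense_nonconservative")
  expect_identical(c(eff$aa_ref, eff$aa_alt), c("W", "G"))
  # codon 5 CTT -> CTC: Leu wobble, synonymous
  eff <- classify(snv("chr1", 10 + 15, "T", "C"), fix$gene, fix$genome)
  expect_identical(eff$eclass, "synonymous")
  expect_identical(eff$aa_ref, eff$aa_alt)
  # codon 4 TGG -> TAG: premature stop after 3 residues
  eff <- classify(snv("chr1", 10 + 11, "G", "A"), fix$gene, fix$genome)
  expect_identical(eff$eclass, "nonsense")
  expect_equal(eff$truncated_length, 3L)
})

test_that("coding indels classify by re-translation with truncation length from the mutant protein", {
  fix <- toy_coding_gene()
  g <- fix$genome[["chr1"]]
  # 1-bp deletion inside codon 2
  eff <- classify(list(scaffold = "chr1", pos = 13L,
                       ref = substr(g, 13, 14), alt = substr(g, 13, 13)),
                  fix$gene, fix$genome)
  expect_identical(eff$eclass, "frameshift")
  ora <- oracle_classify("chr1", 13L, substr(g, 13, 14), substr(g, 13, 13),
                         fix$gene, fix$genome, blosum_matrix())
  expect_equal(eff$truncated_length, ora$truncated_length)
  # 3-bp in-frame insertion of a non-stop codon
  eff <- classify(list(scaffold = "chr1", pos = 13L,
                       ref = substr(g, 13, 13),
                       alt = paste0(substr(g, 13, 13), "GCA")),
                  fix$gene, fix$genome)
  expect_identical(eff$eclass, "inframe_indel")
  # 3-bp insertion that brings a stop codon in frame
  eff <- classify(list(scaffold = "chr1", pos = 13L,
                       ref = substr(g, 13, 13),
                       alt = paste0(substr(g, 13, 13), "TAA")),
                  fix$gene, fix$genome)
  expect_identical(eff$eclass, "nonsense")
  expect_lt(eff$truncated_length, nchar(fix$protein))
})

test_that("classification is pure and intronic/intergenic positions are recognized", {
  fix <- toy_splice_gene("+")
  intr <- gene_introns(fix$gene)
  i1 <- intr[intr$index == 1L, ]
  mid <- i1$start + 3L
  b <- substr(fix$genome[["chr1"]], mid, mid)
  v <- snv("chr1", mid, b, setdiff(c("A", "C", "G", "T"), b)[1])
  e1 <- classify(v, fix$gene, fix$genome)
  e2 <- classify(v, fix$gene, fix$genome)
  expect_identical(e1, e2)
  expect_identical(e1$eclass, "intronic")
  e <- classify(snv("chr1", 3L, "A", "G"), fix$gene, fix$genome)
  expect_identical(e$eclass, "intergenic")
})

test_that("conservative-exchange policy reproduces the canonical examples", {
  pol <- substitution_policy()
  expect_true(is_conservative("A", "V", pol))
  expect_true(is_conservative("I", "L", pol))
  expect_true(is_conservative("K", "E", pol))
  expect_false(is_conservative("W", "G", pol))
  expect_error(is_conservative("X", "A", pol), "standard")
  expect_error(is_conservative("A", "*", pol), "standard")
})

test_that("conservation filter counts non-gap homolog rows at the mapped column", {
  eff <- data.frame(gene_id = "g1", aa_pos = 2L,
                    eclass = "missense_nonconservative")
  aln <- homolog_alignment("g1", c(
    focal = "MK-AW", h1 = "MKCAW", h2 = "MKAAW", h3 = "MKGAW", h4 = "MKTAW"))
  # focal aa_pos 2 = K, alignment column 2; all four homologs match
  expect_true(conservation_filter(eff, aln))
  # column where no homolog matches
  eff$aa_pos <- 3L  # focal position 3 = A at column 4
  aln0 <- homolog_alignment("g1", c(
    focal = "MK-AW", h1 = "MKCGW", h2 = "MKAGW", h3 = "MKGGW", h4 = "MKTGW"))
  expect_false(conservation_filter(eff, aln0))
  # gaps in 2/4 rows, 1 of the 2 remaining matching, threshold 0.5
  eff$aa_pos <- 4L  # focal position 4 = W at column 5
  aln2 <- homolog_alignment("g1", c(
    focal = "MK-AW", h1 = "MKCA-", h2 = "MKAA-", h3 = "MKGAW", h4 = "MKTAF"))
  expect_true(conservation_filter(eff, aln2))
  # missing alignment: fail-open with a warning
  expect_warning(expect_true(conservation_filter(eff, NULL)), "passes")
  # position beyond the focal protein: error
  eff$aa_pos <- 99L
  expect_error(conservation_filter(eff, aln), "beyond")
})

test_that("retained in-frame stop-free intron yields a longer, untruncated protein", {
  # intron GTACCACAG (9 nt, codons VPQ) at a codon boundary
  cds <- "ATGGCTCATTACGAAGCATGA"
  e1 <- substr(cds, 1, 9); e2 <- substr(cds, 10, 21)
  intron <- "GTACCACAG"
  genome <- c(chr1 = paste0("ACACACACAC", e1, intron, e2, "ACACACACAC"))
  gene <- gene_model("gif", "chr1", "+", c(11, 11 + 9 + 9),
                     c(11 + 8, 11 + 9 + 9 + 11), genome = genome)
  ret <- retained_intron_protein(gene, genome, 1L)
  expect_false(ret$truncated)
  expect_equal(nchar(ret$protein), nchar(gene_protein(gene, genome)) + 3L)
  # retaining nothing reproduces the reference protein
  ret0 <- retained_intron_protein(gene, genome, 0L)
  expect_identical(ret0$protein, gene_protein(gene, genome))
  expect_false(ret0$truncated)
  expect_error(retained_intron_protein(gene, genome, 5L), "out of range")
})

test_that("strand symmetry: mirrored gene gives identical effects", {
  plus <- toy_splice_gene("+")
  minus <- toy_splice_gene("-")
  L <- nchar(plus$genome[["chr1"]])
  comp <- function(b) chartr("ACGT", "TGCA", b)
  # probe every position of the plus-strand gene span with an SNV
  span <- c(min(plus$gene$cds_segments$start),
            max(plus$gene$cds_segments$end))
  for (p in span[1]:span[2]) {
    b <- substr(plus$genome[["chr1"]], p, p)
    a <- setdiff(c("A", "C", "G", "T"), b)[1]
    ep <- classify(snv("chr1", p, b, a), plus$gene, plus$genome)
    pm <- L - p + 1L
    em <- classify(snv("chr1", pm, comp(b), comp(a)), minus$gene,
                   minus$genome)
    expect_identical(em$eclass, ep$eclass)
    expect_identical(em$truncated_length, ep$truncated_length)
    expect_identical(em$aa_pos, ep$aa_pos)
    expect_identical(em$aa_ref, ep$aa_ref)
    expect_identical(em$aa_alt, ep$aa_alt)
  }
})
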