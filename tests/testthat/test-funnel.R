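test_that("lineage intersection keeps exactly the shared keys", {
  genome <- c(s1 = strrep("ACGTTGCA", 50))
  mk <- function(pos, lineage) {
    ref <- substring(genome[["s1"]], pos, pos)
    alt <- ifelse(ref == "A", "G", "A")
    variant_set("s1", pos, ref, alt, lineage = lineage, genome = genome)
  }
  a <- mk(c(10, 20), "A"); b <- mk(c(20, 30), "B")
  common <- intersect_lineages(list(a, b))
  expect_equal(nrow(common), 1L)
  expect_equal(common$pos, 20L)
  expect_identical(common$lineage, "common")

  expect_equal(nrow(intersect_lineages(list(mk(10, "A"), mk(30, "B")))), 0L)
  expect_error(intersect_lineages(list(a)), "two")
})

test_that("equivalent homopolymer indel representations intersect after normalization", {
  genome <- c(s1 = paste0("CT", strrep("A", 6), "GTC", strrep("ACGT", 20)))
  left <- variant_set("s1", 2, "TA", "T", lineage = "A", genome = genome)
  right <- variant_set("s1", 6, "AA", "A", lineage = "B", genome = genome)
  common <- intersect_lineages(list(left, right))
  expect_equal(nrow(common), 1L)
  expect_identical(common$key, "s1:2:TA:T")
})

test_that("percent shares reproduce the printed lineage-sharing tables", {
  # SNV table marginals
  expect_equal(percent_share(43282, 77403), 56L)
  expect_equal(percent_share(43282, 118600), 36L)
  expect_equal(percent_share(14999, 25390), 59L)
  expect_equal(percent_share(14999, 40042), 37L)
  expect_equal(percent_share(14199, 23987), 59L)
  expect_equal(percent_share(14199, 37484), 38L)
  expect_equal(percent_share(638, 1060), 60L)
  expect_equal(percent_share(638, 1687), 38L)
  expect_equal(percent_share(3124, 4806), 65L)
  expect_equal(percent_share(3124, 7044), 44L)
  expect_equal(percent_share(427, 746), 57L)
  expect_equal(percent_share(427, 1127), 38L)
  # indel (DIP) table marginals
  expect_equal(percent_share(4751, 8945), 53L)
  expect_equal(percent_share(4751, 15378), 31L)
  expect_equal(percent_share(829, 1578), 53L)
  expect_equal(percent_share(829, 2920), 28L)
  expect_equal(percent_share(661, 1293), 51L)
  expect_equal(percent_share(661, 2348), 28L)
  expect_equal(percent_share(293, 535), 55L)
  expect_equal(percent_share(293, 907), 32L)
  expect_equal(percent_share(151, 279), 54L)
  expect_equal(percent_share(70, 250), 28L)
  expect_error(percent_share(1, 0), "positive")
})

test_that("half-away-from-zero is the rounding convention", {
  expect_equal(percent_share(1, 8), 13L)    # 12.5 rounds up
  expect_equal(percent_share(829, 1578), 53L)  # 52.53 rounds to 53
  expect_equal(percent_share(661, 1293), 51L)  # 51.12 rounds down
})

test_that("gene-level exclusions remove conservative-only and truncated-inbred genes", {
  fix <- toy_coding_gene()
  genes <- list(cod1 = fix$gene)
  # only effect is A>V: gene eliminated at the conservative-exchange step
  common <- variant_set("chr1", 18, "C", "T", lineage = "common",
                        genome = fix$genome)
  rep <- run_funnel(common, genes, fix$genome)
  expect_equal(nrow(rep$candidates), 0L)
  expect_true("cod1" %in% rep$survivors$no_inbred_truncation)
  expect_false("cod1" %in% rep$survivors$non_conservative)

  # a premature stop in the inbred allele excludes the gene earlier
  common <- variant_set("chr1", 21, "G", "A", lineage = "common",
                        genome = fix$genome)
  rep <- run_funnel(common, genes, fix$genome)
  expect_true("cod1" %in% rep$survivors$aa_changing_genes)
  expect_false("cod1" %in% rep$survivors$no_inbred_truncation)
  expect_equal(nrow(rep$candidates), 0L)

  # an empty common set gives an empty, all-zero report
  empty <- variant_set(lineage = "common")
  rep <- run_funnel(empty, genes, fix$genome)
  expect_equal(nrow(rep$candidates), 0L)
  expect_true(all(rep$steps$n_variants == 0L))
  expect_true(all(rep$steps$n_genes == 0L))
})

test_that("funnel survivor sets shrink monotonically and ignore input order", {
  sim <- simulate_backcross(sim_config(seed = 23))
  rep <- run_funnel(sim$common, sim$genes, sim$genome,
                    alignments = sim$alignments)
  sizes <- vapply(rep$survivors, length, integer(1))
  expect_true(all(diff(sizes) <= 0L))

  # shuffle variant rows and lineage order: identical report
  set.seed(99)
  shuf <- sim$common[sample(nrow(sim$common)), ]
  common2 <- variant_set(shuf$scaffold, shuf$pos, shuf$ref, shuf$alt,
                         lineage = "common", genome = sim$genome)
  rep2 <- run_funnel(common2, sim$genes, sim$genome,
                     alignments = sim$alignments)
  expect_identical(rep$steps, rep2$steps)
  expect_identical(rep$candidates, rep2$candidates)

  common_rev <- intersect_lineages(rev(sim$sets))
  common_fwd <- intersect_lineages(sim$sets)
  expect_identical(common_rev$key, common_fwd$key)
})

test_that("scaffold bias reports length-proportional enrichment and tail probabilities", {
  # 73 candidates, 52 on a scaffold holding 10% of the genome
  genome <- c(s6 = strrep("A", 1000), rest = strrep("C", 9000))
  cand <- data.frame(gene_id = sprintf("g%02d", 1:73),
                     scaffold = c(rep("s6", 52), rep("rest", 21)))
  bias <- scaffold_bias(cand, genome)
  row <- bias[bias$scaffold == "s6", ]
  expect_equal(row$fold, 52 / (73 * 0.1), tolerance = 1e-12)
  expect_gt(row$fold, 7)
  # exact binomial upper tail by independent summation
  p_oracle <- sum(vapply(52:73, function(k)
    choose(73, k) * 0.1^k * 0.9^(73 - k), numeric(1)))
  expect_equal(row$p, p_oracle, tolerance = 1e-12)
  expect_lt(row$p, 1e-10)

  # uniform spread equal to expectation: fold 1 everywhere
  genome2 <- c(a = strrep("A", 500), b = strrep("C", 500))
  cand2 <- data.frame(gene_id = sprintf("g%d", 1:10),
                      scaffold = rep(c("a", "b"), each = 5))
  expect_true(all(scaffold_bias(cand2, genome2)$fold == 1))

  # degenerate single-scaffold genome
  cand1 <- data.frame(gene_id = c("g1", "g2", "g3"), scaffold = "only")
  bias1 <- scaffold_bias(cand1, c(only = strrep("A", 100)))
  expect_equal(bias1$fold, 1)
  expect_equal(bias1$p, 1)

  # hypergeometric tail when a gene universe is supplied
  sim <- simulate_backcross(sim_config(seed = 2))
  rep <- run_funnel(sim$common, sim$genes, sim$genome,
                    alignments = sim$alignments)
  bias_h <- scaffold_bias(rep$candidates, sim$genome,
                          gene_universe = sim$genes)
  gsc <- vapply(sim$genes, function(g) g$scaffold, character(1))
  m <- sum(gsc == "scaffold_1")
  k <- nrow(rep$candidates)
  obs <- bias_h$n_candidates[bias_h$scaffold == "scaffold_1"]
  p_oracle <- sum(stats::dhyper(obs:min(m, k), m, length(gsc) - m, k))
  expect_equal(bias_h$p[bias_h$scaffold == "scaffold_1"], p_oracle,
               tolerance = 1e-12)
})

test_that("funnel report carries lineage totals and integer shares", {
  sim <- simulate_backcross(sim_config(seed = 4))
  rep <- run_funnel(sim$common, sim$genes, sim$genome,
                    alignments = sim$alignments, lineage_sets = sim$sets)
  tot <- rep$lineage_totals
  expect_equal(tot$snv_total, sim$config$snv_total)
  expect_equal(tot$dip_total, sim$config$dip_total)
  ps <- rep$percent_shares
  snv_rows <- ps[ps$metric == "snv_total", ]
  expect_equal(snv_rows$percent, c(56L, 36L))
  dip_rows <- ps[ps$metric == "dip_total", ]
  expect_equal(dip_rows$percent, c(53L, 31L))
  d <- withr::local_tempdir()
  write_funnel_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("funnel_steps.tsv",
                                             "candidates.tsv",
                                             "lineage_totals.tsv",
                                             "percent_shares.tsv")))))
})
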