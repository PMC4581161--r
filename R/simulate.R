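#' Default planted lesions for the synthetic backcross universe
#'
#' One lesion of each kind the exclusion funnel discriminates, each with
#' its expected fate. The surviving kinds sit on the first scaffold to
#' emulate clustering of donor-genome residue around a selected locus.
#'
#' @return data.frame with columns `kind`, `scaffold`, `expected_fate`.
#' @export
default_planted_lesions <- function() {
  data.frame(
    kind = c("donor_site_restore", "nonconservative_missense",
             "nonconservative_missense", "inbred_nonsense",
             "conservative_missense", "silent", "nonconserved_missense"),
    scaffold = c("scaffold_1", "scaffold_1", "scaffold_1", "scaffold_2",
                 "scaffold_2", "scaffold_3", "scaffold_3"),
    expected_fate = c("survive", "survive", "survive",
                      "eliminated_at_step_4", "eliminated_at_step_5",
                      "eliminated_at_step_2", "eliminated_at_step_6"),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic backcross generator
#'
#' The defaults define the study conditions the generator emulates: two
#' inbred lineages derived by repeated backcrossing to the reference
#' strain, sharing 56\% / 36\% of their SNVs and 53\% / 31\% of their
#' short indels with each other (the common pool), realized by explicit
#' partition into a common and two private variant pools so the realized
#' ratios are exact. Scale (a ~150 kb genome, ~24 genes) is chosen so an
#' end-to-end run takes seconds while every funnel rule is exercised.
#'
#' @param seed RNG seed; a single global R stream drives all randomness.
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param n_genes Total genes to place (allocated to scaffolds in
#'   proportion to length).
#' @param lineages Two or more lineage labels.
#' @param snv_total,dip_total Per-lineage total variant counts (same
#'   length as `lineages`).
#' @param snv_common,dip_common Shared (common-pool) counts; defaults give
#'   shares 252/450 = 56\%, 252/700 = 36\%, 62/117 = 53\%, 62/200 = 31\%.
#' @param planted data.frame of planted lesions (see
#'   [default_planted_lesions()]).
#' @param homolog_n Homolog rows per alignment.
#' @param homolog_sub_rate,homolog_gap_rate Per-column substitution and gap
#'   probabilities used to mutate the reference protein into homolog rows.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       scaffold_lengths = c(scaffold_1 = 60000L,
                                            scaffold_2 = 45000L,
                                            scaffold_3 = 30000L,
                                            scaffold_4 = 15000L),
                       n_genes = 24L,
                       lineages = c("inbred_1", "inbred_2"),
                       snv_total = c(450L, 700L), snv_common = 252L,
                       dip_total = c(117L, 200L), dip_common = 62L,
                       planted = default_planted_lesions(),
                       homolog_n = 4L,
                       homolog_sub_rate = 0.05,
                       homolog_gap_rate = 0.02) {
  stopifnot(length(snv_total) == length(lineages),
            length(dip_total) == length(lineages),
            all(snv_common <= snv_total), all(dip_common <= dip_total),
            all(planted$scaffold %in% names(scaffold_lengths)))
  n_planted <- nrow(planted)
  if (snv_common < n_planted) {
    stop("snv_common must cover the ", n_planted, " planted lesions")
  }
  structure(list(seed = as.integer(seed),
                 scaffold_lengths = scaffold_lengths, n_genes = n_genes,
                 lineages = lineages, snv_total = snv_total,
                 snv_common = snv_common, dip_total = dip_total,
                 dip_common = dip_common, planted = planted,
                 homolog_n = homolog_n,
                 homolog_sub_rate = homolog_sub_rate,
                 homolog_gap_rate = homolog_gap_rate),
            class = "sim_config")
}

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build one gene's sense sequence and structure. Returns list(region,
# cds, exon sense intervals, intron offsets/lengths).
build_gene_body <- function(n_codons, n_introns, donor_broken = FALSE) {
  codons <- sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE)
  cds <- paste0("ATG", paste(codons, collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  cds_len <- nchar(cds)
  repeat {
    offs <- sort(sample(seq(6L, cds_len - 6L), n_introns))
    if (all(diff(offs) >= 9L) || n_introns == 1L) {
      if (!donor_broken || (n_introns >= 2L && offs[2L] %% 3L == 2L)) break
      if (donor_broken && n_introns >= 2L) {
        # nudge the second intron onto the required frame offset
        offs[2L] <- offs[2L] - (offs[2L] %% 3L) + 2L
        if (offs[2L] > offs[1L] + 3L &&
            (n_introns < 3L || offs[2L] < offs[3L] - 3L) &&
            offs[2L] <= cds_len - 6L) break
      }
    }
  }
  ilen <- sample(20:60, n_introns, replace = TRUE)
  introns <- vapply(seq_len(n_introns), function(i) {
    body <- if (ilen[i] > 4L) random_dna(ilen[i] - 4L) else ""
    paste0("GT", body, "AG")
  }, character(1))
  if (donor_broken) {
    # reference allele of the second intron starts TTAAGT: a broken donor
    # whose retained sequence supplies an in-frame TAA stop
    introns[2L] <- paste0("TTAAGT", substr(introns[2L], 7L, ilen[2L]))
    if (ilen[2L] < 6L) introns[2L] <- paste0("TTAAGT",
                                             random_dna(20L - 6L), "AG")
  }
  # interleave: exon pieces between intron insertion offsets
  bounds <- c(0L, offs, cds_len)
  exon_pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  region <- exon_pieces[1L]
  exon_iv <- list(c(1L, nchar(exon_pieces[1L])))
  cursor <- nchar(exon_pieces[1L])
  for (i in seq_len(n_introns)) {
    cursor <- cursor + nchar(introns[i])
    a <- cursor + 1L
    region <- paste0(region, introns[i], exon_pieces[i + 1L])
    cursor <- cursor + nchar(exon_pieces[i + 1L])
    exon_iv[[length(exon_iv) + 1L]] <- c(a, cursor)
  }
  list(region = region, cds = cds, exon_iv = exon_iv, offs = offs)
}

# Overwrite a codon of a gene's spliced CDS in the genome, returning the
# updated genome (used to plant specific codons for lesion construction).
plant_codon <- function(genome, gene, codon_idx, codon) {
  for (k in 1:3) {
    cidx <- 3L * codon_idx - 3L + k
    gpos <- cds_to_genomic(gene, cidx)
    base <- substr(codon, k, k)
    if (gene$strand == "-") base <- chartr("ACGT", "TGCA", base)
    sc <- genome[[gene$scaffold]]
    substr(sc, gpos, gpos) <- base
    genome[[gene$scaffold]] <- sc
  }
  genome
}

#' Simulate a synthetic backcross universe
#'
#' Generates a reference genome with intron-containing gene models, two
#' (or more) inbred-lineage variant sets built from an explicit
#' common/private partition, per-gene homolog alignments, and a set of
#' planted lesions with known funnel fates — including one causal gene
#' whose reference allele carries a broken splice donor (sense `TTAAGT`)
#' that the shared inbred variant repairs to `GT`, mirroring the
#' intron-retention mechanism the funnel must recover.
#'
#' All randomness flows through R's global RNG seeded once from
#' `config$seed`; the same seed yields byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, writes `ref.fa`,
#'   `genes.gff3`, one `<lineage>.vcf` per lineage, `alignments/<gene>.fa`,
#'   `truth.tsv` and a `config.tsv` echo.
#' @return list with `genome`, `genes` (named list of `gene_model`),
#'   `sets` (named list of per-lineage `variant_set`s), `common`
#'   (constructed common pool), `alignments`, `truth` (data.frame
#'   `gene_id`, `kind`, `expected_fate`), `annotations`, and `config`.
#' @export
simulate_backcross <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed)
  lens <- config$scaffold_lengths
  genome <- vapply(lens, random_dna, character(1))
  names(genome) <- names(lens)

  # allocate genes to scaffolds by length (at least 2 each)
  alloc <- pmax(2L, as.integer(round(config$n_genes * lens / sum(lens))))
  names(alloc) <- names(lens)
  planted <- config$planted
  need <- table(planted$scaffold)
  alloc[names(need)] <- pmax(alloc[names(need)], as.integer(need) + 1L)

  genes <- list()
  gene_meta <- list()  # per gene: list(kind = NA or lesion row index)
  lesion_of_gene <- character(0)
  # assign planted lesions to the first genes of their scaffold
  assign_queue <- split(seq_len(nrow(planted)), planted$scaffold)

  gnum <- 0L
  for (sc in names(lens)) {
    cursor <- 400L
    queue <- assign_queue[[sc]]
    for (j in seq_len(alloc[[sc]])) {
      lesion_idx <- if (length(queue)) queue[1L] else NA_integer_
      if (length(queue)) queue <- queue[-1L]
      donor_broken <- !is.na(lesion_idx) &&
        planted$kind[lesion_idx] == "donor_site_restore"
      n_codons <- sample(60:160, 1L)
      n_introns <- if (donor_broken) 3L else sample(1:3, 1L)
      body <- build_gene_body(n_codons, n_introns, donor_broken)
      L <- nchar(body$region)
      start <- cursor + sample(200:600, 1L)
      if (start + L + 200L > lens[[sc]]) break
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "+") body$region else revcomp(body$region)
      scseq <- genome[[sc]]
      substr(scseq, start, start + L - 1L) <- placed
      genome[[sc]] <- scseq
      iv <- do.call(rbind, body$exon_iv)
      if (strand == "+") {
        starts <- start + iv[, 1L] - 1L; ends <- start + iv[, 2L] - 1L
      } else {
        starts <- start + L - iv[, 2L]; ends <- start + L - iv[, 1L]
      }
      gnum <- gnum + 1L
      gid <- sprintf("g%03d", gnum)
      genes[[gid]] <- gene_model(gid, sc, strand, starts, ends,
                                 protein_id = paste0(gid, ".t1"))
      lesion_of_gene[gid] <- if (is.na(lesion_idx)) "" else
        planted$kind[lesion_idx]
      cursor <- start + L
    }
  }

  # plant lesion codons and derive the planted (common) variants
  planted_rows <- list()
  truth <- list()
  planted_aa_pos <- stats::setNames(integer(0), character(0))
  comp <- function(b) chartr("ACGT", "TGCA", b)
  for (gid in names(lesion_of_gene)[lesion_of_gene != ""]) {
    kind <- lesion_of_gene[[gid]]
    g <- genes[[gid]]
    n_codons <- total_cds_length(g) %/% 3L
    if (kind == "donor_site_restore") {
      intr <- gene_introns(g)
      row <- which(intr$index == 2L)
      gpos <- if (g$strand == "+") intr$start[row] else intr$end[row]
      ref <- if (g$strand == "+") "T" else "A"
      alt <- if (g$strand == "+") "G" else "C"
      planted_rows[[gid]] <- data.frame(scaffold = g$scaffold, pos = gpos,
                                        ref = ref, alt = alt)
    } else {
      j <- sample(5:(n_codons - 4L), 1L)
      spec <- switch(kind,
        inbred_nonsense = list(codon = "TGG", k = 2L, to = "A"),
        conservative_missense = list(codon = "GCT", k = 2L, to = "T"),
        nonconservative_missense = list(codon = "TGG", k = 1L, to = "G"),
        nonconserved_missense = list(codon = "TGG", k = 1L, to = "G"),
        silent = list(codon = "CTT", k = 3L, to = "C"))
      genome <- plant_codon(genome, g, j, spec$codon)
      cidx <- 3L * j - 3L + spec$k
      gpos <- cds_to_genomic(g, cidx)
      ref <- substr(spec$codon, spec$k, spec$k)
      alt <- spec$to
      if (g$strand == "-") { ref <- comp(ref); alt <- comp(alt) }
      planted_rows[[gid]] <- data.frame(scaffold = g$scaffold, pos = gpos,
                                        ref = ref, alt = alt)
      planted_aa_pos[[gid]] <- j
    }
    truth[[gid]] <- data.frame(
      gene_id = gid, kind = kind,
      expected_fate = planted$expected_fate[match(kind, planted$kind)],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # position grid for background variants, away from planted sites
  spans <- lapply(genes, function(g)
    c(min(g$cds_segments$start) - 12L, max(g$cds_segments$end) + 12L))
  grid <- list()
  for (sc in names(lens)) {
    pos <- seq(15L, lens[[sc]] - 15L, by = 8L)
    in_gene <- rep(FALSE, length(pos))
    for (g in genes) {
      if (g$scaffold != sc) next
      s <- spans[[g$gene_id]]
      in_gene <- in_gene | (pos >= s[1L] & pos <= s[2L])
    }
    for (pr in planted_rows) {
      if (pr$scaffold != sc) next
      drop <- abs(pos - pr$pos) < 12L
      pos <- pos[!drop]; in_gene <- in_gene[!drop]
    }
    grid[[sc]] <- list(intergenic = pos[!in_gene], genic = pos[in_gene])
  }
  all_intergenic <- data.frame(
    scaffold = rep(names(grid), lengths(lapply(grid, `[[`, "intergenic"))),
    pos = unlist(lapply(grid, `[[`, "intergenic"), use.names = FALSE))
  all_any <- data.frame(
    scaffold = rep(names(grid), vapply(grid, function(x)
      length(x$intergenic) + length(x$genic), integer(1))),
    pos = unlist(lapply(grid, function(x) c(x$intergenic, x$genic)),
                 use.names = FALSE))

  # intron-interior positions (3 bp clear of the splice windows)
  intron_pos <- list()
  for (g in genes) {
    intr <- gene_introns(g)
    for (i in seq_len(nrow(intr))) {
      a <- intr$start[i] + 4L; b <- intr$end[i] - 4L
      if (b >= a) intron_pos[[length(intron_pos) + 1L]] <-
          data.frame(scaffold = g$scaffold, pos = a:b)
    }
  }
  intron_pos <- do.call(rbind, intron_pos)
  for (pr in planted_rows) {
    intron_pos <- intron_pos[!(intron_pos$scaffold == pr$scaffold &
                                 abs(intron_pos$pos - pr$pos) < 12L), ,
                             drop = FALSE]
  }

  take <- function(pool, n) {
    idx <- sample(nrow(pool), n)
    pool[idx, , drop = FALSE]
  }
  make_snvs <- function(sites) {
    ref <- substring(genome[sites$scaffold], sites$pos, sites$pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), character(1))
    data.frame(scaffold = sites$scaffold, pos = sites$pos, ref = ref,
               alt = unname(alt), stringsAsFactors = FALSE)
  }
  make_dips <- function(sites) {
    n <- nrow(sites)
    is_del <- sample(c(TRUE, FALSE), n, replace = TRUE)
    k <- sample(1:3, n, replace = TRUE)
    ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      anchor <- substring(genome[[sites$scaffold[i]]], sites$pos[i],
                          sites$pos[i])
      if (is_del[i]) {
        ref[i] <- substring(genome[[sites$scaffold[i]]], sites$pos[i],
                            sites$pos[i] + k[i])
        alt[i] <- anchor
      } else {
        ref[i] <- anchor
        alt[i] <- paste0(anchor, random_dna(k[i]))
      }
    }
    data.frame(scaffold = sites$scaffold, pos = sites$pos, ref = ref,
               alt = alt, stringsAsFactors = FALSE)
  }

  n_planted_snv <- length(planted_rows)
  n_bg_common_snv <- config$snv_common - n_planted_snv
  n_intronic <- min(round(0.15 * n_bg_common_snv),
                    if (is.null(intron_pos)) 0L else nrow(intron_pos))
  common_sites <- rbind(
    if (n_intronic > 0L) take(intron_pos, n_intronic)[, c("scaffold", "pos")],
    take(all_intergenic, n_bg_common_snv - n_intronic))
  used <- paste(common_sites$scaffold, common_sites$pos)
  common_snv <- rbind(do.call(rbind, unname(planted_rows)),
                      make_snvs(common_sites))
  pool <- all_intergenic[!paste(all_intergenic$scaffold,
                                all_intergenic$pos) %in% used, , drop = FALSE]
  dip_sites <- take(pool, config$dip_common)
  used <- c(used, paste(dip_sites$scaffold, dip_sites$pos))
  common_dip <- make_dips(dip_sites)

  private <- list()
  pool_any <- all_any[!paste(all_any$scaffold, all_any$pos) %in% used, ,
                      drop = FALSE]
  for (i in seq_along(config$lineages)) {
    ns <- config$snv_total[i] - config$snv_common
    nd <- config$dip_total[i] - config$dip_common
    sites <- take(pool_any, ns + nd)
    pool_any <- pool_any[!paste(pool_any$scaffold, pool_any$pos) %in%
                           paste(sites$scaffold, sites$pos), , drop = FALSE]
    private[[config$lineages[i]]] <- rbind(
      make_snvs(sites[seq_len(ns), , drop = FALSE]),
      make_dips(sites[ns + seq_len(nd), , drop = FALSE]))
  }

  common_df <- rbind(common_snv, common_dip)
  common <- variant_set(common_df$scaffold, common_df$pos, common_df$ref,
                        common_df$alt, lineage = "common", genome = genome)
  sets <- list()
  for (nm in config$lineages) {
    df <- rbind(common_df, private[[nm]])
    sets[[nm]] <- variant_set(df$scaffold, df$pos, df$ref, df$alt,
                              lineage = nm, genome = genome)
  }

  # homolog alignments: mutate the reference protein per column; planted
  # missense columns are forced conserved (or non-conserved)
  residues <- names(AA_AVG_MASS)
  alignments <- list()
  for (gid in names(genes)) {
    prot <- gene_protein(genes[[gid]], genome)
    chars <- strsplit(prot, "")[[1L]]
    forced <- unname(planted_aa_pos[gid])
    kind <- unname(lesion_of_gene[gid])
    rows <- stats::setNames(vector("list", config$homolog_n + 1L),
                            c("focal", paste0("homolog_",
                                              seq_len(config$homolog_n))))
    rows[["focal"]] <- prot
    for (h in seq_len(config$homolog_n)) {
      hc <- chars
      r <- stats::runif(length(hc))
      sub_i <- which(r < config$homolog_sub_rate)
      gap_i <- which(r >= config$homolog_sub_rate &
                       r < config$homolog_sub_rate + config$homolog_gap_rate)
      for (s in sub_i) hc[s] <- sample(setdiff(residues, chars[s]), 1L)
      hc[gap_i] <- "-"
      if (!is.na(forced) && length(forced) && forced > 0L) {
        if (identical(kind, "nonconserved_missense")) {
          hc[forced] <- sample(setdiff(residues, chars[forced]), 1L)
        } else {
          hc[forced] <- chars[forced]
        }
      }
      rows[[paste0("homolog_", h)]] <- paste(hc, collapse = "")
    }
    alignments[[gid]] <- homolog_alignment(gid, unlist(rows),
                                           focal = "focal")
  }

  annotations <- stats::setNames(
    ifelse(lesion_of_gene[names(genes)] == "", "background gene",
           paste0("planted:", lesion_of_gene[names(genes)])),
    names(genes))

  out <- list(genome = genome, genes = genes, sets = sets, common = common,
              alignments = alignments, truth = truth,
              annotations = annotations, config = config)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_genome(genome, file.path(outdir, "ref.fa"))
    write_gene_models(genes, file.path(outdir, "genes.gff3"))
    for (nm in config$lineages) {
      write_vcf(sets[[nm]], genome, file.path(outdir, paste0(nm, ".vcf")))
    }
    write_homolog_alignments(alignments, file.path(outdir, "alignments"))
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- data.frame(
      key = c("seed", "n_genes", "lineages", "snv_total", "snv_common",
              "dip_total", "dip_common"),
      value = c(config$seed, config$n_genes,
                paste(config$lineages, collapse = ","),
                paste(config$snv_total, collapse = ","), config$snv_common,
                paste(config$dip_total, collapse = ","), config$dip_common))
    utils::write.table(cfg, file.path(outdir, "config.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
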