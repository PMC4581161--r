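#' Integer percent share, rounded half away from zero
#'
#' The percent convention of the lineage-sharing summary tables: the share
#' of common variants in each lineage's total, as an integer percent with
#' halves rounded away from zero (the only convention that reproduces all
#' four headline shares 56/36 for SNVs and 53/31 for indels
#' simultaneously).
#'
#' @param common_count Number of shared variants.
#' @param lineage_total Lineage's total (must be positive).
#' @return Integer percent.
#' @export
percent_share <- function(common_count, lineage_total) {
  if (any(lineage_total <= 0)) stop("lineage_total must be positive")
  as.integer(floor(100 * common_count / lineage_total + 0.5))
}

# Region of each variant relative to the gene set: "coding" (footprint
# touches a CDS segment), "annotated" (within a gene span), or "outside".
variant_region <- function(vset, genes) {
  out <- rep("outside", nrow(vset))
  for (g in genes) {
    seg <- g$cds_segments
    span <- c(min(seg$start), max(seg$end))
    on_sc <- vset$scaffold == g$scaffold
    for (i in which(on_sc)) {
      fp <- variant_footprint(vset$pos[i], vset$ref[i], vset$alt[i])
      is_ins <- nchar(vset$ref[i]) == 1L && nchar(vset$alt[i]) > 1L
      if (is_ins) {
        if (vset$pos[i] >= span[2L] || vset$pos[i] + 1L <= span[1L]) next
      } else {
        if (max(fp) < span[1L] || min(fp) > span[2L]) next
      }
      hit_cds <- any(vapply(fp, function(p)
        any(p >= seg$start & p <= seg$end), logical(1)))
      if (hit_cds) out[i] <- "coding"
      else if (out[i] == "outside") out[i] <- "annotated"
    }
  }
  out
}

count_block <- function(vset, region) {
  c(snv_total = sum(vset$vclass == "SNV"),
    snv_annotated = sum(vset$vclass == "SNV" & region != "outside"),
    snv_coding = sum(vset$vclass == "SNV" & region == "coding"),
    dip_total = sum(vset$vclass == "DIP"),
    dip_annotated = sum(vset$vclass == "DIP" & region != "outside"),
    dip_coding = sum(vset$vclass == "DIP" & region == "coding"))
}

CODING_CLASSES <- c("synonymous", "missense_conservative",
                    "missense_nonconservative", "nonsense", "frameshift",
                    "inframe_indel", "splice_donor_disrupted",
                    "splice_acceptor_disrupted")
TRUNCATING_CLASSES <- c("nonsense", "frameshift")

#' Run the candidate-gene exclusion funnel
#'
#' The fixed gene-reduction procedure over the variants shared by all
#' backcross lineages:
#' \enumerate{
#'   \item restrict to variants with a coding consequence (codon-level
#'     effects plus splice-window disruptions, which act on the coding
#'     product through intron retention);
#'   \item drop synonymous (silent) effects;
#'   \item keep genes with at least one amino-acid-changing effect;
#'   \item exclude genes in which any common variant truncates the protein
#'     of the \emph{inbred} allele (premature stop, frameshift, or
#'     inbred-side splice disruption) — a gene already broken in the
#'     fertile inbred lines cannot explain the reference strain's
#'     phenotype. Splice or stop lesions in the \emph{reference}
#'     orientation (the inbred allele repairs a site broken in the
#'     reference genome) are reported separately and the gene is kept;
#'   \item drop conservative-exchange effects, then genes left with none;
#'   \item drop effects whose changed residue lies in a non-conserved
#'     homolog-alignment region, then genes left with none. Genes without
#'     an alignment pass through (fail-open).
#' }
#' The step order is fixed; per-step variant and gene counts are reported
#' so the reduction is auditable.
#'
#' @param common `variant_set` of variants shared by all lineages.
#' @param genes Named list of `gene_model` objects.
#' @param genome Genome vector.
#' @param policy A [substitution_policy()].
#' @param alignments Named list of `homolog_alignment` objects (by gene
#'   id), or `NULL` to skip the conservation step (all effects pass).
#' @param lineage_sets Optional named list of the per-lineage
#'   `variant_set`s; when given, the report carries per-lineage totals and
#'   integer percent shares of the common set.
#' @param min_column_identity Conservation-filter threshold.
#' @param annotations Optional named character vector of free-text gene
#'   annotations passed through to the candidate table.
#' @return Object of class `funnel_report`: list with `lineage_totals`,
#'   `percent_shares`, `common_counts`, `steps` (data.frame of per-step
#'   variant/gene counts), `survivors` (named list of gene-id vectors per
#'   step), `effects` (all classified effects), `surviving_effects`,
#'   `candidates` (data.frame), and `reference_lesions`.
#' @export
run_funnel <- function(common, genes, genome,
                       policy = substitution_policy(),
                       alignments = NULL, lineage_sets = NULL,
                       min_column_identity = 0.5, annotations = NULL) {
  effects <- classify_variants(common, genes, genome, policy)
  region <- variant_region(common, genes)
  common_counts <- count_block(common, region)

  lineage_totals <- NULL
  percent_shares <- NULL
  if (!is.null(lineage_sets)) {
    lineage_totals <- do.call(rbind, lapply(names(lineage_sets), function(nm) {
      vs <- lineage_sets[[nm]]
      data.frame(lineage = nm, t(count_block(vs, variant_region(vs, genes))))
    }))
    percent_shares <- do.call(rbind, lapply(names(lineage_sets), function(nm) {
      tot <- lineage_totals[lineage_totals$lineage == nm, -1L]
      metric <- names(common_counts)
      data.frame(lineage = nm, metric = metric,
                 common = as.integer(common_counts),
                 lineage_total = as.integer(tot[1L, metric]),
                 percent = ifelse(as.integer(tot[1L, metric]) > 0L,
                                  percent_share(as.integer(common_counts),
                                                as.integer(tot[1L, metric])),
                                  NA_integer_))
    }))
  }

  steps <- list(); survivors <- list()
  note <- function(name, eff) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, n_variants = length(unique(eff$key)),
      n_genes = length(unique(eff$gene_id)))
    survivors[[name]] <<- sort(unique(eff$gene_id))
  }

  e0 <- effects
  steps[[1L]] <- data.frame(step = "input",
                            n_variants = nrow(common),
                            n_genes = length(unique(e0$gene_id)))
  survivors[["input"]] <- sort(unique(e0$gene_id))

  e1 <- e0[e0$eclass %in% CODING_CLASSES, , drop = FALSE]
  note("coding_consequence", e1)

  e2 <- e1[e1$eclass != "synonymous", , drop = FALSE]
  note("non_silent", e2)

  e3 <- e2  # genes with >=1 amino-acid-changing effect
  note("aa_changing_genes", e3)

  inbred_trunc <- e3$eclass %in% TRUNCATING_CLASSES |
    (grepl("^splice_", e3$eclass) &
       e3$allele_disrupted %in% c("inbred", "both"))
  reference_lesions <- e3[grepl("^splice_", e3$eclass) &
                            e3$allele_disrupted == "reference", , drop = FALSE]
  excl4 <- unique(e3$gene_id[inbred_trunc])
  e4 <- e3[!e3$gene_id %in% excl4, , drop = FALSE]
  note("no_inbred_truncation", e4)

  e5 <- e4[e4$eclass != "missense_conservative", , drop = FALSE]
  note("non_conservative", e5)

  if (is.null(alignments)) {
    e6 <- e5
    message("no homolog alignments supplied; conservation step passes ",
            "all effects through")
  } else {
    keep <- vapply(seq_len(nrow(e5)), function(i) {
      eff <- e5[i, , drop = FALSE]
      if (eff$aa_pos <= 0L || eff$eclass != "missense_nonconservative") {
        return(TRUE)
      }
      aln <- alignments[[eff$gene_id]]
      if (is.null(aln)) {
        warning("no homolog alignment for gene ", eff$gene_id,
                "; conservation filter passes the effect through")
        return(TRUE)
      }
      conservation_filter(eff, aln, min_column_identity)
    }, logical(1))
    e6 <- e5[keep, , drop = FALSE]
  }
  note("conserved_region", e6)

  cand_ids <- sort(unique(e6$gene_id))
  candidates <- data.frame(
    gene_id = cand_ids,
    scaffold = vapply(cand_ids, function(g) genes[[g]]$scaffold, character(1)),
    annotation = if (is.null(annotations)) rep("", length(cand_ids)) else {
      a <- annotations[cand_ids]; a[is.na(a)] <- ""; unname(a)
    },
    n_effects = vapply(cand_ids, function(g) sum(e6$gene_id == g), integer(1)),
    effects = vapply(cand_ids, function(g) {
      ee <- e6[e6$gene_id == g, , drop = FALSE]
      paste(sprintf("%s|%s|%s", ee$key, ee$eclass, p_notation(ee)),
            collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$scaffold, candidates$gene_id,
                                 method = "radix"), , drop = FALSE]
  rownames(candidates) <- NULL

  structure(list(lineage_totals = lineage_totals,
                 percent_shares = percent_shares,
                 common_counts = common_counts,
                 steps = do.call(rbind, steps),
                 survivors = survivors,
                 effects = effects,
                 surviving_effects = e6,
                 candidates = candidates,
                 reference_lesions = reference_lesions),
            class = "funnel_report")
}

# p.RefPosAlt protein notation for effect rows (empty when no residue info)
p_notation <- function(eff) {
  ifelse(eff$aa_pos > 0L & eff$aa_ref != "",
         paste0("p.", eff$aa_ref, eff$aa_pos, eff$aa_alt),
         "")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$steps, row.names = FALSE)
  cat("candidates:", nrow(x$candidates), "gene(s)\n")
  invisible(x)
}

#' Scaffold-level positional bias of candidate genes
#'
#' Summarizes whether surviving candidates cluster on particular scaffolds
#' (as expected when they hitchhike with a selected locus such as a mating
#' type region): per scaffold, the observed candidate count, the count
#' expected under a length-proportional null, their fold ratio, and an
#' upper-tail probability. The tail is hypergeometric when a gene universe
#' is supplied (candidates drawn from genes), else binomial under the
#' length-proportional null. The statistic is descriptive — a screening
#' summary, not a calibrated test.
#'
#' @param candidates Candidate data.frame (needs a `scaffold` column).
#' @param genome Genome vector.
#' @param gene_universe Optional named list of `gene_model`s (all annotated
#'   genes); switches the tail to hypergeometric on gene counts.
#' @return data.frame with columns `scaffold`, `length`, `n_candidates`,
#'   `expected`, `fold`, `p`.
#' @export
scaffold_bias <- function(candidates, genome, gene_universe = NULL) {
  if (!nrow(candidates)) stop("no candidates supplied")
  lens <- genome_lengths(genome)
  obs <- table(factor(candidates$scaffold, levels = names(lens)))
  total <- nrow(candidates)
  expected <- total * lens / sum(lens)
  if (is.null(gene_universe)) {
    p <- stats::pbinom(as.integer(obs) - 1L, total, lens / sum(lens),
                       lower.tail = FALSE)
  } else {
    gsc <- vapply(gene_universe, `[[`, character(1), "scaffold")
    m <- as.integer(table(factor(gsc, levels = names(lens))))
    p <- stats::phyper(as.integer(obs) - 1L, m, length(gsc) - m, total,
                       lower.tail = FALSE)
    p[m == 0L & as.integer(obs) == 0L] <- 1
  }
  data.frame(scaffold = names(lens), length = as.integer(lens),
             n_candidates = as.integer(obs),
             expected = as.numeric(expected),
             fold = as.integer(obs) / as.numeric(expected),
             p = as.numeric(p), row.names = NULL)
}

#' Write the candidate table
#'
#' Deterministic TSV: fixed column order, rows sorted by (scaffold,
#' gene_id); [read_candidates()] round-trips it losslessly.
#'
#' @param candidates Candidate data.frame (as in a `funnel_report`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("gene_id", "scaffold", "annotation", "n_effects", "effects")
  df <- candidates[, cols, drop = FALSE]
  df <- df[order(df$scaffold, df$gene_id, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path TSV path.
#' @return Candidate data.frame.
#' @export
read_candidates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "integer", "character"),
                          na.strings = NULL, quote = "")
  df$annotation[is.na(df$annotation)] <- ""
  df$effects[is.na(df$effects)] <- ""
  df
}

#' Write a funnel report's tables
#'
#' Emits `funnel_steps.tsv` (step, n_variants, n_genes),
#' `candidates.tsv`, and, when lineage totals are present,
#' `lineage_totals.tsv` and `percent_shares.tsv`, all byte-stable.
#'
#' @param report A `funnel_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_funnel_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$steps, file.path(dir, "funnel_steps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates(report$candidates, file.path(dir, "candidates.tsv"))
  if (!is.null(report$lineage_totals)) {
    utils::write.table(report$lineage_totals,
                       file.path(dir, "lineage_totals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$percent_shares,
                       file.path(dir, "percent_shares.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
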