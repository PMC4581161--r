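#' Construct a gene model
#'
#' A gene model is the stranded CDS-segment structure of one
#' protein-coding transcript on one scaffold. Introns are derived as the
#' gaps between consecutive CDS segments. All coordinates are 1-based
#' inclusive genomic positions on the plus strand of the scaffold.
#'
#' @param gene_id Gene identifier.
#' @param scaffold Scaffold id the gene lives on.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of CDS segment starts/ends (1-based
#'   inclusive), sorted by genomic coordinate.
#' @param protein_id Optional protein/transcript identifier.
#' @param genome Optional genome vector; when supplied, segment bounds and
#'   coding-length divisibility by 3 are validated against it.
#' @return An object of class `gene_model`: a list with fields `gene_id`,
#'   `scaffold`, `strand`, `cds_segments` (data.frame `start`, `end`) and
#'   `protein_id`.
#' @export
gene_model <- function(gene_id, scaffold, strand, starts, ends,
                       protein_id = NA_character_, genome = NULL) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L,
            strand %in% c("+", "-"))
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (any(ends < starts)) stop("gene ", gene_id, ": segment end < start")
  if (length(starts) > 1L) {
    gap <- starts[-1L] - ends[-length(ends)] - 1L
    if (any(gap < 4L)) {
      stop("gene ", gene_id,
           ": CDS segments overlap or leave an intron shorter than 4 bp")
    }
  }
  gm <- structure(
    list(gene_id = gene_id, scaffold = scaffold, strand = strand,
         cds_segments = data.frame(start = starts, end = ends),
         protein_id = protein_id),
    class = "gene_model")
  if (!is.null(genome)) validate_gene_model(gm, genome)
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  n <- nrow(x$cds_segments)
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d CDS segment%s, %d bp coding\n",
              x$gene_id, x$scaffold, min(x$cds_segments$start),
              max(x$cds_segments$end), x$strand, n, if (n == 1L) "" else "s",
              sum(x$cds_segments$end - x$cds_segments$start + 1L)))
  invisible(x)
}

#' Validate a gene model against a genome
#'
#' Checks scaffold membership, segment bounds and divisibility of the
#' total coding length by 3; violations are errors naming the gene.
#'
#' @param gene A `gene_model`.
#' @param genome Genome vector.
#' @return The gene, invisibly.
#' @export
validate_gene_model <- function(gene, genome) {
  sc <- gene$scaffold
  if (!sc %in% names(genome)) {
    stop("gene ", gene$gene_id, ": scaffold ", sc, " not in genome")
  }
  if (max(gene$cds_segments$end) > nchar(genome[[sc]]) ||
      min(gene$cds_segments$start) < 1L) {
    stop("gene ", gene$gene_id, ": CDS outside scaffold ", sc)
  }
  len <- sum(gene$cds_segments$end - gene$cds_segments$start + 1L)
  if (len %% 3L != 0L) {
    stop("gene ", gene$gene_id, ": CDS length ", len, " not divisible by 3")
  }
  invisible(gene)
}

#' Derived introns of a gene model
#'
#' @param gene A `gene_model`.
#' @return data.frame with columns `start`, `end` (1-based inclusive genomic
#'   coordinates) and `index` (intron number in transcription order: for
#'   minus-strand genes the genomically last gap is intron 1).
#' @export
gene_introns <- function(gene) {
  seg <- gene$cds_segments
  n <- nrow(seg)
  if (n < 2L) {
    return(data.frame(start = integer(0), end = integer(0), index = integer(0)))
  }
  start <- seg$end[-n] + 1L
  end <- seg$start[-1L] - 1L
  index <- if (gene$strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
  data.frame(start = start, end = end, index = index)
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the CDS segments in genomic order and reverse-complements
#' for minus-strand genes, yielding the coding-sense DNA (ATG...stop).
#'
#' @param gene A `gene_model`.
#' @param genome Genome vector.
#' @return Single DNA string in coding orientation.
#' @export
cds_seq <- function(gene, genome) {
  seq <- genome[[gene$scaffold]]
  parts <- substring(seq, gene$cds_segments$start, gene$cds_segments$end)
  out <- paste(parts, collapse = "")
  if (gene$strand == "-") out <- revcomp(out) else out
}

#' Reference protein of a gene
#'
#' @inheritParams cds_seq
#' @return Amino-acid string (translation up to, excluding, the stop codon).
#' @export
gene_protein <- function(gene, genome) {
  translate_cds(cds_seq(gene, genome))
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features; one `gene_model` per gene is retained.
#' When a gene carries several mRNAs, the transcript with the longest total
#' CDS is kept (ties broken by transcript id) — the funnel operates at the
#' gene level and never at the isoform level.
#'
#' @param path GFF3 file.
#' @param genome Genome vector used to validate segment bounds and coding
#'   length (divisible by 3; violations are errors naming the gene).
#' @return Named list of `gene_model` objects (names = gene ids), sorted by
#'   scaffold then start.
#' @export
read_gene_models <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  # mRNA id -> parent gene id
  is_mrna <- type %in% c("mRNA", "transcript")
  mrna_ids <- as.character(md$ID[is_mrna])
  mrna_parent <- vapply(md$Parent[is_mrna], function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  names(mrna_parent) <- mrna_ids

  is_cds <- type == "CDS"
  if (!any(is_cds)) stop("no CDS features in ", path)
  cds <- gr[is_cds]
  cds_parent <- vapply(S4Vectors::mcols(cds)$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  if (anyNA(cds_parent)) stop("CDS feature without Parent in ", path)

  models <- list()
  for (tx in unique(cds_parent)) {
    sel <- cds[cds_parent == tx]
    gene_id <- if (tx %in% names(mrna_parent) && !is.na(mrna_parent[[tx]])) {
      mrna_parent[[tx]]
    } else tx
    sc <- as.character(GenomicRanges::seqnames(sel))
    if (length(unique(sc)) != 1L) {
      stop("gene ", gene_id, ": CDS segments on multiple scaffolds")
    }
    strand <- as.character(BiocGenerics::strand(sel))[1L]
    gm <- gene_model(gene_id, sc[1L], strand,
                     BiocGenerics::start(sel), BiocGenerics::end(sel),
                     protein_id = tx, genome = genome)
    prev <- models[[gene_id]]
    if (is.null(prev) || total_cds_length(gm) > total_cds_length(prev) ||
        (total_cds_length(gm) == total_cds_length(prev) &&
         gm$protein_id < prev$protein_id)) {
      models[[gene_id]] <- gm
    }
  }
  sc <- vapply(models, `[[`, character(1), "scaffold")
  st <- vapply(models, function(g) min(g$cds_segments$start), integer(1))
  models[order(sc, st, names(models), method = "radix")]
}

total_cds_length <- function(gene) {
  sum(gene$cds_segments$end - gene$cds_segments$start + 1L)
}

#' Write gene models to GFF3
#'
#' Deterministic, byte-stable emitter: one gene + mRNA + CDS block per
#' model, sorted by scaffold then start.
#'
#' @param genes Named list of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  sc <- vapply(genes, `[[`, character(1), "scaffold")
  st <- vapply(genes, function(g) min(g$cds_segments$start), integer(1))
  genes <- genes[order(sc, st, vapply(genes, `[[`, character(1), "gene_id"),
                       method = "radix")]
  lines <- "##gff-version 3"
  for (g in genes) {
    lo <- min(g$cds_segments$start); hi <- max(g$cds_segments$end)
    tx <- if (is.na(g$protein_id)) paste0(g$gene_id, ".t1") else g$protein_id
    lines <- c(
      lines,
      sprintf("%s\tvariantfunnel\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$scaffold, lo, hi, g$strand, g$gene_id),
      sprintf("%s\tvariantfunnel\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$scaffold, lo, hi, g$strand, tx, g$gene_id))
    seg <- g$cds_segments
    phase <- cds_phases(g)
    for (i in seq_len(nrow(seg))) {
      lines <- c(lines, sprintf(
        "%s\tvariantfunnel\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
        g$scaffold, seg$start[i], seg$end[i], g$strand, phase[i], tx, tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# GFF3 phase column per CDS segment, in genomic order.
cds_phases <- function(gene) {
  seg <- gene$cds_segments
  len <- seg$end - seg$start + 1L
  ord <- if (gene$strand == "+") seq_len(nrow(seg)) else rev(seq_len(nrow(seg)))
  ph <- integer(nrow(seg))
  acc <- 0L
  for (i in ord) {
    ph[i] <- (3L - acc %% 3L) %% 3L
    acc <- acc + len[i]
  }
  ph
}
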