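#' Substitution policy for conservative-exchange classification
#'
#' Wraps a 20x20 amino-acid substitution matrix and a score threshold: an
#' exchange is "conservative" when its matrix score is at or above the
#' threshold. The default (BLOSUM62, threshold 0) classifies the textbook
#' conservative exchanges A>V (score 0), I>L (2) and K>E (1) as
#' conservative and dissimilar pairs such as W>G (-2) as non-conservative.
#'
#' @param matrix Square integer substitution matrix with amino-acid
#'   dimnames; defaults to BLOSUM62 as shipped with Biostrings.
#' @param conservative_threshold Minimum score (inclusive) for an exchange
#'   to count as conservative.
#' @return Object of class `substitution_policy`.
#' @export
substitution_policy <- function(matrix = NULL, conservative_threshold = 0L) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)))
  structure(list(matrix = matrix,
                 conservative_threshold = conservative_threshold),
            class = "substitution_policy")
}

#' Is an amino-acid exchange conservative?
#'
#' @param aa_ref,aa_alt Single-letter codes of the reference and replacing
#'   residue (standard 20 amino acids only).
#' @param policy A [substitution_policy()].
#' @return `TRUE` iff `matrix[aa_ref, aa_alt] >= conservative_threshold`.
#' @export
is_conservative <- function(aa_ref, aa_alt, policy = substitution_policy()) {
  std <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  if (!(aa_ref %in% std) || !(aa_alt %in% std)) {
    stop("is_conservative() is defined for the 20 standard amino acids; got ",
         aa_ref, " -> ", aa_alt)
  }
  policy$matrix[aa_ref, aa_alt] >= policy$conservative_threshold
}

# Apply a set of non-overlapping variants (columns pos/ref/alt, 1-based) to
# a scaffold string. Returns the mutated string plus a coordinate-shift
# function mapping original positions into the mutated sequence (positions
# falling inside a replaced region are clamped into the replacement).
apply_scaffold_variants <- function(seq, vars) {
  if (is.null(vars) || !nrow(vars)) {
    return(list(seq = seq, shift = function(p, side = "end") as.integer(p)))
  }
  vars <- vars[order(vars$pos), , drop = FALSE]
  vars$pos <- as.integer(vars$pos)
  end_ref <- vars$pos + nchar(vars$ref) - 1L
  if (any(vars$pos[-1L] <= end_ref[-nrow(vars)])) {
    stop("overlapping variants cannot be applied to one sequence")
  }
  for (i in rev(seq_len(nrow(vars)))) {
    p <- vars$pos[i]
    if (substr(seq, p, end_ref[i]) != vars$ref[i]) {
      stop("ref mismatch applying variant at position ", p)
    }
    seq <- paste0(substr(seq, 1L, p - 1L), vars$alt[i],
                  substr(seq, end_ref[i] + 1L, nchar(seq)))
  }
  delta <- nchar(vars$alt) - nchar(vars$ref)
  # side matters only for positions erased by a replacement: an interval
  # start maps to the first surviving base after it, an interval end to the
  # replacement's last base (so a clipped exon boundary stays clipped)
  shift <- function(p, side = "end") {
    vapply(as.integer(p), function(pp) {
      inside <- which(vars$pos < pp & end_ref >= pp)
      if (length(inside)) {
        j <- inside[1L]
        base <- vars$pos[j] + sum(delta[end_ref < vars$pos[j]])
        al <- nchar(vars$alt[j])
        off <- if (side == "start") min(pp - vars$pos[j], al) else
          min(pp - vars$pos[j], al - 1L)
        return(as.integer(base + off))
      }
      as.integer(pp + sum(delta[end_ref < pp]))
    }, integer(1))
  }
  list(seq = seq, shift = shift)
}

# Affected reference positions of one variant (anchor excluded for indels;
# both flanks for pure insertions).
variant_footprint <- function(pos, ref, alt) {
  rl <- nchar(ref); al <- nchar(alt)
  if (rl == al) return(pos:(pos + rl - 1L))
  if (rl > 1L) return((pos + 1L):(pos + rl - 1L))
  c(pos, pos + 1L)
}

#' Splice-site dinucleotide of an intron, in transcription sense
#'
#' Returns the donor (first two) or acceptor (last two) bases of an intron
#' read on the coding strand, so canonical sites read `GT` and `AG`
#' regardless of the gene's genomic strand.
#'
#' @param seq Scaffold sequence (plus strand).
#' @param intron_start,intron_end 1-based genomic bounds of the intron.
#' @param strand `"+"` or `"-"` (the gene's strand).
#' @param site `"donor"` or `"acceptor"`.
#' @return Two-letter string.
#' @export
sense_dinuc <- function(seq, intron_start, intron_end, strand, site) {
  if (site == "donor") {
    if (strand == "+") substr(seq, intron_start, intron_start + 1L)
    else revcomp(substr(seq, intron_end - 1L, intron_end))
  } else {
    if (strand == "+") substr(seq, intron_end - 1L, intron_end)
    else revcomp(substr(seq, intron_start, intron_start + 1L))
  }
}

effect_row <- function(gene_id, v, eclass, aa_ref = "", aa_pos = 0L,
                       aa_alt = "", truncated_length = 0L,
                       allele_disrupted = "", intron_index = 0L) {
  data.frame(gene_id = gene_id, key = paste(v$scaffold, v$pos, v$ref, v$alt,
                                            sep = ":"),
             scaffold = v$scaffold, pos = as.integer(v$pos), ref = v$ref,
             alt = v$alt,
             vclass = if (nchar(v$ref) == nchar(v$alt)) "SNV" else "DIP",
             eclass = eclass, aa_ref = aa_ref, aa_pos = as.integer(aa_pos),
             aa_alt = aa_alt, truncated_length = as.integer(truncated_length),
             allele_disrupted = allele_disrupted,
             intron_index = as.integer(intron_index),
             stringsAsFactors = FALSE)
}

#' Classify the consequence of one variant on one gene
#'
#' Deterministic codon-level consequence prediction with fixed priority:
#' splice-window disruption (the first/last two intron bases, the invariant
#' GT/AG positions) outranks any coding interpretation; coding consequences
#' are computed by applying the variant to the scaffold, re-extracting the
#' spliced coding sequence, and re-translating (never by heuristics); then
#' intronic; then intergenic. Minus-strand genes are handled by operating on
#' the coding-strand sequence.
#'
#' For splice-window hits the disrupted allele is identified by comparing
#' the GT/AG dinucleotide under the reference and the alternate allele:
#' `allele_disrupted` is `"inbred"` when the alternate (inbred-lineage)
#' allele breaks a canonical site, `"reference"` when the variant restores
#' a site that is broken in the reference genome (the orientation in which
#' a reference-strain splice lesion is rescued by the inbred allele),
#' `"both"` or `"neither"` otherwise. Splice disruption is modeled as
#' retention of the affected intron; `truncated_length` is the residue
#' count of the retained-intron translation when it terminates before the
#' reference protein's end.
#'
#' @param variant One-row `variant_set` (or list with `scaffold`, `pos`,
#'   `ref`, `alt`).
#' @param gene A `gene_model`.
#' @param genome Genome vector.
#' @param policy A [substitution_policy()].
#' @return One-row data.frame with columns `gene_id`, `key`, `scaffold`,
#'   `pos`, `ref`, `alt`, `vclass`, `eclass`, `aa_ref`, `aa_pos`, `aa_alt`,
#'   `truncated_length`, `allele_disrupted`, `intron_index`.
#' @export
classify <- function(variant, gene, genome, policy = substitution_policy()) {
  v <- as.list(variant[c("scaffold", "pos", "ref", "alt")])
  v$pos <- as.integer(v$pos)
  rl <- nchar(v$ref); al <- nchar(v$alt)
  is_ins <- rl == 1L && al > 1L
  if (!identical(v$scaffold, gene$scaffold)) {
    return(effect_row(gene$gene_id, v, "intergenic"))
  }
  seq <- genome[[gene$scaffold]]
  seg <- gene$cds_segments
  span <- c(min(seg$start), max(seg$end))
  fp <- variant_footprint(v$pos, v$ref, v$alt)
  if (is_ins && (v$pos >= span[2L] || v$pos + 1L <= span[1L])) {
    return(effect_row(gene$gene_id, v, "intergenic"))
  }
  if (!is_ins && (max(fp) < span[1L] || min(fp) > span[2L])) {
    return(effect_row(gene$gene_id, v, "intergenic"))
  }

  # splice windows: first two and last two bases of each intron
  intr <- gene_introns(gene)
  for (i in seq_len(nrow(intr))) {
    is_ <- intr$start[i]; ie <- intr$end[i]
    don <- if (gene$strand == "+") c(is_, is_ + 1L) else c(ie - 1L, ie)
    acc <- if (gene$strand == "+") c(ie - 1L, ie) else c(is_, is_ + 1L)
    hit_site <- NULL
    if (is_ins) {
      # insertion point between pos and pos+1 disrupts a site when it falls
      # on the intron-side junction or between the two invariant bases
      don_pts <- if (gene$strand == "+") c(is_ - 1L, is_) else c(ie - 1L, ie)
      acc_pts <- if (gene$strand == "+") c(ie - 1L, ie) else c(is_ - 1L, is_)
      if (v$pos %in% don_pts) hit_site <- "donor"
      else if (v$pos %in% acc_pts) hit_site <- "acceptor"
    } else {
      if (any(fp %in% don)) hit_site <- "donor"
      else if (any(fp %in% acc)) hit_site <- "acceptor"
    }
    if (!is.null(hit_site)) {
      vdf <- data.frame(pos = v$pos, ref = v$ref, alt = v$alt,
                        stringsAsFactors = FALSE)
      app <- apply_scaffold_variants(seq, vdf)
      canonical <- if (hit_site == "donor") "GT" else "AG"
      dn_ref <- sense_dinuc(seq, is_, ie, gene$strand, hit_site)
      dn_alt <- sense_dinuc(app$seq, app$shift(is_, "start"),
                            app$shift(ie, "end"), gene$strand, hit_site)
      ref_ok <- dn_ref == canonical; alt_ok <- dn_alt == canonical
      disrupted <- if (ref_ok && !alt_ok) "inbred"
        else if (!ref_ok && alt_ok) "reference"
        else if (!ref_ok && !alt_ok) "both" else "neither"
      trunc <- 0L
      if (disrupted != "neither") {
        ret_vars <- if (disrupted %in% c("inbred", "both")) vdf else NULL
        ret <- retained_intron_protein(gene, genome, intr$index[i],
                                       variants = ret_vars)
        if (ret$truncated) trunc <- nchar(ret$protein)
      }
      eclass <- paste0("splice_", hit_site, "_disrupted")
      return(effect_row(gene$gene_id, v, eclass,
                        truncated_length = trunc,
                        allele_disrupted = disrupted,
                        intron_index = intr$index[i]))
    }
  }

  in_cds <- function(p) any(p >= seg$start & p <= seg$end)
  fp_in_cds <- vapply(fp, in_cds, logical(1))
  if (is_ins) {
    seg_of <- function(p) which(p >= seg$start & p <= seg$end)[1L]
    s1 <- seg_of(v$pos); s2 <- seg_of(v$pos + 1L)
    if (!is.na(s1) && !is.na(s2) && s1 == s2) {
      return(classify_coding(v, gene, genome, policy, seq))
    }
    # insertion point inside one intron (windows already excluded)
    return(effect_row(gene$gene_id, v, "intronic"))
  }
  if (any(fp_in_cds)) {
    return(classify_coding(v, gene, genome, policy, seq))
  }
  effect_row(gene$gene_id, v, "intronic")
}

# Coding-path classification by full re-extraction and re-translation.
classify_coding <- function(v, gene, genome, policy, seq) {
  seg <- gene$cds_segments
  vdf <- data.frame(pos = v$pos, ref = v$ref, alt = v$alt,
                    stringsAsFactors = FALSE)
  app <- apply_scaffold_variants(seq, vdf)
  mut_starts <- app$shift(seg$start, "start")
  mut_ends <- app$shift(seg$end, "end")
  mut_plus <- paste(substring(app$seq, mut_starts, mut_ends), collapse = "")
  ref_plus <- paste(substring(seq, seg$start, seg$end), collapse = "")
  mut_cds <- if (gene$strand == "-") revcomp(mut_plus) else mut_plus
  ref_cds <- if (gene$strand == "-") revcomp(ref_plus) else ref_plus
  ref_tr <- translate_full(ref_cds)
  mut_tr <- translate_full(mut_cds)
  rl <- nchar(v$ref); al <- nchar(v$alt)

  if (rl != al) {
    shift_codons <- first_diff(ref_tr$protein, mut_tr$protein)
    aa_pos <- if (is.na(shift_codons)) 0L else shift_codons
    if ((al - rl) %% 3L != 0L) {
      trunc <- if (mut_tr$stopped &&
                   nchar(mut_tr$protein) < nchar(ref_tr$protein)) {
        nchar(mut_tr$protein)
      } else 0L
      return(effect_row(gene$gene_id, v, "frameshift", aa_pos = aa_pos,
                        truncated_length = trunc))
    }
    if (mut_tr$stopped && nchar(mut_tr$protein) < nchar(ref_tr$protein)) {
      return(effect_row(gene$gene_id, v, "nonsense", aa_pos = aa_pos,
                        truncated_length = nchar(mut_tr$protein)))
    }
    return(effect_row(gene$gene_id, v, "inframe_indel", aa_pos = aa_pos))
  }

  # SNV: locate the affected codon on the coding strand
  cidx <- genomic_to_cds(gene, v$pos)
  codon <- (cidx - 1L) %/% 3L + 1L
  ref_codon <- substr(ref_cds, 3L * codon - 2L, 3L * codon)
  alt_codon <- substr(mut_cds, 3L * codon - 2L, 3L * codon)
  aa_r <- translate_codon(ref_codon)
  aa_a <- translate_codon(alt_codon)
  if (aa_r == aa_a) {
    return(effect_row(gene$gene_id, v, "synonymous", aa_ref = aa_r,
                      aa_pos = codon, aa_alt = aa_a))
  }
  if (aa_a == "*") {
    return(effect_row(gene$gene_id, v, "nonsense", aa_ref = aa_r,
                      aa_pos = codon, aa_alt = aa_a,
                      truncated_length = codon - 1L))
  }
  eclass <- if (aa_r %in% c("*", "X") || aa_a == "X") {
    "missense_nonconservative"
  } else if (is_conservative(aa_r, aa_a, policy)) {
    "missense_conservative"
  } else {
    "missense_nonconservative"
  }
  effect_row(gene$gene_id, v, eclass, aa_ref = aa_r, aa_pos = codon,
             aa_alt = aa_a)
}

first_diff <- function(a, b) {
  n <- max(nchar(a), nchar(b))
  if (n == 0L) return(NA_integer_)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  length(av) <- n; length(bv) <- n
  d <- which(is.na(av) | is.na(bv) | av != bv)
  if (length(d)) d[1L] else NA_integer_
}

# 1-based coding-sequence index of a genomic position inside the CDS.
genomic_to_cds <- function(gene, pos) {
  seg <- gene$cds_segments
  lens <- seg$end - seg$start + 1L
  k <- which(pos >= seg$start & pos <= seg$end)
  if (!length(k)) stop("position ", pos, " is not inside the CDS of ",
                       gene$gene_id)
  plus_off <- sum(lens[seq_len(k - 1L)]) + (pos - seg$start[k] + 1L)
  if (gene$strand == "+") plus_off else sum(lens) - plus_off + 1L
}

# Genomic position of a 1-based coding-sequence index.
cds_to_genomic <- function(gene, cidx) {
  seg <- gene$cds_segments
  lens <- seg$end - seg$start + 1L
  total <- sum(lens)
  stopifnot(cidx >= 1L, cidx <= total)
  plus_off <- if (gene$strand == "+") cidx else total - cidx + 1L
  cum <- cumsum(lens)
  k <- which(plus_off <= cum)[1L]
  before <- if (k > 1L) cum[k - 1L] else 0L
  seg$start[k] + (plus_off - before) - 1L
}

#' Translate a gene with one intron retained
#'
#' Builds the transcript in which the given intron (1-based, transcription
#' order) is left unspliced while all other introns are removed, applies
#' the supplied variants to the genome first, and translates from the start
#' codon to the first stop. This is the mechanistic model for a disrupted
#' donor or acceptor site: the affected intron stays in the mature
#' transcript, and any in-frame stop inside it truncates the protein.
#'
#' @param gene A `gene_model`.
#' @param genome Genome vector.
#' @param intron_index Intron to retain, 1-based in transcription order;
#'   `0` retains none (reference transcript).
#' @param variants Optional data.frame with `pos`, `ref`, `alt` columns of
#'   variants to apply before extraction (e.g. the splice-site variant
#'   itself), or `NULL`.
#' @return list with `protein` (residues up to the first stop) and
#'   `truncated` (`TRUE` iff translation stopped before the reference
#'   protein's end).
#' @export
retained_intron_protein <- function(gene, genome, intron_index,
                                    variants = NULL) {
  seq <- genome[[gene$scaffold]]
  intr <- gene_introns(gene)
  intron_index <- as.integer(intron_index)
  if (intron_index < 0L || intron_index > nrow(intr)) {
    stop("intron_index ", intron_index, " out of range for gene ",
         gene$gene_id, " (", nrow(intr), " introns)")
  }
  app <- apply_scaffold_variants(seq, variants)
  seg <- gene$cds_segments
  pieces <- data.frame(start = seg$start, end = seg$end)
  if (intron_index > 0L) {
    g <- which(intr$index == intron_index)
    pieces <- rbind(pieces,
                    data.frame(start = intr$start[g], end = intr$end[g]))
    pieces <- pieces[order(pieces$start), , drop = FALSE]
  }
  plus <- paste(substring(app$seq, app$shift(pieces$start, "start"),
                          app$shift(pieces$end, "end")), collapse = "")
  transcript <- if (gene$strand == "-") revcomp(plus) else plus
  tr <- translate_full(transcript)
  ref_len <- nchar(gene_protein(gene, genome))
  list(protein = tr$protein,
       truncated = tr$stopped && nchar(tr$protein) < ref_len)
}

#' Classify all variants of a set against all genes
#'
#' Runs [classify()] for every (variant, gene) pair whose footprints
#' overlap (one Effect per gene for variants hitting several genes) and
#' binds the per-pair effects into one table. Variants overlapping no gene
#' produce no rows; they are intergenic by definition.
#'
#' @param vset A `variant_set`.
#' @param genes Named list of `gene_model` objects.
#' @param genome Genome vector.
#' @param policy A [substitution_policy()].
#' @return data.frame of effects (see [classify()] for columns), ordered by
#'   (scaffold, pos, gene_id).
#' @export
classify_variants <- function(vset, genes, genome,
                              policy = substitution_policy()) {
  rows <- list()
  for (g in genes) {
    span <- c(min(g$cds_segments$start), max(g$cds_segments$end))
    sel <- vset$scaffold == g$scaffold &
      vset$pos + nchar(vset$ref) - 1L >= span[1L] - 1L &
      vset$pos <= span[2L] + 1L
    for (i in which(sel)) {
      eff <- classify(vset[i, , drop = FALSE], g, genome, policy)
      if (eff$eclass != "intergenic") rows[[length(rows) + 1L]] <- eff
    }
  }
  if (!length(rows)) {
    return(effect_row("g", list(scaffold = "s", pos = 1L, ref = "A",
                                alt = "C"), "intergenic")[0L, ])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$pos, out$gene_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conservation filter over a homolog alignment column
#'
#' Maps a protein position of the focal (reference) protein to its
#' alignment column and asks whether the homologs support conservation
#' there: the fraction of non-gap homolog rows carrying the focal residue
#' must reach `min_column_identity`. A missing alignment passes the effect
#' through with a warning (fail-open): genes are excluded only on positive
#' evidence that the changed residue lies in a non-conserved region.
#'
#' @param effect One-row effect data.frame (needs `aa_pos > 0`).
#' @param alignment A `homolog_alignment` (see [homolog_alignment()]) or
#'   `NULL`.
#' @param min_column_identity Minimum fraction of non-gap homolog rows
#'   matching the focal residue.
#' @return `TRUE` if the position lies in a conserved region (effect kept).
#' @export
conservation_filter <- function(effect, alignment,
                                min_column_identity = 0.5) {
  if (is.null(alignment)) {
    warning("no homolog alignment for gene ", effect$gene_id,
            "; conservation filter passes the effect through")
    return(TRUE)
  }
  aa_pos <- as.integer(effect$aa_pos)
  if (aa_pos <= 0L) stop("conservation_filter needs an effect with aa_pos > 0")
  focal <- alignment$rows[[alignment$focal]]
  fchars <- strsplit(focal, "")[[1L]]
  ungapped <- which(fchars != "-")
  if (aa_pos > length(ungapped)) {
    stop("aa_pos ", aa_pos, " beyond focal protein length ",
         length(ungapped), " for gene ", effect$gene_id)
  }
  col <- ungapped[aa_pos]
  res <- fchars[col]
  others <- alignment$rows[setdiff(names(alignment$rows), alignment$focal)]
  col_chars <- vapply(others, function(r) substr(r, col, col), character(1))
  col_chars <- col_chars[col_chars != "-"]
  if (!length(col_chars)) return(TRUE)
  mean(col_chars == res) >= min_column_identity
}

#' Construct a homolog alignment
#'
#' @param gene_id Gene the alignment belongs to.
#' @param rows Named character vector of equal-length aligned amino-acid
#'   strings (gap `-`); the focal row must be ungapped-identical to the
#'   gene's reference protein.
#' @param focal Name of the focal (reference species) row; defaults to the
#'   first row.
#' @return Object of class `homolog_alignment`.
#' @export
homolog_alignment <- function(gene_id, rows, focal = names(rows)[1L]) {
  stopifnot(length(rows) >= 1L, !is.null(names(rows)),
            focal %in% names(rows))
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows for ", gene_id, " differ in length")
  }
  structure(list(gene_id = gene_id, rows = as.list(rows), focal = focal),
            class = "homolog_alignment")
}

#' Read per-gene homolog alignments from a directory
#'
#' Each file `<gene_id>.fa` (or `.fasta`/`.afa`) holds one aligned protein
#' FASTA; the first record is the focal (reference) protein.
#'
#' @param dir Directory of aligned FASTA files.
#' @return Named list of `homolog_alignment` objects keyed by gene id.
#' @export
read_homolog_alignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|afa)$", full.names = TRUE)
  out <- list()
  for (f in files) {
    gene_id <- sub("\\.(fa|fasta|afa)$", "", basename(f))
    set <- Biostrings::readAAStringSet(f)
    rows <- stats::setNames(toupper(as.character(set)),
                            vapply(strsplit(names(set), "\\s+"), `[`,
                                   character(1), 1L))
    out[[gene_id]] <- homolog_alignment(gene_id, rows)
  }
  out
}

#' Write homolog alignments to a directory
#'
#' @param alignments Named list of `homolog_alignment` objects.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_homolog_alignments <- function(alignments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (aln in alignments) {
    path <- file.path(dir, paste0(aln$gene_id, ".fa"))
    nm <- c(aln$focal, setdiff(names(aln$rows), aln$focal))
    lines <- unlist(lapply(nm, function(n) c(paste0(">", n), aln$rows[[n]])))
    writeLines(lines, path)
  }
  invisible(dir)
}
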