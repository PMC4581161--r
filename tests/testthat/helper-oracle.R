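# Independent brute-force oracle: applies a variant to the whole scaffold,
# shifts annotation boundaries, re-extracts and splices the transcript,
# translates with seqinr, and classifies from the protein diff. Shares no
# code with the package's classifier.

blosum_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  if (n == 0) return(list(protein = "", stopped = FALSE))
  aa <- seqinr::translate(strsplit(substr(dna, 1, 3 * n), "")[[1]])
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(protein = paste(aa[seq_len(stop_at[1] - 1)], collapse = ""),
         stopped = TRUE)
  } else {
    list(protein = paste(aa, collapse = ""), stopped = FALSE)
  }
}

oracle_splice_translate <- function(seq, starts, ends, strand) {
  tx <- paste(substring(seq, starts, ends), collapse = "")
  if (strand == "-") tx <- oracle_revcomp(tx)
  oracle_translate(tx)
}

# Returns list(eclass, truncated_length); eclass is one of the package's
# class labels, or "splice" when the variant hits a +/-2 intron window
# (site/orientation checked by the dedicated splice tests).
oracle_classify <- function(scaffold, pos, ref, alt, gene, genome,
                            blosum, threshold = 0) {
  seg <- gene$cds_segments
  seq <- genome[[scaffold]]
  rl <- nchar(ref); al <- nchar(alt)
  lo <- min(seg$start); hi <- max(seg$end)
  affected <- if (rl == al) pos:(pos + rl - 1) else
    if (rl > 1) (pos + 1):(pos + rl - 1) else c(pos, pos + 1)

  # splice windows: first and last two bases of every inter-segment gap
  if (nrow(seg) > 1) {
    for (i in seq_len(nrow(seg) - 1)) {
      gap <- c(seg$end[i] + 1, seg$start[i + 1] - 1)
      win <- c(gap[1], gap[1] + 1, gap[2] - 1, gap[2])
      if (rl == 1 && al > 1) {
        pts <- c(gap[1] - 1, gap[1], gap[2] - 1, gap[2])
        if (pos %in% pts) return(list(eclass = "splice",
                                      truncated_length = NA))
      } else if (any(affected %in% win)) {
        return(list(eclass = "splice", truncated_length = NA))
      }
    }
  }

  in_cds <- any(vapply(affected, function(p)
    any(p >= seg$start & p <= seg$end), logical(1)))
  if (rl == 1 && al > 1) {
    s1 <- which(pos >= seg$start & pos <= seg$end)
    s2 <- which(pos + 1 >= seg$start & pos + 1 <= seg$end)
    if (!(length(s1) && length(s2) && s1[1] == s2[1])) in_cds <- FALSE
  }
  if (!in_cds) {
    if (rl == 1 && al > 1) {
      if (pos >= hi || pos + 1 <= lo) return(list(eclass = "intergenic",
                                                  truncated_length = 0))
    } else if (max(affected) < lo || min(affected) > hi) {
      return(list(eclass = "intergenic", truncated_length = 0))
    }
    return(list(eclass = "intronic", truncated_length = 0))
  }

  mut <- paste0(substr(seq, 1, pos - 1), alt,
                substr(seq, pos + rl, nchar(seq)))
  d <- al - rl
  # positions erased by the replacement: an exon start resumes at the first
  # surviving base, an exon end stops at the replacement's last base
  adj_start <- function(b) ifelse(b > pos + rl - 1, b + d,
                                  ifelse(b > pos, pmin(b - pos, al) + pos, b))
  adj_end <- function(b) ifelse(b > pos + rl - 1, b + d,
                                ifelse(b > pos, pmin(b - pos, al - 1) + pos,
                                       b))
  p_ref <- oracle_splice_translate(seq, seg$start, seg$end, gene$strand)
  p_mut <- oracle_splice_translate(mut, adj_start(seg$start),
                                   adj_end(seg$end), gene$strand)
  nref <- nchar(p_ref$protein); nmut <- nchar(p_mut$protein)

  if (rl != al) {
    if (d %% 3 != 0) {
      tl <- if (p_mut$stopped && nmut < nref) nmut else 0
      return(list(eclass = "frameshift", truncated_length = tl))
    }
    if (p_mut$stopped && nmut < nref) {
      return(list(eclass = "nonsense", truncated_length = nmut))
    }
    return(list(eclass = "inframe_indel", truncated_length = 0))
  }

  if (p_ref$protein == p_mut$protein) {
    return(list(eclass = "synonymous", truncated_length = 0))
  }
  if (p_mut$stopped && nmut < nref) {
    return(list(eclass = "nonsense", truncated_length = nmut))
  }
  # substituted residue = first difference
  i <- 1
  while (substr(p_ref$protein, i, i) == substr(p_mut$protein, i, i)) i <- i + 1
  a <- substr(p_ref$protein, i, i); b <- substr(p_mut$protein, i, i)
  if (a == "" || b == "" || nmut > nref) {
    return(list(eclass = "missense_nonconservative", truncated_length = 0))
  }
  cls <- if (blosum[a, b] >= threshold) "missense_conservative" else
    "missense_nonconservative"
  list(eclass = cls, truncated_length = 0)
}
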