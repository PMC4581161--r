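#' Construct a variant table
#'
#' The package represents a variant set as a data.frame with one row per
#' atomic variant: columns `scaffold`, `pos` (1-based position of the first
#' reference base; for indels the retained anchor base), `ref`, `alt`,
#' `vclass` (`"SNV"` or `"DIP"`), `lineage`, and a derived `key`
#' (`scaffold:pos:ref:alt`). SNV means a single-base substitution; DIP
#' (deletion/insertion polymorphism) is the short-indel class.
#'
#' @param scaffold,pos,ref,alt Parallel vectors describing the variants.
#' @param lineage Single lineage label applied to all rows.
#' @param genome Optional genome; when given, `ref` is checked against the
#'   reference sequence and indels are left-normalized against it.
#' @return A `variant_set` data.frame sorted by (scaffold, pos, ref, alt),
#'   duplicate keys collapsed.
#' @export
variant_set <- function(scaffold = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        lineage = "unknown", genome = NULL) {
  df <- data.frame(scaffold = as.character(scaffold), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(grepl("N", df$ref, fixed = TRUE))) {
      stop("variants with N in the reference allele are not supported")
    }
    if (!is.null(genome)) {
      norm <- normalize_variants(df, genome)
      df <- norm
    }
    if (any(df$ref == df$alt)) stop("ref == alt is not a variant")
  }
  df$vclass <- ifelse(nchar(df$ref) == nchar(df$alt), "SNV", "DIP")
  if (any(df$vclass == "SNV" & nchar(df$ref) != 1L)) {
    stop("multi-base substitutions must be decomposed into SNVs first")
  }
  df$lineage <- if (nrow(df)) lineage else character(0)
  df$key <- variant_key(df)
  df <- df[!duplicated(df$key), , drop = FALSE]
  df <- df[order(df$scaffold, df$pos, df$ref, df$alt, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_set", "data.frame")
  df
}

variant_key <- function(df) {
  if (!nrow(df)) return(character(0))
  paste(df$scaffold, df$pos, df$ref, df$alt, sep = ":")
}

#' Left-normalize a single indel or substitution
#'
#' Implements the canonical VCF normalization: shared trailing and leading
#' bases are trimmed, then the representation is shifted to its leftmost
#' equivalent placement, keeping one anchor base for indels. Normalization
#' is idempotent, so equivalent placements of the same homopolymer indel
#' collapse onto one key and cross-lineage intersection becomes
#' representation-independent.
#'
#' @param scaffold,pos,ref,alt One variant (1-based `pos`).
#' @param genome Genome vector.
#' @return list with fields `scaffold`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(scaffold, pos, ref, alt, genome) {
  seq <- genome[[scaffold]]
  if (is.null(seq)) stop("scaffold ", scaffold, " not in genome")
  ref <- toupper(ref); alt <- toupper(alt)
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop("ref allele mismatch at ", scaffold, ":", pos, " (expected ",
         substr(seq, pos, pos + nchar(ref) - 1L), ", got ", ref, ")")
  }
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    # trim identical trailing base, re-extending left when exhausted
    if (rl > 1L && al > 1L &&
        substr(ref, rl, rl) == substr(alt, al, al)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      next
    }
    if ((rl == 1L || al == 1L) && rl != al &&
        substr(ref, rl, rl) == substr(alt, al, al) && pos > 1L) {
      base <- substr(seq, pos - 1L, pos - 1L)
      ref <- paste0(base, substr(ref, 1L, rl - 1L))
      alt <- paste0(base, substr(alt, 1L, al - 1L))
      pos <- pos - 1L
      next
    }
    break
  }
  # trim identical leading bases, keeping one anchor for indels
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (rl > 1L && al > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, rl); alt <- substr(alt, 2L, al)
      pos <- pos + 1L
      next
    }
    break
  }
  list(scaffold = scaffold, pos = as.integer(pos), ref = ref, alt = alt)
}

normalize_variants <- function(df, genome) {
  for (i in seq_len(nrow(df))) {
    v <- normalize_variant(df$scaffold[i], df$pos[i], df$ref[i], df$alt[i],
                           genome)
    df$pos[i] <- v$pos; df$ref[i] <- v$ref; df$alt[i] <- v$alt
  }
  df
}

#' Read a lineage's variants from VCF
#'
#' Loads a VCF 4.x file (site-only or single-sample), decomposes
#' multi-allelic records into one variant per ALT allele, splits multi-base
#' substitutions into atomic SNVs, left-normalizes indels, and rejects
#' records whose REF disagrees with the reference genome. Rejected records
#' are collected and reported in one warning, never silently dropped.
#'
#' @param path VCF file (plain text).
#' @param lineage Lineage label to attach (e.g. an inbred strain name).
#' @param genome Genome vector the calls were made against.
#' @return A `variant_set`; rejected records, if any, are attached as
#'   attribute `"rejected"` (data.frame scaffold/pos/ref/reason).
#' @export
read_variants <- function(path, lineage, genome) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- list()
  rejected <- list()
  for (i in seq_len(nrow(fix))) {
    sc <- fix$CHROM[i]; pos <- as.integer(fix$POS[i])
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1L]]
    alts <- alts[!alts %in% c(".", "*", "")]
    seq <- genome[[sc]]
    if (is.null(seq)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(scaffold = sc, pos = pos, ref = ref,
                   reason = "unknown scaffold")
      next
    }
    if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(scaffold = sc, pos = pos, ref = ref,
                   reason = "ref allele mismatch")
      next
    }
    for (alt in alts) {
      atoms <- atomize_variant(sc, pos, ref, alt)
      out[[length(out) + 1L]] <- atoms
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  vs <- variant_set(df$scaffold, df$pos, df$ref, df$alt, lineage = lineage,
                    genome = genome)
  if (length(rejected)) {
    rej <- do.call(rbind, rejected)
    warning(nrow(rej), " VCF record(s) rejected in ", path, " (",
            paste(unique(rej$reason), collapse = "; "), ")")
    attr(vs, "rejected") <- rej
  }
  vs
}

# Split one REF/ALT pair into atomic SNVs and at most one indel.
atomize_variant <- function(scaffold, pos, ref, alt) {
  rl <- nchar(ref); al <- nchar(alt)
  # trim shared suffix (keep at least 1 base each)
  while (rl > 1L && al > 1L && substr(ref, rl, rl) == substr(alt, al, al)) {
    ref <- substr(ref, 1L, rl - 1L); alt <- substr(alt, 1L, al - 1L)
    rl <- rl - 1L; al <- al - 1L
  }
  if (rl == al) {
    # (multi-)substitution: emit one SNV per differing base
    rb <- strsplit(ref, "")[[1L]]; ab <- strsplit(alt, "")[[1L]]
    d <- which(rb != ab)
    data.frame(scaffold = scaffold, pos = pos + d - 1L, ref = rb[d],
               alt = ab[d], stringsAsFactors = FALSE)
  } else {
    # indel: trim shared prefix down to one anchor base
    while (rl > 1L && al > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, rl); alt <- substr(alt, 2L, al)
      pos <- pos + 1L; rl <- rl - 1L; al <- al - 1L
    }
    data.frame(scaffold = scaffold, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
}

#' Write a variant set to VCF
#'
#' Minimal site-only VCF 4.2 emitter with deterministic, byte-stable
#' ordering (scaffold, position, ref, alt).
#'
#' @param vset A `variant_set`.
#' @param genome Genome vector (provides contig lengths for the header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vset, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   nchar(genome)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  vset$scaffold, vset$pos, vset$ref, vset$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Intersect variant sets across lineages
#'
#' Returns the variants shared by every lineage — the backcross logic:
#' independently derived inbred lines share, beyond noise, exactly the
#' donor-genome residue that resisted backcrossing, so the causal gene
#' must lie among the variants common to all lines.
#'
#' @param sets List of two or more `variant_set` objects normalized against
#'   the same reference.
#' @return A `variant_set` with lineage label `"common"`.
#' @export
intersect_lineages <- function(sets) {
  if (length(sets) < 2L) stop("need at least two lineage variant sets")
  keys <- Reduce(intersect, lapply(sets, `[[`, "key"))
  first <- sets[[1L]]
  common <- first[first$key %in% keys, , drop = FALSE]
  common$lineage <- rep("common", nrow(common))
  rownames(common) <- NULL
  class(common) <- c("variant_set", "data.frame")
  common
}
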