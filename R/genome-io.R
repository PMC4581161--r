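#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file into a named character vector of
#' uppercase DNA strings, one element per scaffold. This vector is the
#' `genome` object used throughout the package (the recurrent parent /
#' reference genome of a backcross design).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences restricted to the
#'   alphabet A/C/G/T/N. Names are the first whitespace-delimited token of
#'   each FASTA header.
#' @details Duplicate scaffold ids and non-DNA characters are errors; an
#'   empty file yields an empty genome with a warning.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-DNA characters (outside A/C/G/T/N) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of scaffold sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Scaffold lengths of a genome
#'
#' @param genome Named character vector of scaffold sequences.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

# Reverse complement of plain character DNA (vectorized).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
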