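# Standard-code translation of one codon; any codon containing an
# ambiguity (N) translates to X.
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (is.na(aa)) "X" else unname(aa)
}

# Translate a DNA string codon-wise up to (excluding) the first stop;
# trailing partial codons are ignored. Returns the protein and whether a
# stop was reached.
translate_full <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return(list(protein = "", stopped = FALSE))
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(protein = paste(aa[seq_len(stop_at[1L] - 1L)], collapse = ""),
         stopped = TRUE)
  } else {
    list(protein = paste(aa, collapse = ""), stopped = FALSE)
  }
}

#' Translate a coding sequence
#'
#' Standard genetic code (translation table 1); translation runs from the
#' first codon and stops at the first stop codon, returning the residues
#' before it. Codons containing N translate to `X`.
#'
#' @param cds Coding-sense DNA string; length must be divisible by 3, and a
#'   non-ATG first codon triggers a warning.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (!nchar(cds)) stop("empty coding sequence")
  if (nchar(cds) %% 3L != 0L) {
    stop("coding sequence length ", nchar(cds), " not divisible by 3")
  }
  if (substr(cds, 1L, 3L) != "ATG") {
    warning("coding sequence does not start with ATG")
  }
  translate_full(cds)$protein
}

# Average (not monoisotopic) residue masses in Da; only average masses
# reproduce the ~178 kDa scale of a 1625-residue protein.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_AVG_MASS <- 18.01528

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water, in kDa.
#'
#' @param protein Amino-acid string (standard 20 residues only).
#' @return Molecular weight in kDa (full precision; round to 3 decimals
#'   for reporting).
#' @export
molecular_weight <- function(protein) {
  if (!nchar(protein)) stop("empty protein")
  chars <- strsplit(protein, "")[[1L]]
  bad <- which(!chars %in% names(AA_AVG_MASS))
  if (length(bad)) {
    stop("non-standard residue(s) at position(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  (sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS) / 1000
}

#' Protein record with derived length and mass
#'
#' @param protein_id Identifier.
#' @param sequence Amino-acid string without stops.
#' @return list with `protein_id`, `sequence`, `length`, `mw_kda`.
#' @export
protein_record <- function(protein_id, sequence) {
  list(protein_id = protein_id, sequence = sequence,
       length = nchar(sequence), mw_kda = molecular_weight(sequence))
}

#' Densest window of one residue
#'
#' Slides a fixed-length window along the protein and returns the window
#' with the most occurrences of `residue` (leftmost on ties) — the
#' operationalization of statements like "35 glutamines within 38
#' residues" for a polyglutamine stretch.
#'
#' @param protein Amino-acid string.
#' @param residue Single residue letter to count.
#' @param window Window length (must be between 1 and the protein length).
#' @return list with `residue`, `start`, `end` (1-based inclusive),
#'   `count`, `window`.
#' @export
residue_rich_windows <- function(protein, residue, window) {
  n <- nchar(protein)
  window <- as.integer(window)
  if (window <= 0L) stop("window must be positive")
  if (window > n) stop("window ", window, " exceeds protein length ", n)
  hits <- as.integer(strsplit(protein, "")[[1L]] == residue)
  cs <- c(0L, cumsum(hits))
  counts <- cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]
  best <- which.max(counts)  # leftmost maximum
  list(residue = residue, start = best, end = best + window - 1L,
       count = counts[best], window = window)
}

#' Proline-rich regions of a protein
#'
#' Finds all windows whose proline fraction reaches `min_fraction` and
#' merges overlapping or adjacent qualifying windows into maximal regions.
#'
#' @param protein Amino-acid string.
#' @param window Window length (default 20).
#' @param min_fraction Minimum P fraction per window (default 0.3).
#' @return data.frame with `start`, `end`, `count` (prolines in region) and
#'   `fraction`; zero rows when no window qualifies.
#' @export
proline_rich_regions <- function(protein, window = 20L,
                                 min_fraction = 0.3) {
  n <- nchar(protein)
  empty <- data.frame(start = integer(0), end = integer(0),
                      count = integer(0), fraction = numeric(0))
  if (window <= 0L || window > n) return(empty)
  hits <- as.integer(strsplit(protein, "")[[1L]] == "P")
  cs <- c(0L, cumsum(hits))
  starts <- seq_len(n - window + 1L)
  counts <- cs[starts + window] - cs[starts]
  ok <- starts[counts / window >= min_fraction]
  if (!length(ok)) return(empty)
  # merge overlapping/adjacent qualifying windows
  reg_start <- ok[1L]; reg_end <- ok[1L] + window - 1L
  out <- list()
  for (s in ok[-1L]) {
    if (s <= reg_end + 1L) {
      reg_end <- s + window - 1L
    } else {
      out[[length(out) + 1L]] <- c(reg_start, reg_end)
      reg_start <- s; reg_end <- s + window - 1L
    }
  }
  out[[length(out) + 1L]] <- c(reg_start, reg_end)
  m <- do.call(rbind, out)
  count <- cs[m[, 2L] + 1L] - cs[m[, 1L]]
  data.frame(start = m[, 1L], end = m[, 2L], count = count,
             fraction = count / (m[, 2L] - m[, 1L] + 1L))
}
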