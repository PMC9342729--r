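# Low-level sequence helpers shared by every module. Sequences are plain
# uppercase character scalars over {A,C,G,T,N}; coordinates are 0-based
# half-open internally and 1-based inclusive in all user-facing tables.

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
#' @examples
#' dna_revcomp("ACGTN")
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# normalize residues: uppercase, IUPAC ambiguity codes beyond N mapped to N
normalize_residues <- function(x, warn_ambiguous = TRUE) {
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    n_bad <- sum(charToRaw(gsub("[ACGTN]", "", x)) != as.raw(0))
    if (warn_ambiguous) {
      warn(sprintf("%d ambiguous residues outside {A,C,G,T,N} mapped to N",
                   nchar(gsub("[ACGTN]", "", x))))
    }
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

# modular substring of a (possibly circular) sequence; 0-based half-open.
# end may exceed nchar(seq) for origin-spanning slices of circular genomes.
seq_slice <- function(seq, start, end, circular = TRUE) {
  n <- nchar(seq)
  len <- end - start
  if (len < 0) abort("slice end before start")
  if (!circular && (start < 0 || end > n)) abort("slice outside a linear sequence")
  if (len > n) abort("slice longer than the sequence")
  start <- start %% n
  if (start + len <= n) return(substr(seq, start + 1, start + len))
  paste0(substr(seq, start + 1, n), substr(seq, 1, len - (n - start)))
}

#' GC content of DNA sequences
#'
#' Computes 100 * (G+C) / (A+C+G+T) pooled over all elements of `x`;
#' N and other ambiguous residues are excluded from both numerator and
#' denominator. Reported to two decimals, half-up.
#'
#' @param x Character vector of DNA strings.
#' @return A single percentage in `[0, 100]`.
#' @export
#' @examples
#' gc_content("ATGC")  # 50
gc_content <- function(x) {
  x <- toupper(paste0(x, collapse = ""))
  s <- Biostrings::DNAString(gsub("[^ACGTN]", "N", x))
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) abort("sequence has no unambiguous A/C/G/T residues")
  round_half_up(100 * (f[["C"]] + f[["G"]]) / tot, 2)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# interval overlap helpers on 0-based half-open intervals
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
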