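# Low-level nucleotide helpers shared across modules. Sequences travel through
# the package as plain uppercase character vectors inside tibbles; Biostrings
# containers are used at file-format boundaries and for translation.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T, IUPAC codes allowed).
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' dna_revcomp("ACGT")
dna_revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split equal-length sequences into a character matrix (rows = sequences).
seq_matrix <- function(seqs) {
  if (length(seqs) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

collapse_rows <- function(mat) apply(mat, 1L, paste0, collapse = "")

# Number of mismatching positions between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch", call. = FALSE)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

random_dna <- function(n, length) {
  vapply(seq_len(n),
         function(i) paste0(sample(DNA_BASES, length, replace = TRUE),
                            collapse = ""),
         character(1))
}

# Substitute single bases at given 1-based positions (vectorised over reads).
substitute_base <- function(seq, pos, base) {
  out <- seq
  substr(out, pos, pos) <- base
  out
}

# Translate in-frame nucleotide strings codon-by-codon using the standard
# genetic code; incomplete trailing codons are dropped.  Stops become "*".
translate_nt <- function(x) {
  code <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n == 0) return("")
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- code[codons]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
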