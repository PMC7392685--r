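#' Simulate a panel of allele sequences
#'
#' Builds `n_alleles` distinct equal-length sequences that differ only at
#' `n_variable_sites` randomly placed biallelic sites. Every requested
#' variable site is guaranteed to be polymorphic in the returned panel, so
#' the panel's segregating-site count equals `n_variable_sites` exactly.
#'
#' @param n_alleles Number of alleles (>= 1).
#' @param length Sequence length in bp.
#' @param n_variable_sites Number of polymorphic sites (<= `length`).
#' @param seed Integer seed.
#' @param name_prefix Prefix for allele names; serials are zero-padded.
#' @return Tibble with columns `name`, `seq`.
#' @export
#' @examples
#' simulate_allele_panel(3, 30, 4, seed = 1)
simulate_allele_panel <- function(n_alleles, length, n_variable_sites,
                                  seed = 1L, name_prefix = "AL*") {
  stopifnot(n_alleles >= 1, n_variable_sites >= 0, n_variable_sites <= length)
  if (n_alleles == 1 && n_variable_sites > 0) {
    stop("a single allele cannot carry polymorphic sites", call. = FALSE)
  }
  if (n_alleles > 1 && n_variable_sites == 0) {
    stop("impossible distinctness: >1 allele with 0 variable sites", call. = FALSE)
  }
  if (n_variable_sites > 0 && n_variable_sites < 1024 &&
      n_alleles > 2^n_variable_sites) {
    stop("impossible distinctness: n_alleles exceeds 2^n_variable_sites",
         call. = FALSE)
  }
  set.seed(seed)
  ref <- strsplit(random_dna(1, length), "", fixed = TRUE)[[1]]
  nm <- paste0(name_prefix, formatC(seq_len(n_alleles), width = 2, flag = "0"))
  if (n_variable_sites == 0) {
    return(tibble::tibble(name = nm, seq = paste0(ref, collapse = "")))
  }
  sites <- sort(sample.int(length, n_variable_sites))
  alt <- vapply(sites, function(p) sample(setdiff(DNA_BASES, ref[p]), 1),
                character(1))
  # Binary state matrix: distinct rows, no constant column (so every site
  # really segregates). Rejection-sample, then repair any constant columns.
  draw_states <- function() {
    m <- matrix(sample(0:1, n_alleles * n_variable_sites, replace = TRUE),
                nrow = n_alleles)
    for (j in seq_len(ncol(m))) {
      if (length(unique(m[, j])) == 1) {
        m[sample.int(n_alleles, 1), j] <- 1 - m[1, j]
      }
    }
    m
  }
  m <- draw_states()
  tries <- 0
  while (anyDuplicated(m) && tries < 1000) {
    m <- draw_states()
    tries <- tries + 1
  }
  if (anyDuplicated(m)) {
    stop("could not generate distinct alleles for this configuration",
         call. = FALSE)
  }
  seqs <- vapply(seq_len(n_alleles), function(i) {
    s <- ref
    s[sites] <- ifelse(m[i, ] == 1, alt, ref[sites])
    paste0(s, collapse = "")
  }, character(1))
  tibble::tibble(name = nm, seq = seqs)
}
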