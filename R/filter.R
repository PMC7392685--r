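# Post-merge read filtering: orientation normalisation, corrupt-primer
# removal, merged-length floor, primer trimming, exact-sequence collapsing,
# per-individual singleton removal, and ranking by descending count.

mismatches_at <- function(seqs, pattern, where = c("start", "end")) {
  where <- match.arg(where)
  np <- nchar(pattern)
  frag <- if (where == "start") substr(seqs, 1, np)
          else substr(seqs, nchar(seqs) - np + 1L, nchar(seqs))
  ok_len <- nchar(seqs) >= np
  pm <- seq_matrix(rep(pattern, length(seqs)))
  out <- rep(np, length(seqs))
  full <- ok_len & nchar(frag) == np
  if (any(full)) {
    fm <- seq_matrix(frag[full])
    out[full] <- rowSums(fm != pm[seq_len(sum(full)), , drop = FALSE])
  }
  out
}

#' Normalise merged-read orientation against the forward primer
#'
#' Reads whose reverse complement carries the forward primer at its 5' end
#' (closer than the read itself does) are flipped, so that all returned reads
#' begin with the forward primer whenever it is present in either
#' orientation. Reads lacking the primer in both orientations pass through
#' unchanged (and are later dropped as corrupt).
#'
#' @param reads Tibble with a `seq` column (and optionally `count`), or a
#'   character vector.
#' @param fwd_primer Forward primer sequence.
#' @param max_mismatch Mismatch tolerance when locating the primer.
#' @return Input with `seq` orientation normalised.
#' @export
reverse_complement_normalize <- function(reads, fwd_primer, max_mismatch = 0) {
  vec <- is.character(reads)
  seqs <- if (vec) reads else reads$seq
  if (length(seqs) == 0) return(reads)
  mm_f <- mismatches_at(seqs, fwd_primer, "start")
  rc <- dna_revcomp(seqs)
  mm_r <- mismatches_at(rc, fwd_primer, "start")
  flip <- mm_r <= max_mismatch & mm_r < mm_f
  seqs[flip] <- rc[flip]
  if (vec) seqs else dplyr::mutate(reads, seq = seqs)
}

#' Filter merged amplicon reads and rank the surviving variants
#'
#' Applies, in order: orientation normalisation; removal of reads with
#' corrupt primers (forward primer at the 5' terminus and reverse-primer
#' complement at the 3' terminus, each within `max_mismatch`); removal of
#' merged reads shorter than `min_len` (measured before primer trimming);
#' primer trimming; exact-sequence collapsing; removal of sequences occurring
#' only once within the individual; ranking by descending count (ties broken
#' lexicographically for determinism).
#'
#' @param reads Tibble with columns `seq` and optionally `count`,
#'   `individual_id`, `locus`; or a character vector of reads. When several
#'   individuals are present the filter is applied per individual and locus.
#' @param fwd_primer,rev_primer Primer sequences (reverse primer as ordered,
#'   i.e. its reverse complement is expected at the read 3' end).
#' @param min_len Minimum merged-read length (pre-trim), default 290.
#' @param max_mismatch Primer mismatch tolerance, default 0 (strict).
#' @return Ranked variant tibble with columns `individual_id`, `locus`,
#'   `rank`, `seq` (primer-trimmed), `count`; the stage-wise read accounting
#'   is attached as attribute `"stages"` (tibble with `stage`, `reads_in`,
#'   `reads_removed`, per individual/locus).
#' @export
filter_merged_reads <- function(reads, fwd_primer, rev_primer,
                                min_len = 290, max_mismatch = 0) {
  if (nchar(fwd_primer) == 0 || nchar(rev_primer) == 0) {
    stop("primers must be non-empty", call. = FALSE)
  }
  if (min_len <= nchar(fwd_primer) + nchar(rev_primer)) {
    stop("min_len must exceed the combined primer length", call. = FALSE)
  }
  if (is.character(reads)) {
    reads <- tibble::tibble(seq = reads)
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"individual_id" %in% names(reads)) reads$individual_id <- NA_character_
  if (!"locus" %in% names(reads)) reads$locus <- NA_character_
  empty <- tibble::tibble(individual_id = character(0), locus = character(0),
                          rank = integer(0), seq = character(0),
                          count = integer(0))
  if (nrow(reads) == 0) {
    attr(empty, "stages") <- tibble::tibble(
      individual_id = character(0), locus = character(0), stage = character(0),
      reads_in = integer(0), reads_removed = integer(0))
    return(empty)
  }
  rc_rev <- dna_revcomp(rev_primer)
  trim_n <- nchar(fwd_primer)
  groups <- dplyr::group_split(reads, .data$individual_id, .data$locus)
  res <- list(); logs <- list()
  for (g in groups) {
    id <- g$individual_id[1]; loc <- g$locus[1]
    n0 <- sum(g$count)
    g <- reverse_complement_normalize(g, fwd_primer, max_mismatch)
    ok_primer <- mismatches_at(g$seq, fwd_primer, "start") <= max_mismatch &
      mismatches_at(g$seq, rc_rev, "end") <= max_mismatch &
      nchar(g$seq) > nchar(fwd_primer) + nchar(rev_primer)
    g1 <- g[ok_primer, ]
    n1 <- sum(g1$count)
    g2 <- g1[nchar(g1$seq) >= min_len, ]
    n2 <- sum(g2$count)
    if (nrow(g2) > 0) {
      g2$seq <- substr(g2$seq, trim_n + 1L, nchar(g2$seq) - nchar(rev_primer))
      coll <- dplyr::summarise(dplyr::group_by(g2, .data$seq),
                               count = sum(.data$count), .groups = "drop")
      coll <- coll[coll$count >= 2L, ]
    } else {
      coll <- tibble::tibble(seq = character(0), count = integer(0))
    }
    n3 <- sum(coll$count)
    coll <- dplyr::arrange(coll, dplyr::desc(.data$count), .data$seq)
    if (nrow(coll) > 0) {
      res[[length(res) + 1L]] <- tibble::tibble(
        individual_id = id, locus = loc, rank = seq_len(nrow(coll)),
        seq = coll$seq, count = as.integer(coll$count))
    }
    logs[[length(logs) + 1L]] <- tibble::tibble(
      individual_id = id, locus = loc,
      stage = c("input", "corrupt_primer", "short_read", "singleton"),
      reads_in = c(n0, n0, n1, n2),
      reads_removed = c(0L, n0 - n1, n1 - n2, n2 - n3))
  }
  out <- if (length(res)) dplyr::bind_rows(res) else empty
  attr(out, "stages") <- dplyr::bind_rows(logs)
  out
}
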