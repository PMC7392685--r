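# Translation, amino-acid collapsing and pairwise distances.

# Codon-window translation over alignment columns (windows of 3 columns):
# "---" -> "-", any other gap-containing window -> "X".
translate_aligned <- function(seqs) {
  code <- Biostrings::GENETIC_CODE
  vapply(seqs, function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n == 0) return("")
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- ifelse(codons == "---", "-",
                 ifelse(grepl("-", codons, fixed = TRUE), "X",
                        unname(code[codons])))
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a nucleotide panel and collapse identical proteins
#'
#' Removes alignment gaps (in-frame indels, i.e. gap runs in multiples of
#' 3, are tolerated), drops `frame_offset` leading bases and any trailing
#' partial codon, translates with the standard code, and merges alleles
#' whose protein sequences are identical. Internal stop codons are flagged
#' with a warning but the sequence is retained (exon fragments can
#' legitimately span a stop in a different frame).
#'
#' @param panel An [aligned_panel()] of nucleotide sequences.
#' @param frame_offset 0, 1 or 2 leading bases to skip before translation.
#' @return List with `proteins` (aligned_panel of unique amino-acid
#'   sequences, named `aa_01`, `aa_02`, ... in first-appearance order, with
#'   summed multiplicities) and `collapse_map` (tibble `name`,
#'   `protein_name`, `protein`).
#' @export
translate_and_collapse <- function(panel, frame_offset = 0) {
  stopifnot(frame_offset %in% 0:2)
  panel <- aligned_panel(panel)
  nt <- gsub("-", "", panel$seq, fixed = TRUE)
  gap_removed <- nchar(panel$seq) - nchar(nt)
  if (any(gap_removed %% 3 != 0)) {
    stop("gaps must occur in multiples of 3 (in-frame indels)", call. = FALSE)
  }
  if (any(gap_removed > 0)) {
    # gapped alignment: translate codon windows over alignment columns so
    # the protein panel stays aligned; an all-gap window becomes "-",
    # a partially gapped window "X"
    aa <- translate_aligned(substr(panel$seq, frame_offset + 1,
                                   nchar(panel$seq)))
  } else {
    aa <- translate_nt(substr(nt, frame_offset + 1, nchar(nt)))
  }
  if (any(grepl("\\*.", aa))) {
    warning("internal stop codon in translated panel; sequence retained",
            call. = FALSE)
  }
  uniq <- unique(aa)
  pname <- paste0("aa_", formatC(match(aa, uniq), width = 2, flag = "0"))
  map <- tibble::tibble(name = panel$name, protein_name = pname, protein = aa)
  agg <- dplyr::summarise(dplyr::group_by(map, .data$protein_name,
                                          .data$protein),
                          mult = sum(panel$mult[match(.data$name,
                                                      panel$name)]),
                          .groups = "drop")
  agg <- dplyr::arrange(agg, .data$protein_name)
  prot <- aligned_panel(tibble::tibble(name = agg$protein_name,
                                       seq = agg$protein,
                                       mult = agg$mult))
  list(proteins = prot, collapse_map = map)
}

#' Pairwise p-distances and Poisson-corrected amino-acid distances
#'
#' p-distance = differences / valid sites (complete deletion of gap
#' columns); the Poisson correction for amino-acid panels is
#' `d = -log(1 - p)` (infinite when p >= 1, flagged `Inf`).
#'
#' @param panel An [aligned_panel()] (nucleotide or protein).
#' @param kind `"nucleotide-p"` for the plain proportion, `"poisson-aa"`
#'   to add the Poisson correction.
#' @return Tibble of unordered pairs: `name_1`, `name_2`, `p`, `distance`
#'   (equal to `p` for `"nucleotide-p"`). Summary attribute `"summary"`
#'   holds mean/min/max of `distance`.
#' @export
distances <- function(panel, kind = c("nucleotide-p", "poisson-aa")) {
  kind <- match.arg(kind)
  core <- panel_core(aligned_panel(panel))
  m <- nrow(core$mat)
  if (m < 2) stop("distances require at least two sequences", call. = FALSE)
  rows <- list()
  for (u in 1:(m - 1)) {
    for (v in (u + 1):m) {
      p <- sum(core$mat[u, ] != core$mat[v, ]) / core$L
      d <- if (kind == "poisson-aa") {
        if (p >= 1) Inf else -log(1 - p)
      } else p
      rows[[length(rows) + 1]] <- tibble::tibble(
        name_1 = core$names[u], name_2 = core$names[v], p = p, distance = d)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- tibble::tibble(
    mean = mean(out$distance[is.finite(out$distance)]),
    min = min(out$distance), max = max(out$distance[is.finite(out$distance)]))
  out
}
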