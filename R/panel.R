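# Allele-panel construction: population frequencies from resolved calls, the
# minimum-allele-frequency filter, and serial-number nomenclature.

#' Build an allele panel from resolved genotype calls
#'
#' Collects the distinct allele sequences appearing in resolved calls
#' (homozygote/heterozygote) at one locus and computes their population
#' frequencies (allele copies / 2n over resolved individuals). An allele is
#' marked validated when it appears in at least one unambiguous ratio-based
#' call (i.e. it was not introduced solely through resolution of an
#' ambiguous individual).
#'
#' @param calls Call tibble from [call_genotypes()] / [resolve_ambiguous()],
#'   one locus.
#' @return Tibble `seq`, `validated`, `copies`, `frequency`, sorted by
#'   descending frequency.
#' @export
build_allele_panel <- function(calls) {
  res <- calls[calls$status %in% c("homozygote", "heterozygote"), ]
  if (nrow(res) == 0) {
    return(tibble::tibble(seq = character(0), validated = logical(0),
                          copies = integer(0), frequency = numeric(0)))
  }
  copies <- c(res$seq_1, res$seq_2)
  tab <- table(copies)
  ratio_based <- unique(c(res$seq_1[res$resolution_source == "ratio"],
                          res$seq_2[res$resolution_source == "ratio"]))
  out <- tibble::tibble(seq = names(tab),
                        validated = names(tab) %in% ratio_based,
                        copies = as.integer(tab),
                        frequency = as.integer(tab) / sum(tab))
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$seq)
}

#' Minimum-allele-frequency threshold
#'
#' `5 / (2 n)`: five allele copies among `2 n` sampled chromosomes.
#'
#' @param n_individuals Number of genotyped individuals.
#' @return The frequency threshold.
#' @export
#' @examples
#' maf_threshold(375) # 0.00667 (0.67%)
maf_threshold <- function(n_individuals) {
  stopifnot(n_individuals > 0)
  5 / (2 * n_individuals)
}

#' Apply the population minimum-allele-frequency filter
#'
#' Unvalidated alleles with population frequency below `5 / (2 n)` are not
#' considered true alleles and are removed; alleles flagged validated (by
#' pedigree or external data) are retained regardless of frequency.
#' Individuals whose only supporting evidence is a removed allele are listed
#' for exclusion. The filter is applied once (frequencies are not
#' iteratively recomputed) and is idempotent.
#'
#' @param panel Panel tibble from [build_allele_panel()] (columns `seq`,
#'   `validated`, `frequency`; optionally `copies`).
#' @param calls Call tibble used to locate affected individuals.
#' @param n_individuals Number of genotyped individuals used for the
#'   threshold (default: resolved individuals in `calls`).
#' @return List with `panel` (filtered), `removed_alleles`,
#'   `excluded_individuals` and `threshold`.
#' @export
apply_maf_filter <- function(panel, calls,
                             n_individuals = NULL) {
  res <- calls[calls$status %in% c("homozygote", "heterozygote"), ]
  n <- n_individuals %||% nrow(res)
  thr <- maf_threshold(n)
  drop <- !panel$validated & panel$frequency < thr
  removed <- panel$seq[drop]
  excluded <- character(0)
  if (length(removed) > 0) {
    hit <- res$seq_1 %in% removed | res$seq_2 %in% removed
    excluded <- unique(res$individual_id[hit])
  }
  list(panel = panel[!drop, ], removed_alleles = removed,
       excluded_individuals = excluded, threshold = thr)
}

#' Assign serial-number nomenclature to a panel
#'
#' Sequences identical to a known allele keep their published name; novel
#' sequences receive consecutive serial numbers continuing after the highest
#' serial in the known panel (locus-prefixed, zero-padded to two digits, as
#' in `DRB*19` following a known panel ending at `DRB*18`). Novel sequences
#' are numbered in the order they appear in `panel` (conventionally by
#' descending population frequency), which makes the mapping deterministic.
#'
#' @param panel Panel tibble with a `seq` column (ordered).
#' @param known_alleles Tibble with `name`, `seq` of published alleles, or
#'   `NULL` for a fresh locus.
#' @param prefix Name prefix used for novel alleles when `known_alleles` is
#'   empty (e.g. `"DOB*"`).
#' @return `panel` with a `name` column added (first column).
#' @export
assign_nomenclature <- function(panel, known_alleles = NULL, prefix = "AL*") {
  if (!is.null(known_alleles) && nrow(known_alleles) > 0) {
    if (anyDuplicated(known_alleles$name)) {
      stop("duplicate names in known allele panel", call. = FALSE)
    }
    if (anyDuplicated(known_alleles$seq)) {
      stop("duplicate sequences in known allele panel", call. = FALSE)
    }
    m <- regmatches(known_alleles$name,
                    regexpr("[0-9]+$", known_alleles$name))
    serial <- suppressWarnings(max(as.integer(m), na.rm = TRUE))
    if (!is.finite(serial)) serial <- 0L
    pref <- sub("[0-9]+$", "", known_alleles$name[1])
  } else {
    known_alleles <- tibble::tibble(name = character(0), seq = character(0))
    serial <- 0L
    pref <- prefix
  }
  name <- known_alleles$name[match(panel$seq, known_alleles$seq)]
  novel <- which(is.na(name))
  if (length(novel) > 0) {
    name[novel] <- paste0(pref, formatC(serial + seq_along(novel),
                                        width = 2, flag = "0"))
  }
  dplyr::bind_cols(tibble::tibble(name = name), panel)
}
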