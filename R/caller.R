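# Ratio-threshold diploid genotype calling, PCR-chimera detection and
# pedigree/panel-based resolution of ambiguous calls.

#' Classify individuals as homozygous/heterozygous from ranked variants
#'
#' The top-two ratio is `count_2 / (count_1 + count_2)`, the share of the
#' second-ranked sequence among the top two. Calls follow the standard
#' amplicon-genotyping bands: ratio below `homo` (default 0.10, i.e. 90:10)
#' is a homozygote; ratio from `het_low` (default 0.35, i.e. 65:35) up to
#' 0.5 (50:50) is a heterozygote; the band in between is ambiguous and left
#' without a second allele until resolved by [resolve_ambiguous()]. A single
#' surviving variant is a homozygote; an empty table yields an unresolved
#' call. The call is invariant to rescaling all counts.
#'
#' @param variants Ranked variant tibble from [filter_merged_reads()]
#'   (columns `individual_id`, `locus`, `rank`, `seq`, `count`).
#' @param homo Homozygote threshold on the top-two ratio (default 0.10).
#' @param het_low Lower heterozygote threshold (default 0.35, inclusive).
#' @return Tibble with one row per individual x locus: `individual_id`,
#'   `locus`, `seq_1`, `seq_2`, `status`
#'   (`homozygote`/`heterozygote`/`ambiguous`/`unresolved`), `top2_ratio`,
#'   `resolution_source` (`ratio` or `none`).
#' @export
call_genotypes <- function(variants, homo = 0.10, het_low = 0.35) {
  stopifnot(homo > 0, homo < het_low, het_low <= 0.5)
  if (nrow(variants) == 0) {
    return(tibble::tibble(individual_id = character(0), locus = character(0),
                          seq_1 = character(0), seq_2 = character(0),
                          status = character(0), top2_ratio = numeric(0),
                          resolution_source = character(0)))
  }
  groups <- dplyr::group_split(variants, .data$individual_id, .data$locus)
  rows <- lapply(groups, function(g) {
    g <- dplyr::arrange(g, .data$rank)
    if (nrow(g) == 0 || sum(g$count) == 0) {
      return(tibble::tibble(individual_id = g$individual_id[1],
                            locus = g$locus[1], seq_1 = NA_character_,
                            seq_2 = NA_character_, status = "unresolved",
                            top2_ratio = NA_real_,
                            resolution_source = "none"))
    }
    if (nrow(g) == 1) {
      return(tibble::tibble(individual_id = g$individual_id[1],
                            locus = g$locus[1], seq_1 = g$seq[1],
                            seq_2 = g$seq[1], status = "homozygote",
                            top2_ratio = 0,
                            resolution_source = "ratio"))
    }
    r <- g$count[2] / (g$count[1] + g$count[2])
    if (r < homo) {
      tibble::tibble(individual_id = g$individual_id[1], locus = g$locus[1],
                     seq_1 = g$seq[1], seq_2 = g$seq[1],
                     status = "homozygote", top2_ratio = r,
                     resolution_source = "ratio")
    } else if (r >= het_low) {
      tibble::tibble(individual_id = g$individual_id[1], locus = g$locus[1],
                     seq_1 = g$seq[1], seq_2 = g$seq[2],
                     status = "heterozygote", top2_ratio = r,
                     resolution_source = "ratio")
    } else {
      tibble::tibble(individual_id = g$individual_id[1], locus = g$locus[1],
                     seq_1 = g$seq[1], seq_2 = NA_character_,
                     status = "ambiguous", top2_ratio = r,
                     resolution_source = "ratio")
    }
  })
  dplyr::bind_rows(rows)
}

#' Detect a single-crossover PCR chimera
#'
#' Tests whether `candidate` can be written as `prefix(a) + suffix(b)` or
#' `prefix(b) + suffix(a)` for some internal split point, i.e. whether it is
#' a single-crossover recombinant of the two parent sequences. Sequences
#' must be equal length (gap-free comparison) and the candidate must differ
#' from both parents. The detector is symmetric in the parents and never
#' flags a parent itself (that is a precondition violation).
#'
#' @param candidate,parent_a,parent_b Equal-length nucleotide strings.
#' @return List with `is_chimera` (logical) and `intervals`, a tibble of the
#'   maximal compatible crossover intervals (`first_parent`, `from`, `to`:
#'   the candidate equals `first_parent` up to split point s and the other
#'   parent after it, for every s in `[from, to]`, 1-based prefix lengths).
#' @export
detect_chimera <- function(candidate, parent_a, parent_b) {
  L <- nchar(candidate)
  if (nchar(parent_a) != L || nchar(parent_b) != L) {
    stop("candidate and parents must have equal lengths", call. = FALSE)
  }
  if (candidate == parent_a || candidate == parent_b) {
    stop("candidate must differ from both parents", call. = FALSE)
  }
  cc <- strsplit(candidate, "", fixed = TRUE)[[1]]
  aa <- strsplit(parent_a, "", fixed = TRUE)[[1]]
  bb <- strsplit(parent_b, "", fixed = TRUE)[[1]]
  iv <- list()
  for (first in 1:2) {
    x <- if (first == 1) aa else bb
    y <- if (first == 1) bb else aa
    eq_x <- cc == x
    eq_y <- cc == y
    # longest prefix of candidate matching x, shortest suffix start matching y
    pre <- if (all(eq_x)) L else which(!eq_x)[1] - 1L
    suf <- if (all(eq_y)) 1L else max(which(!eq_y)) + 1L
    # split s (prefix length) valid iff s >= suf-1 and s <= pre, 1 <= s <= L-1
    lo <- max(1L, suf - 1L)
    hi <- min(pre, L - 1L)
    if (lo <= hi) {
      iv[[length(iv) + 1L]] <- tibble::tibble(
        first_parent = if (first == 1) "a" else "b", from = lo, to = hi)
    }
  }
  intervals <- if (length(iv)) dplyr::bind_rows(iv)
               else tibble::tibble(first_parent = character(0),
                                   from = integer(0), to = integer(0))
  list(is_chimera = nrow(intervals) > 0, intervals = intervals)
}

#' Screen lower-ranked variants for chimeras of the top two
#'
#' For every individual with three or more surviving variants, tests each
#' variant of rank 3 and below (of matching length) against the top two
#' sequences with [detect_chimera()].
#'
#' @param variants Ranked variant tibble from [filter_merged_reads()].
#' @return Tibble `individual_id`, `locus`, `rank`, `seq`, `is_chimera`.
#' @export
screen_chimeras <- function(variants) {
  groups <- dplyr::group_split(variants, .data$individual_id, .data$locus)
  rows <- lapply(groups, function(g) {
    g <- dplyr::arrange(g, .data$rank)
    if (nrow(g) < 3) return(NULL)
    lower <- g[-(1:2), ]
    flag <- vapply(lower$seq, function(s) {
      if (nchar(s) != nchar(g$seq[1]) || nchar(s) != nchar(g$seq[2])) {
        return(FALSE)
      }
      if (s == g$seq[1] || s == g$seq[2]) return(FALSE)
      detect_chimera(s, g$seq[1], g$seq[2])$is_chimera
    }, logical(1), USE.NAMES = FALSE)
    tibble::tibble(individual_id = lower$individual_id,
                   locus = lower$locus, rank = lower$rank, seq = lower$seq,
                   is_chimera = flag)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(individual_id = character(0), locus = character(0),
                          rank = integer(0), seq = character(0),
                          is_chimera = logical(0))
  }
  out
}

#' Resolve ambiguous genotype calls with panel, pedigree and external data
#'
#' An ambiguous call (top-two ratio between the homozygote and heterozygote
#' bands) is upgraded to a heterozygote when its second-ranked sequence
#' matches a validated panel allele and the implied genotype does not
#' contradict the assigned parents' genotypes (individuals without assigned
#' parents are treated as unconstrained; a Sanger-style external-validation
#' route is available through `external`). It is downgraded to a homozygote
#' when the second sequence is a detected chimera of the top sequence and a
#' panel allele, or fails panel membership; otherwise it stays unresolved.
#'
#' @param calls Call tibble from [call_genotypes()].
#' @param variants Ranked variant tibble (to recover the second-ranked
#'   sequence of ambiguous individuals).
#' @param panel Validated allele panel: tibble with columns `seq` and
#'   optionally `validated` (default all validated).
#' @param pedigree Optional pedigree tibble (`individual_id`, `sire`, `dam`).
#' @param external Optional character vector of individual ids covered by an
#'   external validation assay (e.g. Sanger).
#' @return `calls` with ambiguous rows resolved where possible;
#'   `resolution_source` set to `pedigree` or `external` for upgraded rows.
#' @export
resolve_ambiguous <- function(calls, variants, panel, pedigree = NULL,
                              external = NULL) {
  if (!"validated" %in% names(panel)) panel$validated <- TRUE
  valid_seqs <- panel$seq[panel$validated]
  second_of <- function(id, loc) {
    g <- variants[variants$individual_id == id & variants$locus == loc, ]
    g <- dplyr::arrange(g, .data$rank)
    if (nrow(g) >= 2) g$seq[2] else NA_character_
  }
  geno_of <- function(id, loc) {
    r <- calls[calls$individual_id == id & calls$locus == loc, ]
    if (nrow(r) == 1 && r$status[1] %in% c("homozygote", "heterozygote")) {
      c(r$seq_1[1], r$seq_2[1])
    } else NULL
  }
  for (i in which(calls$status == "ambiguous")) {
    id <- calls$individual_id[i]; loc <- calls$locus[i]
    s2 <- second_of(id, loc)
    if (is.na(s2)) next
    if (!is.null(external) && id %in% external) {
      calls$seq_2[i] <- s2
      calls$status[i] <- "heterozygote"
      calls$resolution_source[i] <- "external"
      next
    }
    in_panel <- s2 %in% valid_seqs
    if (in_panel) {
      consistent <- TRUE
      used_pedigree <- FALSE
      if (!is.null(pedigree)) {
        pr <- pedigree[pedigree$individual_id == id, ]
        if (nrow(pr) == 1) {
          parents <- na.omit(c(pr$sire[1], pr$dam[1]))
          pgeno <- lapply(parents, geno_of, loc = loc)
          pgeno <- pgeno[!vapply(pgeno, is.null, logical(1))]
          if (length(pgeno) > 0) {
            used_pedigree <- TRUE
            consistent <- pair_consistent(c(calls$seq_1[i], s2), pgeno)
          }
        }
      }
      if (consistent) {
        calls$seq_2[i] <- s2
        calls$status[i] <- "heterozygote"
        calls$resolution_source[i] <- "pedigree"
        next
      }
    }
    # a second sequence that is a chimera of the top sequence and a panel
    # allele is an artifact: call a homozygote. A non-panel, non-chimeric
    # second sequence without confirming data stays unresolved.
    is_chim <- FALSE
    if (!in_panel) {
      for (p in valid_seqs) {
        if (nchar(p) == nchar(s2) && p != s2 && p != calls$seq_1[i] &&
            nchar(calls$seq_1[i]) == nchar(s2)) {
          if (detect_chimera(s2, calls$seq_1[i], p)$is_chimera) {
            is_chim <- TRUE
            break
          }
        }
      }
    }
    if (is_chim) {
      calls$seq_2[i] <- calls$seq_1[i]
      calls$status[i] <- "homozygote"
      calls$resolution_source[i] <- "ratio"
    } else {
      calls$status[i] <- "unresolved"
      calls$resolution_source[i] <- "none"
    }
  }
  calls
}

# Can genotype (two allele identifiers) be explained by the available parent
# genotypes via a bipartite assignment (one allele attributed to each
# assigned parent simultaneously)?
pair_consistent <- function(geno, parent_genos) {
  if (length(parent_genos) == 0) return(TRUE)
  if (length(parent_genos) == 1) {
    return(any(geno %in% parent_genos[[1]]))
  }
  (geno[1] %in% parent_genos[[1]] && geno[2] %in% parent_genos[[2]]) ||
    (geno[2] %in% parent_genos[[1]] && geno[1] %in% parent_genos[[2]])
}
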