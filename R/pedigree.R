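# Pedigree validation of genotype calls.

#' Mendelian consistency of genotype calls against a pedigree
#'
#' An offspring is consistent at a locus when one of its alleles can be
#' attributed to each assigned parent simultaneously (a bipartite
#' assignment, not two independent share-checks: parents AA x BB cannot
#' explain an AA offspring even though the offspring shares an allele with a
#' parent). Offspring with a single assigned, genotyped parent are checked
#' against that parent alone; offspring with no assigned genotyped parent
#' are not counted. Inconsistent calls are flagged, not discarded.
#'
#' @param sample Genotype tibble (`individual_id`, `locus`, `allele_1`,
#'   `allele_2`), e.g. truth from [simulate_genotypes()] or named calls.
#' @param pedigree Pedigree tibble (`individual_id`, `sire`, `dam`); `NA`
#'   parents mean unknown. Cyclic pedigrees are an error.
#' @return List with `flags` (tibble `individual_id`, `locus`, `consistent`)
#'   and `fraction` (consistent / checked, over all loci).
#' @export
mendelian_consistency <- function(sample, pedigree) {
  check_pedigree_acyclic(pedigree)
  rows <- list()
  for (loc in unique(sample$locus)) {
    gl <- sample[sample$locus == loc, ]
    geno <- function(id) {
      r <- gl[gl$individual_id == id, ]
      if (nrow(r) == 1) c(r$allele_1[1], r$allele_2[1]) else NULL
    }
    for (i in seq_len(nrow(pedigree))) {
      id <- pedigree$individual_id[i]
      kid <- geno(id)
      if (is.null(kid)) next
      parents <- na.omit(c(pedigree$sire[i], pedigree$dam[i]))
      pgeno <- lapply(parents, geno)
      pgeno <- pgeno[!vapply(pgeno, is.null, logical(1))]
      if (length(pgeno) == 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        individual_id = id, locus = loc,
        consistent = pair_consistent(kid, pgeno))
    }
  }
  flags <- if (length(rows)) dplyr::bind_rows(rows)
           else tibble::tibble(individual_id = character(0),
                               locus = character(0), consistent = logical(0))
  list(flags = flags,
       fraction = if (nrow(flags)) mean(flags$consistent) else NA_real_)
}

check_pedigree_acyclic <- function(pedigree) {
  parent_of <- split(
    c(pedigree$sire, pedigree$dam),
    c(pedigree$individual_id, pedigree$individual_id))
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- state[[id]] %||% "new"
    if (st == "active") stop("cyclic pedigree", call. = FALSE)
    if (st == "done") return(invisible())
    assign(id, "active", envir = state)
    for (p in parent_of[[id]]) {
      if (!is.na(p) && p %in% pedigree$individual_id) visit(p)
    }
    assign(id, "done", envir = state)
    invisible()
  }
  for (id in pedigree$individual_id) visit(id)
  invisible(TRUE)
}
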