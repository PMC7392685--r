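# Allele and genotype frequency tables and demographic quantities.

#' Allele and genotype frequencies per locus and cohort
#'
#' Allele frequency = allele copies / 2n over resolved individuals;
#' genotype frequencies are over unordered allele pairs. When a `cohort`
#' column is present, tables are produced per cohort.
#'
#' @param sample Genotype tibble (`individual_id`, `locus`, `allele_1`,
#'   `allele_2`, optional `cohort`).
#' @return List with tibbles `alleles` (`locus`, `cohort`, `allele`,
#'   `copies`, `frequency`) and `genotypes` (`locus`, `cohort`, `genotype`,
#'   `count`, `frequency`). Genotype frequencies sum to 1 per locus/cohort.
#' @export
frequencies <- function(sample) {
  sample <- sample[!is.na(sample$allele_1) & !is.na(sample$allele_2), ]
  if (!"cohort" %in% names(sample)) sample$cohort <- "all"
  al <- dplyr::bind_rows(
    dplyr::select(sample, "locus", "cohort", allele = "allele_1"),
    dplyr::select(sample, "locus", "cohort", allele = "allele_2"))
  alleles <- dplyr::count(al, .data$locus, .data$cohort, .data$allele,
                          name = "copies")
  alleles <- dplyr::mutate(
    dplyr::group_by(alleles, .data$locus, .data$cohort),
    frequency = .data$copies / sum(.data$copies))
  alleles <- dplyr::ungroup(alleles)
  gt <- dplyr::mutate(sample,
                      genotype = paste(pmin(.data$allele_1, .data$allele_2),
                                       pmax(.data$allele_1, .data$allele_2),
                                       sep = "/"))
  genotypes <- dplyr::count(gt, .data$locus, .data$cohort, .data$genotype,
                            name = "count")
  genotypes <- dplyr::mutate(
    dplyr::group_by(genotypes, .data$locus, .data$cohort),
    frequency = .data$count / sum(.data$count))
  genotypes <- dplyr::ungroup(genotypes)
  list(alleles = dplyr::arrange(alleles, .data$locus, .data$cohort,
                                dplyr::desc(.data$frequency)),
       genotypes = dplyr::arrange(genotypes, .data$locus, .data$cohort,
                                  dplyr::desc(.data$frequency)))
}

#' Effective population size under unequal breeding sex ratio
#'
#' `Ne = 4 Nm Nf / (Nm + Nf)`.
#'
#' @param n_m,n_f Numbers of breeding males and females (> 0).
#' @return Ne (numeric). Always `<= n_m + n_f`.
#' @export
#' @examples
#' effective_population_size(46, 25) # 64.79
effective_population_size <- function(n_m, n_f) {
  if (n_m <= 0 || n_f <= 0) {
    stop("both sexes must have at least one breeder", call. = FALSE)
  }
  4 * n_m * n_f / (n_m + n_f)
}
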