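# Two-locus genotypic linkage-disequilibrium (independence) test.

#' Genotypic linkage-disequilibrium test between two loci
#'
#' Tests the null hypothesis that the single-locus genotypes at two loci
#' are independent among individuals (i.e. the loci are not closely
#' linked), without assuming gametic phase. The statistic is the
#' log-likelihood-ratio G on the two-locus genotype contingency table; its
#' null distribution is obtained by permuting one locus' genotypes among
#' individuals in batches, giving a Monte Carlo p-value with a batch-means
#' standard error.
#'
#' @param sample Genotype tibble (`individual_id`, `locus`, `allele_1`,
#'   `allele_2`); both loci must be resolved in the same individuals.
#' @param locus_a,locus_b Locus names.
#' @param settings [mcmc_settings()]; total permutations =
#'   `batches * iterations_per_batch`.
#' @return An `ld_test` object with fields `p`, `se`, `g_obs`, `n`,
#'   `n_genotypes_a`, `n_genotypes_b`; monomorphic loci give `p = NA` with
#'   method `"not-applicable"`.
#' @export
ld_genotypic_test <- function(sample, locus_a, locus_b,
                              settings = mcmc_settings()) {
  ga <- sample[sample$locus == locus_a, ]
  gb <- sample[sample$locus == locus_b, ]
  ids <- intersect(ga$individual_id, gb$individual_id)
  ga <- ga[match(ids, ga$individual_id), ]
  gb <- gb[match(ids, gb$individual_id), ]
  geno_label <- function(g) {
    a1 <- pmin(g$allele_1, g$allele_2)
    a2 <- pmax(g$allele_1, g$allele_2)
    paste(a1, a2, sep = "/")
  }
  la <- geno_label(ga); lb <- geno_label(gb)
  fa <- factor(la); fb <- factor(lb)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    return(structure(list(p = NA_real_, se = NA_real_, g_obs = NA_real_,
                          n = length(ids), n_genotypes_a = nlevels(fa),
                          n_genotypes_b = nlevels(fb),
                          method = "not-applicable", settings = settings),
                     class = "ld_test"))
  }
  set.seed(settings$seed)
  res <- ld_perm_cpp(as.integer(fa) - 1L, as.integer(fb) - 1L,
                     nlevels(fa), nlevels(fb),
                     settings$batches, settings$iterations_per_batch)
  s <- batch_summary(res$batch_means)
  structure(list(p = s$p, se = s$se, g_obs = res$g_obs, n = length(ids),
                 n_genotypes_a = nlevels(fa), n_genotypes_b = nlevels(fb),
                 method = "permutation", settings = settings),
            class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  cat("<ld_test> G =", format(x$g_obs, digits = 4),
      "| p =", format(x$p, digits = 4))
  if (is.finite(x$se %||% NA)) cat(" (SE", format(x$se, digits = 3), ")")
  cat(" |", x$n, "individuals\n")
  invisible(x)
}
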