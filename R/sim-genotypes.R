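# Genotype-level simulation: diploid two-locus genotypes with tunable HWE
# deviation (inbreeding f) and inter-locus association (standardised D'),
# plus pedigree-structured populations with Mendelian inheritance.

genotype_prob_table <- function(freqs, f, allele_names) {
  k <- length(freqs)
  rows <- list()
  idx <- 1L
  for (i in seq_len(k)) {
    for (j in i:k) {
      p <- if (i == j) freqs[i]^2 + f * freqs[i] * (1 - freqs[i])
           else 2 * freqs[i] * freqs[j] * (1 - f)
      rows[[idx]] <- c(i, j, p)
      idx <- idx + 1L
    }
  }
  tab <- do.call(rbind, rows)
  if (any(tab[, 3] < -1e-12)) {
    stop("inbreeding_f infeasible for these allele frequencies", call. = FALSE)
  }
  tab[, 3] <- pmax(tab[, 3], 0)
  tab
}

# Haplotype probability matrix for two loci with standardised D' applied to
# the (allele 1, allele 1) pair; the compensation is spread proportionally so
# that both allele-frequency margins are preserved.
haplotype_prob_matrix <- function(pA, pB, d_prime) {
  H <- outer(pA, pB)
  if (d_prime != 0) {
    d_max <- if (d_prime > 0) min(pA[1] * (1 - pB[1]), (1 - pA[1]) * pB[1])
             else min(pA[1] * pB[1], (1 - pA[1]) * (1 - pB[1]))
    D <- d_prime * d_max
    H[1, 1] <- H[1, 1] + D
    H[1, -1] <- H[1, -1] - D * pB[-1] / (1 - pB[1])
    H[-1, 1] <- H[-1, 1] - D * pA[-1] / (1 - pA[1])
    H[-1, -1] <- H[-1, -1] + D * outer(pA[-1], pB[-1]) /
      ((1 - pA[1]) * (1 - pB[1]))
  }
  if (any(H < -1e-12)) {
    stop("ld_coefficient infeasible for these allele frequencies", call. = FALSE)
  }
  pmax(H, 0)
}

ind_ids <- function(n) sprintf("ind_%04d", seq_len(n))

#' Simulate diploid genotypes at the configured loci
#'
#' Genotype frequencies follow `p_i^2 + f p_i (1 - p_i)` for homozygotes and
#' `2 p_i p_j (1 - f)` for heterozygotes. With `ld_coefficient != 0` (and
#' `f = 0`) the first two loci are drawn as paired haplotypes whose
#' association is the standardised D' between the first allele of each locus;
#' with `ld_coefficient = 0` the loci are independent.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `individual_id`, `locus`, `allele_1`,
#'   `allele_2` (the true genotypes; this is also the truth table for
#'   downstream validation).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- ind_ids(n)
  loci <- config$loci
  out <- list()
  if (config$ld_coefficient != 0 && length(loci) >= 2) {
    la <- loci[[1]]; lb <- loci[[2]]
    H <- haplotype_prob_matrix(la$frequencies, lb$frequencies,
                               config$ld_coefficient)
    cells <- which(H >= 0, arr.ind = TRUE)
    pr <- H[cells]
    h1 <- sample.int(nrow(cells), n, replace = TRUE, prob = pr)
    h2 <- sample.int(nrow(cells), n, replace = TRUE, prob = pr)
    out[[names(loci)[1]]] <- tibble::tibble(
      individual_id = ids, locus = names(loci)[1],
      allele_1 = la$alleles$name[cells[h1, 1]],
      allele_2 = la$alleles$name[cells[h2, 1]])
    out[[names(loci)[2]]] <- tibble::tibble(
      individual_id = ids, locus = names(loci)[2],
      allele_1 = lb$alleles$name[cells[h1, 2]],
      allele_2 = lb$alleles$name[cells[h2, 2]])
    rest <- loci[-(1:2)]
  } else {
    rest <- loci
  }
  for (nm in names(rest)) {
    ld <- rest[[nm]]
    tab <- genotype_prob_table(ld$frequencies, config$inbreeding_f,
                               ld$alleles$name)
    g <- sample.int(nrow(tab), n, replace = TRUE, prob = tab[, 3])
    out[[nm]] <- tibble::tibble(
      individual_id = ids, locus = nm,
      allele_1 = ld$alleles$name[tab[g, 1]],
      allele_2 = ld$alleles$name[tab[g, 2]])
  }
  dplyr::arrange(dplyr::bind_rows(out[names(loci)]),
                 .data$individual_id, .data$locus)
}

#' Simulate a pedigree-structured population with Mendelian inheritance
#'
#' Founders receive genotypes from the configured allele frequencies; every
#' non-founder inherits exactly one allele from its recorded sire and one
#' from its recorded dam at each locus, so the pedigree is Mendelian by
#' construction.
#'
#' @param n_founders Number of founders (>= 2; even split of sexes).
#' @param n_generations Number of offspring generations to append.
#' @param seed Integer seed (defaults to the config seed).
#' @param config A [sim_config()] providing loci, frequencies and f.
#' @param n_offspring_per_gen Offspring produced per generation (default:
#'   `n_founders`).
#' @return List with `pedigree` (tibble: `individual_id`, `sire`, `dam`,
#'   `sex`, `generation`; founders have `NA` parents) and `genotypes`
#'   (truth-table tibble as in [simulate_genotypes()]).
#' @export
simulate_pedigree <- function(n_founders, n_generations, seed = NULL,
                              config = sim_config(),
                              n_offspring_per_gen = n_founders) {
  stopifnot(inherits(config, "sim_config"), n_founders >= 2,
            n_generations >= 0)
  set.seed(seed %||% config$seed)
  loci <- config$loci
  sex <- rep(c("M", "F"), length.out = n_founders)
  n_total <- n_founders + n_generations * n_offspring_per_gen
  ids <- ind_ids(n_total)
  ped <- tibble::tibble(individual_id = ids[seq_len(n_founders)],
                        sire = NA_character_, dam = NA_character_,
                        sex = sex, generation = 0L)
  geno <- list()
  for (nm in names(loci)) {
    ld <- loci[[nm]]
    tab <- genotype_prob_table(ld$frequencies, config$inbreeding_f,
                               ld$alleles$name)
    g <- sample.int(nrow(tab), n_founders, replace = TRUE, prob = tab[, 3])
    geno[[nm]] <- tibble::tibble(
      individual_id = ids[seq_len(n_founders)], locus = nm,
      allele_1 = ld$alleles$name[tab[g, 1]],
      allele_2 = ld$alleles$name[tab[g, 2]])
  }
  next_id <- n_founders + 1L
  for (gen in seq_len(n_generations)) {
    sires <- ped$individual_id[ped$sex == "M"]
    dams <- ped$individual_id[ped$sex == "F"]
    if (length(sires) == 0 || length(dams) == 0) {
      stop("pedigree needs at least one founder of each sex", call. = FALSE)
    }
    kid_ids <- ids[next_id:(next_id + n_offspring_per_gen - 1L)]
    next_id <- next_id + n_offspring_per_gen
    kid_sire <- sample(sires, n_offspring_per_gen, replace = TRUE)
    kid_dam <- sample(dams, n_offspring_per_gen, replace = TRUE)
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      individual_id = kid_ids, sire = kid_sire, dam = kid_dam,
      sex = sample(c("M", "F"), n_offspring_per_gen, replace = TRUE),
      generation = gen))
    for (nm in names(loci)) {
      gl <- geno[[nm]]
      sg <- gl[match(kid_sire, gl$individual_id), ]
      dg <- gl[match(kid_dam, gl$individual_id), ]
      from_sire <- ifelse(runif(n_offspring_per_gen) < 0.5,
                          sg$allele_1, sg$allele_2)
      from_dam <- ifelse(runif(n_offspring_per_gen) < 0.5,
                         dg$allele_1, dg$allele_2)
      geno[[nm]] <- dplyr::bind_rows(gl, tibble::tibble(
        individual_id = kid_ids, locus = nm,
        allele_1 = from_sire, allele_2 = from_dam))
    }
  }
  genotypes <- dplyr::arrange(dplyr::bind_rows(geno),
                              .data$individual_id, .data$locus)
  list(pedigree = ped, genotypes = genotypes)
}
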