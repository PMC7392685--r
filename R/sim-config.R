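#' Define an amplicon locus for simulation and filtering
#'
#' A locus bundles the primer pair, the post-trim amplicon length, an optional
#' in-frame exon subinterval (0-based, half-open, on the post-trim amplicon)
#' and the allele panel with its population frequencies.
#'
#' @param name Locus name (e.g. `"DRB"`).
#' @param alleles Tibble with columns `name`, `seq` (equal-length allele
#'   sequences, post-trim coordinates), as returned by
#'   [simulate_allele_panel()].
#' @param frequencies Numeric simplex vector, one frequency per allele (sums
#'   to 1 within 1e-9). Defaults to a geometric-decay spectrum resembling a
#'   polymorphic MHC locus.
#' @param fwd_primer,rev_primer Primer sequences (5'->3'; the reverse primer
#'   is given on the opposite strand, as ordered from a vendor).
#' @param min_len Minimum merged-read length retained by the length filter
#'   (applied before primer trimming; default 290 bp).
#' @param exon Optional `c(start, end)` 0-based half-open interval of the
#'   coding exon within the post-trim amplicon, used for translation and
#'   dN/dS. `NULL` means the whole amplicon is coding frame 0.
#' @return A `locus_def` list.
#' @export
locus_def <- function(name, alleles, frequencies = NULL,
                      fwd_primer, rev_primer,
                      min_len = 290, exon = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  stopifnot(is.data.frame(alleles), all(c("name", "seq") %in% names(alleles)))
  L <- unique(nchar(alleles$seq))
  if (length(L) != 1) stop("allele sequences must share one length", call. = FALSE)
  if (is.null(frequencies)) {
    r <- 0.78
    frequencies <- r^(seq_len(nrow(alleles)) - 1)
    frequencies <- frequencies / sum(frequencies)
  }
  if (length(frequencies) != nrow(alleles)) {
    stop("one frequency per allele required", call. = FALSE)
  }
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(frequencies < 0)) stop("allele frequencies must be >= 0", call. = FALSE)
  if (nchar(fwd_primer) == 0 || nchar(rev_primer) == 0) {
    stop("primers must be non-empty", call. = FALSE)
  }
  if (min_len <= nchar(fwd_primer) + nchar(rev_primer)) {
    stop("min_len must exceed the combined primer length", call. = FALSE)
  }
  if (!is.null(exon)) {
    stopifnot(length(exon) == 2, exon[1] >= 0, exon[2] <= L, exon[1] < exon[2])
  }
  structure(
    list(name = name, alleles = tibble::as_tibble(alleles[c("name", "seq")]),
         frequencies = as.numeric(frequencies),
         fwd_primer = toupper(fwd_primer), rev_primer = toupper(rev_primer),
         min_len = min_len, exon = exon),
    class = "locus_def"
  )
}

#' Default two-locus study design
#'
#' A classical, highly polymorphic class II locus ("DRB": 19 alleles of
#' 250 bp with 85 segregating sites, all coding) and a conserved
#' non-classical locus ("DOB": 11 alleles of 360 bp with 7 segregating
#' sites, containing a 270 bp exon) -- the allele-count/length/polymorphism
#' shape of a typical cervid MHC survey. Primer sequences are synthetic.
#'
#' @param seed Integer seed used to draw the allele panels.
#' @return Named list of two [locus_def()] objects.
#' @export
default_loci <- function(seed = 99L) {
  drb <- simulate_allele_panel(19, 250, 85, seed = seed, name_prefix = "DRB*")
  dob <- simulate_allele_panel(11, 360, 7, seed = seed + 1L, name_prefix = "DOB*")
  r <- 0.72
  fq_dob <- r^(0:10); fq_dob <- fq_dob / sum(fq_dob)
  list(
    DRB = locus_def("DRB", drb,
                    fwd_primer = "GATCAGCTGTCACTGTGACCACGTTTCCT",
                    rev_primer = "CACGGTGACAGTTGACTCGACGTTGCTT",
                    min_len = 290, exon = NULL),
    DOB = locus_def("DOB", dob, frequencies = fq_dob,
                    fwd_primer = "AAAGCCCTCCTCTCCAATCC",
                    rev_primer = "CCACCAAGGAGACCCCAAC",
                    min_len = 290, exon = c(45L, 315L))
  )
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic amplicon generator. The defaults
#' are the package's reference study conditions: mean filtered depth 20,000
#' reads per individual per locus, 0.1% per-base error, 2% chimeric reads in
#' heterozygotes, no allelic dropout, heterozygote allele balance
#' Beta(9, 9) (median top-two ratio approximately 58:42), plus small
#' short-read and singleton-noise channels.
#'
#' @param seed Integer master seed; identical seed + config reproduce
#'   bit-identical output.
#' @param n_individuals Number of diploid individuals.
#' @param loci Named list of [locus_def()] objects (default [default_loci()]).
#' @param inbreeding_f Within-locus HWE deviation f in `[-1, 1]`: homozygote
#'   genotype probability `p^2 + f p (1-p)`, heterozygote `2 p q (1-f)`.
#' @param ld_coefficient Standardised association D' in `[-1, 1]` between the
#'   first alleles of the first two loci (0 = independent loci). Cannot be
#'   combined with nonzero `inbreeding_f`.
#' @param depth_mean,depth_dispersion Negative-binomial read depth per
#'   individual per locus (mean and size).
#' @param het_balance_alpha_beta Beta shape pair for the pre-dropout share of
#'   the second allele in heterozygotes.
#' @param error_rate_per_base Per-base substitution error probability.
#' @param chimera_rate Probability that a heterozygote read is a single
#'   crossover chimera of the two true alleles.
#' @param dropout_alleles Named numeric vector of amplification-efficiency
#'   multipliers in (0, 1], keyed by allele name (e.g.
#'   `c("DRB*02" = 0.25)`). Unlisted alleles have multiplier 1.
#' @param short_read_rate Probability that a read is an undersized merge
#'   fragment (dropped by the length filter).
#' @param singleton_noise_rate Probability that a read is a heavily mutated
#'   singleton (2 substitutions, occurs once).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 200L,
                       loci = default_loci(),
                       inbreeding_f = 0,
                       ld_coefficient = 0,
                       depth_mean = 20000,
                       depth_dispersion = 10,
                       het_balance_alpha_beta = c(9, 9),
                       error_rate_per_base = 0.001,
                       chimera_rate = 0.02,
                       dropout_alleles = NULL,
                       short_read_rate = 0.02,
                       singleton_noise_rate = 0.005) {
  stopifnot(length(seed) == 1, is.finite(seed))
  stopifnot(n_individuals >= 1)
  if (!is.list(loci) || is.null(names(loci)) ||
      !all(vapply(loci, inherits, logical(1), "locus_def"))) {
    stop("`loci` must be a named list of locus_def objects", call. = FALSE)
  }
  stopifnot(inbreeding_f >= -1, inbreeding_f <= 1)
  stopifnot(ld_coefficient >= -1, ld_coefficient <= 1)
  if (inbreeding_f != 0 && ld_coefficient != 0) {
    stop("inbreeding_f and ld_coefficient cannot both be nonzero", call. = FALSE)
  }
  stopifnot(depth_mean > 0, depth_dispersion > 0)
  stopifnot(length(het_balance_alpha_beta) == 2, all(het_balance_alpha_beta > 0))
  probs <- c(error_rate_per_base, chimera_rate, short_read_rate,
             singleton_noise_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  if (!is.null(dropout_alleles)) {
    stopifnot(is.numeric(dropout_alleles), !is.null(names(dropout_alleles)),
              all(dropout_alleles > 0), all(dropout_alleles <= 1))
  }
  structure(
    list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
         loci = loci, inbreeding_f = inbreeding_f,
         ld_coefficient = ld_coefficient, depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         het_balance_alpha_beta = het_balance_alpha_beta,
         error_rate_per_base = error_rate_per_base,
         chimera_rate = chimera_rate,
         dropout_alleles = dropout_alleles,
         short_read_rate = short_read_rate,
         singleton_noise_rate = singleton_noise_rate),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_individuals, "individuals;",
      length(x$loci), "loci:", paste(names(x$loci), collapse = ", "), "\n")
  cat("  depth NB(mean =", x$depth_mean, ", size =", x$depth_dispersion, ")\n")
  cat("  error/base =", x$error_rate_per_base,
      " chimera =", x$chimera_rate,
      " short =", x$short_read_rate,
      " singleton-noise =", x$singleton_noise_rate, "\n")
  cat("  f =", x$inbreeding_f, " D' =", x$ld_coefficient,
      " het balance Beta(", paste(x$het_balance_alpha_beta, collapse = ", "),
      ")\n")
  if (!is.null(x$dropout_alleles)) {
    cat("  dropout:", paste(names(x$dropout_alleles), "=",
                            x$dropout_alleles, collapse = "; "), "\n")
  }
  invisible(x)
}
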