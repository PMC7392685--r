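# Amplicon read simulation. Reads are generated as per-individual tallies of
# distinct merged-read sequences (sequence, count, provenance) rather than as
# individual records: every downstream stage consumes tallies, and
# write_reads_fastq() expands them to standard 4-line FASTQ records on demand.

amplicon_seq <- function(locus, allele_seq) {
  paste0(locus$fwd_primer, allele_seq, dna_revcomp(locus$rev_primer))
}

# One individual x locus read tally; returns tibble(seq, count, provenance).
sim_reads_one <- function(locus, alleles, config) {
  amps <- vapply(alleles, function(a) {
    amplicon_seq(locus, locus$alleles$seq[match(a, locus$alleles$name)])
  }, character(1))
  if (anyNA(match(alleles, locus$alleles$name))) {
    stop("genotype allele missing from the locus panel", call. = FALSE)
  }
  L <- nchar(amps[1])
  het <- alleles[1] != alleles[2]
  depth <- max(1L, rnbinom(1, mu = config$depth_mean,
                           size = config$depth_dispersion))
  parts <- list()
  # short merge fragments (dropped later by the length filter)
  n_short <- rbinom(1, depth, config$short_read_rate)
  if (n_short > 0) {
    lens <- sample(seq(max(30L, locus$min_len %/% 4), locus$min_len - 1L),
                   n_short, replace = TRUE)
    tab <- table(lens)
    parts$short <- tibble::tibble(
      seq = substr(rep(amps[1], length(tab)), 1, as.integer(names(tab))),
      count = as.integer(tab), provenance = "short")
  }
  rem <- depth - n_short
  # Single-crossover PCR chimeras of the two true alleles (heterozygotes).
  # Crossover points are uniform over the breakpoints that yield a sequence
  # distinct from both parents (a crossover outside the distinguishing
  # interval regenerates a parent molecule and is unobservable); alleles
  # differing at fewer than 2 positions admit no chimera.
  diffs <- if (het) which(strsplit(amps[1], "", fixed = TRUE)[[1]] !=
                            strsplit(amps[2], "", fixed = TRUE)[[1]])
           else integer(0)
  n_chim <- if (length(diffs) >= 2) rbinom(1, rem, config$chimera_rate)
            else 0L
  rem <- rem - n_chim
  if (n_chim > 0) {
    breaks <- diffs[1]:(diffs[length(diffs)] - 1L)
    dir <- sample(1:2, n_chim, replace = TRUE)
    brk <- breaks[sample.int(length(breaks), n_chim, replace = TRUE)]
    key <- paste(dir, brk)
    tab <- table(key)
    ks <- strsplit(names(tab), " ", fixed = TRUE)
    chim_seq <- vapply(ks, function(k) {
      d <- as.integer(k[1]); b <- as.integer(k[2])
      a <- amps[d]; bb <- amps[3 - d]
      paste0(substr(a, 1, b), substr(bb, b + 1, L))
    }, character(1))
    parts$chimera <- tibble::tibble(seq = chim_seq, count = as.integer(tab),
                                    provenance = "chimera")
  }
  # heavily mutated singleton reads (2 substitutions each, occur once)
  n_noise <- rbinom(1, rem, config$singleton_noise_rate)
  rem <- rem - n_noise
  if (n_noise > 0) {
    src <- amps[sample(1:2, n_noise, replace = TRUE)]
    for (k in 1:2) {
      pos <- sample.int(L, n_noise, replace = TRUE)
      cur <- substr(src, pos, pos)
      alt <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1), USE.NAMES = FALSE)
      src <- substitute_base(src, pos, alt)
    }
    parts$noise <- tibble::tibble(seq = src, count = 1L, provenance = "error")
  }
  # true-allele reads with dropout-scaled heterozygote balance
  mult <- function(a) {
    m <- config$dropout_alleles[a]
    if (is.null(config$dropout_alleles) || is.na(m)) 1 else unname(m)
  }
  if (het) {
    w <- rbeta(1, config$het_balance_alpha_beta[1],
               config$het_balance_alpha_beta[2])
    m1 <- mult(alleles[1]); m2 <- mult(alleles[2])
    w2 <- m2 * w / (m1 * (1 - w) + m2 * w)
    n2 <- rbinom(1, rem, w2)
    n_true <- c(rem - n2, n2)
  } else {
    n_true <- c(rem, 0L)
  }
  p_read_err <- 1 - (1 - config$error_rate_per_base)^L
  for (i in 1:2) {
    if (n_true[i] == 0) next
    n_err <- rbinom(1, n_true[i], p_read_err)
    if (n_true[i] - n_err > 0) {
      parts[[paste0("true", i)]] <- tibble::tibble(
        seq = amps[i], count = n_true[i] - n_err, provenance = "true_allele")
    }
    if (n_err > 0) {
      v <- sample.int(3L * L, n_err, replace = TRUE)
      tab <- table(v)
      vi <- as.integer(names(tab))
      pos <- (vi - 1L) %/% 3L + 1L
      off <- (vi - 1L) %% 3L + 1L
      cur <- substr(rep(amps[i], length(vi)), pos, pos)
      alt <- vapply(seq_along(vi), function(j) {
        setdiff(DNA_BASES, cur[j])[off[j]]
      }, character(1))
      parts[[paste0("err", i)]] <- tibble::tibble(
        seq = substitute_base(rep(amps[i], length(vi)), pos, alt),
        count = as.integer(tab), provenance = "error")
    }
  }
  out <- dplyr::bind_rows(parts)
  out <- dplyr::summarise(dplyr::group_by(out, .data$seq, .data$provenance),
                          count = sum(.data$count), .groups = "drop")
  out
}

#' Simulate per-individual amplicon read tallies
#'
#' Generates, for every individual and locus in `sample`, a negative-binomial
#' read depth partitioned into true-allele reads (heterozygote balance drawn
#' from the configured Beta distribution and scaled by any allelic-dropout
#' efficiency multipliers), single-crossover chimeras of the individual's two
#' alleles, per-base substitution errors, heavily mutated singleton reads,
#' and undersized merge fragments. Per-read provenance is recorded so every
#' downstream stage can be scored against truth.
#'
#' @param sample Genotype tibble from [simulate_genotypes()] or
#'   [simulate_pedigree()].
#' @param config The [sim_config()] used to generate `sample`.
#' @param seed Seed for the read-level randomness (defaults to
#'   `config$seed + 1`).
#' @return Tibble with columns `individual_id`, `locus`, `seq`, `count`,
#'   `provenance` (`true_allele`, `error`, `chimera`, `short`). Per
#'   individual and locus, counts sum to the simulated depth.
#' @export
simulate_reads <- function(sample, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(c("individual_id", "locus", "allele_1", "allele_2") %in%
                  names(sample)))
  set.seed(seed %||% (config$seed + 1L))
  sample <- dplyr::arrange(sample, .data$individual_id, .data$locus)
  out <- vector("list", nrow(sample))
  for (r in seq_len(nrow(sample))) {
    locus <- config$loci[[sample$locus[r]]]
    if (is.null(locus)) {
      stop("locus ", sample$locus[r], " not present in config", call. = FALSE)
    }
    tal <- sim_reads_one(locus, c(sample$allele_1[r], sample$allele_2[r]),
                         config)
    tal$individual_id <- sample$individual_id[r]
    tal$locus <- sample$locus[r]
    out[[r]] <- tal
  }
  dplyr::select(dplyr::bind_rows(out), "individual_id", "locus", "seq",
                "count", "provenance")
}

#' Write read tallies as per-individual FASTQ files
#'
#' Expands a read tally into standard 4-line FASTQ records (constant Q37
#' quality placeholder; base qualities are unused after merging) with the
#' read provenance kept in the header description.
#'
#' @param reads Tally tibble from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (one file per individual x locus).
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- dplyr::group_split(reads, .data$individual_id, .data$locus)
  paths <- character(0)
  for (g in groups) {
    path <- file.path(dir, paste0(g$individual_id[1], "_", g$locus[1],
                                  ".fastq"))
    seqs <- rep(g$seq, g$count)
    prov <- rep(g$provenance, g$count)
    ids <- sprintf("@%s_%s_read%06d %s", g$individual_id[1], g$locus[1],
                   seq_along(seqs), prov)
    qual <- vapply(nchar(seqs), function(n) strrep("F", n), character(1))
    writeLines(rbind(ids, seqs, "+", qual), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read merged amplicon reads from FASTQ/FASTA into a tally tibble
#'
#' @param path FASTQ or FASTA file of merged reads for one individual.
#' @param individual_id,locus Labels attached to the tally.
#' @return Tibble with `individual_id`, `locus`, `seq`, `count`.
#' @export
read_merged_reads <- function(path, individual_id = NA_character_,
                              locus = NA_character_) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  tab <- table(as.character(ss))
  tibble::tibble(individual_id = individual_id, locus = locus,
                 seq = names(tab), count = as.integer(tab))
}
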