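# End-to-end pipeline: simulate -> filter -> genotype -> stats -> tests,
# plus exon extraction and FASTA/CSV round-trip helpers.

#' Extract an exon subinterval from an aligned panel and collapse
#'
#' Cuts a 0-based, half-open column interval out of every (aligned)
#' sequence, then merges alleles whose subsequences are identical. Merged
#' alleles are renamed by concatenating their serial numbers (e.g. alleles
#' `*01`, `*02`, `*11` sharing one exon become `*010211_exon`), mirroring
#' the usual nomenclature for extended sequences that share an exon.
#'
#' @param panel An [aligned_panel()] (alignment coordinates).
#' @param interval `c(start, end)`, 0-based half-open, within the alignment.
#' @param suffix Suffix appended to collapsed names (default `"_exon"`).
#' @return List with `panel` (collapsed exon panel, multiplicities summed)
#'   and `name_map` (tibble `name`, `exon_name`).
#' @export
extract_exon <- function(panel, interval, suffix = "_exon") {
  panel <- aligned_panel(panel)
  L <- nchar(panel$seq[1])
  if (interval[1] < 0 || interval[2] > L || interval[1] >= interval[2]) {
    stop("exon interval out of bounds", call. = FALSE)
  }
  sub <- substr(panel$seq, interval[1] + 1L, interval[2])
  groups <- split(seq_len(nrow(panel)), sub)
  serial_of <- function(nm) {
    s <- regmatches(nm, regexpr("[0-9]+$", nm))
    if (length(s) == 0) nm else s
  }
  rows <- lapply(groups, function(idx) {
    idx <- sort(idx)
    nms <- panel$name[idx]
    new_name <- if (length(idx) == 1) paste0(nms, suffix) else {
      pref <- sub("[0-9]+$", "", nms[1])
      paste0(pref, paste(vapply(nms, serial_of, character(1)),
                         collapse = ""), suffix)
    }
    tibble::tibble(name = new_name, seq = sub[idx[1]],
                   mult = sum(panel$mult[idx]), first = idx[1],
                   members = list(nms))
  })
  tab <- dplyr::arrange(dplyr::bind_rows(rows), .data$first)
  name_map <- tibble::tibble(
    name = unlist(tab$members),
    exon_name = rep(tab$name, lengths(tab$members)))
  list(panel = aligned_panel(tab[c("name", "seq", "mult")]),
       name_map = name_map)
}

#' Write / read an allele panel as FASTA
#'
#' @param panel Tibble with `name`, `seq`.
#' @param path FASTA file path.
#' @return `write_panel_fasta`: the path, invisibly. `read_panel_fasta`:
#'   a tibble `name`, `seq`.
#' @export
write_panel_fasta <- function(panel, path) {
  ss <- Biostrings::DNAStringSet(setNames(gsub("-", "", panel$seq), panel$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(name = names(ss), seq = unname(as.character(ss)))
}

#' Run the full genotyping and population-genetics pipeline
#'
#' Simulates a (by default pedigree-structured) population under `config`,
#' generates amplicon read tallies, applies the post-merge filters, calls
#' genotypes by ratio thresholds, screens lower-ranked variants for
#' chimeras, resolves ambiguous calls with the validated panel and
#' pedigree, applies the minimum-allele-frequency filter, assigns
#' nomenclature against the simulated reference panel, and computes
#' frequency tables, diversity and neutrality statistics, dN/dS, exact HWE
#' tests per locus and the between-locus LD test. Identical seeds
#' reproduce the report bit-for-bit.
#'
#' @param config A [sim_config()].
#' @param use_pedigree Simulate founders plus one offspring generation and
#'   use the pedigree for resolution/validation (default TRUE).
#' @param settings [mcmc_settings()] for the exact tests.
#' @param significance Compute simulation-based significance bands for the
#'   Fu & Li statistics (slower; default FALSE).
#' @param out_dir Optional directory to write CSV/FASTA artifacts into.
#' @return An `mhc_report` list: `truth`, `pedigree`, `calls`, `variants`
#'   (stage log attached), `chimera_screen`, `panels`, `frequencies`,
#'   `diversity`, `neutrality`, `dnds`, `hwe`, `ld`, `mendelian`,
#'   `recovery` (per-locus fraction of calls matching truth).
#' @export
run_pipeline <- function(config, use_pedigree = TRUE,
                         settings = mcmc_settings(seed = config$seed),
                         significance = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  if (use_pedigree) {
    n_founders <- max(2L, n %/% 2L)
    ped <- simulate_pedigree(n_founders, 1L, seed = config$seed,
                             config = config,
                             n_offspring_per_gen = n - n_founders)
    truth <- ped$genotypes
    pedigree <- ped$pedigree
  } else {
    truth <- simulate_genotypes(config)
    pedigree <- NULL
  }
  reads <- simulate_reads(truth, config)
  variants_all <- list(); calls_all <- list(); screens <- list()
  panels <- list(); freq_in <- list(); divs <- list(); neut <- list()
  dnds <- list(); hwe <- list(); excluded <- list()
  for (nm in names(config$loci)) {
    locus <- config$loci[[nm]]
    variants <- filter_merged_reads(reads[reads$locus == nm, ],
                                    locus$fwd_primer, locus$rev_primer,
                                    min_len = locus$min_len)
    calls <- call_genotypes(variants)
    screen <- screen_chimeras(variants)
    panel0 <- build_allele_panel(calls)
    calls <- resolve_ambiguous(calls, variants, panel0, pedigree = pedigree)
    panel <- build_allele_panel(calls)
    maf <- apply_maf_filter(panel, calls)
    named <- assign_nomenclature(maf$panel, known_alleles = locus$alleles)
    # attach names to calls; drop excluded individuals
    calls$allele_1 <- named$name[match(calls$seq_1, named$seq)]
    calls$allele_2 <- named$name[match(calls$seq_2, named$seq)]
    calls <- calls[!calls$individual_id %in% maf$excluded_individuals, ]
    res <- calls[calls$status %in% c("homozygote", "heterozygote") &
                   !is.na(calls$allele_1) & !is.na(calls$allele_2), ]
    ap <- aligned_panel(tibble::tibble(name = named$name, seq = named$seq,
                                       mult = pmax(1L, named$copies)),
                        locus = nm)
    divs[[nm]] <- dplyr::bind_cols(tibble::tibble(locus = nm), diversity(ap))
    neut[[nm]] <- dplyr::bind_cols(tibble::tibble(locus = nm),
                                   neutrality_tests(ap,
                                                    significance = significance,
                                                    seed = config$seed))
    coding <- if (!is.null(locus$exon)) {
      extract_exon(ap, locus$exon)$panel
    } else ap
    dnds[[nm]] <- dplyr::bind_cols(tibble::tibble(locus = nm),
                                   panel_dnds(coding))
    arr <- genotype_array(res, locus = nm)
    hwe[[nm]] <- list(probability = hwe_probability_test(arr, settings),
                      excess = hwe_score_tests(arr, settings, "excess"),
                      deficit = hwe_score_tests(arr, settings, "deficit"))
    variants_all[[nm]] <- variants
    calls_all[[nm]] <- calls
    screens[[nm]] <- screen
    panels[[nm]] <- named
    excluded[[nm]] <- maf$excluded_individuals
    freq_in[[nm]] <- res
  }
  calls <- dplyr::bind_rows(calls_all)
  res_all <- dplyr::bind_rows(freq_in)
  freq <- frequencies(res_all)
  ld <- if (length(config$loci) >= 2) {
    ld_genotypic_test(res_all, names(config$loci)[1], names(config$loci)[2],
                      settings = settings)
  } else NULL
  mendel <- if (!is.null(pedigree)) {
    mendelian_consistency(res_all, pedigree)
  } else NULL
  # per-locus recovery against truth (unordered allele pairs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rec <- dplyr::inner_join(
    dplyr::select(calls, "individual_id", "locus",
                  c1 = "allele_1", c2 = "allele_2", "status"),
    dplyr::select(truth, "individual_id", "locus",
                  t1 = "allele_1", t2 = "allele_2"),
    by = c("individual_id", "locus"))
  rec$match <- !is.na(rec$c1) & !is.na(rec$c2) &
    rec$status %in% c("homozygote", "heterozygote") &
    key(rec$c1, rec$c2) == key(rec$t1, rec$t2)
  recovery <- dplyr::summarise(dplyr::group_by(rec, .data$locus),
                               n = dplyr::n(), recovered = mean(.data$match),
                               .groups = "drop")
  report <- structure(
    list(config = config, truth = truth, pedigree = pedigree,
         variants = dplyr::bind_rows(variants_all), calls = calls,
         chimera_screen = dplyr::bind_rows(screens), panels = panels,
         excluded_individuals = excluded, frequencies = freq,
         diversity = dplyr::bind_rows(divs),
         neutrality = dplyr::bind_rows(neut), dnds = dplyr::bind_rows(dnds),
         hwe = hwe, ld = ld, mendelian = mendel, recovery = recovery),
    class = "mhc_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mhc_report <- function(x, ...) {
  cat("<mhc_report>", x$config$n_individuals, "individuals,",
      length(x$panels), "loci\n\nDiversity:\n")
  print(x$diversity)
  cat("\nNeutrality:\n"); print(x$neutrality)
  cat("\ndN/dS:\n"); print(x$dnds)
  for (nm in names(x$hwe)) {
    h <- x$hwe[[nm]]
    cat("\nHWE ", nm, ": probability p = ", format(h$probability$p, digits = 3),
        ", excess p = ", format(h$excess$p, digits = 3),
        ", deficit p = ", format(h$deficit$p, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$ld)) {
    cat("\nLD: G =", format(x$ld$g_obs, digits = 4),
        "p =", format(x$ld$p, digits = 3), "\n")
  }
  if (!is.null(x$mendelian)) {
    cat("Mendelian consistency:",
        format(100 * x$mendelian$fraction, digits = 4), "%\n")
  }
  cat("Genotype recovery:\n"); print(x$recovery)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$calls, file.path(out_dir, "genotype_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(report$variants, file.path(out_dir, "ranked_variants.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(report$variants, "stages") %||%
                     tibble::tibble(),
                   file.path(out_dir, "filter_stages.csv"),
                   row.names = FALSE)
  utils::write.csv(report$diversity, file.path(out_dir, "diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(report$neutrality, file.path(out_dir, "neutrality.csv"),
                   row.names = FALSE)
  utils::write.csv(report$frequencies$alleles,
                   file.path(out_dir, "allele_frequencies.csv"),
                   row.names = FALSE)
  for (nm in names(report$panels)) {
    write_panel_fasta(report$panels[[nm]],
                      file.path(out_dir, paste0("panel_", nm, ".fasta")))
  }
  invisible(out_dir)
}
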