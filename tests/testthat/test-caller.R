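rv <- function(counts, seqs = NULL) {
  seqs <- seqs %||% paste0("SEQ", seq_along(counts))
  tibble::tibble(individual_id = "i1", locus = "L",
                 rank = seq_along(counts), seq = seqs,
                 count = as.integer(counts))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("ratio thresholds reproduce the calling bands", {
  hom <- call_genotypes(rv(c(9900, 100)))
  expect_equal(hom$status, "homozygote")
  expect_equal(hom$top2_ratio, 0.01)
  expect_equal(hom$seq_2, hom$seq_1)

  het <- call_genotypes(rv(c(580, 420)))
  expect_equal(het$status, "heterozygote")
  expect_equal(het$top2_ratio, 0.42)

  amb <- call_genotypes(rv(c(800, 200)))
  expect_equal(amb$status, "ambiguous")
  expect_equal(amb$top2_ratio, 0.2)
  expect_true(is.na(amb$seq_2)) # no second allele until resolved

  single <- call_genotypes(rv(5000))
  expect_equal(single$status, "homozygote")

  # an individual whose reads were all filtered away yields an unresolved
  # call; a fully empty table yields an empty (typed) result
  zero <- call_genotypes(rv(0L, seqs = "AAAA"))
  expect_equal(zero$status, "unresolved")
  empty <- call_genotypes(rv(integer(0), seqs = character(0)))
  expect_equal(nrow(empty), 0L)
  expect_true("status" %in% names(empty))

  # band edges: 0.10 is ambiguous (homozygote is strictly below 10%),
  # 0.35 is heterozygote (50:50 to 65:35 inclusive)
  expect_equal(call_genotypes(rv(c(900, 100)))$status, "ambiguous")
  expect_equal(call_genotypes(rv(c(650, 350)))$status, "heterozygote")
})

test_that("classification is invariant to rescaling counts", {
  for (cts in list(c(9900, 100), c(580, 420), c(800, 200))) {
    a <- call_genotypes(rv(cts))
    b <- call_genotypes(rv(cts * 7L))
    expect_equal(a$status, b$status)
    expect_equal(a$top2_ratio, b$top2_ratio)
  }
})

test_that("chimera detection finds single crossovers and only those", {
  r <- detect_chimera("ACGTTGCA", "ACGTACGT", "TGCATGCA")
  expect_true(r$is_chimera)
  expect_equal(r$intervals$first_parent, "a")
  expect_equal(r$intervals$from, 4L)
  expect_equal(r$intervals$to, 4L)

  # a base present in neither parent at that site cannot be a chimera
  expect_false(detect_chimera("ACCTACGT", "ACGTACGT", "ACTTACGT")$is_chimera)

  # symmetric in the parents
  r2 <- detect_chimera("ACGTTGCA", "TGCATGCA", "ACGTACGT")
  expect_true(r2$is_chimera)

  # a parent itself is a precondition violation, never flagged
  expect_error(detect_chimera("ACGTACGT", "ACGTACGT", "TGCATGCA"),
               "differ")
  expect_error(detect_chimera("ACGT", "ACGTA", "ACGTC"), "length")
})

test_that("ambiguous calls resolve through panel, pedigree and chimera", {
  panel <- tibble::tibble(seq = c("AAAA", "CCCC", "GGGG"), validated = TRUE)
  # parents both carry CCCC -> upgrade to heterozygote via pedigree
  variants <- dplyr::bind_rows(
    tibble::tibble(individual_id = "kid", locus = "L", rank = 1:2,
                   seq = c("AAAA", "CCCC"), count = c(800L, 200L)),
    tibble::tibble(individual_id = c("pa", "ma"), locus = "L", rank = 1L,
                   seq = c("AAAA", "CCCC"), count = 900L))
  calls <- call_genotypes(variants)
  ped <- tibble::tibble(individual_id = "kid", sire = "pa", dam = "ma")
  out <- resolve_ambiguous(calls, variants, panel, pedigree = ped)
  kid <- out[out$individual_id == "kid", ]
  expect_equal(kid$status, "heterozygote")
  expect_equal(kid$seq_2, "CCCC")
  expect_equal(kid$resolution_source, "pedigree")

  # second sequence is a chimera of top sequence and a panel allele ->
  # homozygote
  v2 <- tibble::tibble(individual_id = "x", locus = "L", rank = 1:2,
                       seq = c("AACC", "AAGG"), count = c(800L, 200L))
  p2 <- tibble::tibble(seq = c("AACC", "TTGG"), validated = TRUE)
  out2 <- resolve_ambiguous(call_genotypes(v2), v2, p2)
  expect_equal(out2$status, "homozygote")
  expect_equal(out2$seq_2, out2$seq_1)

  # a validated panel member with no pedigree constraint upgrades
  v3 <- tibble::tibble(individual_id = "y", locus = "L", rank = 1:2,
                       seq = c("AAAA", "CCCC"), count = c(800L, 200L))
  out3 <- resolve_ambiguous(call_genotypes(v3), v3, panel)
  expect_equal(out3$status, "heterozygote")
  expect_equal(out3$resolution_source, "pedigree")

  # an unknown, non-chimeric second sequence with no confirming data stays
  # unresolved
  v3b <- tibble::tibble(individual_id = "z", locus = "L", rank = 1:2,
                        seq = c("AAAA", "TTTT"), count = c(800L, 200L))
  out3b <- resolve_ambiguous(call_genotypes(v3b), v3b, panel)
  expect_equal(out3b$status, "unresolved")

  # pedigree contradiction blocks the upgrade -> unresolved
  ped_bad <- tibble::tibble(individual_id = "kid", sire = "pa", dam = "pa2")
  variants_bad <- dplyr::bind_rows(
    variants[variants$individual_id != "ma", ],
    tibble::tibble(individual_id = "pa2", locus = "L", rank = 1L,
                   seq = "GGGG", count = 900L))
  calls_bad <- call_genotypes(variants_bad)
  out4 <- resolve_ambiguous(calls_bad, variants_bad, panel,
                            pedigree = ped_bad)
  expect_equal(out4$status[out4$individual_id == "kid"], "unresolved")

  # external validation flag covers the individual -> heterozygote
  out5 <- resolve_ambiguous(calls, variants, panel, external = "kid")
  expect_equal(out5$status[out5$individual_id == "kid"], "heterozygote")
  expect_equal(out5$resolution_source[out5$individual_id == "kid"],
               "external")
})

test_that("the MAF threshold and filter follow 5/(2n)", {
  expect_equal(round(100 * maf_threshold(375), 2), 0.67)
  expect_equal(round(100 * maf_threshold(380), 2), 0.66)

  # an allele seen once in 375 individuals is removed unless validated
  panel <- tibble::tibble(
    seq = c("AAAA", "CCCC", "GGGG"),
    validated = c(TRUE, FALSE, TRUE),
    copies = c(748L, 1L, 1L),
    frequency = c(748, 1, 1) / 750)
  calls <- tibble::tibble(
    individual_id = c(paste0("i", 1:375)),
    locus = "L",
    seq_1 = c(rep("AAAA", 373), "CCCC", "GGGG"),
    seq_2 = c(rep("AAAA", 375)),
    status = "heterozygote", top2_ratio = 0.4,
    resolution_source = "ratio")
  out <- apply_maf_filter(panel, calls, n_individuals = 375)
  expect_equal(out$threshold, 5 / 750)
  expect_equal(out$removed_alleles, "CCCC")
  expect_equal(out$excluded_individuals, "i374")
  expect_true("GGGG" %in% out$panel$seq) # validated allele retained

  # idempotent
  again <- apply_maf_filter(out$panel, calls, n_individuals = 375)
  expect_identical(as.data.frame(again$panel), as.data.frame(out$panel))
  expect_equal(length(again$removed_alleles), 0L)
})

test_that("nomenclature reuses known names and continues the serials", {
  known <- tibble::tibble(name = paste0("DRB*", formatC(1:18, width = 2,
                                                        flag = "0")),
                          seq = paste0("KNOWN", 1:18))
  panel <- tibble::tibble(seq = c("KNOWN5", paste0("NOVEL", 1:12)))
  named <- assign_nomenclature(panel, known)
  expect_equal(named$name[1], "DRB*05")
  expect_equal(named$name[-1], paste0("DRB*", 19:30))

  # duplicate names in the known panel are an explicit error
  bad <- tibble::tibble(name = c("X*01", "X*01"), seq = c("AA", "CC"))
  expect_error(assign_nomenclature(panel, bad), "duplicate")
})

test_that("mendelian consistency uses a bipartite parent assignment", {
  ped <- tibble::tibble(individual_id = "kid", sire = "pa", dam = "ma")
  gt <- function(kid, pa, ma) {
    tibble::tibble(
      individual_id = c("kid", "pa", "ma"), locus = "L",
      allele_1 = c(kid[1], pa[1], ma[1]),
      allele_2 = c(kid[2], pa[2], ma[2]))
  }
  # AB x CD offspring AC: consistent
  expect_true(mendelian_consistency(gt(c("A", "C"), c("A", "B"),
                                       c("C", "D")), ped)$flags$consistent)
  # AA x BB offspring AB consistent; AA not (B side has no A)
  expect_true(mendelian_consistency(gt(c("A", "B"), c("A", "A"),
                                       c("B", "B")), ped)$flags$consistent)
  expect_false(mendelian_consistency(gt(c("A", "A"), c("A", "A"),
                                        c("B", "B")), ped)$flags$consistent)
  # AB x AB offspring AA: consistent (an A from each parent)
  expect_true(mendelian_consistency(gt(c("A", "A"), c("A", "B"),
                                       c("A", "B")), ped)$flags$consistent)
  # cyclic pedigree is an explicit error
  cyc <- tibble::tibble(individual_id = c("a", "b"), sire = c("b", "a"),
                        dam = NA_character_)
  g <- tibble::tibble(individual_id = c("a", "b"), locus = "L",
                      allele_1 = "A", allele_2 = "A")
  expect_error(mendelian_consistency(g, cyc), "cyclic")
})

test_that("noiseless synthetic data is recovered perfectly end to end", {
  al <- simulate_allele_panel(4, 60, 8, seed = 8, name_prefix = "A*")
  loci <- list(A = locus_def("A", al, frequencies = rep(0.25, 4),
                             fwd_primer = "ACGTACGTAC",
                             rev_primer = "TTGCAGGTCA", min_len = 40))
  cfg <- sim_config(seed = 13, n_individuals = 40, loci = loci,
                    depth_mean = 500, error_rate_per_base = 0,
                    chimera_rate = 0, short_read_rate = 0,
                    singleton_noise_rate = 0,
                    het_balance_alpha_beta = c(5000, 5000))
  g <- simulate_genotypes(cfg)
  reads <- simulate_reads(g, cfg)
  v <- filter_merged_reads(reads, loci$A$fwd_primer, loci$A$rev_primer,
                           min_len = 40)
  calls <- call_genotypes(v)
  named <- assign_nomenclature(build_allele_panel(calls), al)
  calls$allele_1 <- named$name[match(calls$seq_1, named$seq)]
  calls$allele_2 <- named$name[match(calls$seq_2, named$seq)]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- merge(calls, g, by = c("individual_id", "locus"))
  expect_true(all(key(m$allele_1.x, m$allele_2.x) ==
                    key(m$allele_1.y, m$allele_2.y)))
})
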