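test_that("segregating sites and pairwise differences on small panels", {
  expect_equal(as.integer(segregating_sites(aligned_panel(
    c(a = "ACGT", b = "ACGT", c = "ACGT")))), 0L)
  s <- segregating_sites(aligned_panel(c(a = "ACGT", b = "ACGA",
                                         c = "ACCA")))
  expect_equal(as.integer(s), 2L)
  expect_equal(attr(s, "sites"), c(3L, 4L))

  expect_equal(as.numeric(pairwise_differences(aligned_panel(
    c(a = "ACGT", b = "ACGT")))), 0)
  expect_equal(as.numeric(pairwise_differences(aligned_panel(
    c(a = "ACGT", b = "AGGT")))), 1)
  expect_equal(as.numeric(pairwise_differences(aligned_panel(
    c(a = "ACGT", b = "ACGA", c = "ACCA")))), 4 / 3)
})

test_that("diversity follows the closed forms", {
  d0 <- diversity(aligned_panel(c(a = "ACGT", b = "ACGT")))
  expect_equal(d0$pi, 0)
  expect_equal(d0$hd, 0)

  d1 <- diversity(aligned_panel(c(a = "ACGT", b = "ACGA")))
  expect_equal(d1$hd, 1) # (2/1)(1 - 0.5)

  d2 <- diversity(aligned_panel(c(a = "ACGT", b = "ACGA"), mult = c(3, 1)))
  expect_equal(d2$hd, 0.5) # (4/3)(1 - 9/16 - 1/16)
  expect_equal(d2$n, 4L)
})

test_that("pi * L = k under identical gap handling, gaps excluded", {
  p <- aligned_panel(c(a = "AC-GTT", b = "AC-GAT", c = "ACTGAA"),
                     mult = c(2, 1, 3))
  d <- diversity(p)
  expect_equal(d$pi * d$L, d$k)
  expect_equal(d$L, 5L) # the gap column is excluded for everyone
})

test_that("S ignores multiplicities while k, hd respond", {
  base <- c(a = "ACGT", b = "ACGA", c = "ACCA")
  p1 <- aligned_panel(base)
  p2 <- aligned_panel(base, mult = c(5, 2, 1))
  expect_equal(as.integer(segregating_sites(p1)),
               as.integer(segregating_sites(p2)))
  expect_false(isTRUE(all.equal(as.numeric(pairwise_differences(p1)),
                                as.numeric(pairwise_differences(p2)))))
  expect_false(isTRUE(all.equal(diversity(p1)$hd, diversity(p2)$hd)))
})

test_that("translation collapses synonymous variants", {
  # third-position synonymous change: one protein allele
  p <- aligned_panel(c(x = "GGGACT", y = "GGAACT"))
  tc <- translate_and_collapse(p)
  expect_equal(nrow(tc$proteins), 1L)
  expect_equal(tc$proteins$mult, 2L)
  expect_equal(unique(tc$collapse_map$protein), "GT")

  # nonsynonymous change: two proteins
  p2 <- aligned_panel(c(x = "GGGACT", y = "GTGACT"))
  expect_equal(nrow(translate_and_collapse(p2)$proteins), 2L)

  # internal stop flagged but retained
  p3 <- aligned_panel(c(x = "TAAACT", y = "GGGACT"))
  expect_warning(tc3 <- translate_and_collapse(p3), "stop")
  expect_equal(nrow(tc3$proteins), 2L)

  # in-frame 3-bp deletion tolerated; frame-breaking gaps are an error
  p4 <- aligned_panel(c(x = "GGG---ACT", y = "GGGAAAACT"))
  expect_silent(translate_and_collapse(p4))
  p5 <- aligned_panel(c(x = "GG-GACTAA", y = "GGGGACTAA"))
  expect_error(translate_and_collapse(p5), "multiples of 3")
})

test_that("poisson-corrected distances follow -log(1 - p) and invert", {
  aa <- c(a = strrep("A", 89), b = paste0(strrep("A", 87), "CC"))
  d <- distances(aligned_panel(aa), kind = "poisson-aa")
  expect_equal(d$p, 2 / 89, tolerance = 1e-12)
  expect_equal(d$distance, -log(1 - 2 / 89), tolerance = 1e-12)
  expect_equal(round(100 * d$distance, 2), 2.27)
  # inversion to machine precision
  expect_equal(1 - exp(-d$distance), d$p, tolerance = 1e-14)
  # identical pair is 0 for both kinds; small p agrees to first order
  same <- distances(aligned_panel(c(a = "AAAA", b = "AAAA")), "poisson-aa")
  expect_equal(same$distance, 0)
  expect_lt(abs(d$distance - d$p), d$p^2)
})

test_that("nei-gojobori counts canonical single-codon cases", {
  # TTT -> TTC: synonymous (Phe/Phe); TTT has 1/3 synonymous site at pos 3
  ng <- nei_gojobori("TTT", "TTC")
  expect_equal(ng$syn_subs, 1)
  expect_equal(ng$nonsyn_subs, 0)
  expect_equal(ng$syn_sites, 1 / 3, tolerance = 1e-12)
  expect_equal(ng$syn_sites + ng$nonsyn_sites, 3)

  # TTT -> TTA: nonsynonymous (Phe -> Leu)
  ng2 <- nei_gojobori("TTT", "TTA")
  expect_equal(ng2$syn_subs, 0)
  expect_equal(ng2$nonsyn_subs, 1)

  # identical sequences: no substitutions, undefined ratio
  ng3 <- nei_gojobori("TTTAAA", "TTTAAA")
  expect_equal(ng3$syn_subs + ng3$nonsyn_subs, 0)
  expect_true(is.na(ng3$dnds))

  # symmetry in the arguments and 3-per-codon site conservation
  a <- "ATGCGTTTA"; b <- "ATGAGTCTA"
  f <- nei_gojobori(a, b); r <- nei_gojobori(b, a)
  expect_equal(f$syn_subs, r$syn_subs, tolerance = 1e-12)
  expect_equal(f$nonsyn_subs, r$nonsyn_subs, tolerance = 1e-12)
  expect_equal(f$syn_sites + f$nonsyn_sites, 3 * f$codons, tolerance = 1e-12)
})

test_that("two-step codon differences average over shortest pathways", {
  # TTT -> GTA: pathways TTT->GTT->GTA (Phe->Val->Val: 1N+1S... check by
  # hand) and TTT->TTA->GTA (Phe->Leu->Val: 2N). Averaged counts must come
  # from enumerating both orders.
  ng <- nei_gojobori("TTT", "GTA")
  # path1: TTT->GTT (F->V, N), GTT->GTA (V->V, S) => 1N 1S
  # path2: TTT->TTA (F->L, N), TTA->GTA (L->V, N) => 2N 0S
  expect_equal(ng$syn_subs, 0.5, tolerance = 1e-12)
  expect_equal(ng$nonsyn_subs, 1.5, tolerance = 1e-12)
})

test_that("cumulative profile matches the pairwise totals and brute force", {
  panel <- aligned_panel(c(a = "TTTAAAGGG", b = "TTCAAAGGG",
                           c = "TTTAGAGGG"))
  prof <- cumulative_dnds_profile(panel)
  expect_equal(nrow(prof), 3L)
  # final cumulative totals equal the mean over pairs from nei_gojobori
  pairs <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  seqs <- c(a = "TTTAAAGGG", b = "TTCAAAGGG", c = "TTTAGAGGG")
  tot <- sapply(pairs, function(p) {
    ng <- nei_gojobori(seqs[p[1]], seqs[p[2]])
    c(ng$syn_subs, ng$nonsyn_subs)
  })
  expect_equal(prof$cum_syn[3], mean(tot[1, ]), tolerance = 1e-12)
  expect_equal(prof$cum_nonsyn[3], mean(tot[2, ]), tolerance = 1e-12)
  # a panel with only synonymous variation has a flat nonsynonymous curve
  syn_only <- aligned_panel(c(a = "TTTAAA", b = "TTCAAA"))
  expect_true(all(cumulative_dnds_profile(syn_only)$cum_nonsyn == 0))
  # plot method returns a ggplot
  expect_s3_class(autoplot(prof), "ggplot")
})

test_that("panel dN/dS averages dn and ds before taking the ratio", {
  panel <- aligned_panel(c(a = "TTTAAAGGG", b = "TTCAAAGGG",
                           c = "TTTAGAGGG"))
  pd <- panel_dnds(panel)
  expect_equal(pd$n_pairs, 3L)
  expect_true(is.finite(pd$dnds))
})
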