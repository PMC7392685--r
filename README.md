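# mhctyper

Diploid genotyping of highly polymorphic amplicons — MHC class II genes are
the canonical case — directly from merged amplicon-sequencing reads, plus
the population-genetic analyses that usually follow: diversity and
neutrality statistics, exact Hardy–Weinberg tests, a genotypic
linkage-disequilibrium test, and Nei–Gojobori dN/dS. The package is aimed
at wildlife and molecular-ecology labs that genotype one or two MHC loci in
a few hundred individuals and need the whole path from reads to Table-1
style statistics to be reproducible and testable.

Calling diploid genotypes at an MHC locus is harder than it sounds: PCR
builds chimeras of the two true alleles, per-base errors create clouds of
near-alleles, primer-site mutations cause allelic dropout that pushes
heterozygotes toward homozygote-looking read ratios, and a naive caller
will happily mint artifact alleles. `mhctyper` implements the
ratio-threshold calling scheme used in amplicon MHC studies, together with
the auxiliary evidence (chimera detection, pedigree consistency, external
validation flags, a population minimum-allele-frequency filter) needed to
resolve the cases the thresholds cannot.

## The method

**Allele calling.** Per individual, distinct merged-read sequences are
ranked by count after filtering (intact primers, merged length ≥ 290 bp,
sequence seen ≥ 2 times in that individual). With counts c₁ ≥ c₂ the
top-two ratio is r = c₂/(c₁+c₂):

- r < 0.10 (i.e. beyond 90:10) → homozygote;
- 0.35 ≤ r ≤ 0.5 (50:50 to 65:35) → heterozygote;
- 0.10 ≤ r < 0.35 → ambiguous, resolved by chimera screening, validated
  panel membership and Mendelian consistency against a pedigree (or an
  external assay flag), else left unresolved.

Candidate alleles below the population frequency threshold 5/(2n) are
discarded unless independently validated. A sequence is a chimera of
parents A, B if it equals prefix(A)+suffix(B) (or the reverse) at some
internal crossover; the detector returns the maximal compatible crossover
interval.

**Population genetics.** On the called allele panels the package computes
S, k (mean pairwise differences), π = k/L, haplotype diversity
Hd = n/(n−1)(1−Σpᵢ²), Watterson's θ, Tajima's D, Fu & Li's D\* and F\*
(η/η_s form, no outgroup), and Fu's Fs via the Ewens sampling formula with
log-space Stirling numbers. Exact Hardy–Weinberg tests use the Levene
distribution conditional on allele counts — exhaustively enumerated when
the array space is small, otherwise by a Markov chain over pairings of the
2n allele copies (Rcpp) with batch-mean standard errors; heterozygote
excess/deficiency score tests share the same null. Between-locus
independence is tested with a G statistic on the two-locus genotype table
against a permutation null. Substitution analysis follows Nei & Gojobori
(1986): pathway-averaged synonymous/nonsynonymous counts, Jukes–Cantor
correction, panel dN/dS as mean(dN)/mean(dS) over pairs, and cumulative
codon-by-codon profiles.

**Synthetic data.** A first-class generator produces pedigrees, two-locus
diploid genotypes with tunable inbreeding f and standardized inter-locus
association D′, and per-individual read tallies with the full error
structure the caller must survive: negative-binomial depth, Beta-distributed
heterozygote allele balance (median ≈ 58:42), per-base errors, single
crossover chimeras, allele-specific dropout, singleton noise and
short merge fragments — all with per-read provenance so every downstream
stage can be scored against truth.

## Worked example

```r
library(mhctyper)

cfg <- sim_config(seed = 42, n_individuals = 60, depth_mean = 5000)
report <- run_pipeline(cfg, settings = mcmc_settings(seed = 42))
report
```

```
<mhc_report> 60 individuals, 2 loci

Diversity:
  locus     n     L     S   eta     k      pi    hd n_haplotypes
1 DRB     120   250    85    85 38.6  0.154   0.894           15
2 DOB     120   360     7     7  3.16 0.00877 0.847            9

Neutrality:
  locus     n     S   eta eta_s theta_w tajima_d fu_li_dstar fu_li_fstar fus_fs
1 DRB     120    85    85     0   15.9      4.61        2.44        3.98 Inf
2 DOB     120     7     7     0    1.31     3.23        1.18        2.10   2.15

dN/dS:
  locus n_pairs mean_ds mean_dn  dnds
1 DRB       105 0.167    0.198   1.19
2 DOB        36 0.00719  0.0163  2.27

HWE DRB: probability p = 0.67, excess p = 0.0316, deficit p = 0.993
HWE DOB: probability p = 0.0928, excess p = 0.571, deficit p = 0.577

LD: G = 291.6 p = 0.0881
Mendelian consistency: 100 %
Genotype recovery:
  locus     n recovered
1 DOB      60         1
2 DRB      60         1
```

Reading this: both loci were recovered perfectly from noisy reads (the
`recovered` column is checked against the generator's truth table). The
simulated DRB-like locus is highly polymorphic (π = 0.154, 85 segregating
sites) with strongly positive neutrality statistics — the signature of an
excess of intermediate-frequency alleles, as expected when allele
frequencies are balanced; the DOB-like locus is nearly monomorphic at the
nucleotide level (`eta_s = 0`: none of the called alleles carries a
singleton mutation). `tidy(report)` returns the same per-
locus table as a tibble; `glance(report)` a one-row summary; components
(`report$calls`, `report$variants`, `report$hwe`, …) are ordinary tibbles
and test objects with `tidy()` methods.

Individual stages compose with pipes, e.g.

```r
reads <- simulate_genotypes(cfg) |> simulate_reads(cfg)
calls <- reads |>
  filter_merged_reads(cfg$loci$DRB$fwd_primer, cfg$loci$DRB$rev_primer) |>
  call_genotypes()
plot_read_ratios(calls)
```

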