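---
title: "Amplicon MHC genotyping and its population-genetic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon MHC genotyping and its population-genetic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

This vignette is the package's own account of the methods it implements:
the genotype-calling model and its thresholds, the statistics, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## The calling model

An amplicon library from a diploid individual at a single locus should, in
an ideal world, contain reads from at most two allele sequences at roughly
equal abundance. In practice the ranked tally of distinct merged-read
sequences contains, below the one or two true alleles: single-crossover
PCR chimeras of the two alleles, clouds of single-substitution error
variants, undersized merge fragments, and occasional heavily mutated
singletons. The caller works on the ranked tally after four filters
(intact primers at both termini, merged length of at least `min_len`
measured before primer trimming, primer trimming, and removal of
sequences seen only once within the individual).

With top-two counts $c_1 \ge c_2$ the call is made on
$r = c_2/(c_1 + c_2)$:

* $r < 0.10$ — homozygote. The second sequence at a few percent is what
  per-base error leaves after collapsing (typical observed ratio around
  99:1).
* $0.35 \le r \le 0.5$ — heterozygote. The band corresponds to ratios
  between 50:50 and 65:35; allele amplification is rarely exactly
  balanced, and a median around 58:42 is normal.
* $0.10 \le r < 0.35$ — ambiguous. This band is where allelic dropout
  (a primer-site mismatch reducing one allele's amplification efficiency)
  places genuine heterozygotes, and also where unusually noisy
  homozygotes can land. The call is deferred, not guessed.

The band edges are tunable (`homo`, `het_low` in `call_genotypes()`), with
the defaults above; $r = 0.35$ is included in the heterozygote band, and
homozygosity requires $r$ strictly below 0.10.

Ambiguous calls are then resolved with independent evidence, in this
order: an external-validation flag (representing e.g. a Sanger assay)
upgrades to heterozygote outright; a second sequence matching a
*validated* panel allele upgrades to heterozygote provided no genotyped,
assigned parent contradicts the implied genotype; a second sequence that
is a detected chimera of the top sequence and a panel allele downgrades to
homozygote; anything else stays unresolved. Two points deserve emphasis:

* *Validated* means the allele occurs in at least one unambiguous
  ratio-based call elsewhere in the population — resolution never invents
  alleles.
* An individual without assigned parents is treated as unconstrained by
  the pedigree (the Mendelian condition is vacuously met). The
  alternative — requiring parents — would make founder animals
  unresolvable without an external assay, which is not how such data are
  handled in practice.

Mendelian consistency itself is a bipartite condition: one allele must be
attributable to each assigned parent *simultaneously* (parents AA × BB can
explain an AB offspring but not an AA one, even though AA shares an allele
with a parent). Inconsistent calls are flagged, not discarded: a
pedigree assembled at 95% confidence is expected to contradict a few
percent of correct genotypes.

The population-level minimum-allele-frequency filter removes candidate
alleles below $5/(2n)$ (five copies among $2n$ chromosomes) unless
validated; individuals whose genotype rests only on a removed allele are
flagged for exclusion. The filter is applied once, on frequencies from
resolved calls, and is idempotent.

## Chimera detection

A candidate is a single-crossover chimera of parents $A$ and $B$ iff
$\mathrm{candidate} = A_{1..s} \Vert B_{s+1..L}$ (or with parents swapped)
for some internal split $s$. The detector computes the longest prefix
shared with one parent and the shortest suffix shared with the other; the
set of compatible splits is the (possibly empty) interval between them,
and the maximal interval is returned. Comparison is gap-free and requires
equal lengths; calling it with a candidate equal to a parent is a
precondition violation, which the screen honours by skipping exact
matches. The screen tests every variant ranked third or lower against the
individual's top two sequences.

## Diversity and neutrality statistics

All site-based statistics use *complete deletion*: any alignment column
containing a gap in any sequence is dropped for every sequence. This
choice is material whenever an allele carries an in-frame deletion, and it
keeps the identity $\pi \cdot L = k$ exact, with $L$ the retained column
count.

Statistics operate on a panel of aligned sequences with *multiplicities*
(copies among genotyped individuals). $S$ ignores multiplicities (it is a
property of the distinct alleles); $k$, $\pi$, $H_d$ and all neutrality
statistics respond to them. Whether a published table was computed from
the 2N sampled copies or from the distinct alleles is often unstated in
the literature; the package makes the choice explicit — pass unit
multiplicities for distinct-allele statistics.

* Tajima's $D = (k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the standard
  $n$-dependent constants.
* Fu & Li's $D^*$ and $F^*$ (no outgroup) use total mutations $\eta$
  (a column with three states contributes two) and singleton mutations
  $\eta_s$ (states carried by exactly one sequence copy; with no outgroup,
  a derived-vs-ancestral orientation is unavailable, so "carried once" is
  the operative definition), with the corrected variance constants in
  standard use.
* Fu's $F_s = \ln(S'/(1-S'))$, $S' = P(K \ge k_{obs}\mid\theta = k)$
  under the Ewens sampling formula. The unsigned Stirling numbers of the
  first kind grow super-exponentially, so the whole computation runs in
  log space via a log-sum-exp recurrence — stable for $n$ well into the
  hundreds, which is where naive arithmetic overflows. When $S'$
  saturates at 0 or 1 (e.g. a single observed haplotype) a signed
  infinity is returned with an overflow flag rather than a fabricated
  finite value; undefined statistics ($S=0$, or $k=0$ for $F_s$) are `NA`,
  never 0.
* Significance bands for $D^*$/$F^*$ (`significance = TRUE`) come from a
  fixed-$\eta$ neutral-coalescent null: Kingman genealogies with $\eta$
  mutations placed multinomially by branch length, two-sided empirical
  $p$, bands `*` ($p<0.05$) and `^` ($0.05 \le p < 0.10$). A simulation
  null was chosen over transcribed critical-value tables because the
  tables cover a coarse grid of $n$ and transcription is itself an error
  source; the simulation is seeded and its size (`n_sim`, default 2000)
  is explicit.

All four statistics are verified in the test suite against independent
brute-force oracles (explicit pair loops, exact integer Stirling
coefficients) on panels with $n \le 8$, $S \le 10$, at tolerance $10^{-9}$.

## Exact Hardy–Weinberg and linkage tests

Conditional on allele counts, the probability of a genotype array
$\{n_{ij}\}$ is Levene's
$P = n!\,\prod_i m_i!\,2^H / \big((2n)!\,\prod_{i\le j} n_{ij}!\big)$,
$H$ the heterozygote count. The probability test sums $P$ over arrays no
more probable than the observed one; the score tests sum over arrays with
$H$ at least (excess) or at most (deficit) the observed $H$, so
$p_{excess} + p_{deficit} \ge 1$ always.

Small problems are enumerated exhaustively (auto mode enumerates when the
array space stays within $10^5$ arrays *and* the problem is small enough
— at most 6 alleles and 50 individuals — that the recursive walk itself is
cheap; the array-count cap alone does not bound time spent in dead ends).
Larger problems use a Markov chain built on one observation: the Levene
distribution is exactly the pushforward of the *uniform* distribution on
pairings of the $2n$ allele copies. A chain that transposes two uniformly
chosen copies per step (a no-op when both fall in the same individual) is
therefore uniform over pairings and induces the exact conditional
distribution on arrays — no Metropolis ratio, none of the degenerate-case
bookkeeping of switch-based samplers. Array probability and $H$ update in
O(1) per step. Ties in the $p\le p_{obs}$ comparison use an absolute
$10^{-9}$ log-probability tolerance so the observed array always counts
itself. Monte Carlo $p$-values carry batch-mean standard errors
(defaults: dememorization 1000, 100 batches of 1000 — the conventional
defaults for this family of tests). The test suite checks the chain
against exhaustive enumeration, and enumeration against an independent
oracle that enumerates the pairing space itself.

The linkage test makes no phase assumption: it is a $G$ statistic on the
two-locus table of single-locus genotypes, with a null obtained by
permuting one locus' genotypes among individuals (distributionally the
same null as contingency-table shuffling). Monomorphic loci are reported
not-applicable.

Note on calibration runs: an MCMC exact test started at the observed
array needs a burn-in comfortably above the $\sim 2n\ln 2n$ transposition
mixing scale; the calibration experiments in the tests and acceptance
script use dememorization 5000 with 10,000 sampled steps per dataset at
$n = 100$, which brings the empirical type-I error at nominal 0.05 within
Monte Carlo error of 0.05 over 1000 datasets.

## Substitution analysis

Nei–Gojobori pathway counting: per codon, each position contributes the
fraction of its three possible changes that are synonymous (changes to
stop codons count as nonsynonymous, preserving exactly 3 sites per
codon); substitution counts for codons differing at 2–3 positions are
averaged over all orderings, excluding pathways through stop codons
(falling back to all pathways in the degenerate case where every pathway
hits one). Rates are Jukes–Cantor corrected,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, and the panel summary is
$\overline{d_N}/\overline{d_S}$ — means over pairs taken *before* the
ratio, the convention of codon-substitution programs, not the mean of
per-pair ratios. `cumulative_dnds_profile()` emits the running
codon-indexed cumulative means whose endpoints equal the pairwise-mean
totals. Gapped or ambiguous codons are skipped; trailing partial codons
are dropped (a 250 bp exon fragment analyses 82–83 codons depending on
frame offset).

Pairwise distances are plain $p$-distances for nucleotides and
Poisson-corrected $d = -\ln(1-p)$ for amino acids (the correction inverts
exactly: $1 - e^{-d} = p$). Model-based nucleotide distances
(composite-likelihood and friends) are out of scope — published values
that depend on them are not reproduced here.

## The synthetic-data generator

The generator is the package's substitute for a sequencing run, and its
defaults are the reference study conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| depth per individual/locus | NB(mean 20,000, size 10) | filtered per-individual depths in amplicon MHC studies run in the tens of thousands with heavy overdispersion; size 10 gives a realistic 8k–40k central range |
| heterozygote balance | Beta(9, 9) | symmetric; yields a median top-two ratio of ≈58:42, the empirically typical imbalance |
| per-base error | 0.001 | post-merge residual error of paired-end short reads |
| chimera rate | 0.02 | a few percent of heterozygote reads |
| short-fragment rate | 0.02 | undersized merges, removed by the length filter |
| singleton noise | 0.005 | heavily damaged reads occurring once |
| dropout | none | enabled per allele as an efficiency multiplier in (0, 1] |
| allele panels | 19 alleles / 250 bp / 85 segregating sites and 11 alleles / 360 bp / 7 sites (270 bp exon) | the polymorphism shape of a classical vs non-classical class II locus pair |
| allele frequencies | geometric decay (top allele ≈22% and ≈29%) | MHC loci typically show a gently decaying frequency spectrum, not uniform |

Modelling choices worth knowing when interpreting test results:

* Reads are generated and carried as *tallies* (sequence, count,
  provenance), not individual records; `write_reads_fastq()` expands to
  standard 4-line FASTQ (constant Q37 placeholder — the pipeline never
  uses base qualities after merging).
* The error channel applies at most one substitution per read, with
  per-read probability $1-(1-e)^L$ and a uniformly chosen site; reads
  with multiple errors are represented by the separate singleton-noise
  channel (two substitutions, count 1). This keeps the generator exact at
  the tally level and fast; its consequence — the error cloud sits at
  Hamming distance 1 from a true allele — matches what the singleton and
  ratio filters actually face.
* Chimera crossover points are uniform over the breakpoints that yield a
  sequence distinct from both parents. A crossover outside the
  distinguishing interval regenerates a parent molecule; such events are
  unobservable and would only silently rescale the effective chimera
  rate. Alleles differing at fewer than two positions admit no chimera.
* Homozygote "second sequences" arise from the error channel only; there
  is no cross-contamination model.
* With `ld_coefficient` nonzero the two loci are drawn as paired
  haplotypes with standardized D′ applied to the (first allele, first
  allele) cell and the compensation spread to preserve margins;
  infeasible D′ for the given frequencies is an error. Combining nonzero
  `inbreeding_f` with nonzero `ld_coefficient` is refused — a joint
  two-locus inbreeding model would be a different (and bigger) design.
* Depth dispersion is a free parameter: per-genotype-class depth variance
  is rarely reported, so `depth_dispersion = 10` was fixed once from the
  plausible range above and is not tuned anywhere.

What the generator does *not* emulate: index hopping or between-individual
contamination, quality-score structure, length-dependent merge failure
beyond the short-fragment channel, copy-number variation (each locus is
one diploid gene), and coalescent genealogy among the alleles (panels are
constructed, not evolved). Passing tests therefore demonstrate that the
pipeline survives the listed artifact classes at realistic rates — not
that it is robust to contamination or paralogy.

## Pipeline, formats, interfaces

`run_pipeline()` chains simulate → filter → genotype → screen → resolve →
MAF filter → nomenclature → statistics → exact tests and returns a single
report object; every stage is also exported on its own and operates on
tibbles, so the shell-level workflow is simply R scripts over these
functions. FASTA (panels) and FASTQ (reads) go through Biostrings; calls,
tallies and frequency tables are CSV round-trippable. Coordinates are
0-based half-open everywhere an interval appears (exon subintervals,
`extract_exon()`). Nomenclature continues the serial numbering of a known
panel (novel alleles get the next unused serials, ordered by descending
frequency); exon-collapsed alleles concatenate their members' serials, so
three extended alleles `*01`, `*02`, `*11` sharing an exon become
`*010211_exon`. Multiple-testing correction is deliberately not applied
anywhere; reported p-values are unadjusted and say so.

The length floor (`min_len = 290` by default) applies to every locus,
including loci whose amplicon is much longer — the floor exists to remove
failed merges, not to size-select, so a single conservative default
serves both loci; it is per-locus configurable.

## Problem sizes used in tests

The acceptance checks run at the reference conditions: 200
pedigree-structured individuals (100 founders, 100 offspring) at full
default depth for recovery and dropout; 1000 simulated null datasets of
100 individuals and 3 alleles per locus for test calibration; oracle
comparisons at $n \le 8$, $S \le 10$. These sizes were chosen as the
smallest at which the contracts under test are sharp (binomial standard
errors small enough that the acceptance bands are meaningful), and the
whole suite plus acceptance script completes in well under half an hour
on one CPU.

## Known limitations

* One diploid locus per assay: no deconvolution of co-amplifying
  paralogues (more than two true alleles per individual is out of scope).
* The chimera model is single-crossover; double-crossover artifacts
  exist at low rates in long amplicons and would not be detected.
* Fu & Li significance bands are simulation-based; for publication-grade
  boundary cases increase `n_sim`.
* The exact-test enumeration cutoff is conservative; very asymmetric
  arrays within the cutoff are still enumerated, but most real datasets
  of this size go through the Markov chain, whose error is quantified by
  the reported batch-mean SE.
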