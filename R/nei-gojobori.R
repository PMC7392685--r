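# Nei-Gojobori (1986) pathway counting of synonymous and nonsynonymous
# sites/substitutions with Jukes-Cantor correction, pairwise panel summaries
# and the cumulative codon-by-codon profile.

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

# Synonymous site fraction of one codon: for each position, the fraction of
# the three possible changes that preserve the amino acid. Changes to stop
# codons count as nonsynonymous, so syn + nonsyn sites total 3 per codon.
codon_syn_sites <- function(codon) {
  aa0 <- codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    b0 <- substr(codon, p, p)
    for (b in setdiff(DNA_BASES, b0)) {
      alt <- codon
      substr(alt, p, p) <- b
      if (codon_aa(alt) == aa0 && codon_aa(alt) != "*") s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous substitution counts between two codons
# over all shortest pathways; pathways passing through a stop codon are
# excluded (falling back to all pathways if none survive).
codon_subs <- function(ca, cb) {
  diff_pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- perm_list(diff_pos)
  tally <- list()
  for (ord in perms) {
    cur <- ca
    syn <- 0; nonsyn <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (codon_aa(nxt) == "*") hit_stop <- TRUE
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    tally[[length(tally) + 1]] <- c(syn, nonsyn, hit_stop)
  }
  tm <- do.call(rbind, tally)
  ok <- tm[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(tm)) # all pathways hit a stop: keep all
  c(syn = mean(tm[ok, 1]), nonsyn = mean(tm[ok, 2]))
}

perm_list <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perm_list(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Nei-Gojobori synonymous/nonsynonymous analysis of a sequence pair
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and substitutions (multi-step codon differences averaged over
#' all shortest pathways, stop-codon pathways excluded), then applies the
#' Jukes-Cantor correction `d = -3/4 log(1 - 4/3 p)` to each class.
#'
#' @param codon_seq_a,codon_seq_b In-frame nucleotide strings of equal
#'   length divisible by 3. Codons containing gaps or ambiguous bases are
#'   skipped.
#' @return One-row tibble: `codons`, `syn_sites`, `nonsyn_sites`,
#'   `syn_subs`, `nonsyn_subs`, `ps`, `pn`, `ds`, `dn`, `dnds` (NA when ds
#'   is 0 or undefined). Attribute `"per_codon"` holds the per-codon
#'   substitution counts used by [cumulative_dnds_profile()].
#' @export
nei_gojobori <- function(codon_seq_a, codon_seq_b) {
  a <- toupper(codon_seq_a); b <- toupper(codon_seq_b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length", call. = FALSE)
  if (nchar(a) %% 3 != 0) stop("length must be divisible by 3", call. = FALSE)
  nc <- nchar(a) / 3
  starts <- 3 * (seq_len(nc) - 1) + 1
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  per <- matrix(0, nc, 2, dimnames = list(NULL, c("syn", "nonsyn")))
  syn_sites <- 0; nonsyn_sites <- 0
  for (i in seq_len(nc)) {
    if (!clean[i]) next
    sa <- codon_syn_sites(ca[i]); sb <- codon_syn_sites(cb[i])
    syn_sites <- syn_sites + (sa + sb) / 2
    nonsyn_sites <- nonsyn_sites + 3 - (sa + sb) / 2
    per[i, ] <- codon_subs(ca[i], cb[i])
  }
  syn_subs <- sum(per[, "syn"]); nonsyn_subs <- sum(per[, "nonsyn"])
  ps <- if (syn_sites > 0) syn_subs / syn_sites else NA_real_
  pn <- if (nonsyn_sites > 0) nonsyn_subs / nonsyn_sites else NA_real_
  jc <- function(p) {
    if (!is.finite(p)) return(NA_real_)
    if (p >= 0.75) return(Inf)
    -0.75 * log(1 - 4 * p / 3)
  }
  ds <- jc(ps); dn <- jc(pn)
  out <- tibble::tibble(codons = sum(clean), syn_sites = syn_sites,
                        nonsyn_sites = nonsyn_sites, syn_subs = syn_subs,
                        nonsyn_subs = nonsyn_subs, ps = ps, pn = pn,
                        ds = ds, dn = dn,
                        dnds = if (is.finite(ds) && ds > 0) dn / ds
                               else NA_real_)
  attr(out, "per_codon") <- per
  out
}

#' Panel-wide dN/dS summary
#'
#' Runs [nei_gojobori()] on every unordered pair of distinct panel
#' sequences and summarises as `mean(dn) / mean(ds)` over pairs (the
#' pairwise-mean averaging used by codon-level substitution programs), not
#' the mean of per-pair ratios.
#'
#' @param panel An [aligned_panel()] of in-frame sequences (multiplicities
#'   are not used: substitution patterns are a property of the alleles).
#' @return One-row tibble: `n_pairs`, `mean_ds`, `mean_dn`, `dnds`.
#' @export
panel_dnds <- function(panel) {
  panel <- aligned_panel(panel)
  seqs <- gsub("-", "", panel$seq, fixed = TRUE)
  if (length(unique(nchar(seqs))) > 1) {
    stop("degapped panel sequences must share one length", call. = FALSE)
  }
  seqs <- substr(seqs, 1, nchar(seqs) - nchar(seqs) %% 3) # whole codons
  prs <- combn(length(seqs), 2)
  ds <- numeric(ncol(prs)); dn <- numeric(ncol(prs))
  for (j in seq_len(ncol(prs))) {
    ng <- nei_gojobori(seqs[prs[1, j]], seqs[prs[2, j]])
    ds[j] <- ng$ds; dn[j] <- ng$dn
  }
  mean_ds <- mean(ds[is.finite(ds)])
  mean_dn <- mean(dn[is.finite(dn)])
  tibble::tibble(n_pairs = ncol(prs), mean_ds = mean_ds, mean_dn = mean_dn,
                 dnds = if (is.finite(mean_ds) && mean_ds > 0)
                   mean_dn / mean_ds else NA_real_)
}

#' Cumulative codon-by-codon substitution profile
#'
#' Running cumulative mean synonymous and nonsynonymous substitution counts
#' along the coding sequence, averaged over all unordered pairs of panel
#' sequences -- the codon-indexed profile used to visualise where in a gene
#' the substitution classes accumulate. The final cumulative totals equal
#' the pairwise-mean totals from [nei_gojobori()].
#'
#' @param panel An [aligned_panel()] of in-frame sequences.
#' @return Tibble `codon`, `cum_syn`, `cum_nonsyn` (class
#'   `mhc_dnds_profile`; see [autoplot.mhc_dnds_profile()]).
#' @export
cumulative_dnds_profile <- function(panel) {
  panel <- aligned_panel(panel)
  seqs <- gsub("-", "", panel$seq, fixed = TRUE)
  if (length(unique(nchar(seqs))) > 1) {
    stop("degapped panel sequences must share one length", call. = FALSE)
  }
  seqs <- substr(seqs, 1, nchar(seqs) - nchar(seqs) %% 3) # whole codons
  prs <- combn(length(seqs), 2)
  nc <- (nchar(seqs[1]) - nchar(seqs[1]) %% 3) / 3
  syn <- matrix(0, ncol(prs), nc); nonsyn <- matrix(0, ncol(prs), nc)
  for (j in seq_len(ncol(prs))) {
    ng <- nei_gojobori(seqs[prs[1, j]], seqs[prs[2, j]])
    per <- attr(ng, "per_codon")
    syn[j, ] <- per[, "syn"]; nonsyn[j, ] <- per[, "nonsyn"]
  }
  out <- tibble::tibble(codon = seq_len(nc),
                        cum_syn = cumsum(colMeans(syn)),
                        cum_nonsyn = cumsum(colMeans(nonsyn)))
  class(out) <- c("mhc_dnds_profile", class(out))
  out
}
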