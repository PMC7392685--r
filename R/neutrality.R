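# Frequency-spectrum and haplotype-count neutrality tests: Tajima's D,
# Fu & Li's D* and F* (without outgroup), and Fu's Fs via the Ewens sampling
# formula. All statistics operate on the sampled sequence set, i.e. they
# respond to haplotype multiplicities.

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

fu_li_constants <- function(n) {
  i <- seq_len(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2)
  an1 <- an + 1 / n # a_{n+1}
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  list(an = an, bn = bn, vD = vD, uD = uD, vF = vF, uF = uF)
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' n-dependent constants. Requires n >= 4 sampled sequences and at least one
#' segregating site; otherwise `NA` (never reported as 0).
#'
#' @param panel An [aligned_panel()].
#' @return Numeric D (NA when undefined).
#' @export
tajimas_d <- function(panel) {
  core <- panel_core(panel)
  S <- as.integer(segregating_sites(panel))
  if (core$n < 4 || S < 1) return(NA_real_)
  k <- as.numeric(pairwise_differences(panel))
  cst <- tajima_constants(core$n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Uses total mutations eta (sites with more than two states contribute
#' several mutations) and singleton mutations eta_s (states carried by
#' exactly one sequence copy) with the corrected n-dependent variance
#' constants:
#' `D* = (n/(n-1) eta - a_n eta_s) / sqrt(uD eta + vD eta^2)` and
#' `F* = (k - (n-1)/n eta_s) / sqrt(uF eta + vF eta^2)`.
#' Significance bands, when requested, come from a fixed-eta neutral
#' coalescent null simulation (see [neutrality_null_sim()]).
#'
#' @param panel An [aligned_panel()].
#' @param significance Logical; also report the simulation-based two-sided
#'   significance band for each statistic.
#' @param n_sim Null replicates for the band (default 2000).
#' @param seed Seed for the null simulation.
#' @return One-row tibble: `dstar`, `fstar`, `eta`, `eta_s` (plus `dstar_p`,
#'   `dstar_sig`, `fstar_p`, `fstar_sig` when `significance = TRUE`;
#'   bands: `"*"` p < 0.05, `"^"` 0.05 <= p < 0.10, `"ns"` otherwise).
#' @export
fu_li_star_tests <- function(panel, significance = FALSE, n_sim = 2000,
                             seed = 1L) {
  core <- panel_core(panel)
  S <- as.integer(segregating_sites(panel))
  if (core$n < 4 || S < 1) {
    return(tibble::tibble(dstar = NA_real_, fstar = NA_real_,
                          eta = NA_integer_, eta_s = NA_integer_))
  }
  mut <- mutation_counts(core)
  k <- as.numeric(pairwise_differences(panel))
  n <- core$n
  cst <- fu_li_constants(n)
  eta <- mut$eta; eta_s <- mut$eta_s
  dstar <- (n / (n - 1) * eta - cst$an * eta_s) /
    sqrt(cst$uD * eta + cst$vD * eta^2)
  fstar <- (k - (n - 1) / n * eta_s) / sqrt(cst$uF * eta + cst$vF * eta^2)
  out <- tibble::tibble(dstar = dstar, fstar = fstar,
                        eta = eta, eta_s = eta_s)
  if (significance) {
    null <- neutrality_null_sim(n, eta, n_sim = n_sim, seed = seed)
    band <- function(obs, sims) {
      p <- 2 * min(mean(sims <= obs), mean(sims >= obs))
      p <- min(p, 1)
      list(p = p, sig = if (p < 0.05) "*" else if (p < 0.10) "^" else "ns")
    }
    bd <- band(dstar, null$dstar); bf <- band(fstar, null$fstar)
    out$dstar_p <- bd$p; out$dstar_sig <- bd$sig
    out$fstar_p <- bf$p; out$fstar_sig <- bf$sig
  }
  out
}

#' Neutral-coalescent null distribution of D, D*, F* (fixed mutation count)
#'
#' Simulates Kingman genealogies for `n` sequences, places `eta` mutations
#' multinomially on branches proportional to branch length, and returns the
#' resulting statistics. Used for simulation-based significance bands.
#'
#' @param n Sample size (sequences).
#' @param eta Total mutations to place.
#' @param n_sim Number of replicates.
#' @param seed Integer seed.
#' @return Tibble with columns `d`, `dstar`, `fstar`.
#' @export
neutrality_null_sim <- function(n, eta, n_sim = 2000, seed = 1L) {
  stopifnot(n >= 4, eta >= 1)
  set.seed(seed)
  tj <- tajima_constants(n)
  fl <- fu_li_constants(n)
  npairs <- choose(n, 2)
  res <- matrix(NA_real_, n_sim, 3)
  for (s in seq_len(n_sim)) {
    # genealogy: branch lengths and subtended leaf counts
    leaf <- as.list(rep(1L, n))
    len <- rep(0, n)
    bl <- numeric(0); bleaf <- integer(0)
    k <- n
    while (k > 1) {
      t <- rexp(1, rate = k * (k - 1) / 2)
      len <- len + t
      pick <- sample.int(k, 2)
      bl <- c(bl, len[pick])
      bleaf <- c(bleaf, unlist(leaf[pick]))
      merged <- sum(unlist(leaf[pick]))
      leaf <- c(leaf[-pick], list(merged))
      len <- c(len[-pick], 0)
      k <- k - 1L
    }
    keep <- bleaf < n # drop the root's child spanning all leaves (if any)
    bl <- bl[keep]; bleaf <- bleaf[keep]
    muts <- as.integer(rmultinom(1, eta, prob = bl))
    S_sim <- sum(muts > 0) # distinct sites under infinite sites = mutations
    eta_s <- sum(muts[bleaf == 1L | bleaf == (n - 1L)])
    ksim <- sum(muts * bleaf * (n - bleaf)) / npairs
    d <- if (eta > 0) (ksim - eta / tj$a1) /
      sqrt(tj$e1 * eta + tj$e2 * eta * (eta - 1)) else NA_real_
    dstar <- (n / (n - 1) * eta - fl$an * eta_s) /
      sqrt(fl$uD * eta + fl$vD * eta^2)
    fstar <- (ksim - (n - 1) / n * eta_s) /
      sqrt(fl$uF * eta + fl$vF * eta^2)
    res[s, ] <- c(d, dstar, fstar)
  }
  tibble::tibble(d = res[, 1], dstar = res[, 2], fstar = res[, 3])
}

# log of unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n,
# via the stable log-sum-exp recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)|.
log_stirling_first <- function(n) {
  ls <- rep(-Inf, n + 1) # index k+1
  ls[2] <- 0 # |s(1,1)| = 1
  if (n == 1) return(ls[-1])
  for (m in 1:(n - 1)) {
    new <- rep(-Inf, n + 1)
    for (k in seq_len(m + 1)) {
      a <- log(m) + ls[k + 1] # m * |s(m,k)|
      b <- if (k >= 2) ls[k] else -Inf # |s(m,k-1)|
      hi <- pmax(a, b)
      new[k + 1] <- ifelse(is.finite(hi),
                           hi + log(exp(a - hi) + exp(b - hi)), -Inf)
    }
    ls <- new
  }
  ls[-1]
}

#' Ewens sampling-formula distribution of the haplotype count
#'
#' `P(K = k | theta, n) = |s(n,k)| theta^k / (theta)_n` with unsigned
#' Stirling numbers of the first kind and the rising factorial
#' `(theta)_n`. Computed in log space, stable to n in the hundreds.
#'
#' @param n Sample size.
#' @param theta Scaled mutation parameter (> 0).
#' @return Numeric vector of probabilities for K = 1..n.
#' @export
ewens_haplotype_pmf <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(logp)
}

#' Fu's Fs
#'
#' `Fs = ln(S' / (1 - S'))` with `S' = P(K >= k_obs | theta = k)` under the
#' Ewens sampling formula, where `k_obs` is the observed haplotype count and
#' theta is estimated by the mean pairwise difference k. When S' reaches 0
#' or 1 numerically (e.g. a single observed haplotype), a signed infinity is
#' returned as the overflow flag.
#'
#' @param panel An [aligned_panel()].
#' @return Numeric Fs (`-Inf`/`Inf` on overflow, `NA` when undefined);
#'   attribute `"sprime"` carries S'.
#' @export
fus_fs <- function(panel) {
  core <- panel_core(panel)
  if (core$n < 2) return(structure(NA_real_, sprime = NA_real_))
  theta <- as.numeric(pairwise_differences(panel))
  if (!is.finite(theta) || theta <= 0) {
    return(structure(NA_real_, sprime = NA_real_))
  }
  k_obs <- length(unique(collapse_rows(core$mat)))
  pmf <- ewens_haplotype_pmf(core$n, theta)
  sprime <- sum(pmf[k_obs:core$n])
  if (sprime <= 0) return(structure(-Inf, sprime = 0))
  if (sprime >= 1) return(structure(Inf, sprime = 1))
  structure(log(sprime / (1 - sprime)), sprime = sprime)
}

#' All neutrality statistics of a panel
#'
#' Bundles Watterson's theta, Tajima's D, Fu and Li's D*/F* and Fu's Fs into
#' one tidy row; statistics that are undefined for the panel (e.g. S = 0)
#' are reported as `NA`, never as 0.
#'
#' @inheritParams fu_li_star_tests
#' @return One-row tibble with `n`, `S`, `eta`, `eta_s`, `theta_w`,
#'   `tajima_d`, `fu_li_dstar`, `fu_li_fstar`, `fus_fs`, `fs_overflow` (and
#'   significance columns when requested).
#' @export
neutrality_tests <- function(panel, significance = FALSE, n_sim = 2000,
                             seed = 1L) {
  core <- panel_core(panel)
  S <- as.integer(segregating_sites(panel))
  mut <- mutation_counts(core)
  theta_w <- if (core$n >= 2 && S >= 1) S / sum(1 / seq_len(core$n - 1))
             else NA_real_
  fl <- fu_li_star_tests(panel, significance = significance, n_sim = n_sim,
                         seed = seed)
  fs <- fus_fs(panel)
  out <- tibble::tibble(n = core$n, S = S, eta = mut$eta, eta_s = mut$eta_s,
                        theta_w = theta_w,
                        tajima_d = tajimas_d(panel),
                        fu_li_dstar = fl$dstar, fu_li_fstar = fl$fstar,
                        fus_fs = as.numeric(fs),
                        fs_overflow = is.infinite(as.numeric(fs)))
  if (significance) {
    out$dstar_p <- fl$dstar_p; out$dstar_sig <- fl$dstar_sig
    out$fstar_p <- fl$fstar_p; out$fstar_sig <- fl$fstar_sig
  }
  out
}
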