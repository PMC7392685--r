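# Independent brute-force oracles. These re-derive every statistic from
# first principles on tiny inputs (explicit pair loops, exact enumeration of
# pairings, integer Stirling coefficients) without touching the package's
# computation paths.

# Expand a panel to one row per sampled copy and compute S, eta, eta_s and k
# by explicit loops.
oracle_site_stats <- function(seqs, mult = rep(1L, length(seqs))) {
  rows <- rep(seqs, mult)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- apply(m, 2, function(col) !any(col == "-"))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- 0L; eta <- 0L; eta_s <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) > 1) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1)
    }
  }
  tot <- 0; np <- 0
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      tot <- tot + sum(m[u, ] != m[v, ])
      np <- np + 1
    }
  }
  list(n = n, L = ncol(m), S = S, eta = eta, eta_s = eta_s, k = tot / np,
       k_hap = length(unique(rows)))
}

oracle_tajima_d <- function(n, S, k) {
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

oracle_fu_li <- function(n, eta, eta_s, k) {
  i <- 1:(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2); an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  list(dstar = (n / (n - 1) * eta - an * eta_s) /
         sqrt(uD * eta + vD * eta^2),
       fstar = (k - (n - 1) / n * eta_s) / sqrt(uF * eta + vF * eta^2))
}

# Unsigned Stirling numbers of the first kind as exact integer coefficients
# of the rising factorial x (x+1) ... (x+n-1); exact in doubles for n <= 20.
oracle_stirling <- function(n) {
  coef <- c(0, 1) # polynomial x, coefficient of x^0, x^1, ...
  if (n >= 2) {
    for (m in 1:(n - 1)) {
      shifted <- c(0, coef) # x * P(x)
      scaled <- c(coef * m, 0) # m * P(x)
      coef <- shifted + scaled
    }
  }
  coef[-1][seq_len(n)] # |s(n, 1..n)|
}

oracle_fus_fs <- function(n, k_obs, theta) {
  st <- oracle_stirling(n)
  probs <- st * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
  sprime <- sum(probs[k_obs:n])
  log(sprime / (1 - sprime))
}

# Exact Levene distribution by enumerating all perfect pairings of the 2n
# labelled allele copies. `copies` is the vector of allele copy counts.
oracle_levene_distribution <- function(copies) {
  labels <- rep(seq_along(copies), copies)
  results <- list()
  rec <- function(idx, geno) {
    if (length(idx) == 0) {
      key <- paste(sort(geno), collapse = ";")
      results[[key]] <<- (results[[key]] %||% 0) + 1
      return(invisible())
    }
    a <- idx[1]
    for (j in 2:length(idx)) {
      b <- idx[j]
      g <- paste(min(labels[a], labels[b]), max(labels[a], labels[b]),
                 sep = "/")
      rec(idx[-c(1, j)], c(geno, g))
    }
    invisible()
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  rec(seq_along(labels), character(0))
  total <- sum(unlist(results))
  keys <- names(results)
  tibble::tibble(
    key = keys,
    prob = unlist(results) / total,
    H = vapply(strsplit(keys, ";"), function(g) {
      sum(vapply(strsplit(g, "/"), function(p) p[1] != p[2], logical(1)))
    }, numeric(1)))
}

# Genotype-array key in the same format for an observed counts matrix.
oracle_array_key <- function(counts) {
  k <- nrow(counts)
  geno <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (counts[i, j] > 0) {
        geno <- c(geno, rep(paste(i, j, sep = "/"), counts[i, j]))
      }
    }
  }
  paste(sort(geno), collapse = ";")
}
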