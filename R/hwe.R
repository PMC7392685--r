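# Exact Hardy-Weinberg tests conditional on allele counts (Levene
# distribution): the probability test and the one-sided heterozygote
# excess/deficiency score tests, by exhaustive enumeration when the array
# space is small and by Markov chain Monte Carlo otherwise.

#' Markov chain settings for the exact tests
#'
#' @param dememorization Burn-in steps (default 1000).
#' @param batches Number of batches (default 100).
#' @param iterations_per_batch Steps per batch (default 1000).
#' @param seed Integer seed.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(dememorization = 1000, batches = 100,
                          iterations_per_batch = 1000, seed = 1L) {
  stopifnot(dememorization > 0, batches > 0, iterations_per_batch > 0)
  structure(list(dememorization = as.integer(dememorization),
                 batches = as.integer(batches),
                 iterations_per_batch = as.integer(iterations_per_batch),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Build a genotype array from diploid calls
#'
#' @param sample Tibble with `allele_1`, `allele_2` (and optionally
#'   `locus`, filtered by the `locus` argument).
#' @param locus Optional locus to select.
#' @return A `genotype_array`: symmetric counts matrix (upper triangle
#'   filled) with allele names, plus `n` individuals and allele copy counts.
#' @export
genotype_array <- function(sample, locus = NULL) {
  if (!is.null(locus) && "locus" %in% names(sample)) {
    sample <- sample[sample$locus == locus, ]
  }
  stopifnot(all(c("allele_1", "allele_2") %in% names(sample)))
  sample <- sample[!is.na(sample$allele_1) & !is.na(sample$allele_2), ]
  alleles <- sort(unique(c(sample$allele_1, sample$allele_2)))
  k <- length(alleles)
  counts <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (r in seq_len(nrow(sample))) {
    i <- match(sample$allele_1[r], alleles)
    j <- match(sample$allele_2[r], alleles)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    counts[i, j] <- counts[i, j] + 1L
  }
  structure(list(counts = counts, alleles = alleles,
                 n = nrow(sample),
                 allele_copies = allele_copies_from_counts(counts)),
            class = "genotype_array")
}

allele_copies_from_counts <- function(counts) {
  k <- nrow(counts)
  copies <- integer(k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (counts[i, j] > 0) {
        copies[i] <- copies[i] + counts[i, j]
        copies[j] <- copies[j] + counts[i, j]
      }
    }
  }
  copies
}

#' @export
print.genotype_array <- function(x, ...) {
  cat("<genotype_array>", x$n, "individuals,", length(x$alleles),
      "alleles\n")
  print(x$counts)
  invisible(x)
}

# Relative log Levene probability (constant terms dropped):
# H log 2 - sum lgamma(n_ij + 1).
levene_logp_rel <- function(counts) {
  k <- nrow(counts)
  H <- 0L; lf <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i != j) H <- H + counts[i, j]
      lf <- lf + lgamma(counts[i, j] + 1)
    }
  }
  c(logp = H * log(2) - lf, H = H)
}

# Exact conditional probability of one array given allele counts.
levene_prob <- function(counts) {
  copies <- allele_copies_from_counts(counts)
  n <- sum(counts[upper.tri(counts, diag = TRUE)])
  lp <- levene_logp_rel(counts)
  const <- lfactorial(n) + sum(lfactorial(copies)) - lfactorial(2 * n)
  exp(const + lp["logp"])
}

# Enumerate every genotype array with the given allele copy counts,
# recording (logp_rel, H, prob). Aborts (returns NULL) beyond `limit`.
enumerate_arrays <- function(copies, limit = 1e5) {
  k <- length(copies)
  n <- sum(copies) / 2
  const <- lfactorial(n) + sum(lfactorial(copies)) - lfactorial(2 * n)
  acc <- new.env(parent = emptyenv())
  acc$logp <- numeric(1024); acc$H <- integer(1024); acc$count <- 0L
  acc$overflow <- FALSE
  counts <- matrix(0L, k, k)
  rec <- function(i, j, rem) {
    if (acc$overflow) return(invisible())
    if (i > k) {
      lp <- levene_logp_rel(counts)
      acc$count <- acc$count + 1L
      if (acc$count > limit) { acc$overflow <- TRUE; return(invisible()) }
      if (acc$count > length(acc$logp)) { # amortized growth
        acc$logp <- c(acc$logp, numeric(length(acc$logp)))
        acc$H <- c(acc$H, integer(length(acc$H)))
      }
      acc$logp[acc$count] <- lp["logp"]
      acc$H[acc$count] <- as.integer(lp["H"])
      return(invisible())
    }
    if (j > k) { # row i exhausted?
      if (rem[i] == 0) rec(i + 1L, i + 1L, rem) # nolint
      return(invisible())
    }
    if (i == j) {
      for (nii in 0:(rem[i] %/% 2)) {
        counts[i, i] <<- nii
        rem2 <- rem; rem2[i] <- rem2[i] - 2L * nii
        rec(i, j + 1L, rem2)
        if (acc$overflow) break
      }
      counts[i, i] <<- 0L
    } else {
      top <- min(rem[i], rem[j])
      forced <- (j == k)
      vals <- if (forced) {
        if (rem[i] <= rem[j]) rem[i] else integer(0)
      } else 0:top
      for (nij in vals) {
        counts[i, j] <<- nij
        rem2 <- rem
        rem2[i] <- rem2[i] - nij; rem2[j] <- rem2[j] - nij
        rec(i, j + 1L, rem2)
        if (acc$overflow) break
      }
      counts[i, j] <<- 0L
    }
    invisible()
  }
  rec(1L, 1L, as.integer(copies))
  if (acc$overflow) return(NULL)
  logp <- acc$logp[seq_len(acc$count)]
  tibble::tibble(logp = logp, H = acc$H[seq_len(acc$count)],
                 prob = exp(const + logp))
}

hwe_result <- function(test, p, se, method, arr, settings = NULL,
                       extra = list()) {
  structure(c(list(test = test, p = p, se = se, method = method,
                   n = arr$n, k = length(arr$alleles),
                   settings = settings), extra),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("<hwe_test>", x$test, "| p =", format(x$p, digits = 4))
  if (is.finite(x$se %||% NA)) cat(" (SE", format(x$se, digits = 3), ")")
  cat(" |", x$method, "|", x$n, "individuals,", x$k, "alleles\n")
  invisible(x)
}

run_hwe_mcmc <- function(arr, settings) {
  k <- length(arr$alleles)
  pairing <- integer(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      nij <- arr$counts[i, j]
      if (nij > 0) pairing <- c(pairing, rep(c(i - 1L, j - 1L), nij))
    }
  }
  obs <- levene_logp_rel(arr$counts)
  set.seed(settings$seed)
  hwe_chain_cpp(pairing, k, obs["logp"], as.integer(obs["H"]),
                settings$dememorization, settings$batches,
                settings$iterations_per_batch)
}

batch_summary <- function(bm) {
  list(p = mean(bm), se = sd(bm) / sqrt(length(bm)))
}

# Auto mode enumerates only problems small enough that the recursive walk
# of the array space is itself cheap (the 1e5-array cap alone does not
# bound the time spent in dead ends of large spaces).
enum_feasible <- function(arr) {
  length(arr$alleles) <= 6 && arr$n <= 50
}

hwe_applicable <- function(arr) {
  length(arr$alleles) >= 2 && arr$n >= 1 && sum(arr$allele_copies > 0) >= 2
}

#' Exact Hardy-Weinberg probability test
#'
#' Computes the probability, under the exact conditional (Levene)
#' distribution of genotype arrays given the observed allele counts, of
#' arrays no more probable than the observed one. Small array spaces
#' (at most `enum_limit` arrays) are enumerated exhaustively; larger ones
#' use a Markov chain with the given settings, reporting the Monte Carlo
#' standard error from batch means.
#'
#' @param arr A [genotype_array()].
#' @param settings [mcmc_settings()] used in MCMC mode.
#' @param mode `"auto"` (default), `"enumerate"` or `"mcmc"`.
#' @param enum_limit Maximum enumerable arrays in auto mode.
#' @return An `hwe_test` object (fields `p`, `se`, `method`); monomorphic
#'   loci give `p = NA` with method `"not-applicable"`.
#' @export
hwe_probability_test <- function(arr, settings = mcmc_settings(),
                                 mode = c("auto", "enumerate", "mcmc"),
                                 enum_limit = 1e5) {
  mode <- match.arg(mode)
  stopifnot(inherits(arr, "genotype_array"))
  if (!hwe_applicable(arr)) {
    return(hwe_result("probability", NA_real_, NA_real_, "not-applicable",
                      arr))
  }
  if (mode != "mcmc") {
    en <- if (mode == "enumerate" || enum_feasible(arr)) {
      enumerate_arrays(arr$allele_copies,
                       limit = if (mode == "enumerate") Inf else enum_limit)
    } else NULL
    if (!is.null(en)) {
      obs <- levene_logp_rel(arr$counts)
      tol <- 1e-9
      p <- sum(en$prob[en$logp <= obs["logp"] + tol])
      return(hwe_result("probability", min(p, 1), NA_real_, "enumeration",
                        arr, extra = list(n_arrays = nrow(en))))
    }
    if (mode == "enumerate") {
      stop("array space too large to enumerate", call. = FALSE)
    }
  }
  res <- run_hwe_mcmc(arr, settings)
  s <- batch_summary(res$batch_p)
  hwe_result("probability", s$p, s$se, "mcmc", arr, settings = settings)
}

#' Exact score tests for heterozygote excess or deficiency
#'
#' One-sided tests using the total heterozygote count as the score
#' statistic under the same conditional null as the probability test:
#' `p_excess` is the null probability of arrays at least as heterozygous as
#' observed, `p_deficit` of arrays at most as heterozygous. On any array
#' `p_excess + p_deficit >= 1` (both sides include ties).
#'
#' @inheritParams hwe_probability_test
#' @param direction `"excess"` or `"deficit"`.
#' @return An `hwe_test` object.
#' @export
hwe_score_tests <- function(arr, settings = mcmc_settings(),
                            direction = c("excess", "deficit"),
                            mode = c("auto", "enumerate", "mcmc"),
                            enum_limit = 1e5) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(inherits(arr, "genotype_array"))
  if (!hwe_applicable(arr)) {
    return(hwe_result(paste0("score_", direction), NA_real_, NA_real_,
                      "not-applicable", arr))
  }
  h_obs <- sum(arr$counts[upper.tri(arr$counts)])
  if (mode != "mcmc") {
    en <- if (mode == "enumerate" || enum_feasible(arr)) {
      enumerate_arrays(arr$allele_copies,
                       limit = if (mode == "enumerate") Inf else enum_limit)
    } else NULL
    if (!is.null(en)) {
      p <- if (direction == "excess") sum(en$prob[en$H >= h_obs])
           else sum(en$prob[en$H <= h_obs])
      return(hwe_result(paste0("score_", direction), min(p, 1), NA_real_,
                        "enumeration", arr,
                        extra = list(h_obs = h_obs, n_arrays = nrow(en))))
    }
    if (mode == "enumerate") {
      stop("array space too large to enumerate", call. = FALSE)
    }
  }
  res <- run_hwe_mcmc(arr, settings)
  bm <- if (direction == "excess") res$batch_excess else res$batch_deficit
  s <- batch_summary(bm)
  hwe_result(paste0("score_", direction), s$p, s$se, "mcmc", arr,
             settings = settings, extra = list(h_obs = h_obs))
}
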