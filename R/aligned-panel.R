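# Aligned sequence panels. A panel is a tibble (name, seq, mult) of
# equal-length (possibly gapped) sequences; `mult` is the sample
# multiplicity of each haplotype (copies among genotyped individuals).
# All site-based statistics use complete deletion: every column containing a
# gap in any sequence is excluded.

#' Construct an aligned panel
#'
#' @param x Tibble with columns `name`, `seq` (equal length, `-` for gaps)
#'   and optional `mult`, or a (optionally named) character vector.
#' @param mult Optional integer vector of sample multiplicities (>= 1),
#'   recycled; overrides an existing `mult` column.
#' @param locus Optional locus label kept as an attribute.
#' @return An `aligned_panel` tibble.
#' @export
aligned_panel <- function(x, mult = NULL, locus = NULL) {
  if (is.character(x)) {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    x <- tibble::tibble(name = nm, seq = unname(x))
  }
  stopifnot(all(c("name", "seq") %in% names(x)))
  out <- tibble::as_tibble(x)
  out$seq <- toupper(out$seq)
  if (length(unique(nchar(out$seq))) > 1) {
    stop("aligned panel requires equal-length sequences", call. = FALSE)
  }
  if (!is.null(mult)) {
    out$mult <- as.integer(rep(mult, length.out = nrow(out)))
  } else if (!"mult" %in% names(out)) {
    out$mult <- 1L
  }
  if (any(out$mult < 1)) stop("multiplicities must be >= 1", call. = FALSE)
  structure(out, class = c("aligned_panel", class(tibble::tibble())),
            locus = locus)
}

# Internal: matrix of non-gap columns + bookkeeping.
panel_core <- function(panel) {
  panel <- aligned_panel(panel)
  mat <- seq_matrix(panel$seq)
  gap_col <- if (ncol(mat)) apply(mat == "-", 2, any) else logical(0)
  list(mat = mat[, !gap_col, drop = FALSE], mult = panel$mult,
       n = sum(panel$mult), L = sum(!gap_col), gap_cols = which(gap_col),
       names = panel$name)
}

#' Segregating sites of an aligned panel
#'
#' Counts alignment columns (gap columns excluded under complete deletion)
#' holding two or more distinct bases. Multiplicities are ignored.
#'
#' @param panel An [aligned_panel()] (or coercible tibble/character vector).
#' @return Integer S; the 1-based column indices (in original alignment
#'   coordinates) are attached as attribute `"sites"`.
#' @export
segregating_sites <- function(panel) {
  core <- panel_core(panel)
  if (nrow(core$mat) == 0 || ncol(core$mat) == 0) {
    return(structure(0L, sites = integer(0)))
  }
  keep <- setdiff(seq_len(nchar(aligned_panel(panel)$seq[1])), core$gap_cols)
  poly <- vapply(seq_len(ncol(core$mat)),
                 function(j) length(unique(core$mat[, j])) > 1, logical(1))
  structure(sum(poly), sites = keep[poly])
}

# Total mutations eta (states - 1 per column) and singleton mutations eta_s
# (states carried by exactly one sequence copy), multiplicity-aware.
mutation_counts <- function(core) {
  eta <- 0L; eta_s <- 0L
  for (j in seq_len(ncol(core$mat))) {
    copies <- tapply(core$mult, core$mat[, j], sum)
    if (length(copies) > 1) {
      eta <- eta + length(copies) - 1L
      eta_s <- eta_s + sum(copies == 1L)
    }
  }
  list(eta = eta, eta_s = eta_s)
}

#' Mean pairwise nucleotide differences (k)
#'
#' Multiplicity-weighted mean Hamming distance over all unordered pairs of
#' sampled sequences, gap columns excluded. With unit multiplicities this is
#' the plain mean over `choose(n, 2)` pairs.
#'
#' @param panel An [aligned_panel()].
#' @return k (numeric); the per-pair distance matrix between distinct
#'   haplotypes is attached as attribute `"pairs"`. `NA` when n < 2.
#' @export
pairwise_differences <- function(panel) {
  core <- panel_core(panel)
  if (core$n < 2) return(structure(NA_real_, pairs = NULL))
  m <- nrow(core$mat)
  d <- matrix(0, m, m, dimnames = list(core$names, core$names))
  if (m > 1) {
    for (u in 1:(m - 1)) {
      for (v in (u + 1):m) {
        d[u, v] <- d[v, u] <- sum(core$mat[u, ] != core$mat[v, ])
      }
    }
  }
  tot <- 0
  for (u in seq_len(m)) {
    for (v in seq_len(m)) {
      if (v > u) tot <- tot + core$mult[u] * core$mult[v] * d[u, v]
    }
  }
  k <- tot / choose(core$n, 2)
  structure(k, pairs = d)
}

#' Nucleotide and haplotype diversity of a panel
#'
#' `pi = k / L` with L the number of non-gap columns, and
#' `Hd = n/(n-1) * (1 - sum p_i^2)` over haplotype frequencies.
#'
#' @param panel An [aligned_panel()].
#' @return One-row tibble: `n`, `L`, `S`, `eta`, `k`, `pi`, `hd`,
#'   `n_haplotypes`.
#' @export
diversity <- function(panel) {
  core <- panel_core(panel)
  if (core$n < 2) stop("diversity requires n >= 2 sampled sequences",
                       call. = FALSE)
  S <- as.integer(segregating_sites(panel))
  mut <- mutation_counts(core)
  k <- as.numeric(pairwise_differences(panel))
  # haplotype frequencies over distinct sequences (rows sharing a sequence
  # pool their multiplicities)
  hap <- tapply(core$mult, collapse_rows(core$mat), sum)
  p <- hap / core$n
  hd <- core$n / (core$n - 1) * (1 - sum(p^2))
  tibble::tibble(n = core$n, L = core$L, S = S, eta = mut$eta, k = k,
                 pi = if (core$L > 0) k / core$L else NA_real_, hd = hd,
                 n_haplotypes = length(hap))
}
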