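# broom-style tidiers for fitted test objects and reports.

#' Tidy an exact HWE test
#'
#' @param x An `hwe_test` object.
#' @param ... Unused.
#' @return One-row tibble: `test`, `p.value`, `std.error`, `method`, `n`,
#'   `k`.
#' @export
tidy.hwe_test <- function(x, ...) {
  tibble::tibble(test = x$test, p.value = x$p, std.error = x$se,
                 method = x$method, n = x$n, k = x$k)
}

#' @rdname tidy.hwe_test
#' @export
glance.hwe_test <- function(x, ...) tidy(x)

#' Tidy a genotypic LD test
#'
#' @param x An `ld_test` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic` (G), `p.value`, `std.error`, `n`,
#'   `method`.
#' @export
tidy.ld_test <- function(x, ...) {
  tibble::tibble(statistic = x$g_obs, p.value = x$p, std.error = x$se,
                 n = x$n, method = x$method)
}

#' @rdname tidy.ld_test
#' @export
glance.ld_test <- function(x, ...) tidy(x)

#' Tidy / summarise a pipeline report
#'
#' `tidy()` returns the per-locus statistic table (diversity, neutrality
#' and dN/dS joined); `glance()` a one-row overview (individuals, loci,
#' overall recovery, LD p, Mendelian consistency).
#'
#' @param x An `mhc_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mhc_report <- function(x, ...) {
  out <- dplyr::left_join(x$diversity, x$neutrality,
                          by = c("locus", "n", "S", "eta"))
  dplyr::left_join(out, x$dnds, by = "locus")
}

#' @rdname tidy.mhc_report
#' @export
glance.mhc_report <- function(x, ...) {
  tibble::tibble(
    n_individuals = x$config$n_individuals,
    n_loci = length(x$panels),
    recovery = sum(x$recovery$recovered * x$recovery$n) / sum(x$recovery$n),
    ld_p = if (!is.null(x$ld)) x$ld$p else NA_real_,
    mendelian = if (!is.null(x$mendelian)) x$mendelian$fraction else NA_real_)
}
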