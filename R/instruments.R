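#' Greedy LD clumping of GWAS summary statistics
#'
#' Selects independent association signals: restrict to variants with
#' `pval < p_threshold`, then repeatedly take the smallest-p remaining
#' variant as an index and discard every remaining variant on the same
#' chromosome within `window_bp` of it whose squared correlation with it is
#' at least `r2_cutoff`. Ties in p are broken by lexicographic rsid, so the
#' result is invariant to input row order. The window is one-sided from the
#' index (PLINK convention: distance from index <= `window_bp`, i.e. a
#' 20 Mb span for the 10 Mb default).
#'
#' @param stats A [summary_stats] object.
#' @param ld An [ld_matrix]; variants absent from it are dropped with a
#'   warning before selection.
#' @param p_threshold Association p-value cutoff for candidate instruments,
#'   default 5e-6.
#' @param window_bp Clumping window in base pairs, default 10 Mb.
#' @param r2_cutoff Squared-correlation threshold above which a neighbour is
#'   absorbed by its index variant, default 0.001.
#' @return Character vector of index rsids in selection order (possibly
#'   empty: the pair is then untestable).
#' @export
clump <- function(stats, ld, p_threshold = 5e-6, window_bp = 1e7,
                  r2_cutoff = 0.001) {
  stopifnot(inherits(stats, "summary_stats"), inherits(ld, "ld_matrix"))
  cand <- tibble::as_tibble(stats) |>
    dplyr::filter(.data$pval < p_threshold)
  absent <- setdiff(cand$rsid, rownames(ld))
  if (length(absent) > 0) {
    rlang::warn(sprintf("clump: %d candidate variant(s) absent from LD matrix, dropped",
                        length(absent)))
    cand <- dplyr::filter(cand, !.data$rsid %in% absent)
  }
  cand <- dplyr::arrange(cand, .data$pval, .data$rsid)

  index <- character(0)
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    index <- c(index, top$rsid)
    cand <- cand[-1, ]
    if (nrow(cand) == 0) break
    r2_with_top <- ld[top$rsid, cand$rsid]
    absorbed <- cand$chrom == top$chrom &
      abs(cand$pos - top$pos) <= window_bp &
      r2_with_top >= r2_cutoff
    cand <- cand[!absorbed, ]
  }
  index
}

#' Per-variant explained variance
#'
#' Proportion of trait variance explained by one variant, computed from
#' summary statistics as
#' `R2 = 2 b^2 f(1-f) / (2 b^2 f(1-f) + 2 n se^2 f(1-f))`,
#' which cancels to `b^2 / (b^2 + n se^2)` — so a missing allele frequency
#' never blocks the diagnostic (`maf` is accepted for interface symmetry and
#' checked when given, but does not enter the value).
#'
#' @param beta Effect estimate.
#' @param se Its standard error (> 0).
#' @param maf Optional minor-allele frequency in (0, 1).
#' @param n GWAS sample size.
#' @return Explained-variance proportion in \[0, 1).
#' @examples
#' snp_r2(beta = 0.1, se = 0.02, maf = 0.3, n = 7738)
#' @export
snp_r2 <- function(beta, se, maf = NA_real_, n) {
  if (any(se <= 0) || any(n < 1)) stop_bad_arg("snp_r2: need se > 0 and n >= 1")
  if (any(!is.na(maf) & (maf <= 0 | maf >= 1))) {
    stop_bad_arg("snp_r2: maf must be in (0, 1)")
  }
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F-statistic
#'
#' `F = R2 (n - k - 1) / (k (1 - R2))` for an instrument of `k` variants
#' jointly explaining `r2_total` of the exposure in a GWAS of `n` samples.
#' Instrument sets with F > 10 are conventionally considered strong enough
#' to avoid weak-instrument bias, and that is the screen the pipeline
#' applies.
#'
#' @param r2_total Total explained variance in \[0, 1).
#' @param n Exposure GWAS sample size (must exceed `k + 1`).
#' @param k Number of variants in the instrument.
#' @return The F-statistic (>= 0).
#' @examples
#' f_statistic(0.5, n = 3, k = 1)  # 1
#' @export
f_statistic <- function(r2_total, n, k) {
  if (k < 1) stop_bad_arg("f_statistic: k must be >= 1")
  if (n <= k + 1) stop_bad_arg("f_statistic: need n > k + 1")
  if (r2_total < 0 || r2_total >= 1) stop_bad_arg("f_statistic: r2_total must be in [0, 1)")
  r2_total * (n - k - 1) / (k * (1 - r2_total))
}

#' Instrument diagnostics for a clumped variant set
#'
#' Sums [snp_r2()] over the selected variants and derives the joint
#' [f_statistic()].
#'
#' @param stats Exposure [summary_stats].
#' @param rsids Instrument rsids (typically from [clump()]).
#' @return One-row tibble: `r2_total`, `f_stat`, `k`, `n`.
#' @export
instrument_diagnostics <- function(stats, rsids) {
  rows <- tibble::as_tibble(stats)[match(rsids, stats$rsid), ]
  if (any(is.na(rows$rsid))) stop_bad_arg("instrument_diagnostics: unknown rsid(s)")
  k <- nrow(rows)
  n <- max(rows$n)
  r2_total <- sum(snp_r2(rows$beta, rows$se, rows$eaf, rows$n))
  tibble::tibble(r2_total = r2_total, f_stat = f_statistic(r2_total, n, k),
                 k = k, n = n)
}

#' Is a trait eligible as an MR exposure?
#'
#' Eligibility requires at least one genome-wide significant association
#' (`min p < gw_threshold`), the screen that reduces confounding through
#' weakly genetically determined traits.
#'
#' @param stats A [summary_stats] object.
#' @param gw_threshold Genome-wide significance level, default 5e-8.
#' @return `TRUE`/`FALSE`.
#' @export
check_exposure_eligibility <- function(stats, gw_threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"))
  nrow(stats) > 0 && min(stats$pval) < gw_threshold
}
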