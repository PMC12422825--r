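#' Resampling-based pleiotropy test (PRESSO-style)
#'
#' Re-implementation of the residual-sum-of-squares outlier framework for
#' two-sample MR: a global test for horizontal pleiotropy, a per-variant
#' outlier test, and a distortion test for the shift of the causal estimate
#' after outlier removal.
#'
#' The observed statistic is the leave-one-out weighted residual sum of
#' squares `RSS = sum_j w_j (beta_out_j - beta_c^(-j) beta_exp_j)^2` with
#' `w_j = 1 / se_out_j^2` and `beta_c^(-j)` the IVW estimate excluding
#' variant j. Its null distribution is built from `n_sim` parametric
#' replicates drawing `beta_exp* ~ N(beta_exp_j, se_exp_j^2)` and
#' `beta_out* ~ N(beta_c^(-j) beta_exp_j, se_out_j^2)` and recomputing RSS
#' the same way; the global p-value is `(1 + #\{RSS* >= RSS_obs\}) /
#' (1 + n_sim)`, never zero. Per-variant p-values compare each observed
#' weighted squared residual against its simulated distribution and are
#' Bonferroni-corrected against `outlier_alpha`. When outliers are found,
#' the distortion test compares the change in IVW estimate after removing
#' them against a null of removing equally many randomly chosen variants,
#' and an outlier-corrected IVW fit is reported.
#'
#' Randomness is consumed from `seed` only, after sorting instruments by
#' rsid, so the result is invariant to instrument order.
#'
#' @param instruments Tibble of harmonized instruments; fewer than 4 rows
#'   yields an untestable result (`NA` p-values, `untestable = TRUE`).
#' @param n_sim Parametric replicates for the null, default 1000.
#' @param outlier_alpha Family-wise level for the Bonferroni outlier call,
#'   default 0.05.
#' @param seed Integer seed.
#' @return One-row tibble: `global_rss_obs`, `global_pval`, `rss_null_mean`
#'   (mean simulated null RSS, a calibration diagnostic), `n_outliers`,
#'   `outlier_rsids` (list column), `distortion_pval`,
#'   `beta_outlier_corrected`, `se_outlier_corrected`,
#'   `p_outlier_corrected`, `n_sim`, `seed`, `untestable`, plus an
#'   `outlier_pvals` list column of per-variant Bonferroni-adjusted
#'   p-values (named by rsid).
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05, seed) {
  if (missing(seed)) stop_bad_arg("mr_presso: `seed` is mandatory")
  m <- nrow(instruments)
  untestable_row <- tibble::tibble(
    global_rss_obs = NA_real_, global_pval = NA_real_, rss_null_mean = NA_real_,
    n_outliers = NA_integer_, outlier_rsids = list(character(0)),
    distortion_pval = NA_real_, beta_outlier_corrected = NA_real_,
    se_outlier_corrected = NA_real_, p_outlier_corrected = NA_real_,
    n_sim = as.integer(n_sim), seed = as.integer(seed),
    untestable = TRUE, outlier_pvals = list(numeric(0))
  )
  if (m < 4) return(untestable_row)

  inst <- dplyr::arrange(instruments, .data$rsid)
  bx <- inst$beta_exp; by <- inst$beta_out
  sx <- inst$se_exp; sy <- inst$se_out
  w_ratio <- bx^2 / sy^2          # IVW weights on the ratio scale
  w_res <- 1 / sy^2               # residual weights
  r <- by / bx

  loo_est <- function(bx, by, sy) {
    w <- bx^2 / sy^2
    rr <- by / bx
    (sum(w * rr) - w * rr) / (sum(w) - w)  # vector of beta_c^(-j)
  }
  bc_loo <- loo_est(bx, by, sy)
  res_obs <- w_res * (by - bc_loo * bx)^2
  rss_obs <- sum(res_obs)

  withr::with_seed(as.integer(seed), {
    bx_star <- matrix(stats::rnorm(m * n_sim, bx, sx), nrow = m)
    by_star <- matrix(stats::rnorm(m * n_sim, bc_loo * bx, sy), nrow = m)
    w_star <- bx_star^2 / sy^2
    r_star <- by_star / bx_star
    sum_wr <- colSums(w_star * r_star)
    sum_w <- colSums(w_star)
    bc_loo_star <- (matrix(sum_wr, m, n_sim, byrow = TRUE) - w_star * r_star) /
      (matrix(sum_w, m, n_sim, byrow = TRUE) - w_star)
    res_star <- w_res * (by_star - bc_loo_star * bx_star)^2
    rss_star <- colSums(res_star)

    global_pval <- (1 + sum(rss_star >= rss_obs)) / (1 + n_sim)
    outlier_p_raw <- (1 + rowSums(res_star >= res_obs)) / (1 + n_sim)
    outlier_p_adj <- pmin(1, outlier_p_raw * m)
    names(outlier_p_adj) <- inst$rsid
    out_idx <- which(outlier_p_adj < outlier_alpha)

    ivw_all <- mr_ivw(inst)
    distortion_pval <- NA_real_
    if (length(out_idx) > 0 && m - length(out_idx) >= 2) {
      corrected <- mr_ivw(inst[-out_idx, ])
      d_obs <- corrected$estimate - ivw_all$estimate
      d_null <- vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(m, length(out_idx))
        mr_ivw(inst[-drop_idx, ])$estimate - ivw_all$estimate
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
    } else if (length(out_idx) > 0) {
      corrected <- ivw_all  # too few variants left to re-estimate
    } else {
      corrected <- ivw_all
    }

    tibble::tibble(
      global_rss_obs = rss_obs, global_pval = global_pval,
      rss_null_mean = mean(rss_star),
      n_outliers = length(out_idx),
      outlier_rsids = list(inst$rsid[out_idx]),
      distortion_pval = distortion_pval,
      beta_outlier_corrected = corrected$estimate,
      se_outlier_corrected = corrected$std.error,
      p_outlier_corrected = corrected$p.value,
      n_sim = as.integer(n_sim), seed = as.integer(seed),
      untestable = FALSE, outlier_pvals = list(outlier_p_adj)
    )
  })
}
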