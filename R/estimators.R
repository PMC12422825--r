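#' Single-variant Wald ratio estimate
#'
#' The base causal estimate from one harmonized instrument:
#' `beta_c = beta_out / beta_exp`, with first-order (delta-method) standard
#' error `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param instruments Tibble of harmonized instruments (as from
#'   [harmonize()]); must contain exactly one row.
#' @return One-row tibble: `method`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `n_snps`.
#' @export
mr_wald_ratio <- function(instruments) {
  if (nrow(instruments) != 1) stop_bad_arg("mr_wald_ratio: exactly one instrument required")
  if (instruments$beta_exp == 0) stop_bad_arg("mr_wald_ratio: beta_exp must be nonzero")
  est <- instruments$beta_out / instruments$beta_exp
  se <- instruments$se_out / abs(instruments$beta_exp)
  z <- est / se
  tibble::tibble(method = "wald", estimate = est, std.error = se,
                 statistic = z, p.value = two_sided_normal_p(z), n_snps = 1L)
}

#' Inverse-variance-weighted causal estimate with Cochran's Q
#'
#' The primary two-sample MR estimator: the inverse-variance-weighted
#' average of per-variant Wald ratios `r_j = beta_out_j / beta_exp_j` with
#' weights `w_j = beta_exp_j^2 / se_out_j^2` — algebraically the
#' zero-intercept weighted regression of outcome on exposure effects.
#' Under the `"fixed"` model `se = 1/sqrt(sum w)`; the default
#' multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q/(m-1)))`, where `Q = sum w_j (r_j - beta_c)^2` is
#' Cochran's heterogeneity statistic (upper-tail chi-square on `m - 1` df).
#' P-values are two-sided normal. A single instrument defers to
#' [mr_wald_ratio()]; heterogeneity is then undefined.
#'
#' @param instruments Tibble of harmonized instruments, >= 1 row.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row tibble: the [mr_wald_ratio()] columns with
#'   `method = "ivw"` plus heterogeneity columns `q`, `q_df`, `q_pval`.
#' @export
mr_ivw <- function(instruments, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  m <- nrow(instruments)
  if (m < 1) stop_bad_arg("mr_ivw: empty instrument set")
  if (any(instruments$beta_exp == 0)) stop_bad_arg("mr_ivw: beta_exp must be nonzero")
  if (m == 1) {
    out <- mr_wald_ratio(instruments)
    out$method <- "ivw"
    return(dplyr::mutate(out, q = NA_real_, q_df = NA_integer_, q_pval = NA_real_))
  }
  r <- instruments$beta_out / instruments$beta_exp
  w <- instruments$beta_exp^2 / instruments$se_out^2
  est <- sum(w * r) / sum(w)
  q <- sum(w * (r - est)^2)
  se_fixed <- 1 / sqrt(sum(w))
  se <- if (model == "fixed") se_fixed else se_fixed * max(1, sqrt(q / (m - 1)))
  z <- est / se
  tibble::tibble(method = "ivw", estimate = est, std.error = se,
                 statistic = z, p.value = two_sided_normal_p(z), n_snps = m,
                 q = q, q_df = m - 1L,
                 q_pval = stats::pchisq(q, m - 1, lower.tail = FALSE))
}

# weighted-median point estimate on sorted ratios; weights need not be
# normalized. Cumulative midpoints p_j = (S_j - w_j/2)/S_m, linear
# interpolation of the ratio over p at 0.5.
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  s <- cumsum(w)
  p <- (s - w / 2) / s[length(s)]
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The median of the per-variant Wald ratios under the IVW weights,
#' consistent when at least half the weight comes from valid instruments.
#' The point estimate interpolates the sorted ratios over cumulative weight
#' midpoints at 0.5; the standard error has no closed form and is estimated
#' by a seeded parametric bootstrap (exposure and outcome effects resampled
#' from their normal sampling distributions, weights recomputed each draw).
#' The p-value is a two-sided normal test on estimate / bootstrap-se.
#'
#' @param instruments Tibble of harmonized instruments, >= 3 rows.
#' @param n_boot Bootstrap draws for the standard error, default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed) {
  m <- nrow(instruments)
  if (m < 3) stop_bad_arg("mr_weighted_median: at least 3 instruments required")
  if (missing(seed)) stop_bad_arg("mr_weighted_median: `seed` is mandatory")
  r <- instruments$beta_out / instruments$beta_exp
  w <- instruments$beta_exp^2 / instruments$se_out^2
  est <- weighted_median_point(r, w)
  se <- withr::with_seed(as.integer(seed), {
    boots <- vapply(seq_len(n_boot), function(b) {
      be <- stats::rnorm(m, instruments$beta_exp, instruments$se_exp)
      bo <- stats::rnorm(m, instruments$beta_out, instruments$se_out)
      ok <- be != 0
      weighted_median_point(bo[ok] / be[ok], be[ok]^2 / instruments$se_out[ok]^2)
    }, numeric(1))
    stats::sd(boots)
  })
  z <- est / se
  tibble::tibble(method = "weighted_median", estimate = est, std.error = se,
                 statistic = z, p.value = two_sided_normal_p(z), n_snps = m)
}

#' MR-Egger regression: pleiotropy-adjusted slope and intercept
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept, weights `1 / se_out^2`, after orienting every instrument
#' to a non-negative exposure effect (both signs flipped where needed —
#' results differ if this step is omitted). The slope is a causal estimate
#' robust to directional pleiotropy under the InSIDE assumption; the
#' intercept estimates the average direct (pleiotropic) effect. Standard
#' errors carry a multiplicative overdispersion factor
#' `max(1, sqrt(RSS_w / (m - 2)))`; p-values use Student's t on `m - 2` df.
#'
#' @param instruments Tibble of harmonized instruments, >= 3 rows.
#' @return Two-row tibble, `method = c("egger_slope", "egger_intercept")`.
#' @export
mr_egger <- function(instruments) {
  m <- nrow(instruments)
  if (m < 3) stop_bad_arg("mr_egger: at least 3 instruments required")
  flip <- sign(instruments$beta_exp)
  flip[flip == 0] <- 1
  x <- instruments$beta_exp * flip
  y <- instruments$beta_out * flip
  w <- 1 / instruments$se_out^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (abs(det) < 1e-300 || stats::var(x) == 0) {
    stop_bad_arg("mr_egger: exposure effects constant after orientation (singular design)")
  }
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  rss <- sum(w * resid^2)
  phi <- max(1, sqrt(rss / (m - 2)))
  se_slope <- sqrt(sw / det) * phi
  se_intercept <- sqrt(swxx / det) * phi
  t_slope <- slope / se_slope
  t_intercept <- intercept / se_intercept
  p2t <- function(t) 2 * stats::pt(-abs(t), df = m - 2)
  tibble::tibble(
    method = c("egger_slope", "egger_intercept"),
    estimate = c(slope, intercept),
    std.error = c(se_slope, se_intercept),
    statistic = c(t_slope, t_intercept),
    p.value = c(p2t(t_slope), p2t(t_intercept)),
    n_snps = m
  )
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Repeats the (multiplicative random-effects) IVW estimate dropping each
#' instrument in turn, flagging whether any subset estimate changes sign
#' relative to the full-set estimate — an automated proxy for the visual
#' inspection of leave-one-out plots.
#'
#' @param instruments Tibble of harmonized instruments, >= 3 rows.
#' @return A tibble with one row per left-out rsid (`rsid_left_out`,
#'   `estimate`, `p.value`), carrying attributes `estimate_full`,
#'   `estimate_min`, `estimate_max` and `flag_sign_change`; see
#'   [loo_sign_change()].
#' @export
mr_leave_one_out <- function(instruments) {
  m <- nrow(instruments)
  if (m < 3) stop_bad_arg("mr_leave_one_out: at least 3 instruments required")
  full <- mr_ivw(instruments)
  rows <- purrr::map(seq_len(m), function(j) {
    fit <- mr_ivw(instruments[-j, ])
    tibble::tibble(rsid_left_out = instruments$rsid[j],
                   estimate = fit$estimate, p.value = fit$p.value)
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    estimate_full = full$estimate,
    estimate_min = min(out$estimate),
    estimate_max = max(out$estimate),
    flag_sign_change = any(out$estimate * full$estimate < 0)
  )
}

#' @rdname mr_leave_one_out
#' @param loo Result of [mr_leave_one_out()].
#' @export
loo_sign_change <- function(loo) isTRUE(attr(loo, "flag_sign_change"))

#' Scatter-plot data for per-variant effects and fitted MR lines
#'
#' The table behind the classic MR scatter plot: one point per instrument
#' (exposure and outcome effects with their standard errors) and one
#' `(slope, intercept)` line per estimator — IVW and weighted-median lines
#' pass through the origin by construction, the Egger line carries its
#' estimated intercept.
#'
#' @param instruments Tibble of harmonized instruments.
#' @param results Tibble of estimator rows (as returned by [mr_ivw()],
#'   [mr_weighted_median()], [mr_egger()], bound together).
#' @return List of two tibbles: `points` and `lines`.
#' @export
mr_scatter_data <- function(instruments, results) {
  points <- dplyr::select(instruments, "rsid", "beta_exp", "se_exp",
                          "beta_out", "se_out")
  egger_int <- results$estimate[results$method == "egger_intercept"]
  lines <- results |>
    dplyr::filter(.data$method %in% c("ivw", "weighted_median", "egger_slope")) |>
    dplyr::transmute(
      slope = .data$estimate,
      intercept = ifelse(.data$method == "egger_slope" & length(egger_int) == 1,
                         egger_int[1], 0),
      method = ifelse(.data$method == "egger_slope", "egger", .data$method)
    ) |>
    dplyr::select("method", "slope", "intercept")
  list(points = points, lines = lines)
}
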