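# shared kernel: Power = Phi( sqrt(N * R2) * |beta| * c - z_{1 - alpha/2} ),
# the standard non-centrality approximation for an IV analysis; c = 1 for
# continuous outcomes and sqrt(ratio)/(1 + ratio) for binary (log-odds)
# outcomes. The alternative reading Phi(x) - z of the same expression is not
# a probability and is rejected; see the methods vignette.
power_kernel <- function(beta_c, n, r2, alpha, scale) {
  if (n < 1) stop_bad_arg("power: n must be >= 1")
  assert_prob(r2, "r2")
  assert_prob(alpha, "alpha")
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(n * r2) * abs(beta_c) * scale - z)
}

#' Post-hoc power of an MR test, continuous outcome
#'
#' Approximate probability that an IVW test at level `alpha` detects a true
#' causal effect `beta_c`, given the outcome GWAS sample size `n` and the
#' variance `r2` of the exposure explained by the instrument:
#' `Power = Phi( sqrt(N R2) |beta_c| - z_{1-alpha/2} )`. At `beta_c = 0`
#' this is the one-tail rejection mass `alpha / 2`.
#'
#' @param beta_c Causal effect (outcome units per exposure SD).
#' @param n Outcome GWAS sample size.
#' @param r2 Exposure variance explained by the instrument, in (0, 1).
#' @param alpha Significance level, default 0.05.
#' @return One-row tibble: `power`, `beta_c`, `n`, `r2`, `alpha`, `ratio`
#'   (`NA` here), `outcome_type`.
#' @examples
#' power_continuous(beta_c = -0.11, n = 54219, r2 = 0.01)
#' @export
power_continuous <- function(beta_c, n, r2, alpha = 0.05) {
  tibble::tibble(
    power = power_kernel(beta_c, n, r2, alpha, scale = 1),
    beta_c = beta_c, n = as.numeric(n), r2 = r2, alpha = alpha,
    ratio = NA_real_, outcome_type = "continuous"
  )
}

#' Post-hoc power of an MR test, binary outcome
#'
#' As [power_continuous()] with the case/control design factor:
#' `Power = Phi( sqrt(N R2 beta_c^2 ratio / (1 + ratio)^2) - z_{1-alpha/2} )`,
#' `ratio` = cases/controls and `beta_c` on the log-odds scale. The factor
#' `ratio/(1+ratio)^2` is the product of case and control fractions, so it
#' is symmetric in `ratio` vs `1/ratio` and maximal for a balanced design.
#'
#' @inheritParams power_continuous
#' @param ratio Cases divided by controls (> 0).
#' @return One-row tibble as in [power_continuous()].
#' @export
power_binary <- function(beta_c, n, r2, ratio, alpha = 0.05) {
  if (!is.numeric(ratio) || is.na(ratio) || ratio <= 0) {
    stop_bad_arg("power_binary: ratio must be > 0")
  }
  tibble::tibble(
    power = power_kernel(beta_c, n, r2, alpha, scale = sqrt(ratio) / (1 + ratio)),
    beta_c = beta_c, n = as.numeric(n), r2 = r2, alpha = alpha,
    ratio = ratio, outcome_type = "binary"
  )
}

#' Power across a grid of causal effect sizes
#'
#' One power estimate per `beta_grid` value at fixed design parameters —
#' the data behind a power curve.
#'
#' @param beta_grid Non-empty numeric vector of causal effects.
#' @inheritParams power_binary
#' @param outcome_type `"continuous"` or `"binary"` (requires `ratio`).
#' @return Tibble with one row per grid point, columns as in
#'   [power_continuous()].
#' @export
power_curve <- function(beta_grid, n, r2, alpha = 0.05,
                        outcome_type = c("continuous", "binary"),
                        ratio = NA_real_) {
  outcome_type <- match.arg(outcome_type)
  if (length(beta_grid) == 0) stop_bad_arg("power_curve: empty beta grid")
  purrr::map_dfr(beta_grid, function(b) {
    if (outcome_type == "continuous") power_continuous(b, n, r2, alpha)
    else power_binary(b, n, r2, ratio, alpha)
  })
}
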