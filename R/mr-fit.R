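#' Fit the full MR estimator battery to one instrument set
#'
#' Runs IVW (with Cochran's Q), the weighted median, MR-Egger and the
#' leave-one-out analysis on a harmonized instrument table, returning a
#' single `mr_fit` object with [generics::tidy()] / [generics::glance()]
#' methods and plotting helpers. Sensitivity analyses that need more
#' instruments than are available are recorded as untestable rather than
#' failing the fit.
#'
#' @param instruments Tibble of harmonized instruments (from [harmonize()]).
#' @param n_boot Bootstrap draws for the weighted-median standard error.
#' @param seed Integer seed for the bootstrap.
#' @param model IVW variance model, see [mr_ivw()].
#' @return An object of class `mr_fit`.
#' @examples
#' sim <- simulate_pair(sim_scenario(m_snps = 8, beta_causal = 0.2,
#'                                   exposure_r2_total = 0.05, seed = 7))
#' inst <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(inst, seed = 7)
#' generics::tidy(fit)
#' @export
mr_fit <- function(instruments, n_boot = 1000, seed,
                   model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  if (missing(seed)) stop_bad_arg("mr_fit: `seed` is mandatory")
  m <- nrow(instruments)
  if (m < 1) stop_bad_arg("mr_fit: empty instrument set")
  ivw <- mr_ivw(instruments, model = model)
  wm <- if (m >= 3) mr_weighted_median(instruments, n_boot = n_boot, seed = seed) else NULL
  egger <- if (m >= 3) tryCatch(mr_egger(instruments), error = function(e) NULL) else NULL
  loo <- if (m >= 3) mr_leave_one_out(instruments) else NULL
  structure(list(instruments = instruments, ivw = ivw, wm = wm,
                 egger = egger, loo = loo, seed = as.integer(seed),
                 model = model),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR fit on %d instrument(s)\n", nrow(x$instruments)))
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy an MR fit into one row per estimator
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `method`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `n_snps`.
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::select(x$ivw, -dplyr::any_of(c("q", "q_df", "q_pval"))),
    x$wm, x$egger
  )
}

#' One-row model-level summary of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `n_snps`, IVW estimate and p, heterogeneity `q`
#'   and `q_pval`, Egger intercept and its p, `loo_sign_change`.
#' @export
glance.mr_fit <- function(x, ...) {
  egger_int <- if (!is.null(x$egger)) {
    x$egger[x$egger$method == "egger_intercept", ]
  } else NULL
  tibble::tibble(
    n_snps = nrow(x$instruments),
    estimate_ivw = x$ivw$estimate, p_ivw = x$ivw$p.value,
    q = x$ivw$q, q_pval = x$ivw$q_pval,
    egger_intercept = if (is.null(egger_int)) NA_real_ else egger_int$estimate,
    p_egger_intercept = if (is.null(egger_int)) NA_real_ else egger_int$p.value,
    loo_sign_change = if (is.null(x$loo)) NA else loo_sign_change(x$loo)
  )
}
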