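#' Screen configuration
#'
#' All thresholds of the screening pipeline in one list, overridable
#' individually or from YAML via [read_mr_config()]. Defaults are the
#' conventional screen settings: instrument p < 5e-6 after clumping in a
#' 10 Mb window at r-squared 0.001, exposure eligibility at genome-wide
#' significance 5e-8, the +/- 4 SD effect-size filter, an F > 10 strength
#' screen, FDR 0.05 within each outcome, and nominal 0.05 for every
#' sensitivity gate.
#'
#' @param p_threshold Instrument association p-value cutoff (clumping).
#' @param gw_threshold Genome-wide significance level for exposure
#'   eligibility.
#' @param window_bp Clumping window (bp, one-sided from the index variant).
#' @param r2_cutoff Clumping squared-correlation cutoff.
#' @param sd_threshold Exposure effect-size filter, in SD units.
#' @param f_threshold Minimum instrument F-statistic (exclusive).
#' @param fdr_alpha Significance level on BH-adjusted IVW p-values.
#' @param gate_alpha Nominal level for the sensitivity gates.
#' @param palindromic_eaf_window Ambiguity band for palindromic variants.
#' @param n_boot Weighted-median bootstrap draws.
#' @param n_sim PRESSO resampling replicates.
#' @param outlier_alpha Family-wise level for the PRESSO outlier call.
#' @param ivw_model `"multiplicative_random"` or `"fixed"`.
#' @param seed Master seed; every stochastic step derives its own sub-seed
#'   from it and the pair's identifiers.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_threshold = 5e-6, gw_threshold = 5e-8,
                      window_bp = 1e7, r2_cutoff = 0.001,
                      sd_threshold = 4, f_threshold = 10,
                      fdr_alpha = 0.05, gate_alpha = 0.05,
                      palindromic_eaf_window = 0.08,
                      n_boot = 1000, n_sim = 1000, outlier_alpha = 0.05,
                      ivw_model = c("multiplicative_random", "fixed"),
                      seed = 1) {
  structure(list(
    p_threshold = p_threshold, gw_threshold = gw_threshold,
    window_bp = window_bp, r2_cutoff = r2_cutoff,
    sd_threshold = sd_threshold, f_threshold = f_threshold,
    fdr_alpha = fdr_alpha, gate_alpha = gate_alpha,
    palindromic_eaf_window = palindromic_eaf_window,
    n_boot = n_boot, n_sim = n_sim, outlier_alpha = outlier_alpha,
    ivw_model = match.arg(ivw_model), seed = as.integer(seed)
  ), class = "mr_config")
}

#' @rdname mr_config
#' @param path YAML file whose top-level keys override the defaults
#'   (unknown keys are an error). A `column_map` key, if present, is carried
#'   through for [read_summary_stats()].
#' @export
read_mr_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  column_map <- overrides$column_map
  overrides$column_map <- NULL
  known <- names(formals(mr_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0) {
    stop_bad_arg(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- do.call(mr_config, overrides)
  cfg$column_map <- column_map
  cfg
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`stats::p.adjust(method = "BH")`),
#' returned in input order; an empty input yields an empty output.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1)) {
    stop_bad_arg("bh_fdr: p-values must be in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# result-table columns, in export order
RESULT_COLUMNS <- c("exposure", "outcome", "n_snps", "beta_ivw", "se_ivw",
                    "p_ivw", "p_fdr", "beta_wm", "p_wm", "beta_egger",
                    "p_egger", "p_egger_intercept", "q", "p_q",
                    "presso_global_p", "presso_distortion_p",
                    "loo_sign_change", "reverse_p", "status")

untestable_pair <- function(exposure_id, outcome_id, reason) {
  tibble::tibble(
    exposure = exposure_id, outcome = outcome_id, n_snps = 0L,
    beta_ivw = NA_real_, se_ivw = NA_real_, p_ivw = NA_real_,
    p_fdr = NA_real_, beta_wm = NA_real_, p_wm = NA_real_,
    beta_egger = NA_real_, p_egger = NA_real_, p_egger_intercept = NA_real_,
    q = NA_real_, p_q = NA_real_, presso_global_p = NA_real_,
    presso_distortion_p = NA_real_, presso_p_corrected = NA_real_,
    loo_sign_change = NA, reverse_p = NA_real_, status = "untestable",
    gates_na = NA_character_, untestable_reason = reason,
    f_stat = NA_real_, r2_total = NA_real_,
    instrument_rsids = list(character(0))
  )
}

#' Run the exposure-by-outcome MR screen
#'
#' Orchestrates the full screen: exposure eligibility and quality control,
#' one clumping per exposure (reused across outcomes), harmonization and
#' the estimator + sensitivity battery per pair, BH-FDR on IVW p-values
#' within each outcome (across its exposures), bidirectional MR for
#' FDR-passing pairs, and the conjunctive significance gate. A pair is
#' `"significant"` iff its FDR-adjusted IVW p is below `fdr_alpha` AND the
#' weighted median is nominally significant AND the PRESSO
#' (outlier-corrected) test is significant AND neither the Egger intercept
#' nor Cochran's Q is significant AND there is no significant reverse
#' effect AND no leave-one-out sign change. Sensitivity tests that cannot
#' run (too few instruments) pass by NA and are listed in `gates_na`, so
#' the table can always be re-gated with [regate()].
#'
#' @param exposures,outcomes Named lists of [summary_stats] (names default
#'   to trait ids).
#' @param ld An [ld_matrix] covering the variants of all traits.
#' @param config An [mr_config].
#' @param reverse Run bidirectional MR on FDR-passing pairs (default TRUE).
#' @return A tibble with one row per exposure-outcome pair: the canonical
#'   result columns (see [export_results()]) plus `presso_p_corrected`,
#'   `gates_na`, `untestable_reason`, `f_stat`, `r2_total` and the
#'   `instrument_rsids` list column.
#' @export
run_screen <- function(exposures, outcomes, ld, config = mr_config(),
                       reverse = TRUE) {
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- purrr::map_chr(exposures, trait_id)
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- purrr::map_chr(outcomes, trait_id)
  }
  cfg <- config

  # per-exposure instrument selection, done once and reused
  prep <- purrr::map(names(exposures), function(eid) {
    ss <- exposures[[eid]]
    if (!check_exposure_eligibility(ss, cfg$gw_threshold)) {
      return(list(status = "ineligible"))
    }
    ss <- suppressMessages(filter_extreme_effects(ss, cfg$sd_threshold))
    ivs <- clump(ss, ld, p_threshold = cfg$p_threshold,
                 window_bp = cfg$window_bp, r2_cutoff = cfg$r2_cutoff)
    if (length(ivs) == 0) return(list(status = "no_instruments"))
    diag <- instrument_diagnostics(ss, ivs)
    if (diag$f_stat <= cfg$f_threshold) {
      return(list(status = "weak_instruments"))
    }
    list(status = "ok", stats = ss, ivs = ivs, diag = diag)
  })
  names(prep) <- names(exposures)

  pair_rows <- purrr::map(names(exposures), function(eid) {
    pe <- prep[[eid]]
    purrr::map(names(outcomes), function(oid) {
      if (pe$status != "ok") return(untestable_pair(eid, oid, pe$status))
      inst <- suppressMessages(harmonize(pe$stats, outcomes[[oid]], pe$ivs,
                                         cfg$palindromic_eaf_window))
      m <- nrow(inst)
      if (m == 0) return(untestable_pair(eid, oid, "no_shared_instruments"))

      ivw <- mr_ivw(inst, model = cfg$ivw_model)
      wm <- if (m >= 3) {
        mr_weighted_median(inst, n_boot = cfg$n_boot,
                           seed = derive_seed(cfg$seed, "wm", eid, oid))
      } else NULL
      egger <- if (m >= 3) tryCatch(mr_egger(inst), error = function(e) NULL) else NULL
      loo_flag <- if (m >= 3) loo_sign_change(mr_leave_one_out(inst)) else NA
      presso <- mr_presso(inst, n_sim = cfg$n_sim,
                          outlier_alpha = cfg$outlier_alpha,
                          seed = derive_seed(cfg$seed, "presso", eid, oid))
      eg_slope <- if (!is.null(egger)) egger[egger$method == "egger_slope", ] else NULL
      eg_int <- if (!is.null(egger)) egger[egger$method == "egger_intercept", ] else NULL

      tibble::tibble(
        exposure = eid, outcome = oid, n_snps = m,
        beta_ivw = ivw$estimate, se_ivw = ivw$std.error, p_ivw = ivw$p.value,
        p_fdr = NA_real_,
        beta_wm = if (is.null(wm)) NA_real_ else wm$estimate,
        p_wm = if (is.null(wm)) NA_real_ else wm$p.value,
        beta_egger = if (is.null(eg_slope)) NA_real_ else eg_slope$estimate,
        p_egger = if (is.null(eg_slope)) NA_real_ else eg_slope$p.value,
        p_egger_intercept = if (is.null(eg_int)) NA_real_ else eg_int$p.value,
        q = ivw$q, p_q = ivw$q_pval,
        presso_global_p = presso$global_pval,
        presso_distortion_p = presso$distortion_pval,
        presso_p_corrected = presso$p_outlier_corrected,
        loo_sign_change = loo_flag,
        reverse_p = NA_real_, status = NA_character_,
        gates_na = NA_character_, untestable_reason = NA_character_,
        f_stat = pe$diag$f_stat, r2_total = pe$diag$r2_total,
        instrument_rsids = list(inst$rsid)
      )
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(pair_rows))

  # BH-FDR within each outcome, across its exposures (testable pairs only)
  res <- res |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(p_fdr = {
      p <- .data$p_ivw
      adj <- rep(NA_real_, length(p))
      adj[!is.na(p)] <- bh_fdr(p[!is.na(p)])
      adj
    }) |>
    dplyr::ungroup()

  # bidirectional MR for FDR-passing pairs only
  if (reverse) {
    hits <- which(!is.na(res$p_fdr) & res$p_fdr < cfg$fdr_alpha)
    for (i in hits) {
      res$reverse_p[i] <- reverse_mr(outcomes[[res$outcome[i]]],
                                     exposures[[res$exposure[i]]], ld, cfg)
    }
  }

  regate(res, cfg)
}

#' Re-derive gate decisions and status from a results table
#'
#' Applies the conjunctive significance gate to the recorded per-pair test
#' columns, so a (re-imported) results table can be re-gated under the same
#' or altered thresholds without recomputation.
#'
#' @param results A results tibble with the canonical columns.
#' @param config An [mr_config] supplying `fdr_alpha` and `gate_alpha`.
#' @return `results` with `status` and `gates_na` recomputed.
#' @export
regate <- function(results, config = mr_config()) {
  a <- config$gate_alpha
  gate <- function(x, pass) ifelse(is.na(x), NA, pass(x))
  g_wm <- gate(results$p_wm, function(x) x < a)
  g_presso <- gate(results$presso_p_corrected, function(x) x < a)
  g_egger <- gate(results$p_egger_intercept, function(x) x > a)
  g_het <- gate(results$p_q, function(x) x > a)
  g_rev <- gate(results$reverse_p, function(x) x >= a)
  g_loo <- ifelse(is.na(results$loo_sign_change), NA, !results$loo_sign_change)

  gates <- cbind(wm = g_wm, presso = g_presso, egger_intercept = g_egger,
                 heterogeneity = g_het, reverse = g_rev, loo = g_loo)
  all_pass <- apply(gates, 1, function(g) all(g | is.na(g)))
  gates_na <- apply(gates, 1, function(g) {
    nas <- colnames(gates)[is.na(g)]
    if (length(nas) == 0) NA_character_ else paste(nas, collapse = ",")
  })

  fdr_hit <- !is.na(results$p_fdr) & results$p_fdr < config$fdr_alpha
  status <- dplyr::case_when(
    is.na(results$p_ivw) ~ "untestable",
    fdr_hit & all_pass ~ "significant",
    fdr_hit ~ "fdr_only",
    TRUE ~ "not_significant"
  )
  results$status <- status
  results$gates_na <- ifelse(status == "untestable", results$gates_na, gates_na)
  results
}

#' Bidirectional (reverse) MR p-value
#'
#' Runs the instrument-selection and IVW machinery with the roles swapped —
#' the outcome trait as exposure, the exposure trait as outcome — at the
#' same thresholds, and returns the reverse IVW p-value. A reverse p of at
#' least `gate_alpha` supports the absence of reverse causation. `NA` when
#' the outcome trait yields no instruments (the gate then passes by NA).
#'
#' @param outcome_as_exposure The original outcome [summary_stats].
#' @param exposure_as_outcome The original exposure [summary_stats].
#' @param ld An [ld_matrix].
#' @param config An [mr_config].
#' @return Reverse IVW p-value, or `NA_real_`.
#' @export
reverse_mr <- function(outcome_as_exposure, exposure_as_outcome, ld,
                       config = mr_config()) {
  cfg <- config
  ss <- suppressMessages(suppressWarnings(
    filter_extreme_effects(outcome_as_exposure, cfg$sd_threshold)))
  ivs <- suppressWarnings(clump(ss, ld, p_threshold = cfg$p_threshold,
                                window_bp = cfg$window_bp,
                                r2_cutoff = cfg$r2_cutoff))
  if (length(ivs) == 0) {
    rlang::inform("reverse_mr: no reverse instruments; gate passes by NA")
    return(NA_real_)
  }
  inst <- suppressMessages(harmonize(ss, exposure_as_outcome, ivs,
                                     cfg$palindromic_eaf_window))
  if (nrow(inst) == 0) return(NA_real_)
  mr_ivw(inst, model = cfg$ivw_model)$p.value
}

#' Replication of significant screen results
#'
#' Re-runs IVW for each significant pair against each replication outcome
#' dataset, re-harmonizing the same instruments (variants absent from a
#' replication dataset are skipped, without proxies). A result replicates
#' when the replication p-value is below `gate_alpha` and the effect has
#' the same direction as in the main analysis.
#'
#' @param results Screen results from [run_screen()].
#' @param exposures Named list of exposure [summary_stats] used in the
#'   screen.
#' @param replication_outcomes Named list of replication [summary_stats];
#'   names are dataset ids.
#' @param config An [mr_config].
#' @return Tibble: `exposure`, `outcome`, `dataset_id`, `beta`, `se`, `p`,
#'   `replicated`.
#' @export
replicate_pairs <- function(results, exposures, replication_outcomes,
                            config = mr_config()) {
  if (is.null(names(replication_outcomes))) {
    names(replication_outcomes) <- purrr::map_chr(replication_outcomes, trait_id)
  }
  sig <- dplyr::filter(results, .data$status == "significant")
  rows <- purrr::pmap(list(sig$exposure, sig$outcome, sig$beta_ivw,
                           sig$instrument_rsids), function(eid, oid, beta_main, ivs) {
    purrr::map(names(replication_outcomes), function(did) {
      inst <- suppressMessages(harmonize(exposures[[eid]],
                                         replication_outcomes[[did]], ivs,
                                         config$palindromic_eaf_window))
      if (nrow(inst) == 0) {
        return(tibble::tibble(exposure = eid, outcome = oid, dataset_id = did,
                              beta = NA_real_, se = NA_real_, p = NA_real_,
                              replicated = FALSE))
      }
      fit <- mr_ivw(inst, model = config$ivw_model)
      tibble::tibble(
        exposure = eid, outcome = oid, dataset_id = did,
        beta = fit$estimate, se = fit$std.error, p = fit$p.value,
        replicated = is_replicated(fit$estimate, fit$p.value, beta_main,
                                   config$gate_alpha)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' @rdname replicate_pairs
#' @param beta,p Replication estimate and p-value.
#' @param beta_main Main-analysis estimate.
#' @param alpha Replication significance level, default 0.05.
#' @export
is_replicated <- function(beta, p, beta_main, alpha = 0.05) {
  !is.na(p) && !is.na(beta) && p < alpha && sign(beta) == sign(beta_main)
}

#' Export screen results as tab-delimited tables
#'
#' Writes four files under `dir`: `results.tsv` (one row per pair, the
#' canonical columns `exposure outcome n_snps beta_ivw se_ivw p_ivw p_fdr
#' beta_wm p_wm beta_egger p_egger p_egger_intercept q p_q presso_global_p
#' presso_distortion_p loo_sign_change reverse_p status`),
#' `significant.tsv` (significant pairs only, the headline-table shape:
#' estimate plus every gate p-value), and `forest.tsv` (estimate with 95%
#' CI bounds `beta +/- 1.96 se` and a label, plot-ready), and
#' `results_full.tsv`, which adds the gate bookkeeping columns
#' (`presso_p_corrected`, `gates_na`, instrument lists, diagnostics) so
#' that re-importing it and applying [regate()] reproduces the significant
#' set exactly.
#'
#' @param results Screen results tibble.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
export_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(dir, "results.tsv"),
             results_full = file.path(dir, "results_full.tsv"),
             significant = file.path(dir, "significant.tsv"),
             forest = file.path(dir, "forest.tsv"))
  canonical <- dplyr::select(results, dplyr::all_of(RESULT_COLUMNS))
  readr::write_tsv(canonical, paths[["results"]], na = "NA", progress = FALSE)
  full <- results |>
    dplyr::mutate(instrument_rsids = purrr::map_chr(.data$instrument_rsids,
                                                    paste, collapse = ",")) |>
    dplyr::select(dplyr::all_of(c(RESULT_COLUMNS, "presso_p_corrected",
                                  "gates_na", "untestable_reason", "f_stat",
                                  "r2_total", "instrument_rsids")))
  readr::write_tsv(full, paths[["results_full"]], na = "NA", progress = FALSE)

  sig <- results |>
    dplyr::filter(.data$status == "significant") |>
    dplyr::transmute(
      exposure = .data$exposure, outcome = .data$outcome,
      beta_c = .data$beta_ivw, p_fdr = .data$p_fdr, p_wm = .data$p_wm,
      p_presso = .data$presso_p_corrected,
      p_pleiotropy = .data$p_egger_intercept,
      p_heterogeneity = .data$p_q, p_reverse = .data$reverse_p
    )
  readr::write_tsv(sig, paths[["significant"]], na = "NA", progress = FALSE)

  readr::write_tsv(forest_data(dplyr::filter(results, !is.na(.data$beta_ivw))),
                   paths[["forest"]], na = "NA", progress = FALSE)
  invisible(paths)
}
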