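#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- (or otherwise) delimited file with a header row and returns a
#' validated [summary_stats] tibble. Non-canonical headers (e.g. GWAS-Catalog
#' exports) are mapped onto the canonical names through `column_map`, which
#' may also be supplied from YAML via [read_mr_config()].
#'
#' @param path Path to the file.
#' @param column_map Named character vector or list mapping canonical field
#'   names (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`, `n_cases`, `n_controls`) to the file's column
#'   names. `NULL` assumes canonical headers.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_id Trait name; defaults to the file name without extension.
#' @param delim Field delimiter, tab by default.
#' @return A [summary_stats] tibble; rows failing validation are dropped with
#'   a warning. Missing mandatory columns and files with zero valid rows are
#'   errors.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("continuous", "binary"),
                               trait_id = NULL, delim = "\t") {
  trait_type <- match.arg(trait_type)
  trait_id <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_delim(path, delim = delim, na = c("NA", ""),
                           show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      stop_bad_arg(paste0("column_map names absent from file: ",
                          paste(missing_src, collapse = ", ")))
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(column_map, names(column_map)))
  }
  mandatory <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pval", "n")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop_bad_arg(paste0("missing mandatory column(s) in ", basename(path),
                        ": ", paste(missing_cols, collapse = ", ")))
  }
  out <- summary_stats(raw, trait_id = trait_id, trait_type = trait_type)
  if (nrow(out) == 0) {
    stop_bad_arg(paste0("no valid variant rows in ", basename(path)))
  }
  out
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Writes the canonical header
#' `rsid chrom pos effect_allele other_allele eaf beta se pval n n_cases
#' n_controls` with missing values as `NA`. [read_summary_stats()] inverts it
#' exactly (up to floating-point text round-trip, 17 significant digits are
#' written).
#'
#' @param stats A [summary_stats] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- tibble::as_tibble(stats)
  for (col in c("eaf", "beta", "se", "pval")) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        sprintf("%.17g", df[[col]]))
  }
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Remove variants with extreme effect sizes
#'
#' Quality-control filter for exposure GWASs: removes variants whose
#' per-allele effect exceeds `sd_threshold` standard-deviation units of the
#' trait (`|beta| > sd_threshold`, with `beta` on a standardized-trait
#' scale). Effects of that magnitude are biologically implausible for a
#' complex trait and almost always reflect unit or coding artifacts in a
#' deposited GWAS. The cut is deliberately absolute rather than relative to
#' the spread of the panel's effects: variant-wise SD of a summary-statistic
#' panel is on the scale of the median standard error, so a mean-centred
#' SD band would remove precisely the genome-wide-significant instruments
#' the screen needs.
#'
#' @param stats A [summary_stats] object with effects in trait-SD units.
#' @param sd_threshold Absolute effect bound in trait-SD units, default 4;
#'   `Inf` disables the filter.
#' @return A filtered [summary_stats]; the removal count is reported via a
#'   message when positive.
#' @export
filter_extreme_effects <- function(stats, sd_threshold = 4) {
  stopifnot(inherits(stats, "summary_stats"))
  keep <- abs(stats$beta) <= sd_threshold
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    rlang::inform(sprintf("filter_extreme_effects('%s'): removed %d variant(s) beyond %.3g SD",
                          trait_id(stats), n_removed, sd_threshold))
  }
  restats(stats, tibble::as_tibble(stats)[keep, ])
}

#' Harmonize exposure and outcome summary statistics onto one allele frame
#'
#' Aligns the outcome's per-variant effects to the exposure's effect allele so
#' both refer to the same allele count, the precondition for any two-sample MR
#' estimator. For each shared variant: matching alleles are copied; swapped
#' alleles flip the outcome beta's sign and reflect `eaf_out`; alleles given
#' on the opposite strand are complemented first, then the same logic applies.
#' Palindromic variants (A/T or C/G), whose strand cannot be resolved from
#' allele labels, are kept only when both allele frequencies are available,
#' both fall outside `0.5 +/- palindromic_eaf_window`, and both sit on the
#' same side of 0.5; otherwise they are dropped as ambiguous.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param variant_ids Optional character vector restricting harmonization to
#'   these rsids (typically the clumped instruments); ids absent from either
#'   study are skipped with a message.
#' @param palindromic_eaf_window Half-width of the ambiguous frequency band
#'   around 0.5, default 0.08.
#' @return A tibble of harmonized instruments with columns `rsid`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#'   `palindromic`, `flipped`, ordered as in `variant_ids` (or exposure
#'   order).
#' @examples
#' exp <- summary_stats(tibble::tibble(
#'   rsid = "rs1", chrom = "1", pos = 1L, effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02,
#'   pval = 1e-8, n = 10000L), "exp")
#' out <- summary_stats(tibble::tibble(
#'   rsid = "rs1", chrom = "1", pos = 1L, effect_allele = "G",
#'   other_allele = "A", eaf = 0.7, beta = -0.05, se = 0.01,
#'   pval = 1e-4, n = 20000L), "out")
#' harmonize(exp, out)  # beta_out flipped to +0.05
#' @export
harmonize <- function(exposure, outcome, variant_ids = NULL,
                      palindromic_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  assert_prob(palindromic_eaf_window, "palindromic_eaf_window",
              open_left = FALSE, open_right = TRUE)
  ids <- variant_ids %||% exposure$rsid
  missing_ids <- setdiff(ids, intersect(exposure$rsid, outcome$rsid))
  if (length(missing_ids) > 0) {
    rlang::inform(sprintf("harmonize: %d variant(s) absent from one study, skipped",
                          length(missing_ids)))
    ids <- setdiff(ids, missing_ids)
  }

  e <- tibble::as_tibble(exposure)[match(ids, exposure$rsid), ]
  o <- tibble::as_tibble(outcome)[match(ids, outcome$rsid), ]

  rows <- purrr::map(seq_along(ids), function(i) {
    ea_e <- e$effect_allele[i]; oa_e <- e$other_allele[i]
    ea_o <- o$effect_allele[i]; oa_o <- o$other_allele[i]
    pal <- is_palindromic(ea_e, oa_e)

    if (identical(c(ea_o, oa_o), c(ea_e, oa_e))) {
      flip <- FALSE
    } else if (identical(c(ea_o, oa_o), c(oa_e, ea_e))) {
      flip <- TRUE
    } else if (!pal &&
               identical(c(complement_allele(ea_o), complement_allele(oa_o)),
                         c(ea_e, oa_e))) {
      flip <- FALSE
    } else if (!pal &&
               identical(c(complement_allele(ea_o), complement_allele(oa_o)),
                         c(oa_e, ea_e))) {
      flip <- TRUE
    } else {
      rlang::inform(sprintf("harmonize: %s dropped, incompatible alleles (%s/%s vs %s/%s)",
                            ids[i], ea_e, oa_e, ea_o, oa_o))
      return(NULL)
    }

    beta_out <- if (flip) -o$beta[i] else o$beta[i]
    eaf_out <- if (flip) 1 - o$eaf[i] else o$eaf[i]

    if (pal) {
      w <- palindromic_eaf_window
      f_e <- e$eaf[i]; f_o <- eaf_out
      informative <- !is.na(f_e) && !is.na(f_o) &&
        abs(f_e - 0.5) > w && abs(f_o - 0.5) > w &&
        sign(f_e - 0.5) == sign(f_o - 0.5)
      if (!informative) {
        rlang::inform(sprintf("harmonize: palindromic %s dropped (ambiguous strand)", ids[i]))
        return(NULL)
      }
    }

    tibble::tibble(
      rsid = ids[i],
      beta_exp = e$beta[i], se_exp = e$se[i],
      beta_out = beta_out, se_out = o$se[i],
      eaf_exp = e$eaf[i], eaf_out = eaf_out,
      palindromic = pal, flipped = flip
    )
  })
  template <- tibble::tibble(
    rsid = character(), beta_exp = numeric(), se_exp = numeric(),
    beta_out = numeric(), se_out = numeric(), eaf_exp = numeric(),
    eaf_out = numeric(), palindromic = logical(), flipped = logical()
  )
  dplyr::bind_rows(template, !!!rows)
}
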