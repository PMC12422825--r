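#' Construct a GWAS summary-statistics table
#'
#' A `summary_stats` object is a tibble with one row per variant and the
#' canonical columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, `n_cases`, `n_controls`, carrying the
#' trait identity and type as attributes. It is the package's unit of
#' exchange for one trait's GWAS: effects (`beta`) are per effect-allele
#' copies, on the trait scale for continuous traits and the log-odds scale
#' for binary ones.
#'
#' Rows violating the per-variant contract (non-positive `se`, `pval` outside
#' (0, 1], identical alleles, missing `beta`) are dropped with a warning
#' giving the count; duplicated rsids and case/control totals inconsistent
#' with `n` are hard errors.
#'
#' @param variants A data frame with at least `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `n`. Optional:
#'   `eaf`, `n_cases`, `n_controls` (filled with `NA` when absent).
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param genome_build Metadata label only (no liftover is performed).
#' @return A tibble of class `summary_stats`.
#' @examples
#' ss <- summary_stats(
#'   tibble::tibble(
#'     rsid = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'     effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'     eaf = c(0.2, 0.4), beta = c(0.1, -0.05), se = 0.02,
#'     pval = c(1e-8, 0.01), n = 10000L
#'   ),
#'   trait_id = "toy_trait"
#' )
#' trait_id(ss)
#' @export
summary_stats <- function(variants, trait_id, trait_type = c("continuous", "binary"),
                          genome_build = "GRCh37") {
  trait_type <- match.arg(trait_type)
  mandatory <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pval", "n")
  missing_cols <- setdiff(mandatory, names(variants))
  if (length(missing_cols) > 0) {
    stop_bad_arg(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  v <- tibble::as_tibble(variants)
  for (col in c("eaf", "n_cases", "n_controls")) {
    if (!col %in% names(v)) v[[col]] <- NA_real_
  }
  v <- dplyr::mutate(v,
    rsid = as.character(.data$rsid),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pval = as.numeric(.data$pval),
    n = round(as.numeric(.data$n)),
    n_cases = round(as.numeric(.data$n_cases)),
    n_controls = round(as.numeric(.data$n_controls))
  )
  v <- v[, c(mandatory[1:5], "eaf", "beta", "se", "pval", "n",
             "n_cases", "n_controls")]

  ok <- !is.na(v$rsid) & !is.na(v$beta) & !is.na(v$se) & v$se > 0 &
    !is.na(v$pval) & v$pval > 0 & v$pval <= 1 &
    !is.na(v$n) & v$n >= 1 &
    !is.na(v$effect_allele) & !is.na(v$other_allele) &
    v$effect_allele != v$other_allele &
    (is.na(v$eaf) | (v$eaf > 0 & v$eaf < 1))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    rlang::warn(sprintf("summary_stats('%s'): dropped %d invalid row(s)",
                        trait_id, n_bad))
    v <- v[ok, ]
  }
  if (anyDuplicated(v$rsid)) {
    stop_bad_arg(sprintf("summary_stats('%s'): duplicated rsid(s)", trait_id))
  }
  cc <- !is.na(v$n_cases) & !is.na(v$n_controls)
  if (any(cc) && any(v$n_cases[cc] + v$n_controls[cc] != v$n[cc])) {
    stop_bad_arg("n_cases + n_controls must equal n where both are present")
  }

  structure(v,
    class = c("summary_stats", class(tibble::tibble())),
    trait_id = as.character(trait_id),
    trait_type = trait_type,
    genome_build = as.character(genome_build)
  )
}

#' @rdname summary_stats
#' @param x A `summary_stats` object.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @rdname summary_stats
#' @export
trait_type <- function(x) attr(x, "trait_type")

#' Case:control ratio of a binary trait
#'
#' Derived from the per-variant `n_cases`/`n_controls` columns (first
#' complete pair). `NA` for continuous traits or when counts are absent.
#'
#' @param x A `summary_stats` object.
#' @return Numeric scalar, cases divided by controls, or `NA`.
#' @export
case_control_ratio <- function(x) {
  if (!identical(trait_type(x), "binary")) return(NA_real_)
  cc <- which(!is.na(x$n_cases) & !is.na(x$n_controls))
  if (length(cc) == 0) return(NA_real_)
  i <- cc[[1]]
  x$n_cases[i] / x$n_controls[i]
}

# rebuild a summary_stats from a filtered variant table, keeping metadata
restats <- function(template, variants) {
  summary_stats(variants,
    trait_id = trait_id(template),
    trait_type = trait_type(template),
    genome_build = attr(template, "genome_build") %||% "GRCh37"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("# GWAS summary statistics: %s (%s, %s), %d variants\n",
              trait_id(x), trait_type(x),
              attr(x, "genome_build") %||% "?", nrow(x)))
  NextMethod()
}
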