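#' Define a synthetic two-sample MR scenario
#'
#' Bundles the generative parameters for one paired exposure/outcome GWAS
#' simulation with known ground truth. The generative model (see
#' [simulate_pair()]) is the standard two-sample MR data-generating process:
#' a standardized exposure with `m_snps` independent causal variants jointly
#' explaining `exposure_r2_total` of its variance, a linear causal effect
#' `beta_causal` on the outcome, optional per-variant horizontal pleiotropy
#' (directional via `pleiotropy_mean`, balanced via `pleiotropy_sd`), and a
#' planted fraction of outlier variants whose pleiotropy is shifted by
#' `outlier_shift`.
#'
#' Defaults mirror a microbiome-exposure screen: a small exposure GWAS
#' (n = 7738), modest explained variance, a large continuous outcome GWAS.
#'
#' @param m_snps Number of instrument variants.
#' @param maf_range Uniform sampling range for minor-allele frequencies.
#' @param exposure_r2_total Variance of the (standardized) exposure explained
#'   jointly by the `m_snps` variants, in (0, 1).
#' @param beta_causal True causal effect of exposure on outcome (log-odds per
#'   exposure SD for binary outcomes).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-variant direct
#'   (pleiotropic) effects on the outcome.
#' @param outlier_fraction Fraction of variants receiving an extra
#'   `outlier_shift` of pleiotropy, in \[0, 1).
#' @param outlier_shift Pleiotropy added to outlier variants, outcome units.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param outcome_type `"continuous"` or `"binary"` (log-odds scale betas).
#' @param case_control_ratio Cases/controls for binary outcomes.
#' @param ld_block_size Variants per LD block (1 = independent).
#' @param ld_rho Within-block correlation in \[0, 1); the emitted LD matrix
#'   holds `ld_rho^2` off-diagonal within blocks.
#' @param seed Integer seed; mandatory, no global RNG state is consumed.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(m_snps = 10,
                         maf_range = c(0.05, 0.45),
                         exposure_r2_total = 0.02,
                         beta_causal = 0,
                         pleiotropy_mean = 0,
                         pleiotropy_sd = 0,
                         outlier_fraction = 0,
                         outlier_shift = 0,
                         n_exposure = 7738,
                         n_outcome = 50000,
                         outcome_type = c("continuous", "binary"),
                         case_control_ratio = NA_real_,
                         ld_block_size = 1,
                         ld_rho = 0,
                         seed) {
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stop_bad_arg("sim_scenario: `seed` is mandatory")
  stopifnot(m_snps >= 1, length(maf_range) == 2)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] < 0.5)) {
    stop_bad_arg("maf_range must satisfy 0 < low <= high < 0.5")
  }
  assert_prob(exposure_r2_total, "exposure_r2_total")
  assert_prob(outlier_fraction, "outlier_fraction", open_left = FALSE)
  assert_prob(ld_rho, "ld_rho", open_left = FALSE)
  if (outcome_type == "binary" && (is.na(case_control_ratio) || case_control_ratio <= 0)) {
    stop_bad_arg("binary outcomes need case_control_ratio > 0")
  }
  structure(list(
    m_snps = as.integer(m_snps), maf_range = as.numeric(maf_range),
    exposure_r2_total = exposure_r2_total, beta_causal = beta_causal,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
    n_exposure = as.numeric(n_exposure), n_outcome = as.numeric(n_outcome),
    outcome_type = outcome_type, case_control_ratio = case_control_ratio,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

# standard error of a per-allele GWAS effect on a standardized trait;
# binary traits scale by the case/control variance factor r/(1+r)^2
# (log-odds). Floored so the noise-free limit n -> Inf stays numerically sane.
gwas_se <- function(n, maf, trait_type = "continuous", ratio = NA_real_) {
  v <- 2 * n * maf * (1 - maf)
  if (trait_type == "binary") v <- v * ratio / (1 + ratio)^2
  pmax(1 / sqrt(v), 1e-8)
}

#' Simulate a paired exposure/outcome GWAS with known ground truth
#'
#' Deterministic given `scenario$seed`. MAFs are drawn uniformly in
#' `maf_range`; raw exposure effects are rescaled so the summed per-variant
#' explained variance `sum(2 * maf * (1 - maf) * b^2)` equals
#' `exposure_r2_total` exactly (standardized trait). Per-variant pleiotropy
#' is Normal(`pleiotropy_mean`, `pleiotropy_sd`^2), with `outlier_shift`
#' added for planted outliers. Pleiotropy is applied in the
#' exposure-increasing-allele frame (its sign follows `sign(b_j)`), so a
#' nonzero `pleiotropy_mean` is directional in the sense the Egger intercept
#' estimates. The true outcome effect of variant j is
#' `beta_causal * b_j + sign(b_j) * alpha_j`. Observed effects add Wald sampling noise
#' with `se = 1 / sqrt(2 n maf (1 - maf))` (times the case/control factor
#' `ratio/(1+ratio)^2` on the log-odds scale for binary outcomes); p-values
#' are two-sided normal. The LD matrix is block-diagonal with within-block
#' r-squared `ld_rho^2`; variants of a block are placed within one clumping
#' window, blocks far apart.
#'
#' Sampling noise is drawn independently across variants: the LD structure
#' is consumed by clumping only, not propagated into the correlation of
#' effect estimates.
#'
#' @param scenario A [sim_scenario].
#' @param exposure_id,outcome_id Trait ids stamped on the outputs.
#' @return A list with elements `exposure` and `outcome` ([summary_stats]),
#'   `truth` (per-variant true effects `b_exp`, pleiotropy `alpha`,
#'   `beta_causal`, `outlier_idx`, `maf`), and `ld` ([ld_matrix]).
#' @examples
#' sim <- simulate_pair(sim_scenario(m_snps = 5, seed = 1))
#' sim$truth$beta_causal
#' @export
simulate_pair <- function(scenario, exposure_id = "sim_exposure",
                          outcome_id = "sim_outcome") {
  stopifnot(inherits(scenario, "sim_scenario"))
  s <- scenario
  withr::with_seed(s$seed, {
    m <- s$m_snps
    maf <- stats::runif(m, s$maf_range[1], s$maf_range[2])
    b_raw <- stats::rnorm(m)
    het <- 2 * maf * (1 - maf)
    b_exp <- b_raw * sqrt(s$exposure_r2_total / sum(het * b_raw^2))
    alpha <- stats::rnorm(m, s$pleiotropy_mean, s$pleiotropy_sd)
    n_out_snps <- floor(s$outlier_fraction * m)
    outlier_idx <- if (n_out_snps > 0) sort(sample.int(m, n_out_snps)) else integer(0)
    alpha[outlier_idx] <- alpha[outlier_idx] + s$outlier_shift
    # pleiotropy acts in the exposure-increasing-allele frame, so a nonzero
    # mean is directional in the sense MR-Egger estimates
    orient <- ifelse(b_exp >= 0, 1, -1)
    b_out_true <- s$beta_causal * b_exp + orient * alpha

    se_exp <- gwas_se(s$n_exposure, maf)
    se_out <- gwas_se(s$n_outcome, maf, s$outcome_type, s$case_control_ratio)
    beta_exp_hat <- stats::rnorm(m, b_exp, se_exp)
    beta_out_hat <- stats::rnorm(m, b_out_true, se_out)

    n_blocks <- ceiling(m / s$ld_block_size)
    block <- rep(seq_len(n_blocks), each = s$ld_block_size)[seq_len(m)]
    # one chromosome per LD block: block members sit within one clumping
    # window of each other, blocks can never clump together
    chrom <- as.character(block)
    pos <- as.integer((seq_len(m) - (block - 1) * s$ld_block_size) * 1e4)
    rsid <- sprintf("rs%s_%04d", gsub("[^A-Za-z0-9]", "", exposure_id), seq_len(m))

    alleles_ea <- sample(c("A", "C"), m, replace = TRUE)
    alleles_oa <- ifelse(alleles_ea == "A", "G", "T")  # never palindromic

    make_stats <- function(beta_hat, se, n, id, type, ratio) {
      n_cases <- n_controls <- rep(NA_real_, m)
      if (type == "binary") {
        n_cases <- rep(round(n * ratio / (1 + ratio)), m)
        n_controls <- rep(n, m) - n_cases
      }
      summary_stats(tibble::tibble(
        rsid = rsid, chrom = chrom, pos = pos,
        effect_allele = alleles_ea, other_allele = alleles_oa,
        eaf = maf, beta = beta_hat, se = se,
        pval = pmax(two_sided_normal_p(beta_hat / se), 1e-320),
        n = rep(n, m), n_cases = n_cases, n_controls = n_controls
      ), trait_id = id, trait_type = type)
    }

    r2 <- diag(m)
    for (bk in unique(block)) {
      idx <- which(block == bk)
      r2[idx, idx] <- s$ld_rho^2
    }
    diag(r2) <- 1

    list(
      exposure = make_stats(beta_exp_hat, se_exp, s$n_exposure, exposure_id,
                            "continuous", NA_real_),
      outcome = make_stats(beta_out_hat, se_out, s$n_outcome, outcome_id,
                           s$outcome_type, s$case_control_ratio),
      truth = list(b_exp = b_exp, alpha = orient * alpha,
                   beta_causal = s$beta_causal,
                   outlier_idx = outlier_idx, maf = maf),
      ld = ld_matrix(r2, rsid)
    )
  })
}

#' Enumerate an exposure-by-outcome screening manifest
#'
#' Pure pair enumeration (no files): the cross product of exposure and
#' outcome ids as a tibble, one row per MR test, as used to size a screen
#' before materializing any data.
#'
#' @param exposure_ids,outcome_ids Character vectors (or single integers,
#'   taken as counts and expanded to placeholder ids).
#' @return A tibble with columns `exposure`, `outcome`.
#' @examples
#' nrow(grid_manifest(37, 1490))  # 55130 MR tests
#' @export
grid_manifest <- function(exposure_ids, outcome_ids) {
  if (is.numeric(exposure_ids) && length(exposure_ids) == 1) {
    exposure_ids <- sprintf("exposure_%03d", seq_len(exposure_ids))
  }
  if (is.numeric(outcome_ids) && length(outcome_ids) == 1) {
    outcome_ids <- sprintf("outcome_%04d", seq_len(outcome_ids))
  }
  tidyr::crossing(exposure = exposure_ids, outcome = outcome_ids)
}

#' Simulate a small exposure-by-outcome screening grid
#'
#' Generates one GWAS per trait over a shared variant panel, with each trait
#' owning a block of directly associated variants, plus causal edges between
#' traits given in `causal_pairs`. Outcome summary statistics include the
#' mediated effects `beta * b_exp` of their causal exposures, so the full
#' pipeline (clumping, harmonization, estimation, FDR, bidirectional MR) can
#' run end to end against known truth. Reverse-direction edges
#' (`direction = "reverse"`) plant outcome-to-exposure causality for testing
#' the reverse-causality gate.
#'
#' @param n_exposures,n_outcomes Number of traits of each role.
#' @param causal_pairs Tibble with columns `exposure`, `outcome`, `beta` and
#'   optionally `direction` (`"forward"`, default, or `"reverse"`). Ids are
#'   `exposure_001`..., `outcome_0001`....
#' @param m_per_trait Directly associated variants per trait.
#' @param r2_exposure,r2_outcome Explained variance of each trait by its own
#'   variant block.
#' @param n_exposure_gwas,n_outcome_gwas GWAS sample sizes.
#' @param seed Integer seed.
#' @param dir Optional directory: when given, writes one summary-statistics
#'   file per trait, the LD matrix (`ld_matrix.txt`) and a YAML manifest
#'   (`manifest.yaml`) naming every pair and its true effect.
#' @return A list with `exposures`, `outcomes` (named lists of
#'   [summary_stats]), `ld`, `manifest` (tibble: `exposure`, `outcome`,
#'   `beta_true`, `direction`), `truth` (per-variant direct and total true
#'   effect matrices, one column per trait, plus `rsid`, `maf`, `trait_n`),
#'   and `dir`.
#' @export
simulate_grid <- function(n_exposures, n_outcomes,
                          causal_pairs = NULL,
                          m_per_trait = 8,
                          r2_exposure = 0.02, r2_outcome = 0.05,
                          n_exposure_gwas = 7738, n_outcome_gwas = 100000,
                          seed, dir = NULL) {
  stopifnot(n_exposures >= 1, n_outcomes >= 1)
  if (missing(seed)) stop_bad_arg("simulate_grid: `seed` is mandatory")
  exp_ids <- sprintf("exposure_%03d", seq_len(n_exposures))
  out_ids <- sprintf("outcome_%04d", seq_len(n_outcomes))
  trait_ids <- c(exp_ids, out_ids)
  n_traits <- length(trait_ids)
  trait_n <- c(rep(n_exposure_gwas, n_exposures), rep(n_outcome_gwas, n_outcomes))
  trait_r2 <- c(rep(r2_exposure, n_exposures), rep(r2_outcome, n_outcomes))

  edges <- tibble::tibble(exposure = character(), outcome = character(),
                          beta = numeric(), direction = character())
  if (!is.null(causal_pairs) && nrow(causal_pairs) > 0) {
    edges <- tibble::as_tibble(causal_pairs)
    if (!"direction" %in% names(edges)) edges$direction <- "forward"
    edges$direction[is.na(edges$direction)] <- "forward"
    bad <- setdiff(c(edges$exposure, edges$outcome), trait_ids)
    if (length(bad) > 0) {
      stop_bad_arg(paste0("causal_pairs names unknown traits: ",
                          paste(bad, collapse = ", ")))
    }
  }

  m_total <- n_traits * m_per_trait
  owner <- rep(seq_len(n_traits), each = m_per_trait)

  withr::with_seed(seed, {
    maf <- stats::runif(m_total, 0.05, 0.45)
    het <- 2 * maf * (1 - maf)
    rsid <- sprintf("rs_grid_%05d", seq_len(m_total))
    pos <- as.integer(seq_len(m_total) * 1e4)  # LD matrix is identity: nothing clumps
    ea <- sample(c("A", "C"), m_total, replace = TRUE)
    oa <- ifelse(ea == "A", "G", "T")

    # direct (own-block) effects, rescaled per trait to its r2 target
    b_direct <- matrix(0, m_total, n_traits)
    for (t in seq_len(n_traits)) {
      idx <- which(owner == t)
      raw <- stats::rnorm(length(idx))
      b_direct[idx, t] <- raw * sqrt(trait_r2[t] / sum(het[idx] * raw^2))
    }

    # causal edges: receiver inherits sender's direct effects, scaled
    b_true <- b_direct
    for (i in seq_len(nrow(edges))) {
      from <- if (edges$direction[i] == "forward") edges$exposure[i] else edges$outcome[i]
      to <- if (edges$direction[i] == "forward") edges$outcome[i] else edges$exposure[i]
      fi <- match(from, trait_ids); ti <- match(to, trait_ids)
      b_true[, ti] <- b_true[, ti] + edges$beta[i] * b_direct[, fi]
    }

    traits <- purrr::map(seq_len(n_traits), function(t) {
      se <- gwas_se(trait_n[t], maf)
      beta_hat <- stats::rnorm(m_total, b_true[, t], se)
      summary_stats(tibble::tibble(
        rsid = rsid, chrom = "1", pos = pos,
        effect_allele = ea, other_allele = oa, eaf = maf,
        beta = beta_hat, se = se,
        pval = pmax(two_sided_normal_p(beta_hat / se), 1e-320),
        n = rep(trait_n[t], m_total)
      ), trait_id = trait_ids[t], trait_type = "continuous")
    })
    names(traits) <- trait_ids
    ld <- ld_matrix(diag(m_total), rsid)
  })

  manifest <- grid_manifest(exp_ids, out_ids) |>
    dplyr::left_join(edges, by = c("exposure", "outcome")) |>
    dplyr::mutate(beta_true = dplyr::coalesce(.data$beta, 0),
                  direction = dplyr::coalesce(.data$direction, "none")) |>
    dplyr::select("exposure", "outcome", "beta_true", "direction")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in trait_ids) {
      write_summary_stats(traits[[id]], file.path(dir, paste0(id, ".tsv")))
    }
    write_ld_matrix(ld, file.path(dir, "ld_matrix.txt"))
    yaml::write_yaml(list(
      seed = seed,
      exposures = as.list(exp_ids), outcomes = as.list(out_ids),
      pairs = purrr::pmap(manifest, function(exposure, outcome, beta_true, direction) {
        list(exposure = exposure, outcome = outcome,
             beta_true = beta_true, direction = direction)
      })
    ), file.path(dir, "manifest.yaml"))
  }

  list(exposures = traits[exp_ids], outcomes = traits[out_ids],
       ld = ld, manifest = manifest,
       truth = list(b_direct = `colnames<-`(b_direct, trait_ids),
                    b_true = `colnames<-`(b_true, trait_ids),
                    rsid = rsid, maf = maf, trait_n = trait_n),
       dir = dir)
}
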