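# shared fixture builders (all data generated in code)

toy_variants <- function(n = 5, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    rsid = sprintf("rs%03d", seq_len(n)),
    chrom = "1",
    pos = as.integer(seq_len(n) * 1000),
    effect_allele = sample(c("A", "C"), n, replace = TRUE),
    other_allele = "G",
    eaf = round(stats::runif(n, 0.05, 0.95), 4),
    beta = round(stats::rnorm(n, 0, 0.1), 6),
    se = round(stats::runif(n, 0.01, 0.05), 6),
    pval = round(stats::runif(n, 1e-9, 0.5), 10),
    n = 10000
  ))
}

toy_stats <- function(n = 5, seed = 1, trait_id = "toy", ...) {
  summary_stats(toy_variants(n, seed), trait_id = trait_id, ...)
}

# hand-built harmonized instrument table
make_instruments <- function(beta_exp, se_exp, beta_out, se_out) {
  tibble::tibble(
    rsid = sprintf("rs%03d", seq_along(beta_exp)),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    eaf_exp = 0.3, eaf_out = 0.3,
    palindromic = FALSE, flipped = FALSE
  )
}

random_instruments <- function(m, seed) {
  withr::with_seed(seed, make_instruments(
    beta_exp = stats::rnorm(m, 0, 0.1) + 0.05 * sign(stats::rnorm(m)),
    se_exp = stats::runif(m, 0.005, 0.03),
    beta_out = stats::rnorm(m, 0, 0.05),
    se_out = stats::runif(m, 0.005, 0.03)
  ))
}

# instruments straight from a simulated pair (alleles already aligned,
# avoids harmonization overhead inside tight Monte-Carlo loops)
sim_instruments <- function(sim) {
  tibble::tibble(
    rsid = sim$exposure$rsid,
    beta_exp = sim$exposure$beta, se_exp = sim$exposure$se,
    beta_out = sim$outcome$beta, se_out = sim$outcome$se,
    eaf_exp = sim$exposure$eaf, eaf_out = sim$outcome$eaf,
    palindromic = FALSE, flipped = FALSE
  )
}

# screening-grid fixture with three planted causal pairs (used by the
# pipeline and acceptance tests)
fast_config <- function(seed = 1, ...) {
  mr_config(n_boot = 150, n_sim = 200, seed = seed, ...)
}

planted_grid <- function(seed = 1, n_exposures = 5, n_outcomes = 8) {
  pairs <- tibble::tibble(
    exposure = c("exposure_001", "exposure_002", "exposure_004"),
    outcome = c("outcome_0001", "outcome_0003", "outcome_0007"),
    beta = c(0.35, -0.35, 0.4)
  )
  keep <- pairs$exposure %in% sprintf("exposure_%03d", seq_len(n_exposures)) &
    pairs$outcome %in% sprintf("outcome_%04d", seq_len(n_outcomes))
  simulate_grid(
    n_exposures, n_outcomes, causal_pairs = pairs[keep, ],
    m_per_trait = 8, r2_exposure = 0.02, r2_outcome = 0.1,
    n_exposure_gwas = 5e4, n_outcome_gwas = 5e4, seed = seed
  )
}

# replication outcome: same ground truth as a grid outcome, fresh noise
redraw_outcome <- function(g, oid, n_rep, seed) {
  tr <- g$truth
  se <- 1 / sqrt(2 * n_rep * tr$maf * (1 - tr$maf))
  template <- tibble::as_tibble(g$outcomes[[oid]])
  withr::with_seed(seed, {
    template$beta <- stats::rnorm(length(se), tr$b_true[, oid], se)
  })
  template$se <- se
  template$pval <- pmax(2 * stats::pnorm(-abs(template$beta / template$se)), 1e-320)
  template$n <- n_rep
  summary_stats(template, paste0("rep_", oid))
}
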