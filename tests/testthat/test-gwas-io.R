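test_that("summary statistics survive a write/read round trip unchanged", {
  ss <- toy_stats(n = 20, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_id = "toy")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ss))
  expect_identical(trait_id(back), "toy")

  # randomized second case, binary trait with case/control counts
  v <- toy_variants(n = 15, seed = 7)
  v$n_cases <- 3000; v$n_controls <- 7000
  ss2 <- summary_stats(v, "toybin", trait_type = "binary")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss2, path2)
  back2 <- read_summary_stats(path2, trait_type = "binary", trait_id = "toybin")
  expect_equal(tibble::as_tibble(back2), tibble::as_tibble(ss2))
  expect_equal(case_control_ratio(back2), 3 / 7)
})

test_that("reading a toy file with canonical headers keeps all valid rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(toy_stats(n = 5), path)
  ss <- read_summary_stats(path)
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 5)
})

test_that("invalid rows are dropped with a warning; empty files and missing columns error", {
  v <- toy_variants(n = 4)
  v$se[2] <- 0              # invalid standard error
  v$pval[3] <- 1.5          # invalid p
  expect_warning(ss <- summary_stats(v, "toy"), "dropped 2")
  expect_equal(nrow(ss), 2)

  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(toy_variants(3), -"se"), path)
  expect_error(read_summary_stats(path), "se")

  # all rows invalid -> zero valid rows is a hard error
  v2 <- toy_variants(n = 2)
  v2$se <- 0
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(v2, path2)
  expect_error(suppressWarnings(read_summary_stats(path2)), "no valid")
})

test_that("column_map renames GWAS-catalog style headers onto canonical fields", {
  v <- toy_variants(n = 3)
  names(v) <- c("variant_id", "chromosome", "base_pair_location",
                "ea", "oa", "effect_allele_frequency", "beta_hat",
                "standard_error", "p_value", "sample_size")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(v, path)
  cmap <- c(rsid = "variant_id", chrom = "chromosome", pos = "base_pair_location",
            effect_allele = "ea", other_allele = "oa",
            eaf = "effect_allele_frequency", beta = "beta_hat",
            se = "standard_error", pval = "p_value", n = "sample_size")
  ss <- read_summary_stats(path, column_map = cmap)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$beta, toy_variants(3)$beta)
})

test_that("an empty-variant table writes a header-only file", {
  ss <- toy_stats(n = 3)
  ss0 <- summary_stats(toy_variants(3)[0, ], "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss0, path)
  expect_length(readr::read_lines(path), 1)
  # and a 3-variant table writes 4 lines
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path2)
  expect_length(readr::read_lines(path2), 4)
})

test_that("extreme-effect filter removes implausibly large effects only", {
  v <- toy_variants(n = 4)
  v$beta <- c(0, 0.01, -0.01, 100)
  ss <- summary_stats(v, "toy")
  expect_message(out <- filter_extreme_effects(ss, 4), "removed 1")
  expect_setequal(out$beta, c(0, 0.01, -0.01))

  # plausible equal effects: nothing removed
  v$beta <- rep(0.2, 4)
  expect_equal(nrow(filter_extreme_effects(summary_stats(v, "toy"), 4)), 4)

  # infinite threshold is the identity
  v$beta <- c(0, 0.01, -0.01, 100)
  expect_equal(nrow(filter_extreme_effects(summary_stats(v, "toy"), Inf)), 4)

  # the band is symmetric: large negative artifacts go too
  v$beta <- c(0.5, -50, 3.9, -4.1)
  expect_setequal(suppressMessages(filter_extreme_effects(
    summary_stats(v, "toy"), 4))$beta, c(0.5, 3.9))
})

test_that("the effect filter never touches genome-wide hits at GWAS scale", {
  # sparse-signal panel: nulls at the se scale, hits ~ 20 se, one artifact
  withr::with_seed(8, {
    n_var <- 500
    v <- tibble::tibble(
      rsid = sprintf("rs%04d", seq_len(n_var)), chrom = "1",
      pos = as.integer(seq_len(n_var) * 1e3),
      effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = stats::rnorm(n_var, 0, 0.01), se = 0.01,
      pval = stats::runif(n_var, 0.01, 1), n = 10000
    )
    v$beta[1:5] <- 0.2   # true hits, z = 20
    v$beta[6] <- 40      # unit artifact
  })
  out <- suppressMessages(filter_extreme_effects(summary_stats(v, "t"), 4))
  expect_equal(nrow(out), n_var - 1)
  expect_true(all(v$rsid[1:5] %in% out$rsid))
  expect_false("rs0006" %in% out$rsid)
})

make_pair <- function(ea_e, oa_e, beta_e, eaf_e, ea_o, oa_o, beta_o, eaf_o) {
  exp <- summary_stats(tibble::tibble(
    rsid = "rs1", chrom = "1", pos = 1L, effect_allele = ea_e,
    other_allele = oa_e, eaf = eaf_e, beta = beta_e, se = 0.02,
    pval = 1e-8, n = 10000), "exp")
  out <- summary_stats(tibble::tibble(
    rsid = "rs1", chrom = "1", pos = 1L, effect_allele = ea_o,
    other_allele = oa_o, eaf = eaf_o, beta = beta_o, se = 0.01,
    pval = 1e-4, n = 20000), "out")
  harmonize(exp, out)
}

test_that("harmonization copies, flips, and strand-complements correctly", {
  same <- make_pair("A", "G", 0.1, 0.3, "A", "G", 0.05, 0.3)
  expect_equal(same$beta_out, 0.05)
  expect_false(same$flipped)

  swapped <- make_pair("A", "G", 0.1, 0.3, "G", "A", 0.05, 0.7)
  expect_equal(swapped$beta_out, -0.05)
  expect_true(swapped$flipped)
  expect_equal(swapped$eaf_out, 0.3)

  # outcome reported on the opposite strand: A/G vs T/C
  strand <- make_pair("A", "G", 0.1, 0.3, "T", "C", 0.05, 0.3)
  expect_equal(strand$beta_out, 0.05)
  expect_false(strand$flipped)

  # opposite strand AND swapped: A/G vs C/T
  both <- make_pair("A", "G", 0.1, 0.3, "C", "T", 0.05, 0.7)
  expect_equal(both$beta_out, -0.05)
  expect_true(both$flipped)

  # incompatible allele sets are dropped
  expect_equal(nrow(suppressMessages(
    make_pair("A", "G", 0.1, 0.3, "A", "C", 0.05, 0.3))), 0)
})

test_that("palindromic variants are kept only with informative, concordant frequencies", {
  # eaf at exactly 0.5: ambiguous, dropped
  expect_equal(nrow(suppressMessages(
    make_pair("A", "T", 0.1, 0.5, "A", "T", 0.05, 0.2))), 0)
  # both clear of the window and on the same side: kept
  kept <- make_pair("A", "T", 0.1, 0.2, "A", "T", 0.05, 0.25)
  expect_equal(nrow(kept), 1)
  expect_true(kept$palindromic)
  # opposite sides of 0.5: dropped
  expect_equal(nrow(suppressMessages(
    make_pair("C", "G", 0.1, 0.2, "C", "G", 0.05, 0.8))), 0)
  # inside the 0.08 window: dropped
  expect_equal(nrow(suppressMessages(
    make_pair("C", "G", 0.1, 0.46, "C", "G", 0.05, 0.46))), 0)
  # missing outcome frequency: dropped
  expect_equal(nrow(suppressMessages(
    make_pair("A", "T", 0.1, 0.2, "A", "T", 0.05, NA))), 0)
})

test_that("harmonization is idempotent and respects the orientation gauge", {
  sim <- simulate_pair(sim_scenario(m_snps = 8, beta_causal = 0.3,
                                    exposure_r2_total = 0.05, seed = 11))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome already expressed on the exposure's alleles
  v <- tibble::as_tibble(sim$outcome)
  h2 <- harmonize(sim$exposure, summary_stats(v, "sim_outcome"))
  expect_equal(h1, h2)
  expect_false(any(h1$flipped))

  # flipping outcome alleles and sign yields the same instrument set
  v_flip <- v
  v_flip$effect_allele <- v$other_allele
  v_flip$other_allele <- v$effect_allele
  v_flip$beta <- -v$beta
  v_flip$eaf <- 1 - v$eaf
  h3 <- harmonize(sim$exposure, summary_stats(v_flip, "sim_outcome"))
  expect_equal(h3$beta_out, h1$beta_out)
  expect_true(all(h3$flipped))
})

test_that("restricting harmonization to absent variant ids skips them with a message", {
  sim <- simulate_pair(sim_scenario(m_snps = 5, seed = 3))
  expect_message(
    h <- harmonize(sim$exposure, sim$outcome,
                   variant_ids = c(sim$exposure$rsid[1:2], "rs_not_there")),
    "absent")
  expect_equal(nrow(h), 2)
})
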