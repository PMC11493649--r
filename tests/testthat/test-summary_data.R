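# Reading/validation, instrument selection, harmonization, instrument strength

test_that("reading preserves well-formed rows and drops invariant violations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- tiny_gwas_df(3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_gwas_table(path, trait_type = "quantitative", trait_name = "t")
  expect_s3_class(tab, "gwas_table")
  expect_equal(nrow(tab$data), 3L)
  expect_equal(tab$data$variant_id, df$variant_id)

  df_bad <- df
  df_bad$se[2] <- 0
  utils::write.table(df_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(tab2 <- read_gwas_table(path, trait_type = "quantitative",
                                         trait_name = "t"),
                 "dropped 1")
  expect_equal(nrow(tab2$data), 2L)
  expect_equal(tab2$dropped$reason, "invalid_se")
})

test_that("reading applies a column map, uppercases alleles, and errors on schema gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tiny_gwas_df(3)
  names(df)[names(df) == "variant_id"] <- "SNP"
  df$effect_allele <- tolower(df$effect_allele)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  tab <- read_gwas_table(path, column_map = c(variant_id = "SNP"),
                         trait_type = "binary", trait_name = "t")
  expect_equal(tab$data$effect_allele, c("A", "C", "G"))
  expect_error(read_gwas_table(path, column_map = c(variant_id = "nope"),
                               trait_type = "binary"),
               class = "mrscreen_schema_error")
  expect_error(read_gwas_table(tempfile(), trait_type = "binary"),
               class = "mrscreen_io_error")
})

test_that("a simulated table survives a write/read round-trip", {
  sim <- simulate_gwas(simulation_config(n_exposures = 1,
                                         instruments_per_exposure = 5,
                                         n_null_snps = 10, seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(sim$exposures[[1]], path)
  back <- read_gwas_table(path, trait_type = "quantitative",
                          trait_name = sim$exposures[[1]]$trait_name)
  expect_equal(back$data, sim$exposures[[1]]$data, tolerance = 1e-12)
})

test_that("instrument selection follows the greedy clump-and-fallback rule", {
  # five SNPs on one chromosome spaced one full clump window apart, p-values
  # spanning both thresholds: the two genome-wide hits fall in one window so
  # only one survives; that is below min_snps, so the lenient rerun also
  # admits the sub-threshold 1e-6 SNP outside the first window
  df <- tiny_gwas_df(5)
  df$pos <- as.integer(1:5 * 1e7)
  df$pval <- c(1e-9, 1e-9, 1e-6, 0.5, 0.5)
  tab <- gwas_table(df, "t", "quantitative")
  iv <- select_instruments(tab)
  expect_equal(iv$threshold_used, 5e-6)
  expect_equal(sort(iv$variants$variant_id), c("rs1", "rs3"))

  # single strong SNP with min_snps = 1 stays at the primary threshold
  one <- gwas_table(tiny_gwas_df(1), "t", "quantitative")
  iv1 <- select_instruments(one, min_snps = 1)
  expect_equal(iv1$threshold_used, 5e-8)
  expect_equal(nrow(iv1$variants), 1L)

  # two SNPs 20,000 kb apart are outside the window: both kept
  df2 <- tiny_gwas_df(2)
  df2$pos <- as.integer(c(1e6, 1e6 + 2e7))
  df2$pval <- c(1e-9, 1e-9)
  iv2 <- select_instruments(gwas_table(df2, "t", "quantitative"), min_snps = 1)
  expect_equal(nrow(iv2$variants), 2L)

  expect_error(select_instruments(gwas_table(within(tiny_gwas_df(2), pval <- 0.5),
                                             "t", "quantitative")),
               class = "mrscreen_empty_instruments")
})

test_that("clumping is row-order invariant and respects a supplied LD matrix", {
  df <- tiny_gwas_df(4)
  df$pos <- as.integer(c(1e6, 2e6, 3e6, 4e6))
  df$pval <- c(1e-9, 1e-10, 1e-11, 1e-12)
  perm <- df[c(3, 1, 4, 2), ]
  iv_a <- select_instruments(gwas_table(df, "t", "quantitative"), min_snps = 1)
  iv_b <- select_instruments(gwas_table(perm, "t", "quantitative"), min_snps = 1)
  expect_equal(iv_a$variants$variant_id, iv_b$variants$variant_id)
  expect_equal(nrow(iv_a$variants), 1L)
  # retained + dropped partitions the candidates
  expect_equal(nrow(iv_a$variants) + 3L, sum(df$pval <= iv_a$threshold_used))

  # low LD within the window rescues all four
  ld <- diag(4) * 0 + 1e-4
  diag(ld) <- 1
  dimnames(ld) <- list(df$variant_id, df$variant_id)
  iv_ld <- select_instruments(gwas_table(df, "t", "quantitative"),
                              min_snps = 1, ld = ld)
  expect_equal(nrow(iv_ld$variants), 4L)
  # high LD collapses them again
  ld_hi <- ld
  ld_hi[ld_hi < 1] <- 0.9
  iv_hi <- select_instruments(gwas_table(df, "t", "quantitative"),
                              min_snps = 1, ld = ld_hi)
  expect_equal(nrow(iv_hi$variants), 1L)
})

test_that("every retained instrument satisfies the recorded threshold", {
  sim <- simulate_gwas(simulation_config(n_exposures = 3,
                                         instruments_per_exposure = 6,
                                         n_null_snps = 40, seed = 21))
  for (ex in sim$exposures) {
    iv <- select_instruments(ex)
    expect_true(all(iv$variants$pval <= iv$threshold_used))
  }
})

test_that("instrument strength follows the Wald-F and R2 formulas", {
  s <- instrument_strength(0.1, 0.1, 1000)
  expect_equal(s$F, 1)
  expect_true(s$weak)
  s0 <- instrument_strength(0, 0.1, 1000)
  expect_equal(s0$F, 0)
  expect_equal(s0$R2, 0)
  # n from the exposure panel: F = 100 -> R2 = 100/(100 + 8291)
  s2 <- instrument_strength(0.05, 0.005, 8293, eaf = 0.3)
  expect_equal(s2$F, 100)
  expect_equal(s2$R2, 100 / (100 + 8291), tolerance = 1e-12)
  expect_equal(s2$R2_af, 2 * 0.3 * 0.7 * 0.05^2)
  expect_false(s2$weak)
  expect_error(instrument_strength(0.1, 0.1, 2), class = "mrscreen_domain_error")
})

make_pair <- function(exp_alleles, out_alleles, out_beta = 0.05) {
  df <- tiny_gwas_df(1)
  df$effect_allele <- exp_alleles[1]
  df$other_allele <- exp_alleles[2]
  df$beta <- 0.1
  ex <- gwas_table(df, "X", "quantitative")
  df2 <- df
  df2$effect_allele <- out_alleles[1]
  df2$other_allele <- out_alleles[2]
  df2$beta <- out_beta
  list(iv = select_instruments(ex, min_snps = 1),
       out = gwas_table(df2, "Y", "binary"))
}

test_that("harmonization keeps, flips, and drops alleles correctly", {
  same <- make_pair(c("A", "G"), c("A", "G"))
  h <- harmonize(same$iv, same$out)
  expect_equal(unname(h$by), 0.05)

  swap <- make_pair(c("A", "G"), c("G", "A"))
  h2 <- harmonize(swap$iv, swap$out)
  expect_equal(unname(h2$by), -0.05)

  pal <- make_pair(c("A", "T"), c("A", "T"))
  expect_error(harmonize(pal$iv, pal$out),
               class = "mrscreen_empty_harmonization")

  mism <- make_pair(c("A", "G"), c("A", "C"))
  expect_error(harmonize(mism$iv, mism$out),
               class = "mrscreen_empty_harmonization")
})

test_that("palindromic instruments are dropped and listed among kept ones", {
  df <- tiny_gwas_df(3)
  df$pos <- as.integer(c(1e6, 3e7, 6e7))   # outside each other's clump window
  df$effect_allele <- c("A", "A", "C")
  df$other_allele <- c("G", "T", "G")   # rs2 (A/T) and rs3 (C/G) palindromic
  ex <- gwas_table(df, "X", "quantitative")
  out <- gwas_table(df, "Y", "binary")
  h <- harmonize(select_instruments(ex, min_snps = 1), out)
  expect_equal(h$variant_ids, "rs1")
  expect_setequal(h$dropped_palindromic, c("rs2", "rs3"))
})

test_that("harmonization is idempotent and allele flips are involutive", {
  sim <- simulate_gwas(simulation_config(n_exposures = 1,
                                         instruments_per_exposure = 8,
                                         true_causal = 0.2, n_null_snps = 10,
                                         seed = 31))
  iv <- select_instruments(sim$exposures[[1]])
  out <- sim$outcomes[[1]]
  h1 <- harmonize(iv, out)

  # rebuild tables from the harmonized output and re-harmonize: identity
  rebuild <- function(h, trait, type, beta, se) {
    df <- h$variants
    df$beta <- beta
    df$se <- se
    df$pval <- 2 * stats::pnorm(-abs(beta / se))
    df$n <- 10000L
    gwas_table(df, trait, type)
  }
  ex2 <- rebuild(h1, "X", "quantitative", h1$bx[, 1], h1$sx[, 1])
  out2 <- rebuild(h1, "Y", "binary", h1$by, h1$sy)
  h2 <- harmonize(select_instruments(ex2), out2)
  expect_equal(unname(h2$bx), unname(h1$bx))
  expect_equal(unname(h2$by), unname(h1$by))

  # flipping the outcome's allele encoding leaves the harmonized by unchanged
  flip <- out2$data
  tmp <- flip$effect_allele
  flip$effect_allele <- flip$other_allele
  flip$other_allele <- tmp
  flip$beta <- -flip$beta
  flip$eaf <- 1 - flip$eaf
  h3 <- harmonize(select_instruments(ex2), gwas_table(flip, "Y", "binary"))
  expect_equal(unname(h3$by), unname(h2$by))
})

test_that("multivariable harmonization takes the union and drops incomplete rows", {
  sim <- simulate_gwas(simulation_config(n_exposures = 3,
                                         instruments_per_exposure = 5,
                                         shared_instrument_fraction = 0.4,
                                         n_null_snps = 10, seed = 41))
  ivs <- lapply(sim$exposures, select_instruments)
  h <- harmonize(ivs, sim$outcomes[[1]], exposure_tables = sim$exposures)
  expect_equal(ncol(h$bx), 3L)
  union_ids <- unique(unlist(lapply(ivs, function(s) s$variants$variant_id)))
  expect_setequal(h$variant_ids, union_ids)
  # dropping one variant from one exposure's table forces a missing_exposure drop
  crippled <- sim$exposures
  keep <- crippled[[2]]$data$variant_id != h$variant_ids[1]
  crippled[[2]]$data <- crippled[[2]]$data[keep, ]
  ivs2 <- lapply(crippled, select_instruments)
  h2 <- harmonize(ivs2, sim$outcomes[[1]], exposure_tables = crippled)
  if (!(h$variant_ids[1] %in% unlist(lapply(ivs2, function(s) s$variants$variant_id)))) {
    expect_false(h$variant_ids[1] %in% h2$variant_ids)
  } else {
    expect_true(h$variant_ids[1] %in% c(h2$variant_ids, h2$dropped_missing))
  }
})

test_that("harmonized TSV export writes the dataset and its drop log", {
  sim <- simulate_gwas(simulation_config(n_exposures = 1,
                                         instruments_per_exposure = 4,
                                         n_null_snps = 5, seed = 51))
  h <- harmonize(select_instruments(sim$exposures[[1]]), sim$outcomes[[1]])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  back <- utils::read.delim(path)
  expect_equal(back$variant_id, h$variant_ids)
  expect_equal(back$by, unname(h$by), tolerance = 1e-12)
})
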