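# In-code fixtures shared across the suite. All randomness is locally seeded.

# minimal well-formed summary-stats data.frame
tiny_gwas_df <- function(n = 3) {
  data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1e6L,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = seq(0.1, 0.3, length.out = n),
    se = rep(0.05, n),
    pval = rep(1e-10, n),
    n = rep(10000L, n),
    stringsAsFactors = FALSE)
}

# random single-exposure harmonized instance for estimator oracles
random_harmonized <- function(J = 10, theta = 0.2) {
  bx <- runif(J, 0.05, 0.4) * sample(c(-1, 1), J, replace = TRUE)
  sx <- runif(J, 0.005, 0.02)
  sy <- runif(J, 0.005, 0.03)
  by <- theta * bx + rnorm(J, 0, sy)
  harmonized_dataset(bx, sx, by, sy,
                     exposure_names = "X", outcome_name = "Y")
}

# direct multivariable instance: J instruments, K factors, one primary
# factor per instrument, strong instruments, causal vector theta
random_mvmr <- function(J = 60, K = 6, theta = rep(0, K),
                        sx0 = 0.017, sy0 = 0.0099) {
  prim <- rep(seq_len(K), length.out = J)
  gamma <- matrix(0, J, K)
  gamma[cbind(seq_len(J), prim)] <-
    runif(J, 10, 20) * sx0 * sample(c(-1, 1), J, replace = TRUE)
  bx <- gamma + matrix(rnorm(J * K), J, K) * sx0
  sy <- rep(sy0, J)
  by <- as.numeric(gamma %*% theta) + rnorm(J, 0, sy)
  harmonized_dataset(bx, matrix(sx0, J, K), by, sy,
                     exposure_names = paste0("F", seq_len(K)))
}

mips_of <- function(res) {
  res$ranking$mip[match(res$design$factors, res$ranking$factor)]
}
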