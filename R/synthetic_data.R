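# Simulation of GWAS summary statistics with stored ground truth, emulating
# the structure of a cytokine-panel exposure GWAS (quantitative traits,
# n ~ 8,293) and binary digestive-polyp outcome GWAS (e.g. 6,155 cases vs
# 341,871 controls): a handful of strong instruments per exposure, a shared
# fraction inducing measured pleiotropy across correlated exposures,
# optional directional pleiotropy and planted outlier instruments, and
# non-significant filler SNPs.

#' Simulation configuration
#'
#' Defaults mirror the study conditions of a 41-cytokine Finnish exposure
#' panel (quantitative, n = 8293, effects in SD units) screened against a
#' binary gastric-polyp outcome (6155 cases / 341871 controls, effects in
#' log-odds). Exposure-side standard errors follow
#' `1/sqrt(2*maf*(1-maf)*n)` for a standardized phenotype; outcome-side
#' standard errors use the binary-trait effective sample size
#' `n_eff = 4/(1/cases + 1/controls)`.
#'
#' @param n_exposures Number of exposure traits K.
#' @param instruments_per_exposure Scalar or length-K vector of primary
#'   instrument counts.
#' @param n_outcome_traits Number of outcome traits.
#' @param outcome_instruments Instruments planted per outcome trait (for
#'   reverse-direction designs), default 0.
#' @param shared_instrument_fraction Probability that an instrument also
#'   affects one other exposure ("measured pleiotropy"), default 0.25.
#' @param shared_effect_scale Relative size of the secondary effect,
#'   default 0.5.
#' @param true_causal Scalar or length-K vector of causal effects theta
#'   (log-odds per SD of exposure), default 0.
#' @param reverse_causal Causal effect of each outcome trait on every
#'   exposure (for reverse-direction truth), default 0.
#' @param pleiotropy_mode `"none"`, `"balanced"` (alpha ~ N(0, scale^2)) or
#'   `"directional"` (alpha ~ N(scale, (scale/2)^2)).
#' @param pleiotropy_scale Scale of the direct instrument-outcome effects
#'   (log-odds units).
#' @param outlier_count,outlier_shift Number of instruments whose outcome
#'   association is shifted, and the shift in `sy` units.
#' @param n_exposure_sample Exposure GWAS sample size, default 8293.
#' @param n_outcome_cases,n_outcome_controls Outcome GWAS case/control
#'   counts, defaults 6155 / 341871.
#' @param maf_range Minor-allele-frequency range, default c(0.1, 0.5).
#' @param n_null_snps Non-significant filler SNPs, default 50.
#' @param instrument_z_range Range of the true instrument z-scores
#'   (effect / exposure SE); default c(10, 20) gives per-SNP F of 100-400.
#' @param palindromic_fraction Fraction of SNPs assigned A/T or C/G allele
#'   pairs (default 0; used to exercise harmonization drops).
#' @param ld_block_size Instruments per LD block (1 = independent); blocks
#'   share a clumping window and get compound-symmetric r^2.
#' @param within_block_r2 r^2 within an LD block, default 0.8.
#' @param seed Mandatory integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_exposures = 6L,
                              instruments_per_exposure = 11L,
                              n_outcome_traits = 1L,
                              outcome_instruments = 0L,
                              shared_instrument_fraction = 0.25,
                              shared_effect_scale = 0.5,
                              true_causal = 0,
                              reverse_causal = 0,
                              pleiotropy_mode = c("none", "balanced", "directional"),
                              pleiotropy_scale = 0,
                              outlier_count = 0L, outlier_shift = 0,
                              n_exposure_sample = 8293L,
                              n_outcome_cases = 6155L,
                              n_outcome_controls = 341871L,
                              maf_range = c(0.1, 0.5),
                              n_null_snps = 50L,
                              instrument_z_range = c(10, 20),
                              palindromic_fraction = 0,
                              ld_block_size = 1L, within_block_r2 = 0.8,
                              seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1L &&
                is.finite(seed), "mrscreen_config_error", "seed is mandatory")
  K <- as.integer(n_exposures)
  ipe <- as.integer(unlist(instruments_per_exposure))
  if (length(ipe) == 1L) ipe <- rep(ipe, K)
  assert_that(length(ipe) == K && all(ipe >= 1L), "mrscreen_config_error",
              "instruments_per_exposure must be >= 1 for every exposure")
  theta <- as.numeric(unlist(true_causal))
  if (length(theta) == 1L) theta <- rep(theta, K)
  assert_that(length(theta) == K, "mrscreen_config_error",
              "true_causal must have length 1 or n_exposures")
  assert_that(shared_instrument_fraction >= 0 && shared_instrument_fraction <= 1,
              "mrscreen_config_error", "shared_instrument_fraction in [0,1]")
  assert_that(all(c(n_exposure_sample, n_outcome_cases, n_outcome_controls) > 0),
              "mrscreen_config_error", "sample sizes must be positive")
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "mrscreen_config_error", "maf_range must lie in (0, 0.5]")
  structure(list(
    n_exposures = K, instruments_per_exposure = ipe,
    n_outcome_traits = as.integer(n_outcome_traits),
    outcome_instruments = as.integer(outcome_instruments),
    shared_instrument_fraction = shared_instrument_fraction,
    shared_effect_scale = shared_effect_scale,
    true_causal = theta, reverse_causal = reverse_causal,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_scale = pleiotropy_scale,
    outlier_count = as.integer(outlier_count), outlier_shift = outlier_shift,
    n_exposure_sample = n_exposure_sample,
    n_outcome_cases = n_outcome_cases, n_outcome_controls = n_outcome_controls,
    maf_range = maf_range, n_null_snps = as.integer(n_null_snps),
    instrument_z_range = instrument_z_range,
    palindromic_fraction = palindromic_fraction,
    ld_block_size = as.integer(ld_block_size),
    within_block_r2 = within_block_r2,
    seed = as.integer(seed)), class = "simulation_config")
}

NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                 "G", "A", "G", "T", "T", "C", "T", "G"),
                               ncol = 2, byrow = TRUE)

#' Simulate GWAS summary statistics with ground truth
#'
#' Draws true per-SNP instrument effects for each exposure (a shared
#' fraction acting on two exposures), generates noisy exposure and outcome
#' association estimates with standard errors implied by the configured
#' sample sizes and allele frequencies, plants outlier instruments and
#' filler null SNPs, and stores the generating truth. Instrument positions
#' are laid out more than one clump window apart so selection is not
#' confounded with the LD structure unless LD blocks are requested.
#' Fully reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @return List with `exposures` (list of [gwas_table()]s), `outcomes`
#'   (list of [gwas_table()]s), `ld` (square r^2 matrix or NULL) and
#'   `truth` (per-SNP effect matrices, `theta`, pleiotropic effects,
#'   planted outlier ids, the config).
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    K <- config$n_exposures
    ipe <- config$instruments_per_exposure
    Tn <- config$n_outcome_traits
    Jx <- sum(ipe)
    Jo <- Tn * config$outcome_instruments
    N0 <- config$n_null_snps
    total <- Jx + Jo + N0

    snp <- data.frame(
      variant_id = sprintf("rs%07d", seq_len(total)),
      stringsAsFactors = FALSE)
    # grid placement: cycle chromosomes, step 11 Mb > the 10,000-kb window.
    # The grid wraps after 22 x 150 slots (position offset by 1 kb per lap)
    # so coordinates stay within 32-bit range for arbitrarily many filler
    # SNPs; instruments occupy the first slots and never wrap.
    idx0 <- seq_len(total) - 1L
    slot <- idx0 %/% 22L
    snp$chrom <- as.character(idx0 %% 22L + 1L)
    snp$pos <- as.integer(10e6 + (slot %% 150L) * 11e6 + (slot %/% 150L) * 1000L)
    pal <- runif(total) < config$palindromic_fraction
    pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS),
                                            total, replace = TRUE), , drop = FALSE]
    pal_pair <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                       ncol = 2, byrow = TRUE)[sample.int(4, total, replace = TRUE), ,
                                               drop = FALSE]
    snp$effect_allele <- ifelse(pal, pal_pair[, 1], pair[, 1])
    snp$other_allele <- ifelse(pal, pal_pair[, 2], pair[, 2])
    maf <- runif(total, config$maf_range[1], config$maf_range[2])
    snp$eaf <- ifelse(runif(total) < 0.5, maf, 1 - maf)

    sx <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure_sample)
    n_eff <- 4 / (1 / config$n_outcome_cases + 1 / config$n_outcome_controls)
    sy <- 1 / sqrt(2 * maf * (1 - maf) * n_eff)

    # true exposure effects: one primary exposure per instrument, optional
    # secondary effect on one other exposure (measured pleiotropy)
    gamma <- matrix(0, total, K)
    primary <- rep(NA_integer_, total)
    pos <- 1L
    for (k in seq_len(K)) {
      rows <- seq.int(pos, length.out = ipe[k])
      primary[rows] <- k
      z <- runif(ipe[k], config$instrument_z_range[1], config$instrument_z_range[2]) *
        sample(c(-1, 1), ipe[k], replace = TRUE)
      gamma[rows, k] <- z * sx[rows]
      pos <- pos + ipe[k]
    }
    if (K > 1 && config$shared_instrument_fraction > 0) {
      for (j in which(!is.na(primary))) {
        if (runif(1) < config$shared_instrument_fraction) {
          k2 <- sample(setdiff(seq_len(K), primary[j]), 1L)
          gamma[j, k2] <- config$shared_effect_scale * gamma[j, primary[j]] *
            runif(1, 0.5, 1)
        }
      }
    }

    # direct outcome-trait instruments (reverse-direction designs)
    delta <- matrix(0, total, Tn)
    if (Jo > 0) {
      pos <- Jx + 1L
      for (t in seq_len(Tn)) {
        rows <- seq.int(pos, length.out = config$outcome_instruments)
        z <- runif(length(rows), config$instrument_z_range[1],
                   config$instrument_z_range[2]) *
          sample(c(-1, 1), length(rows), replace = TRUE)
        delta[rows, t] <- z * sy[rows]
        pos <- pos + config$outcome_instruments
      }
      if (config$reverse_causal != 0) {
        gamma <- gamma + config$reverse_causal * rowSums(delta)
      }
    }

    alpha <- numeric(total)
    inst <- which(!is.na(primary))
    if (config$pleiotropy_mode == "balanced") {
      alpha[inst] <- rnorm(length(inst), 0, config$pleiotropy_scale)
    } else if (config$pleiotropy_mode == "directional") {
      alpha[inst] <- rnorm(length(inst), config$pleiotropy_scale,
                           config$pleiotropy_scale / 2)
    }

    outlier_ids <- character(0)
    shift <- numeric(total)
    if (config$outlier_count > 0) {
      o <- sample(inst, config$outlier_count)
      shift[o] <- config$outlier_shift * sy[o]
      outlier_ids <- snp$variant_id[o]
    }

    # observed estimates
    bx <- gamma + matrix(rnorm(total * K), total, K) * sx
    exposures <- lapply(seq_len(K), function(k) {
      d <- snp
      d$beta <- bx[, k]
      d$se <- sx
      d$pval <- 2 * pnorm(-abs(d$beta / d$se))
      d$n <- config$n_exposure_sample
      gwas_table(d, trait_name = paste0("exposure_", k),
                 trait_type = "quantitative", quiet = TRUE)
    })

    mu <- gamma %*% config$true_causal + alpha
    outcomes <- lapply(seq_len(Tn), function(t) {
      m <- mu + delta[, t] + if (t == 1L) shift else 0
      d <- snp
      d$beta <- as.numeric(m) + rnorm(total) * sy
      d$se <- sy
      d$pval <- 2 * pnorm(-abs(d$beta / d$se))
      d$n <- config$n_outcome_cases + config$n_outcome_controls
      gwas_table(d, trait_name = paste0("outcome_", t),
                 trait_type = "binary", quiet = TRUE)
    })

    ld <- NULL
    if (config$ld_block_size > 1L) {
      # re-place instruments so block members share a clump window, and build
      # a compound-symmetric r^2 matrix over instrument SNPs
      ids <- snp$variant_id[inst]
      ld <- diag(length(inst))
      dimnames(ld) <- list(ids, ids)
      blocks <- split(seq_along(inst),
                      ceiling(seq_along(inst) / config$ld_block_size))
      for (b in blocks) ld[b, b] <- config$within_block_r2
      diag(ld) <- 1
      # members of one block: same chromosome, 50-kb spacing
      for (bi in seq_along(blocks)) {
        b <- inst[blocks[[bi]]]
        ch <- as.character((bi - 1L) %% 22L + 1L)
        newpos <- as.integer(10e6 + ((bi - 1L) %/% 22L) * 11e6 +
                               (seq_along(b) - 1L) * 5e4)
        for (tab in seq_len(K)) {
          exposures[[tab]]$data$chrom[b] <- ch
          exposures[[tab]]$data$pos[b] <- newpos
        }
        for (tab in seq_len(Tn)) {
          outcomes[[tab]]$data$chrom[b] <- ch
          outcomes[[tab]]$data$pos[b] <- newpos
        }
      }
    }

    truth <- list(gamma = gamma, alpha = alpha, delta = delta,
                  theta = config$true_causal,
                  primary_exposure = primary,
                  sx = sx, sy = sy, maf = maf,
                  variant_id = snp$variant_id,
                  outlier_ids = outlier_ids,
                  config = config)
    list(exposures = exposures, outcomes = outcomes, ld = ld, truth = truth)
  })
}

#' Canonical fixture configurations
#'
#' Three named configurations used across the test-suite and examples:
#' `screen` (a 41-exposure by 3-outcome screen with small instrument counts),
#' `bma` (a 6-factor, 67-instrument multivariable dataset with one planted
#' 10-sy outlier and one weakly causal factor, the shape of the
#' gastric-polyp MR-BMA analysis) and `degenerate` (single-instrument,
#' all-palindromic, and no-significant-SNP traits).
#'
#' @param which `"screen"`, `"bma"` or `"degenerate"`.
#' @param seed Integer seed.
#' @return A [simulation_config()] (for `"degenerate"`, a list of three).
#' @export
fixture_config <- function(which = c("screen", "bma", "degenerate"), seed = 20260101L) {
  which <- match.arg(which)
  switch(which,
    screen = simulation_config(
      n_exposures = 41L, instruments_per_exposure = 4L,
      n_outcome_traits = 3L, outcome_instruments = 6L,
      shared_instrument_fraction = 0.2,
      true_causal = c(0.1, rep(0, 40)),
      n_null_snps = 40L, seed = seed),
    bma = simulation_config(
      n_exposures = 6L,
      instruments_per_exposure = c(12L, 11L, 11L, 11L, 11L, 11L),
      shared_instrument_fraction = 0.3,
      true_causal = c(0.1, rep(0, 5)),
      outlier_count = 1L, outlier_shift = 10,
      instrument_z_range = c(12, 15),
      n_null_snps = 30L, seed = seed),
    degenerate = list(
      single = simulation_config(n_exposures = 1L, instruments_per_exposure = 1L,
                                 n_null_snps = 20L, seed = seed),
      palindromic = simulation_config(n_exposures = 1L, instruments_per_exposure = 4L,
                                      palindromic_fraction = 1,
                                      n_null_snps = 10L, seed = seed + 1L),
      weak = simulation_config(n_exposures = 1L, instruments_per_exposure = 4L,
                               instrument_z_range = c(1, 2),
                               n_null_snps = 10L, seed = seed + 2L))
  )
}

#' Write the canonical fixture suite to disk
#'
#' Materializes the three [fixture_config()] scenarios as tab-delimited
#' summary-statistics files (the same format read by [read_gwas_table()]),
#' with the generating truth as sidecar TSVs.
#'
#' @param out_dir Writable output directory (created if absent).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixture_suite <- function(out_dir, seed = 20260101L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(sim, prefix) {
    for (tb in c(sim$exposures, sim$outcomes)) {
      p <- file.path(out_dir, sprintf("%s_%s.tsv", prefix, tb$trait_name))
      write_gwas_table(tb, p)
      paths <<- c(paths, p)
    }
    tp <- file.path(out_dir, sprintf("%s_truth.tsv", prefix))
    tr <- data.frame(variant_id = sim$truth$variant_id,
                     primary_exposure = sim$truth$primary_exposure,
                     alpha = sim$truth$alpha,
                     outlier = sim$truth$variant_id %in% sim$truth$outlier_ids)
    tr <- cbind(tr, as.data.frame(sim$truth$gamma))
    write_tsv(tr, tp)
    paths <<- c(paths, tp)
  }
  emit(simulate_gwas(fixture_config("screen", seed)), "screen")
  emit(simulate_gwas(fixture_config("bma", seed)), "bma")
  deg <- fixture_config("degenerate", seed)
  for (nm in names(deg)) emit(simulate_gwas(deg[[nm]]), paste0("degenerate_", nm))
  invisible(paths)
}
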