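# Univariable two-sample MR estimators, sensitivity analyses and the
# bidirectional screen.

Z95 <- stats::qnorm(0.975)

# one estimate row; CI on the beta scale plus the exponentiated (OR) scale
mr_estimate <- function(method, exposure, outcome, n_snps, beta, se,
                        df = Inf) {
  crit <- if (is.finite(df)) qt(0.975, df) else Z95
  ci_lo <- beta - crit * se
  ci_hi <- beta + crit * se
  z <- beta / se
  pval <- if (is.finite(df)) 2 * pt(-abs(z), df) else 2 * pnorm(-abs(z))
  structure(list(method = method, exposure = exposure, outcome = outcome,
                 n_snps = n_snps, beta = beta, se = se,
                 ci_lo = ci_lo, ci_hi = ci_hi, pval = pval,
                 or_ = exp(beta), or_lo = exp(ci_lo), or_hi = exp(ci_hi)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s %s -> %s (J=%d): beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$exposure, x$outcome, x$n_snps, x$beta, x$se,
              x$or_, x$or_lo, x$or_hi, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

check_univariable <- function(h) {
  stopifnot(inherits(h, "harmonized_data"))
  assert_that(ncol(h$bx) == 1L, "mrscreen_domain_error",
              "univariable estimator needs exactly one exposure")
  invisible(h)
}

#' Per-SNP Wald ratio estimates
#'
#' The building block of the univariable estimators: for each instrument j,
#' `ratio_j = by_j / bx_j` with first-order delta-method standard error
#' `sy_j / |bx_j|`.
#'
#' @param h A single-exposure `harmonized_data` object.
#' @return data.frame with `variant_id`, `ratio`, `se`.
#' @export
ratio_estimates <- function(h) {
  check_univariable(h)
  bx <- h$bx[, 1]
  zero <- bx == 0
  assert_that(!any(zero), "mrscreen_degenerate_instrument",
              "instrument(s) with zero exposure effect: %s",
              paste(h$variant_ids[zero], collapse = ", "))
  data.frame(variant_id = h$variant_ids,
             ratio = unname(h$by / bx),
             se = unname(h$sy / abs(bx)),
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate with heterogeneity assessment
#'
#' IVW combines the per-SNP Wald ratios with weights `w_j = bx_j^2 / sy_j^2`
#' (equivalent to a no-intercept weighted regression of `by` on `bx` with
#' weights `1/sy^2`). Cochran's Q is referred to a chi-square with J-1 df;
#' with `model = "auto"` the fixed-effect SE is kept when the heterogeneity
#' p-value exceeds `het_p`, otherwise a multiplicative random-effects SE
#' `se_fixed * sqrt(max(1, Q/(J-1)))` is used. The point estimate is
#' identical under both models.
#'
#' @param h Single-exposure `harmonized_data`.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param het_p Heterogeneity p-value above which the fixed model is kept
#'   (default 0.05).
#' @return List with `estimate` (an `mr_estimate`) and `heterogeneity`
#'   (`Q`, `df`, `pval`, `model_selected`; NULL when J = 1, where the
#'   single Wald ratio is returned with method `"wald_ratio"`).
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random"), het_p = 0.05) {
  model <- match.arg(model)
  check_univariable(h)
  r <- ratio_estimates(h)
  J <- nrow(r)
  assert_that(J >= 1L, "mrscreen_empty_input", "no instruments")
  if (J == 1L) {
    return(list(estimate = mr_estimate("wald_ratio", h$exposure_names, h$outcome_name,
                                       1L, r$ratio, r$se),
                heterogeneity = NULL))
  }
  w <- (h$bx[, 1] / h$sy)^2
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (r$ratio - beta)^2)
  df <- J - 1L
  Qp <- pchisq(Q, df, lower.tail = FALSE)
  selected <- switch(model,
                     fixed = "fixed",
                     random = "random",
                     auto = if (Qp > het_p) "fixed" else "random")
  se <- if (selected == "fixed") se_fixed else
    se_fixed * sqrt(max(1, Q / df))
  method <- if (selected == "fixed") "ivw_fixed" else "ivw_random"
  list(estimate = mr_estimate(method, h$exposure_names, h$outcome_name, J, beta, se),
       heterogeneity = list(Q = Q, df = df, pval = Qp, model_selected = selected))
}

#' MR-Egger regression and the intercept test for directional pleiotropy
#'
#' Instruments are first oriented so every exposure effect is positive, then
#' `by` is regressed on `bx` *with* an intercept, weights `1/sy^2`. The
#' intercept estimates the average directional pleiotropic effect; a
#' non-zero intercept (p < 0.05) indicates the IVW estimate may be biased.
#' Coefficient standard errors are inflated by
#' `sqrt(max(1, RSS/(J-2)))` and inference uses the t distribution with
#' J-2 df.
#'
#' @param h Single-exposure `harmonized_data` with at least 3 instruments.
#' @return List with `estimate` (slope, method `"egger"`) and `pleiotropy`
#'   (`intercept`, `se`, `pval`, logical `biased`).
#' @export
mr_egger <- function(h) {
  check_univariable(h)
  J <- length(h$by)
  assert_that(J >= 3L, "mrscreen_insufficient_instruments",
              "MR-Egger needs at least 3 instruments (have %d)", J)
  flip <- sign(h$bx[, 1])
  flip[flip == 0] <- 1
  bx <- h$bx[, 1] * flip
  by <- h$by * flip
  w <- 1 / h$sy^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- sqrt(max(1, sum(w * resid(fit)^2) / (J - 2)))
  se_unscaled <- sm$coefficients[, "Std. Error"] / sm$sigma
  se <- se_unscaled * disp
  est <- coef(fit)
  tstat <- est / se
  pvals <- 2 * pt(-abs(tstat), J - 2)
  list(
    estimate = mr_estimate("egger", h$exposure_names, h$outcome_name, J,
                           unname(est["bx"]), unname(se["bx"]), df = J - 2),
    pleiotropy = list(intercept = unname(est["(Intercept)"]),
                      se = unname(se["(Intercept)"]),
                      pval = unname(pvals["(Intercept)"]),
                      biased = unname(pvals["(Intercept)"]) < 0.05)
  )
}

# weighted median of ratio estimates b with weights w, midpoint-cumulative
# interpolation: s*_j = s_{j-1} + w_j/2 on normalized weights
weighted_median_point <- function(b, w) {
  b <- unname(b)
  w <- unname(w)
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  n <- length(b)
  if (0.5 >= s[n]) return(b[n])
  j <- findInterval(0.5, s)
  b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median estimate
#'
#' The weighted median of the per-SNP Wald ratios with inverse-variance
#' weights `w_j = bx_j^2/sy_j^2`; consistent when at least half the weight
#' comes from valid instruments. The standard error is obtained by
#' parametric bootstrap: each ratio is resampled from
#' `Normal(ratio_j, se_j)` with weights held fixed, and the SD of the
#' resampled medians is taken.
#'
#' @param h Single-exposure `harmonized_data` with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Mandatory integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed) {
  check_univariable(h)
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1L &&
                is.finite(seed), "mrscreen_domain_error",
              "an explicit integer seed is required")
  r <- ratio_estimates(h)
  J <- nrow(r)
  assert_that(J >= 3L, "mrscreen_insufficient_instruments",
              "weighted median needs at least 3 instruments (have %d)", J)
  w <- (h$bx[, 1] / h$sy)^2
  est <- weighted_median_point(r$ratio, w)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    weighted_median_point(rnorm(J, r$ratio, r$se), w)
  }, numeric(1)))
  mr_estimate("weighted_median", h$exposure_names, h$outcome_name, J,
              est, sd(boots))
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Re-estimates the IVW effect J times, each time omitting one instrument.
#' A row is flagged when its confidence interval lies entirely on the
#' opposite side of zero from the full-data point estimate.
#'
#' @param h Single-exposure `harmonized_data` with at least 2 instruments.
#' @param het_p Passed to [mr_ivw()].
#' @return data.frame with one row per omitted variant: `omitted`,
#'   `n_snps`, `beta`, `se`, `ci_lo`, `ci_hi`, `pval`, `flagged`.
#' @export
leave_one_out <- function(h, het_p = 0.05) {
  check_univariable(h)
  J <- length(h$by)
  assert_that(J >= 2L, "mrscreen_insufficient_instruments",
              "leave-one-out needs at least 2 instruments (have %d)", J)
  full <- mr_ivw(h, het_p = het_p)$estimate
  rows <- lapply(seq_len(J), function(j) {
    sub <- subset_harmonized(h, h$variant_ids[-j])
    e <- mr_ivw(sub, het_p = het_p)$estimate
    data.frame(omitted = h$variant_ids[j], n_snps = e$n_snps,
               beta = e$beta, se = e$se, ci_lo = e$ci_lo, ci_hi = e$ci_hi,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- if (full$beta >= 0) out$ci_hi < 0 else out$ci_lo > 0
  out
}

#' Recover the Wald statistic from a published OR and 95% CI
#'
#' Round-trip utility for validating printed odds-ratio rows:
#' `beta = log(OR)`, `se = (log(hi) - log(lo)) / (2 * 1.96)`, `z = beta/se`
#' and a two-sided normal p-value.
#'
#' @param or_,or_lo,or_hi Odds ratio and its 95% CI bounds (all positive,
#'   `or_lo < or_ < or_hi`).
#' @return List with `beta`, `se`, `z`, `pval`.
#' @export
wald_from_or_ci <- function(or_, or_lo, or_hi) {
  assert_that(all(c(or_, or_lo, or_hi) > 0), "mrscreen_domain_error",
              "odds ratios must be positive")
  assert_that(or_lo < or_ && or_ < or_hi, "mrscreen_domain_error",
              "need or_lo < or_ < or_hi")
  beta <- log(or_)
  se <- (log(or_hi) - log(or_lo)) / (2 * Z95)
  z <- beta / se
  list(beta = beta, se = se, z = z, pval = 2 * pnorm(-abs(z)))
}

# run the three estimators for one harmonized pair; returns list(rows, loo)
run_methods_for_pair <- function(h, direction, n_boot, seed, het_p) {
  J <- n_instruments(h)
  ivw <- mr_ivw(h, het_p = het_p)
  rows <- list(estimate_row(ivw$estimate, direction, ivw$heterogeneity, NULL))
  loo <- NULL
  if (J >= 3L) {
    eg <- mr_egger(h)
    wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
    rows <- c(rows,
              list(estimate_row(eg$estimate, direction, NULL, eg$pleiotropy),
                   estimate_row(wm, direction, NULL, NULL)))
  }
  if (J >= 2L) loo <- leave_one_out(h, het_p = het_p)
  list(rows = do.call(rbind, rows), loo = loo)
}

estimate_row <- function(e, direction, het = NULL, pleio = NULL) {
  data.frame(
    exposure = e$exposure, outcome = e$outcome, direction = direction,
    method = e$method, n_snps = e$n_snps,
    beta = e$beta, se = e$se, ci_lo = e$ci_lo, ci_hi = e$ci_hi, pval = e$pval,
    or_ = e$or_, or_lo = e$or_lo, or_hi = e$or_hi,
    Q = het$Q %||% NA_real_, Q_df = het$df %||% NA_integer_,
    Q_pval = het$pval %||% NA_real_,
    model_selected = het$model_selected %||% NA_character_,
    egger_intercept = pleio$intercept %||% NA_real_,
    egger_intercept_se = pleio$se %||% NA_real_,
    egger_intercept_pval = pleio$pval %||% NA_real_,
    status = "ok", stringsAsFactors = FALSE)
}

failure_row <- function(exposure, outcome, direction, reason) {
  r <- estimate_row(mr_estimate("ivw_fixed", exposure, outcome, 0L, NA_real_, 1),
                    direction)
  r[c("beta", "se", "ci_lo", "ci_hi", "pval", "or_", "or_lo", "or_hi")] <- NA_real_
  r$method <- NA_character_
  r$status <- reason
  r
}

#' Bidirectional univariable MR screen
#'
#' For every exposure-outcome pair, in both directions, runs instrument
#' selection, harmonization and the IVW (primary), MR-Egger and
#' weighted-median estimators plus leave-one-out. Pairs failing instrument
#' selection or harmonization are recorded with a reason, never dropped
#' silently; the screen always completes.
#'
#' @param exposures,outcomes Lists of [gwas_table()]s (a single table is
#'   accepted).
#' @param primary_p,lenient_p,min_snps,clump_kb,clump_r2,ld Passed to
#'   [select_instruments()].
#' @param het_p Heterogeneity threshold for IVW model selection.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Integer seed; each pair receives a deterministic offset of it.
#' @param reverse Also run the reverse (outcome-as-exposure) direction
#'   (default TRUE).
#' @return Object of class `mr_screen`: `results` (one row per pair,
#'   direction and method, with heterogeneity/pleiotropy columns, a
#'   Bonferroni-adjusted p per method and a status code) and `details`
#'   (per estimable pair: the harmonized data, instrument set, leave-one-out
#'   table and scatter/funnel plot data).
#' @export
bidirectional_screen <- function(exposures, outcomes,
                                 primary_p = 5e-8, lenient_p = 5e-6,
                                 min_snps = 3L, clump_kb = 10000L,
                                 clump_r2 = 0.001, ld = NULL,
                                 het_p = 0.05, n_boot = 1000L, seed = 1L,
                                 reverse = TRUE) {
  if (inherits(exposures, "gwas_table")) exposures <- list(exposures)
  if (inherits(outcomes, "gwas_table")) outcomes <- list(outcomes)
  pairs <- expand.grid(e = seq_along(exposures), o = seq_along(outcomes))
  results <- list()
  details <- list()
  pair_i <- 0L

  run_one <- function(expo, outc, direction) {
    pair_i <<- pair_i + 1L
    key <- paste(expo$trait_name, outc$trait_name, direction, sep = "|")
    res <- tryCatch({
      iv <- select_instruments(expo, primary_p = primary_p, lenient_p = lenient_p,
                               min_snps = min_snps, clump_kb = clump_kb,
                               clump_r2 = clump_r2, ld = ld)
      h <- harmonize(iv, outc)
      out <- run_methods_for_pair(h, direction, n_boot, seed + pair_i, het_p)
      out$rows$threshold_used <- iv$threshold_used
      r <- ratio_estimates(h)
      details[[key]] <<- list(
        harmonized = h, instruments = iv, leave_one_out = out$loo,
        scatter = data.frame(variant_id = h$variant_ids, bx = h$bx[, 1],
                             sx = h$sx[, 1], by = h$by, sy = h$sy,
                             stringsAsFactors = FALSE),
        funnel = data.frame(variant_id = r$variant_id, ratio = r$ratio,
                            precision = 1 / r$se, stringsAsFactors = FALSE))
      out$rows
    }, mrscreen_error = function(e) {
      r <- failure_row(expo$trait_name, outc$trait_name, direction,
                       conditionMessage(e))
      r$threshold_used <- NA_real_
      r
    })
    results[[key]] <<- res
  }

  for (i in seq_len(nrow(pairs))) {
    run_one(exposures[[pairs$e[i]]], outcomes[[pairs$o[i]]], "forward")
  }
  if (reverse) {
    for (i in seq_len(nrow(pairs))) {
      run_one(outcomes[[pairs$o[i]]], exposures[[pairs$e[i]]], "reverse")
    }
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  # nominal p-values are primary (as reported); Bonferroni within method is
  # advisory only and never gates downstream steps
  res$pval_bonf <- NA_real_
  for (m in unique(res$method[!is.na(res$method)])) {
    idx <- which(res$method %in% m)
    res$pval_bonf[idx] <- p.adjust(res$pval[idx], method = "bonferroni")
  }
  structure(list(results = res, details = details), class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  ok <- x$results$status == "ok"
  cat(sprintf("<mr_screen> %d method rows over %d pair-directions (%d failed)\n",
              sum(ok), length(unique(paste(x$results$exposure, x$results$outcome,
                                           x$results$direction))),
              length(unique(paste(x$results$exposure, x$results$outcome,
                                  x$results$direction)[!ok]))))
  invisible(x)
}
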