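# Multivariable MR via Bayesian model averaging: model enumeration,
# closed-form posterior scoring, factor ranking (MIP/MACE) and
# instrument-outlier diagnostics with a single repeat-after-removal pass.

#' MR-BMA configuration
#'
#' Collects the tunable parameters of the Bayesian model-averaging analysis.
#' `prior_inclusion` is the independent prior probability that any one factor
#' enters a model; `sigma2` the prior variance of each causal-effect
#' coefficient on the standardized scale. Instruments are flagged as outliers
#' when their heterogeneity contribution exceeds `q_flag` or their Cook's
#' distance exceeds `cd_flag_rule` (`"4/J"` or a fixed number) in the
#' best-ranked model.
#'
#' @param prior_inclusion Prior inclusion probability in (0,1), default 0.1.
#' @param sigma2 Prior variance of causal effects, default 0.25.
#' @param max_model_size Optional cap on the number of factors per model.
#' @param q_flag Q-statistic flag threshold, default 10.
#' @param cd_flag_rule Cook's-distance flag rule: `"4/J"` (default) or a
#'   fixed numeric threshold.
#' @param flag_rule Which outlier criteria gate removal: `"q"` (default;
#'   the heterogeneity contribution alone decides, Cook's distance is
#'   reported as an influence diagnostic), `"and"` (both thresholds must be
#'   exceeded) or `"or"` (either suffices). The default reflects two facts
#'   about the alternatives: the plain 4/J Cook's rule alone habitually
#'   flags several unremarkable instruments (upper order statistics of
#'   leverage times residual), while a gross outlier at a low-leverage
#'   position barely moves the fit and so can have negligible Cook's
#'   distance despite q in the hundreds.
#' @param top_pp_threshold Posterior-probability cutoff for reporting
#'   individual models, default 0.01.
#' @param permutations Replicates for the optional permutation p-value per
#'   factor (0 = off, default).
#' @param seed Integer seed (used by the permutation procedure).
#' @return List of class `bma_config`.
#' @export
bma_config <- function(prior_inclusion = 0.1, sigma2 = 0.25,
                       max_model_size = NULL, q_flag = 10,
                       cd_flag_rule = "4/J", flag_rule = c("q", "and", "or"),
                       top_pp_threshold = 0.01,
                       permutations = 0L, seed = 1L) {
  flag_rule <- match.arg(flag_rule)
  assert_that(prior_inclusion > 0 && prior_inclusion < 1, "mrscreen_domain_error",
              "prior_inclusion must lie in (0,1)")
  assert_that(sigma2 > 0, "mrscreen_domain_error", "sigma2 must be positive")
  if (is.character(cd_flag_rule))
    assert_that(identical(cd_flag_rule, "4/J"), "mrscreen_domain_error",
                "cd_flag_rule must be \"4/J\" or numeric")
  structure(list(prior_inclusion = prior_inclusion, sigma2 = sigma2,
                 max_model_size = max_model_size, q_flag = q_flag,
                 cd_flag_rule = cd_flag_rule, flag_rule = flag_rule,
                 top_pp_threshold = top_pp_threshold,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed)),
            class = "bma_config")
}

cd_threshold <- function(config, J) {
  if (is.numeric(config$cd_flag_rule)) config$cd_flag_rule else 4 / J
}

#' Standardize a multivariable dataset for Bayesian model scoring
#'
#' Applies inverse-variance weighting (row j scaled by `1/sy_j`) so every
#' instrument contributes on a unit-variance z-score scale, then scales each
#' factor column to unit Euclidean norm. The outcome vector stays on the
#' weighted z-score scale: that is the scale on which the scoring model's
#' fixed unit residual variance holds, and shrinking it to unit norm would
#' cap the achievable Bayes factor below the complexity penalty, making
#' every model indistinguishable from the null. The column scales are
#' retained so model-specific estimates can be reported back on the
#' original effect-size scale; the weighted design is kept for the outlier
#' diagnostics.
#'
#' @param h A `harmonized_data` object with J instruments and K factors,
#'   J > K.
#' @return List of class `mvmr_design`: `X`, `y` (unit-norm standardized),
#'   `Xw`, `yw` (weighted, pre-normalization), `xscale`, `yscale`,
#'   `variant_ids`, `factors`, `J`, `K`.
#' @export
prepare_multivariable <- function(h) {
  stopifnot(inherits(h, "harmonized_data"))
  J <- length(h$by)
  K <- ncol(h$bx)
  assert_that(J > K, "mrscreen_underdetermined",
              "need more instruments (J=%d) than factors (K=%d)", J, K)
  sw <- 1 / h$sy
  Xw <- h$bx * sw          # row-wise scaling (recycles by column-major rows)
  yw <- h$by * sw
  xscale <- sqrt(colSums(Xw^2))
  assert_that(all(xscale > 0), "mrscreen_degenerate_factor",
              "factor(s) with zero variance: %s",
              paste(h$exposure_names[xscale == 0], collapse = ", "))
  X <- sweep(Xw, 2, xscale, "/")
  structure(list(X = X, y = yw, Xw = Xw, yw = yw,
                 xscale = xscale, yscale = 1,
                 variant_ids = h$variant_ids, factors = h$exposure_names,
                 J = J, K = K),
            class = "mvmr_design")
}

#' Enumerate candidate multivariable models
#'
#' All non-empty subsets of the K factors up to `max_model_size`, ordered by
#' size then lexicographically. The empty model is scored separately as the
#' null baseline during normalization. Exhaustive enumeration is exact and
#' deterministic at screen-scale K; a combinatorial guard refuses K > 20
#' without a size cap.
#'
#' @param K Number of factors (1..20, or larger with `max_model_size`).
#' @param max_model_size Optional cap on model size.
#' @return List of integer vectors (factor indices).
#' @export
enumerate_models <- function(K, max_model_size = NULL) {
  assert_that(is_count(K), "mrscreen_domain_error", "K must be a positive integer")
  assert_that(K <= 20 || !is.null(max_model_size), "mrscreen_combinatorial_guard",
              "K = %d requires max_model_size", K)
  cap <- min(K, max_model_size %||% K)
  unlist(lapply(seq_len(cap), function(m) {
    cmb <- utils::combn(K, m)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }), recursive = FALSE)
}

#' Score one multivariable model
#'
#' Bayesian weighted linear regression of the standardized outcome on the
#' model's factor columns, no intercept, independent Normal(0, sigma2)
#' coefficient priors and residual variance fixed at 1 on the standardized
#' scale. The log marginal likelihood has the closed form
#' `-0.5 * (log det(I + sigma2 * X_S' X_S) + y'y - sigma2 * y'X_S (I + sigma2
#' X_S'X_S)^{-1} X_S'y)` (additive constants drop out of the posterior
#' normalization). Posterior-mean coefficients are mapped back to the
#' original effect-size scale as the model-specific causal estimates (MSCE).
#'
#' @param design An `mvmr_design` from [prepare_multivariable()].
#' @param S Integer vector of factor indices.
#' @param config A [bma_config()].
#' @return List with `S`, `log_marginal`, `log_prior`, `msce` (named, original
#'   scale) and `coef_std` (posterior means on the standardized scale).
#' @export
model_posterior <- function(design, S, config = bma_config()) {
  stopifnot(inherits(design, "mvmr_design"))
  assert_that(all(S >= 1 & S <= design$K), "mrscreen_domain_error",
              "model subset out of range")
  assert_that(all(is.finite(design$X)) && all(is.finite(design$y)),
              "mrscreen_domain_error", "non-finite design values")
  s2 <- config$sigma2
  p <- config$prior_inclusion
  Xs <- design$X[, S, drop = FALSE]
  M <- diag(length(S)) + s2 * crossprod(Xs)
  Xty <- crossprod(Xs, design$y)
  fit <- solve(M, Xty)
  logml <- -0.5 * (as.numeric(determinant(M, logarithm = TRUE)$modulus) +
                     sum(design$y^2) - s2 * sum(Xty * fit))
  coef_std <- as.numeric(s2 * fit)
  msce <- coef_std * design$yscale / design$xscale[S]
  names(msce) <- design$factors[S]
  list(S = sort(as.integer(S)), log_marginal = logml,
       log_prior = length(S) * log(p) + (design$K - length(S)) * log1p(-p),
       msce = msce, coef_std = coef_std)
}

null_posterior <- function(design, config) {
  list(S = integer(), log_marginal = -0.5 * sum(design$y^2),
       log_prior = design$K * log1p(-config$prior_inclusion),
       msce = numeric(), coef_std = numeric())
}

# normalized posterior probabilities over records (incl. null)
normalize_pp <- function(records) {
  lp <- vapply(records, function(r) r$log_marginal + r$log_prior, numeric(1))
  lp <- lp - max(lp)
  exp(lp) / sum(exp(lp))
}

compute_ranking <- function(records, pp, design) {
  K <- design$K
  mip <- mace <- numeric(K)
  for (i in seq_along(records)) {
    S <- records[[i]]$S
    if (length(S)) {
      mip[S] <- mip[S] + pp[i]
      mace[S] <- mace[S] + pp[i] * records[[i]]$msce
    }
  }
  rk <- data.frame(factor = design$factors, mip = mip, mace = mace,
                   stringsAsFactors = FALSE)
  rk <- rk[order(-rk$mip, rk$factor), , drop = FALSE]
  rk$rank <- seq_len(K)
  rownames(rk) <- NULL
  rk
}

#' Rank risk factors by Bayesian model averaging
#'
#' Enumerates all candidate models, scores each in closed form, and reports
#' the per-factor marginal inclusion probability (MIP: the sum of posterior
#' probabilities of all models containing the factor) and the model-averaged
#' causal estimate (MACE: the PP-weighted average of its model-specific
#' estimates, shrunk toward the null by construction). Factors are ranked by
#' descending MIP with ties broken by name. Individual models with posterior
#' probability above `top_pp_threshold` are reported. When
#' `config$permutations > 0`, an empirical per-factor p-value is computed by
#' permuting the outcome associations across instruments and recording the
#' fraction of permuted MIPs at or above the observed one.
#'
#' @param h A `harmonized_data` object (J > K) or an `mvmr_design`.
#' @param config A [bma_config()].
#' @return Object of class `bma_result`: `ranking` (factor, mip, mace, rank,
#'   optional permutation_p), `models` (data.frame of all models: factors,
#'   size, log marginal likelihood, pp, msce), `top_models`, `records`,
#'   `pp_null` and the `design`.
#' @export
bma_rank <- function(h, config = bma_config()) {
  design <- if (inherits(h, "mvmr_design")) h else prepare_multivariable(h)
  models <- enumerate_models(design$K, config$max_model_size)
  records <- lapply(models, function(S) model_posterior(design, S, config))
  records <- c(records, list(null_posterior(design, config)))
  pp <- normalize_pp(records)
  ranking <- compute_ranking(records, pp, design)

  model_df <- data.frame(
    model = vapply(records, function(r)
      if (length(r$S)) paste(design$factors[r$S], collapse = "+") else "(null)",
      character(1)),
    size = vapply(records, function(r) length(r$S), integer(1)),
    log_marginal = vapply(records, `[[`, numeric(1), "log_marginal"),
    pp = pp,
    msce = vapply(records, function(r)
      paste(sprintf("%.6g", r$msce), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  model_df <- model_df[order(-model_df$pp, model_df$model), , drop = FALSE]
  rownames(model_df) <- NULL

  is_null <- vapply(records, function(r) length(r$S) == 0L, logical(1))
  top_idx <- which(pp > config$top_pp_threshold & !is_null)
  top_idx <- top_idx[order(-pp[top_idx])]

  if (config$permutations > 0L) {
    obs <- ranking$mip[match(design$factors, ranking$factor)]
    exceed <- numeric(design$K)
    with_seed(config$seed, for (b in seq_len(config$permutations)) {
      perm <- design
      idx <- sample.int(design$J)
      perm$y <- design$y[idx]
      perm$yw <- design$yw[idx]
      rec_b <- lapply(models, function(S) model_posterior(perm, S, config))
      rec_b <- c(rec_b, list(null_posterior(perm, config)))
      pp_b <- normalize_pp(rec_b)
      rk_b <- compute_ranking(rec_b, pp_b, perm)
      mip_b <- rk_b$mip[match(design$factors, rk_b$factor)]
      exceed <- exceed + (mip_b >= obs)
    })
    perm_p <- (1 + exceed) / (config$permutations + 1)
    ranking$permutation_p <- perm_p[match(ranking$factor, design$factors)]
  }

  structure(list(ranking = ranking, models = model_df,
                 records = records, pp = pp,
                 top_models = lapply(top_idx, function(i)
                   c(records[[i]], list(pp = pp[i]))),
                 pp_null = pp[which(is_null)],
                 design = design, config = config),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("<bma_result> %d factors, %d models (null pp = %.3f)\n",
              x$design$K, length(x$records), x$pp_null))
  print(x$ranking)
  invisible(x)
}

#' Instrument-outlier diagnostics for the top-ranked models
#'
#' For each top model the per-instrument heterogeneity contribution is
#' `q_j = (y_j - yhat_j)^2` on the inverse-variance (z-score) scale, where
#' the observed outcome association is compared with the one predicted by
#' the model's weighted least-squares fit; Cook's distance comes from the
#' same fit. (The unpenalized fit is used for prediction: posterior-mean
#' coefficients are deliberately shrunk, which would leak causal signal
#' into every residual and swamp the q > `q_flag` rule.) Flagging uses the
#' minimum of each statistic across the top models — an instrument must be
#' outlying under every well-supported model, which suppresses
#' model-dependent chance exceedances — according to `config$flag_rule`:
#' by default when the minimum `q_j` exceeds `config$q_flag`, with Cook's
#' distance (threshold 4/J by default) reported alongside and combinable
#' via the `"and"`/`"or"` rules.
#'
#' @param result A `bma_result` (or an `mvmr_design` with `top_models`
#'   supplied).
#' @param top_models Optional list of scored models to diagnose; defaults to
#'   the result's `top_models` (falling back to the single best model).
#' @param config A [bma_config()]; defaults to the result's config.
#' @return Object of class `bma_diagnostics`: `table` (variant, model, q,
#'   cd), `q_best` and `cd_best` (per-instrument minima across the top
#'   models, the quantities the flag rule tests), `flagged_ids`,
#'   `cd_threshold`.
#' @export
bma_diagnostics <- function(result, top_models = NULL, config = NULL) {
  if (inherits(result, "bma_result")) {
    design <- result$design
    config <- config %||% result$config
    top_models <- top_models %||% result$top_models
    if (!length(top_models)) {
      best <- which.max(result$pp * vapply(result$records, function(r)
        length(r$S) > 0, logical(1)))
      top_models <- list(c(result$records[[best]], list(pp = result$pp[best])))
    }
  } else {
    design <- result
    config <- config %||% bma_config()
    assert_that(length(top_models) > 0, "mrscreen_domain_error",
                "top_models must be non-empty")
  }
  thr <- cd_threshold(config, design$J)
  tabs <- lapply(top_models, function(m) {
    fit <- lm(design$yw ~ 0 + design$Xw[, m$S, drop = FALSE])
    q <- unname(resid(fit))^2
    cd <- unname(cooks.distance(fit))
    data.frame(variant_id = design$variant_ids,
               model = paste(design$factors[m$S], collapse = "+"),
               q = q, cd = cd, stringsAsFactors = FALSE)
  })
  ids <- tabs[[1]]$variant_id
  q_min <- do.call(pmin, lapply(tabs, `[[`, "q"))
  cd_min <- do.call(pmin, lapply(tabs, `[[`, "cd"))
  flagged <- switch(config$flag_rule %||% "q",
                    q = q_min > config$q_flag,
                    and = q_min > config$q_flag & cd_min > thr,
                    or = q_min > config$q_flag | cd_min > thr)
  table <- do.call(rbind, tabs)
  table$flagged <- table$variant_id %in% ids[flagged]
  structure(list(table = table, q_best = setNames(q_min, ids),
                 cd_best = setNames(cd_min, ids),
                 flagged_ids = ids[flagged],
                 cd_threshold = thr),
            class = "bma_diagnostics")
}

#' @export
print.bma_diagnostics <- function(x, ...) {
  cat(sprintf("<bma_diagnostics> %d instruments, %d flagged (q > %s or Cd > %.3g)\n",
              length(x$q_best), length(x$flagged_ids), "q_flag", x$cd_threshold))
  invisible(x)
}

#' MR-BMA with a single outlier-removal pass
#'
#' Runs [bma_rank()] and [bma_diagnostics()]; when any instrument is flagged,
#' all flagged instruments are removed at once and the ranking is recomputed
#' exactly once on the reduced dataset. Both passes are retained.
#'
#' @param h A `harmonized_data` object with J > K.
#' @param config A [bma_config()].
#' @return Object of class `bma_outlier_result`: `pass1`, `pass2` (each with
#'   `result` and `diagnostics`; identical when nothing was flagged),
#'   `removed_ids`, and `final` (the pass-2 `bma_result`).
#' @export
bma_with_outlier_removal <- function(h, config = bma_config()) {
  stopifnot(inherits(h, "harmonized_data"))
  res1 <- bma_rank(h, config)
  diag1 <- bma_diagnostics(res1)
  removed <- diag1$flagged_ids
  if (length(removed)) {
    keep <- setdiff(h$variant_ids, removed)
    assert_that(length(keep) > ncol(h$bx), "mrscreen_underdetermined",
                "outlier removal leaves J=%d <= K=%d", length(keep), ncol(h$bx))
    h2 <- subset_harmonized(h, keep)
    res2 <- bma_rank(h2, config)
    diag2 <- bma_diagnostics(res2)
  } else {
    res2 <- res1
    diag2 <- diag1
  }
  structure(list(pass1 = list(result = res1, diagnostics = diag1),
                 pass2 = list(result = res2, diagnostics = diag2),
                 removed_ids = removed, final = res2),
            class = "bma_outlier_result")
}

#' @export
print.bma_outlier_result <- function(x, ...) {
  cat(sprintf("<bma_outlier_result> pass 1: J=%d; removed %d outlier(s)%s; pass 2: J=%d\n",
              x$pass1$result$design$J, length(x$removed_ids),
              if (length(x$removed_ids))
                paste0(" (", paste(x$removed_ids, collapse = ", "), ")") else "",
              x$pass2$result$design$J))
  print(x$final$ranking)
  invisible(x)
}
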