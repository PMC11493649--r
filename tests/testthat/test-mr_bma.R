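# Bayesian model averaging: design standardization, enumeration, closed-form
# posterior, ranking identities, diagnostics, outlier-removal pass

test_that("standardization weights rows by 1/sy and unit-norms factor columns", {
  withr::local_seed(2001)
  h <- random_mvmr(J = 20, K = 3)
  d <- prepare_multivariable(h)
  expect_equal(unname(sqrt(colSums(d$X^2))), rep(1, 3), tolerance = 1e-12)
  # equal sy: X proportional to bx (weights cancel after column scaling)
  h_eq <- harmonized_dataset(h$bx, h$sx, h$by, rep(0.01, 20),
                             exposure_names = h$exposure_names)
  d_eq <- prepare_multivariable(h_eq)
  expect_equal(d_eq$X, sweep(h$bx, 2, sqrt(colSums(h$bx^2)), "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # under-determined guard
  expect_error(prepare_multivariable(
    harmonized_dataset(h$bx[1:3, ], h$sx[1:3, ], h$by[1:3], h$sy[1:3])),
    class = "mrscreen_underdetermined")
})

test_that("model enumeration is exhaustive, capped, ordered, and guarded", {
  m6 <- enumerate_models(6)
  expect_length(m6, 63L)
  expect_equal(enumerate_models(1), list(1L))
  expect_equal(enumerate_models(3, max_model_size = 1), list(1L, 2L, 3L))
  sizes <- vapply(m6, length, integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(enumerate_models(21), class = "mrscreen_combinatorial_guard")
  expect_silent(enumerate_models(21, max_model_size = 2))
})

test_that("the shrinkage prior limit collapses every model onto the null", {
  withr::local_seed(2002)
  h <- random_mvmr(J = 15, K = 3)
  d <- prepare_multivariable(h)
  cfg <- bma_config(sigma2 = 1e-12)
  null_ml <- -0.5 * sum(d$y^2)
  for (S in enumerate_models(3)) {
    rec <- model_posterior(d, S, cfg)
    expect_equal(rec$log_marginal, null_ml, tolerance = 1e-6)
    expect_equal(unname(rec$msce), rep(0, length(S)), tolerance = 1e-6)
  }
})

test_that("the closed-form marginal likelihood matches numerical integration", {
  # J = 5 toy, singleton model: integrate the N(y; x*b, I) * N(b; 0, s2)
  # likelihood over b and compare log Bayes factors against the null
  x <- c(0.9, 0.3, -0.2, 0.5, 0.1)
  x <- x / sqrt(sum(x^2))
  y <- c(1.2, -0.4, 0.3, 0.8, -0.1)
  s2 <- 0.25
  h <- harmonized_dataset(bx = cbind(x, c(0.2, 0.1, 0.4, -0.3, 0.25)),
                          sx = matrix(0.01, 5, 2), by = y, sy = rep(1, 5))
  d <- prepare_multivariable(h)
  d$X[, 1] <- x; d$y <- y        # use the raw toy scales directly
  rec <- model_posterior(d, 1L, bma_config(sigma2 = s2))
  integrand <- function(b) {
    vapply(b, function(bi)
      exp(sum(stats::dnorm(y, x * bi, 1, log = TRUE)) +
            stats::dnorm(bi, 0, sqrt(s2), log = TRUE)), numeric(1))
  }
  num <- log(stats::integrate(integrand, -10, 10, rel.tol = 1e-10)$value)
  null_log <- sum(stats::dnorm(y, 0, 1, log = TRUE))
  expect_equal(rec$log_marginal - (-0.5 * sum(y^2)), num - null_log,
               tolerance = 1e-4)
})

test_that("duplicated factor columns earn identical singleton marginal likelihoods", {
  withr::local_seed(2003)
  h <- random_mvmr(J = 12, K = 2)
  h$bx[, 2] <- h$bx[, 1]
  h$sx[, 2] <- h$sx[, 1]
  d <- prepare_multivariable(h)
  r1 <- model_posterior(d, 1L)
  r2 <- model_posterior(d, 2L)
  expect_equal(r1$log_marginal, r2$log_marginal, tolerance = 1e-10)
})

test_that("posterior-mean coefficients solve the ridge problem and reach WLS in the diffuse limit", {
  withr::local_seed(2004)
  h <- random_mvmr(J = 25, K = 4, theta = c(0.2, 0, -0.1, 0))
  d <- prepare_multivariable(h)
  S <- c(1L, 3L)
  # independent oracle: numerical minimisation of the penalised least squares
  rec <- model_posterior(d, S, bma_config(sigma2 = 0.25))
  obj <- function(b) sum((d$y - d$X[, S] %*% b)^2) + sum(b^2) / 0.25
  opt <- stats::optim(c(0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-16))
  expect_equal(rec$coef_std, opt$par, tolerance = 1e-6)
  # closed-form ridge identity, tighter
  ridge <- solve(crossprod(d$X[, S]) + diag(2) / 0.25, crossprod(d$X[, S], d$y))
  expect_equal(rec$coef_std, as.numeric(ridge), tolerance = 1e-10)
  # diffuse prior: MSCE mapped back equals the WLS coefficient on (bx, by, w)
  rec_inf <- model_posterior(d, S, bma_config(sigma2 = 1e8))
  wls <- coef(lm(h$by ~ 0 + h$bx[, S], weights = 1 / h$sy^2))
  expect_equal(unname(rec_inf$msce), unname(wls), tolerance = 1e-6)
})

test_that("posterior probabilities normalize and the MIP/MACE identities hold", {
  withr::local_seed(2005)
  for (i in 1:5) {
    h <- random_mvmr(J = 30, K = 4, theta = c(runif(1, 0, 0.3), 0, 0, 0))
    res <- bma_rank(h, bma_config())
    expect_equal(sum(res$pp), 1, tolerance = 1e-10)
    # recompute MIP and MACE from the records
    for (k in seq_len(4)) {
      has_k <- vapply(res$records, function(r) k %in% r$S, logical(1))
      mip_k <- sum(res$pp[has_k])
      mace_k <- sum(vapply(which(has_k), function(i)
        res$pp[i] * res$records[[i]]$msce[res$design$factors[k]], numeric(1)))
      row <- res$ranking[res$ranking$factor == res$design$factors[k], ]
      expect_equal(row$mip, mip_k, tolerance = 1e-10)
      expect_equal(row$mace, mace_k, tolerance = 1e-10)
      # MACE shrinkage bound
      max_msce <- max(abs(vapply(which(has_k), function(i)
        res$records[[i]]$msce[res$design$factors[k]], numeric(1))))
      expect_lte(abs(row$mace), row$mip * max_msce + 1e-12)
    }
  }
})

test_that("K = 1 ranking reproduces the two-model closed form", {
  withr::local_seed(2006)
  h <- random_mvmr(J = 10, K = 2, theta = c(0.1, 0))
  h1 <- harmonized_dataset(h$bx[, 1], h$sx[, 1], h$by, h$sy,
                           exposure_names = "F1")
  p <- 0.1
  res <- bma_rank(h1, bma_config(prior_inclusion = p))
  d <- prepare_multivariable(h1)
  ml1 <- exp(model_posterior(d, 1L, bma_config(prior_inclusion = p))$log_marginal)
  ml0 <- exp(-0.5 * sum(d$y^2))
  expect_equal(res$ranking$mip, p * ml1 / (p * ml1 + (1 - p) * ml0),
               tolerance = 1e-10)
})

test_that("factor relabeling permutes MIP and MACE identically", {
  withr::local_seed(2007)
  h <- random_mvmr(J = 24, K = 4, theta = c(0.25, 0, 0.1, 0))
  perm <- c(3, 1, 4, 2)
  h_perm <- harmonized_dataset(h$bx[, perm], h$sx[, perm], h$by, h$sy,
                               exposure_names = h$exposure_names[perm])
  r1 <- bma_rank(h, bma_config())$ranking
  r2 <- bma_rank(h_perm, bma_config())$ranking
  m1 <- r1[order(r1$factor), c("mip", "mace")]
  m2 <- r2[order(r2$factor), c("mip", "mace")]
  expect_equal(m1, m2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("raising the prior inclusion probability never lowers a MIP", {
  withr::local_seed(2008)
  h <- random_mvmr(J = 18, K = 3, theta = c(0.15, 0, 0))
  grid <- c(0.05, 0.1, 0.3)
  mips <- sapply(grid, function(p) mips_of(bma_rank(h, bma_config(prior_inclusion = p))))
  expect_true(all(diff(t(mips)) >= -1e-12))
})

test_that("diagnostics: perfect fit gives zero q; the 4/J rule computes the stated threshold", {
  x <- seq(0.5, 2, length.out = 21)
  h <- harmonized_dataset(bx = x, sx = rep(0.01, 21), by = 0.3 * x,
                          sy = rep(1, 21))
  res <- bma_rank(h, bma_config())
  diag <- bma_diagnostics(res)
  expect_equal(unname(diag$q_best), rep(0, 21), tolerance = 1e-20)
  expect_length(diag$flagged_ids, 0L)
  expect_equal(diag$cd_threshold, 4 / 21, tolerance = 1e-12)
  expect_equal(round(diag$cd_threshold, 2), 0.19)
})

test_that("a corrupted instrument attains the maximal q and is flagged and removed", {
  withr::local_seed(2009)
  h <- random_mvmr(J = 30, K = 3, theta = c(0.2, 0, 0))
  j <- 13
  h$by[[j]] <- h$by[[j]] + 10 * h$sy[[j]]
  res <- bma_rank(h, bma_config())
  diag <- bma_diagnostics(res)
  expect_equal(names(which.max(diag$q_best)), h$variant_ids[j])
  expect_true(h$variant_ids[j] %in% diag$flagged_ids)
  # or-rule flags exactly the union of the two exceedances
  diag_or <- bma_diagnostics(res, config = bma_config(flag_rule = "or"))
  expect_setequal(diag_or$flagged_ids,
                  names(which(diag_or$q_best > 10 |
                                diag_or$cd_best > diag_or$cd_threshold)))

  fit <- bma_with_outlier_removal(h, bma_config())
  expect_true(h$variant_ids[j] %in% fit$removed_ids)
  expect_equal(fit$pass2$result$design$J, 30L - length(fit$removed_ids))
})

test_that("no flags means the second pass is the first pass", {
  withr::local_seed(2012)
  x <- seq(0.5, 2, length.out = 15)
  h <- harmonized_dataset(bx = cbind(x, rev(x)), sx = matrix(0.01, 15, 2),
                          by = 0.3 * x + rnorm(15, 0, 0.2), sy = rep(1, 15))
  fit <- bma_with_outlier_removal(h, bma_config())
  expect_length(fit$removed_ids, 0L)
  expect_identical(fit$pass1$result$ranking, fit$pass2$result$ranking)
})

test_that("outlier removal raises or preserves the causal factor's MIP in most replicates", {
  withr::local_seed(2010)
  wins <- replicate(40, {
    h <- random_mvmr(J = 30, K = 3, theta = c(0.1, 0, 0))
    j <- sample(30, 1)
    h$by[[j]] <- h$by[[j]] + 10 * h$sy[[j]]
    fit <- bma_with_outlier_removal(h, bma_config())
    m1 <- mips_of(fit$pass1$result)[1]
    m2 <- mips_of(fit$pass2$result)[1]
    m2 >= m1 - 1e-12
  })
  expect_gte(mean(wins), 0.5 + 1 / 40)
})

test_that("the permutation p-value separates a causal from a null factor", {
  withr::local_seed(2011)
  h <- random_mvmr(J = 24, K = 3, theta = c(0.3, 0, 0))
  res <- bma_rank(h, bma_config(permutations = 99, seed = 5))
  rk <- res$ranking
  expect_lt(rk$permutation_p[rk$factor == "F1"], 0.05)
  expect_gt(min(rk$permutation_p[rk$factor != "F1"]), 0.05)
})
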