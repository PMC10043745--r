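# Zero-truncated NB likelihood and the two-part hurdle fit.

test_that("truncated pmf is a proper distribution", {
  for (mu in c(0.5, 1.45, 4)) {
    for (alpha in c(0.05, 0.5, 2)) {
      k <- 1:400
      expect_lt(abs(sum(dztnb(k, mu, alpha)) - 1), 1e-8)
    }
  }
  expect_error(dztnb(0, 1, 0.5), "y >= 1")
  expect_error(dztnb(1, 1, -0.1), "alpha")
})

test_that("log-likelihood matches the brute-force summation oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    X <- cbind(1, stats::rnorm(n, sd = 0.4))
    beta <- stats::rnorm(2, sd = 0.5)
    alpha <- stats::runif(1, 0.05, 1.5)
    y <- rztnb(n, exp(drop(X %*% beta)), alpha)
    expect_lt(abs(ztnb_loglik(beta, alpha, y, X) -
                    brute_ztnb_loglik(beta, alpha, y, X)), 1e-8)
  }
})

test_that("small-dispersion limit reduces to the zero-truncated Poisson", {
  # intercept-only, mu = 1, y = 1: term = -1 - log(1 - exp(-1))
  X <- matrix(1, 1, 1)
  ll <- ztnb_loglik(0, 1e-10, 1L, X)
  expect_lt(abs(ll - (-1 - log(1 - exp(-1)))), 1e-6)
  # and on a vector of counts it matches the ZT-Poisson density
  set.seed(3)
  y <- pmax(1L, stats::rpois(50, 2))
  Xv <- matrix(1, 50, 1)
  expect_lt(abs(ztnb_loglik(log(2), 1e-10, y, Xv) -
                  sum(ztpois_logdens(y, 2))), 1e-5)
  expect_error(ztnb_loglik(0, 0.5, c(1L, 0L), matrix(1, 2, 1)), "y >= 1")
  expect_error(ztnb_loglik(0, -1, c(1L, 2L), matrix(1, 2, 1)), "alpha")
})

test_that("the fitted ZTNB is a local maximum of the likelihood", {
  d <- make_cohort(3000, seed = 5)
  d <- generate_outcomes(d, seed = 5)
  fit <- hurdle_fit(n_services ~ plan_type, d)
  X <- fit$X[fit$y > 0, , drop = FALSE]
  y <- fit$y[fit$y > 0]
  ll_hat <- ztnb_loglik(fit$part2$coefficients, fit$part2$alpha, y, X)
  for (j in seq_along(fit$part2$coefficients)) {
    pert <- fit$part2$coefficients
    pert[j] <- pert[j] + 0.05
    expect_lt(ztnb_loglik(pert, fit$part2$alpha, y, X), ll_hat)
  }
  expect_lt(ztnb_loglik(fit$part2$coefficients, fit$part2$alpha * 1.5, y, X),
            ll_hat)
})

test_that("degenerate hurdles and separation are refused", {
  d <- data.frame(y = c(1L, 2L, 3L), x = 1:3)
  expect_error(hurdle_fit(y ~ x, d), "positive")
  d0 <- data.frame(y = c(0L, 0L), x = 1:2)
  expect_error(hurdle_fit(y ~ x, d0), "zero")
  # a perfectly separating covariate
  sep <- data.frame(y = rep(c(0L, 2L), each = 25), x = rep(0:1, each = 25))
  expect_error(suppressWarnings(hurdle_fit(y ~ x, sep)), "[Ss]eparation")
})

test_that("observed-information SEs agree with a function-only Hessian", {
  set.seed(22)
  d <- make_cohort(4000, seed = 22)
  d <- generate_outcomes(d, seed = 22)
  fit <- hurdle_fit(n_services ~ plan_type, d)
  X <- fit$X[fit$y > 0, , drop = FALSE]
  y <- fit$y[fit$y > 0]
  p <- ncol(X)
  negll <- function(th) -ztnb_loglik(th[1:p], exp(th[p + 1]), y, X)
  H <- stats::optimHess(fit$part2$theta, negll)
  se_fd <- sqrt(diag(solve(H)))
  se_pkg <- sqrt(diag(fit$part2$vcov))
  expect_lt(max(abs(se_fd - se_pkg) / se_pkg), 1e-4)
})

test_that("zero-truncated mean identity holds against Monte Carlo draws", {
  set.seed(77)
  mu <- 1.6; alpha <- 0.3
  y <- rztnb(2e5, mu, alpha)
  m_analytic <- mu / (1 - (1 + alpha * mu)^(-1 / alpha))
  expect_lt(abs(mean(y) - m_analytic), 3 * stats::sd(y) / sqrt(length(y)))
  expect_true(all(y >= 1))
})

test_that("hurdle fit recovers planted parameters at moderate n", {
  d <- make_cohort(20000, seed = 31)
  d <- generate_outcomes(d, seed = 31)
  d$age_group <- collapse_age_groups(d$age_group)
  fit <- hurdle_fit(n_services ~ plan_type + age_group + race_ethnicity +
                      cci_category + region, d)
  expect_true(fit$part1$converged)
  expect_true(fit$part2$converged)
  p <- default_outcome_params()
  s <- summary(fit)
  common <- intersect(rownames(s$part1), names(p$beta_logit))
  z1 <- (s$part1[common, 1] - p$beta_logit[common]) / s$part1[common, 2]
  z2 <- (s$part2[common, 1] - p$beta_count[common]) / s$part2[common, 2]
  expect_true(all(abs(z1) < 4))
  expect_true(all(abs(z2) < 4))
  za <- (fit$part2$log_alpha - log(p$alpha)) /
    sqrt(fit$part2$vcov["log_alpha", "log_alpha"])
  expect_lt(abs(za), 4)
})

test_that("model methods are coherent", {
  d <- make_cohort(4000, seed = 8)
  d <- generate_outcomes(d, seed = 8)
  fit <- hurdle_fit(n_services ~ plan_type, d)
  expect_s3_class(fit, "ztnb_hurdle")
  expect_output(print(fit), "hurdle")
  expect_output(print(summary(fit)), "alpha")
  expect_length(coef(fit, "binary"), 4)
  expect_length(coef(fit), 8)
  expect_equal(dim(vcov(fit, "count")), c(5, 5))  # 4 coefs + log_alpha
  expect_s3_class(logLik(fit), "logLik")

  pr <- predict(fit, type = "prob")
  cnt <- predict(fit, type = "count")
  expect_true(all(pr > 0 & pr < 1))
  expect_true(all(cnt >= 1))                      # truncated mean is >= 1
  expect_equal(predict(fit), pr * cnt)
  expect_equal(length(residuals(fit)), nrow(d))
  expect_lt(abs(mean(residuals(fit))), 0.02)

  nd <- data.frame(plan_type = c("coinsurance", "copay"))
  expect_length(predict(fit, nd), 2)

  set.seed(1)
  sims <- simulate(fit, nsim = 2)
  expect_equal(dim(sims), c(nrow(d), 2))
  expect_true(all((sims$sim_1 >= 1) | (sims$sim_1 == 0)))
})
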