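# Two-part hurdle model: logistic regression for whether any subsequent test
# occurs, and a zero-truncated negative binomial (NB2) for how many services
# occur among testers.  The ZTNB part is fitted directly from its
# log-likelihood (quasi-Newton on (coefficients, log alpha)) with standard
# errors from the observed information.

# log f(0; mu, alpha) and log(1 - f(0)) for NB2, in log space.
ztnb_logf0 <- function(mu, k) -k * log1p(mu / k)

ztnb_log1mf0 <- function(mu, k) {
  l0 <- ztnb_logf0(mu, k)
  log(-expm1(l0))
}

#' Zero-truncated negative binomial density
#'
#' NB2 probability mass renormalised over counts \eqn{\ge 1}:
#' \eqn{f(y; \mu, \alpha) / (1 - f(0; \mu, \alpha))}.
#'
#' @param y positive integer counts.
#' @param mu untruncated NB mean.
#' @param alpha NB2 dispersion (> 0); variance is \eqn{\mu + \alpha\mu^2}.
#' @param log return log density?
#' @export
dztnb <- function(y, mu, alpha, log = FALSE) {
  if (any(alpha <= 0)) stop_invalid("alpha must be > 0")
  if (any(y < 1)) stop_invalid("zero-truncated support is y >= 1")
  k <- 1 / alpha
  ll <- stats::dnbinom(y, size = k, mu = mu, log = TRUE) - ztnb_log1mf0(mu, k)
  if (log) ll else exp(ll)
}

#' Zero-truncated negative binomial log-likelihood
#'
#' With \eqn{\mu_i = \exp(X_i \beta)}, returns
#' \eqn{\sum_i [\log f(y_i; \mu_i, \alpha) - \log(1 - f(0; \mu_i, \alpha))]}
#' computed in log space.
#'
#' @param coefs coefficient vector \eqn{\beta}.
#' @param alpha NB2 dispersion (> 0).
#' @param y positive integer counts (an error if any is 0: the hurdle
#'   separates zeros into part 1).
#' @param X design matrix.
#' @export
ztnb_loglik <- function(coefs, alpha, y, X) {
  if (any(y < 1)) stop_invalid("invalid input: hurdle count part requires y >= 1")
  if (alpha <= 0) stop_invalid("invalid input: alpha must be > 0")
  mu <- exp(drop(X %*% coefs))
  k <- 1 / alpha
  sum(stats::dnbinom(y, size = k, mu = mu, log = TRUE) - ztnb_log1mf0(mu, k))
}

# Analytic gradient of the ZTNB log-likelihood wrt (beta, log alpha).
ztnb_grad <- function(theta, y, X) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  k <- exp(-theta[p + 1])           # k = 1/alpha
  mu <- exp(drop(X %*% beta))
  l0 <- ztnb_logf0(mu, k)
  f0r <- exp(l0 - ztnb_log1mf0(mu, k))   # f0 / (1 - f0)
  g_mu <- y / mu - (y + k) / (k + mu) - f0r * k / (k + mu)
  grad_beta <- drop(crossprod(X, mu * g_mu))
  lkr <- log(k) - log(k + mu)
  g_k <- digamma(y + k) - digamma(k) + lkr + (mu - y) / (k + mu) +
    f0r * (lkr + mu / (k + mu))
  c(grad_beta, -k * sum(g_k))
}

# Fit the ZTNB part by BFGS on (beta, log alpha) with the analytic gradient.
# Observed information comes from a central finite-difference Jacobian of the
# analytic gradient.
ztnb_fit <- function(X, y, start = NULL, reltol = 1e-12, maxit = 1000) {
  p <- ncol(X)
  if (is.null(start)) {
    b0 <- stats::glm.fit(X, y, family = stats::poisson())$coefficients
    start <- c(b0, log(0.5))
  }
  # line-search excursions can overflow the likelihood; treat them as barriers
  negll <- function(theta) {
    a <- max(exp(theta[p + 1]), 1e-12)   # alpha underflow acts as a barrier
    v <- suppressWarnings(-ztnb_loglik(theta[seq_len(p)], a, y, X))
    if (is.finite(v)) v else 1e10
  }
  neggr <- function(theta) {
    g <- suppressWarnings(-ztnb_grad(theta, y, X))
    if (all(is.finite(g))) g else rep(0, length(theta))
  }
  if (anyNA(start)) start[is.na(start)] <- 0
  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  gnorm <- sqrt(sum(ztnb_grad(opt$par, y, X)^2))
  if (gnorm > 1e-5 * (1 + abs(opt$value))) {  # polish from the first optimum
    opt2 <- stats::optim(opt$par, negll, neggr, method = "BFGS",
                         control = list(maxit = maxit, reltol = reltol))
    if (opt2$value <= opt$value) opt <- opt2
    gnorm <- sqrt(sum(ztnb_grad(opt$par, y, X)^2))
  }
  theta <- opt$par
  H <- observed_information(function(th) -ztnb_grad(th, y, X), theta)
  vc <- tryCatch(solve(H), error = function(e)
    stop_invalid(paste("observed information is singular; consider a ridge",
                       "term or a simpler design")))
  vc <- (vc + t(vc)) / 2
  nm <- c(colnames(X), "log_alpha")
  names(theta) <- nm
  dimnames(vc) <- list(nm, nm)
  list(coefficients = theta[seq_len(p)],
       alpha = exp(theta[p + 1]),
       log_alpha = theta[p + 1],
       theta = theta,
       vcov = vc,
       loglik = -opt$value,
       gradient_norm = gnorm,
       converged = opt$convergence == 0 && is.finite(gnorm) &&
         gnorm < 1e-4 * (1 + abs(opt$value)),
       iterations = opt$counts[["function"]],
       n = length(y))
}

# Central finite-difference Jacobian of a gradient function: the observed
# information when grad is the negative score.
observed_information <- function(grad_fn, theta, h = NULL) {
  p <- length(theta)
  if (is.null(h)) h <- 1e-6 * (1 + abs(theta))
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    H[, j] <- (grad_fn(tp) - grad_fn(tm)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

#' Fit a two-part hurdle model (logistic + zero-truncated negative binomial)
#'
#' Part 1 models whether the count outcome is positive with a logistic
#' regression (fitted by iteratively reweighted least squares via
#' \code{glm}) over the full sample.  Part 2 models the count among
#' positives with a zero-truncated NB2 fitted by quasi-Newton maximisation
#' of the exact truncated likelihood over \code{(coefficients, log alpha)};
#' standard errors come from the observed information.
#'
#' @param formula model formula; the left-hand side is a non-negative count.
#'   Both parts share the same right-hand side.
#' @param data data.frame containing the variables.
#' @param ... passed to \code{ztnb} internals (e.g. \code{reltol}).
#' @return object of class \code{ztnb_hurdle}.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(500))
#' d$y <- rbinom(500, 1, 0.6) * rztnb(500, exp(0.3 + 0.2 * d$x), 0.5)
#' fit <- hurdle_fit(y ~ x, d)
#' summary(fit)
#' @export
hurdle_fit <- function(formula, data, ...) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != floor(y)))
    stop_invalid("response must be a non-negative integer count")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop_invalid("design matrix is rank deficient")
  if (all(y > 0) || all(y == 0))
    stop_invalid(paste("degenerate hurdle: need both zero and positive",
                       "outcomes (all outcomes are",
                       if (all(y > 0)) "positive)" else "zero)"))

  part1 <- stats::glm.fit(X, as.integer(y > 0), family = stats::binomial())
  if (!part1$converged)
    warning("part 1 (logistic) IRLS did not converge; possible separation")
  p1 <- abs(part1$coefficients)
  if (any(is.na(p1)) || max(p1) > 30)
    stop_invalid(paste("separation suspected in part 1: a fitted logit",
                       "coefficient exceeds 30 in absolute value"))
  # observed = expected information for canonical-link logistic
  w <- part1$weights
  info1 <- crossprod(X * sqrt(w))
  vcov1 <- solve(info1)
  dimnames(vcov1) <- list(colnames(X), colnames(X))

  pos <- y > 0
  X2 <- X[pos, , drop = FALSE]
  if (qr(X2)$rank < ncol(X2)) {
    emptyc <- colnames(X2)[colSums(abs(X2)) == 0]
    stop_invalid(paste("count-part design is rank deficient among positive",
                       "outcomes%s; pool sparse factor levels before fitting"),
                 if (length(emptyc))
                   sprintf(" (no positives for: %s)",
                           paste(emptyc, collapse = ", ")) else "")
  }
  part2 <- ztnb_fit(X2, y[pos], ...)

  eta1 <- drop(X %*% part1$coefficients)
  ll1 <- sum(stats::dbinom(as.integer(y > 0), 1, stats::plogis(eta1),
                           log = TRUE))

  structure(list(call = cl,
                 formula = formula,
                 terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 part1 = list(coefficients = part1$coefficients,
                              vcov = vcov1, loglik = ll1,
                              converged = part1$converged,
                              n = length(y)),
                 part2 = part2,
                 model = mf,
                 X = X,
                 y = y,
                 n = length(y)),
            class = "ztnb_hurdle")
}

# Conditional (truncated) mean mu / (1 - f0), optionally after multiplying
# mu by a smearing factor.
ztnb_cond_mean <- function(mu, alpha, smear = 1) {
  mu2 <- mu * smear
  k <- 1 / alpha
  mu2 / (-expm1(ztnb_logf0(mu2, k)))
}

#' Duan smearing factor for the count part
#'
#' Nonparametric retransformation factor: the mean over the part-2
#' estimation sample of \eqn{y_i / \hat\mu_i}, i.e. the mean of the
#' exponentiated log-scale residuals.  Multiplying \eqn{\hat\mu} by this
#' factor corrects predictions back-transformed from the log scale for
#' residual skew.
#'
#' @param object a fitted \code{ztnb_hurdle}.
#' @export
smearing_factor <- function(object) {
  pos <- object$y > 0
  mu <- exp(drop(object$X[pos, , drop = FALSE] %*% object$part2$coefficients))
  mean(object$y[pos] / mu)
}

#' @export
print.ztnb_hurdle <- function(x, ...) {
  cat("Two-part hurdle model (logistic + zero-truncated NB2)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d (%d positive)\n", x$n, x$part2$n))
  cat("\nPart 1 (any use, logit) coefficients:\n")
  print(round(x$part1$coefficients, 4))
  cat("\nPart 2 (count among users, log link) coefficients:\n")
  print(round(x$part2$coefficients, 4))
  cat(sprintf("\nalpha (NB2 dispersion): %.4f\n", x$part2$alpha))
  cat(sprintf("logLik: %.2f (part 1) + %.2f (part 2)\n",
              x$part1$loglik, x$part2$loglik))
  invisible(x)
}

coef_table <- function(est, vc) {
  se <- sqrt(diag(vc))[names(est)]
  z <- est / se
  cbind(Estimate = est, `Std. Error` = se, `z value` = z,
        `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
}

#' @export
summary.ztnb_hurdle <- function(object, ...) {
  out <- list(call = object$call,
              part1 = coef_table(object$part1$coefficients, object$part1$vcov),
              part2 = coef_table(object$part2$coefficients, object$part2$vcov),
              alpha = object$part2$alpha,
              alpha_se = object$part2$alpha *
                sqrt(object$part2$vcov["log_alpha", "log_alpha"]),
              n = object$n, n_pos = object$part2$n,
              loglik = c(part1 = object$part1$loglik,
                         part2 = object$part2$loglik),
              converged = c(part1 = object$part1$converged,
                            part2 = object$part2$converged))
  class(out) <- "summary.ztnb_hurdle"
  out
}

#' @export
print.summary.ztnb_hurdle <- function(x, ...) {
  cat("Two-part hurdle model (logistic + zero-truncated NB2)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("\nn = %d observations, %d with positive counts\n", x$n, x$n_pos))
  cat("\nPart 1 -- logistic (any use):\n")
  stats::printCoefmat(x$part1, digits = 4)
  cat("\nPart 2 -- zero-truncated NB2 (count among users):\n")
  stats::printCoefmat(x$part2, digits = 4)
  cat(sprintf("\nalpha = %.4f (SE %.4f); logLik = %.2f + %.2f\n",
              x$alpha, x$alpha_se, x$loglik[1], x$loglik[2]))
  invisible(x)
}

#' @export
coef.ztnb_hurdle <- function(object, model = c("both", "binary", "count"), ...) {
  model <- match.arg(model)
  b1 <- object$part1$coefficients
  b2 <- object$part2$coefficients
  switch(model,
         binary = b1,
         count = b2,
         both = c(stats::setNames(b1, paste0("binary_", names(b1))),
                  stats::setNames(b2, paste0("count_", names(b2)))))
}

#' @export
vcov.ztnb_hurdle <- function(object, model = c("binary", "count"), ...) {
  model <- match.arg(model)
  if (model == "binary") object$part1$vcov else object$part2$vcov
}

#' @export
logLik.ztnb_hurdle <- function(object, ...) {
  val <- object$part1$loglik + object$part2$loglik
  attr(val, "df") <- length(object$part1$coefficients) +
    length(object$part2$coefficients) + 1
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' @rdname hurdle_fit
#' @param object a fitted \code{ztnb_hurdle}.
#' @param newdata optional data.frame; defaults to the fitting data.
#' @param type \code{"response"} (unconditional expected count,
#'   P(any) x truncated mean), \code{"prob"} (P(any use)), \code{"count"}
#'   (truncated mean among users), or \code{"mu"} (untruncated NB mean).
#' @export
predict.ztnb_hurdle <- function(object, newdata = NULL,
                                type = c("response", "prob", "count", "mu"),
                                ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else {
    mf <- stats::model.frame(stats::delete.response(object$terms), newdata,
                             xlev = object$xlevels)
    stats::model.matrix(stats::delete.response(object$terms), mf)
  }
  p <- stats::plogis(drop(X %*% object$part1$coefficients))
  mu <- exp(drop(X %*% object$part2$coefficients))
  switch(type,
         prob = p,
         mu = mu,
         count = ztnb_cond_mean(mu, object$part2$alpha),
         response = p * ztnb_cond_mean(mu, object$part2$alpha))
}

#' @export
fitted.ztnb_hurdle <- function(object, ...) predict.ztnb_hurdle(object)

#' @export
residuals.ztnb_hurdle <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  fit <- predict.ztnb_hurdle(object)
  r <- object$y - fit
  if (type == "response") return(r)
  # variance of the hurdle outcome: p * E[Y^2 | Y>=1] - (p * m)^2
  p <- predict.ztnb_hurdle(object, type = "prob")
  mu <- predict.ztnb_hurdle(object, type = "mu")
  a <- object$part2$alpha
  m <- ztnb_cond_mean(mu, a)
  ey2 <- (mu^2 * (1 + a) + mu) / (-expm1(ztnb_logf0(mu, 1 / a))) # E[Y^2|Y>=1]
  r / sqrt(pmax(p * ey2 - fit^2, .Machine$double.eps))
}

#' @export
simulate.ztnb_hurdle <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict.ztnb_hurdle(object, type = "prob")
  mu <- predict.ztnb_hurdle(object, type = "mu")
  out <- as.data.frame(replicate(nsim, {
    ind <- stats::rbinom(object$n, 1, p)
    y <- integer(object$n)
    if (any(ind == 1))
      y[ind == 1] <- rztnb(sum(ind == 1), mu[ind == 1], object$part2$alpha)
    y
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
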