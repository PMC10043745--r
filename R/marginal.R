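# Delta-method average marginal effects for the hurdle model, with optional
# Duan smearing of the count part.

# Build the design matrix with a factor variable forced to a given level.
design_at_level <- function(object, data, variable, level) {
  data[[variable]] <- factor(level, levels = object$xlevels[[variable]])
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, data, xlev = object$xlevels)
  stats::model.matrix(tt, mf)
}

#' Average marginal effects of a factor variable in a hurdle model
#'
#' For each non-reference level of \code{variable}, computes the average
#' marginal effect (AME): the mean over the estimation sample of the
#' difference in the expected number of services when every patient is
#' switched to that level versus the reference level.  By default the effect
#' is conditional on being a user — computed over the part-2 (positive
#' count) sample with the zero-truncated mean \eqn{\mu / (1 - f(0; \mu,
#' \alpha))} — matching an analysis of utilisation among patients who
#' undergo any subsequent testing.  With \code{conditional = FALSE} the
#' unconditional two-part effect \eqn{P(\mathrm{any}) \times} truncated mean
#' is averaged over the full sample instead.
#'
#' When \code{smearing = TRUE} the linear predictor is retransformed with
#' the Duan smearing factor (see \code{\link{smearing_factor}}), which is
#' held fixed in the delta-method variance.  Standard errors propagate the
#' fitted parameter covariance through the AME by the delta method
#' (numerical gradient, central differences); confidence intervals and
#' p-values use the normal reference appropriate to maximum-likelihood
#' asymptotics.
#'
#' @param object fitted \code{\link{hurdle_fit}} model.
#' @param variable name of a factor covariate (default \code{"plan_type"});
#'   its first level is the reference.
#' @param smearing apply Duan smearing (default TRUE)?
#' @param conditional part-2-only effect among users (default TRUE) or
#'   unconditional two-part effect?
#' @param level confidence level (default 0.95).
#' @return data.frame of class \code{costshare_ame}: one row per contrast
#'   with \code{estimate}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{p_value}, \code{smearing_factor}.
#' @export
marginal_effects <- function(object, variable = "plan_type", smearing = TRUE,
                             conditional = TRUE, level = 0.95) {
  if (!variable %in% names(object$xlevels))
    stop_invalid("invalid spec: '%s' is not a factor covariate of the model",
                 variable)
  if (!object$part2$converged)
    warning("count part did not converge; marginal effects may be unreliable")
  levs <- object$xlevels[[variable]]
  ref <- levs[1]
  zcrit <- stats::qnorm(1 - (1 - level) / 2)

  dat <- object$model
  if (conditional) dat <- dat[object$y > 0, , drop = FALSE]
  X_at <- lapply(stats::setNames(levs, levs), function(lv)
    design_at_level(object, dat, variable, lv))

  smear <- if (smearing) smearing_factor(object) else 1
  p2 <- length(object$part2$coefficients)
  theta2 <- object$part2$theta
  theta1 <- object$part1$coefficients

  ame_fn <- function(lv, th2, th1) {
    b <- th2[seq_len(p2)]
    a <- exp(th2[p2 + 1])
    m1 <- ztnb_cond_mean(exp(drop(X_at[[lv]] %*% b)), a, smear)
    m0 <- ztnb_cond_mean(exp(drop(X_at[[ref]] %*% b)), a, smear)
    if (conditional) return(mean(m1 - m0))
    pr1 <- stats::plogis(drop(X_at[[lv]] %*% th1))
    pr0 <- stats::plogis(drop(X_at[[ref]] %*% th1))
    mean(pr1 * m1 - pr0 * m0)
  }

  rows <- lapply(levs[-1], function(lv) {
    est <- ame_fn(lv, theta2, theta1)
    # delta method: numerical gradient over the fitted parameter vector(s)
    g2 <- vapply(seq_along(theta2), function(j) {
      h <- 1e-6 * (1 + abs(theta2[j]))
      tp <- theta2; tp[j] <- tp[j] + h
      tm <- theta2; tm[j] <- tm[j] - h
      (ame_fn(lv, tp, theta1) - ame_fn(lv, tm, theta1)) / (2 * h)
    }, numeric(1))
    v <- drop(g2 %*% object$part2$vcov %*% g2)
    if (!conditional) {
      g1 <- vapply(seq_along(theta1), function(j) {
        h <- 1e-6 * (1 + abs(theta1[j]))
        tp <- theta1; tp[j] <- tp[j] + h
        tm <- theta1; tm[j] <- tm[j] - h
        (ame_fn(lv, theta2, tp) - ame_fn(lv, theta2, tm)) / (2 * h)
      }, numeric(1))
      v <- v + drop(g1 %*% object$part1$vcov %*% g1)
    }
    se <- sqrt(v)
    data.frame(contrast = paste(lv, "vs", ref),
               level = lv,
               estimate = est, se = se,
               ci_low = est - zcrit * se, ci_high = est + zcrit * se,
               p_value = 2 * stats::pnorm(-abs(est / se)),
               smearing_factor = smear,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "variable") <- variable
  attr(out, "conditional") <- conditional
  class(out) <- c("costshare_ame", "data.frame")
  out
}

#' @export
print.costshare_ame <- function(x, digits = 4, ...) {
  cat(sprintf("Average marginal effects of %s (%s)\n",
              attr(x, "variable"),
              if (isTRUE(attr(x, "conditional")))
                "conditional on any use" else "unconditional two-part"))
  if (x$smearing_factor[1] != 1)
    cat(sprintf("Duan smearing factor: %.4f\n", x$smearing_factor[1]))
  df <- data.frame(contrast = x$contrast,
                   estimate = round(x$estimate, digits),
                   ci = sprintf("(%s to %s)",
                                formatC(x$ci_low, digits = digits, format = "f"),
                                formatC(x$ci_high, digits = digits, format = "f")),
                   p = format.pval(x$p_value, digits = 3))
  print(df, row.names = FALSE)
  invisible(x)
}
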