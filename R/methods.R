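# S3 methods for fitted recursive bivariate probit models.

#' @export
print.recprobit <- function(x, ...) {
  cat("Semiparametric recursive bivariate probit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d, log-likelihood = %.4f, total edf = %.3f%s\n",
              x$n, x$loglik, x$edf_total,
              if (x$converged) "" else "  (NOT converged)"))
  if (length(x$lambda)) {
    cat("Smoothing parameters:",
        paste(sprintf("%s = %.4g", names(x$lambda), x$lambda), collapse = ", "),
        "\n")
  }
  if (is.null(x$fix_rho)) {
    ci <- .rho_ci(x)
    cat(.format_rho(x$rho, ci), "\n")
  } else {
    cat(sprintf("rho fixed at %.3g\n", x$fix_rho))
  }
  invisible(x)
}

# delta-method CI for rho on the atanh scale, back-transformed
.rho_ci <- function(x, level = 0.95) {
  z <- atanh(x$rho)
  se <- sqrt(x$V[x$ms$iz, x$ms$iz])
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(z + c(-1, 1) * q * se)
}

.format_rho <- function(rho, ci) {
  sprintf("rho %.3g (%.3g, %.3g)", rho, ci[1], ci[2])
}

#' Summarize a fitted recursive bivariate probit
#'
#' Produces, per equation, a parametric coefficient table (estimate,
#' standard error from the posterior covariance, two-sided normal p-value)
#' and a smooth-term table (effective degrees of freedom, estimated rank,
#' Wald-type p-value from the rank-r pseudo-inverse quadratic form
#' \eqn{\hat\beta_k^T V_k^- \hat\beta_k} against a chi-square(r) reference),
#' plus the latent correlation with its delta-method interval.
#'
#' @param object a fitted \code{"recprobit"} model.
#' @param ... unused.
#' @return a list of class \code{"summary.recprobit"}.
#' @export
summary.recprobit <- function(object, ...) {
  ms <- object$ms
  th <- object$coefficients
  se <- sqrt(pmax(diag(object$V), 0))

  par_table <- function(idx, nms) {
    est <- th[idx]
    s <- se[idx]
    p <- 2 * stats::pnorm(-abs(est) / ifelse(s > 0, s, Inf))
    out <- cbind(Estimate = est, `Std. err.` = s, `P val.` = p)
    rownames(out) <- nms
    out
  }
  # parametric rows only (smooth columns excluded)
  i1p <- ms$i1[seq_len(ms$p1p)]
  i2p <- ms$i2[seq_len(ms$p2p)]
  nm1 <- sub("^eq1:", "", ms$theta_names[i1p])
  nm2 <- sub("^eq2:", "", ms$theta_names[c(ms$igam, i2p)])
  p1 <- par_table(i1p, nm1)
  p2 <- par_table(c(ms$igam, i2p), nm2)

  smooth_table <- function(eq) {
    jj <- which(ms$smooth_eq == eq)
    if (!length(jj)) return(NULL)
    out <- t(vapply(jj, function(j) {
      ii <- ms$smooth_idx[[j]]
      b <- th[ii]
      Vk <- object$V[ii, ii, drop = FALSE]
      ev <- eigen(Vk, symmetric = TRUE)
      r <- sum(ev$values > 1e-7 * max(ev$values))
      pos <- seq_len(r)
      Vinv <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
      stat <- drop(b %*% Vinv %*% b)
      c(Edf = object$edf[j], `Est. rank` = r,
        `P val.` = stats::pchisq(stat, df = r, lower.tail = FALSE))
    }, c(Edf = 0, `Est. rank` = 0, `P val.` = 0)))
    rownames(out) <- ms$smooth_lab[jj]
    out
  }

  rho_ci <- if (is.null(object$fix_rho)) .rho_ci(object) else NULL
  structure(list(
    call = object$call, n = object$n, loglik = object$loglik,
    edf_total = object$edf_total, converged = object$converged,
    lambda = object$lambda,
    p.table1 = p1, s.table1 = smooth_table(1L),
    p.table2 = p2, s.table2 = smooth_table(2L),
    rho = object$rho, rho_ci = rho_ci, fix_rho = object$fix_rho,
    ynames = ms$ynames
  ), class = "summary.recprobit")
}

#' @export
print.summary.recprobit <- function(x, digits = 4, ...) {
  cat("Semiparametric recursive bivariate probit\n")
  cat("Call: "); print(x$call)
  fmt_par <- function(tab) {
    tt <- cbind(format(round(tab[, 1:2, drop = FALSE], digits)),
                `P val.` = format.pval(tab[, 3], digits = digits, eps = 1e-4))
    print(tt, quote = FALSE, right = TRUE)
  }
  fmt_sm <- function(tab) {
    tt <- cbind(Edf = format(round(tab[, 1], 3)),
                `Est. rank` = format(as.integer(round(tab[, 2]))),
                `P val.` = format.pval(tab[, 3], digits = digits, eps = 1e-4))
    rownames(tt) <- rownames(tab)
    print(tt, quote = FALSE, right = TRUE)
  }
  cat(sprintf("\nEquation 1 (%s):\n", x$ynames[1]))
  fmt_par(x$p.table1)
  if (!is.null(x$s.table1)) { cat("Smooth terms:\n"); fmt_sm(x$s.table1) }
  cat(sprintf("\nEquation 2 (%s):\n", x$ynames[2]))
  fmt_par(x$p.table2)
  if (!is.null(x$s.table2)) { cat("Smooth terms:\n"); fmt_sm(x$s.table2) }
  cat("\n")
  if (is.null(x$fix_rho)) {
    cat(.format_rho(x$rho, x$rho_ci), "\n")
  } else {
    cat(sprintf("rho fixed at %.3g\n", x$fix_rho))
  }
  cat(sprintf("n = %d, log-likelihood = %.4f, total edf = %.3f%s\n",
              x$n, x$loglik, x$edf_total,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' Extract coefficients from a recursive bivariate probit fit
#'
#' Returns the packed parameter vector
#' \eqn{(\delta_1, \beta_1, \gamma, \delta_2, \beta_2, \mathrm{atanh}\rho)}.
#'
#' @param object a \code{"recprobit"} fit.
#' @param ... unused.
#' @export
coef.recprobit <- function(object, ...) object$coefficients

#' Posterior covariance of a recursive bivariate probit fit
#'
#' The Bayesian posterior covariance \eqn{V_\theta}: the inverse of the
#' penalized information matrix at convergence (the latent correlation
#' appears on its unconstrained \eqn{\mathrm{atanh}} scale).
#'
#' @param object a \code{"recprobit"} fit.
#' @param ... unused.
#' @export
vcov.recprobit <- function(object, ...) object$V

#' @export
logLik.recprobit <- function(object, ...) {
  structure(object$loglik, df = object$edf_total, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.recprobit <- function(object, ...) object$n

# design matrices for new data (smooths evaluated by PredictMat)
.rp_design <- function(ms, newdata) {
  X1p <- stats::model.matrix(ms$terms1, newdata)
  X2p <- stats::model.matrix(ms$terms2, newdata)
  if (ms$recursive && ms$ynames[1] %in% colnames(X2p)) {
    X2p <- X2p[, setdiff(colnames(X2p), ms$ynames[1]), drop = FALSE]
  }
  blocks <- lapply(ms$smooth_obj, function(s) mgcv::PredictMat(s, newdata))
  eq_of <- ms$smooth_eq
  B1 <- if (any(eq_of == 1)) do.call(cbind, blocks[eq_of == 1]) else NULL
  B2 <- if (any(eq_of == 2)) do.call(cbind, blocks[eq_of == 2]) else NULL
  list(X1 = cbind(X1p, B1), X2 = cbind(X2p, B2))
}

#' Predict from a recursive bivariate probit fit
#'
#' @param object a \code{"recprobit"} fit.
#' @param newdata optional data frame; defaults to the fitting data.
#' @param type \code{"link"} returns the two linear predictors,
#'   \code{"response"} the two marginal success probabilities, and
#'   \code{"joint"} the four cell probabilities.
#' @param set_treatment optionally force the treatment indicator in the
#'   outcome equation to 0 or 1 (counterfactual predictors).
#' @param ... unused.
#' @return a data frame.
#' @export
predict.recprobit <- function(object, newdata = NULL,
                              type = c("link", "response", "joint"),
                              set_treatment = NULL, ...) {
  type <- match.arg(type)
  ms <- object$ms
  if (is.null(newdata)) newdata <- ms$data
  D <- .rp_design(ms, newdata)
  th <- object$coefficients
  eta1 <- drop(D$X1 %*% th[ms$i1])
  eta2 <- drop(D$X2 %*% th[ms$i2])
  if (ms$recursive) {
    tr <- if (is.null(set_treatment)) newdata[[ms$ynames[1]]] else
      rep_len(set_treatment, nrow(newdata))
    eta2 <- eta2 + th[ms$igam] * tr
  }
  switch(type,
    link = data.frame(eta1 = eta1, eta2 = eta2),
    response = data.frame(p1 = stats::pnorm(eta1), p2 = stats::pnorm(eta2)),
    joint = as.data.frame(joint_probs(eta1, eta2, object$rho,
                                      object$control$floor_p)))
}

#' Simulate responses from a fitted recursive bivariate probit
#'
#' Draws new outcome pairs at the observed covariates from the fitted
#' latent-Gaussian system (treatment drawn first, then the outcome given the
#' drawn treatment, with correlated errors).
#'
#' @param object a \code{"recprobit"} fit.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data frame of \code{nsim} pairs of columns.
#' @export
simulate.recprobit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ms <- object$ms
  th <- object$coefficients
  rho <- object$rho
  eta1 <- drop(ms$X1 %*% th[ms$i1])
  eta2b <- drop(ms$X2 %*% th[ms$i2])
  gam <- if (ms$recursive) th[ms$igam] else 0
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    z1 <- stats::rnorm(ms$n)
    z2 <- stats::rnorm(ms$n)
    e1 <- z1
    e2 <- rho * z1 + sqrt(1 - rho^2) * z2
    y1 <- as.integer(eta1 + e1 > 0)
    y2 <- as.integer(gam * y1 + eta2b + e2 > 0)
    out[[s]] <- stats::setNames(data.frame(y1, y2),
                                paste0(ms$ynames, "_", s))
  }
  do.call(cbind, out)
}

#' @export
residuals.recprobit <- function(object, ...) {
  pr <- predict.recprobit(object, type = "response")
  data.frame(r1 = object$ms$y1 - pr$p1, r2 = object$ms$y2 - pr$p2)
}

#' Plot fitted smooth terms with Bayesian credible bands
#'
#' @param x a \code{"recprobit"} fit with at least one smooth term.
#' @param n_grid grid size for curve evaluation.
#' @param ... passed to [graphics::plot()].
#' @export
plot.recprobit <- function(x, n_grid = 200, ...) {
  ms <- x$ms
  if (!length(ms$smooth_idx)) {
    stop("the model has no smooth terms to plot")
  }
  for (j in seq_along(ms$smooth_idx)) {
    sm <- ms$smooth_obj[[j]]
    ii <- ms$smooth_idx[[j]]
    xv <- ms$data[[sm$term]]
    grid <- seq(min(xv), max(xv), length.out = n_grid)
    nd <- stats::setNames(data.frame(grid), sm$term)
    Xg <- mgcv::PredictMat(sm, nd)
    f <- drop(Xg %*% x$coefficients[ii])
    se <- sqrt(pmax(rowSums((Xg %*% x$V[ii, ii]) * Xg), 0))
    graphics::plot(grid, f, type = "l",
                   xlab = sm$term,
                   ylab = sprintf("%s (edf %.2f)", sm$label, x$edf[j]), ...)
    graphics::lines(grid, f + 2 * se, lty = 2)
    graphics::lines(grid, f - 2 * se, lty = 2)
    graphics::rug(xv)
  }
  invisible(x)
}
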