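# Average treatment effect estimators and the tetrachoric correlation.

#' Average treatment effect from a recursive bivariate probit fit
#'
#' The primary estimate is the model's ATE expression computed exactly as
#' reported with the fitted joint distribution,
#' \deqn{\widehat{\mathrm{ATE}} = \frac{1}{n}\sum_i\left[
#'   \frac{\Phi_2(\hat\eta_{2i}(y_1{=}1), \hat\eta_{1i}; \hat\rho)}
#'        {\Phi(\hat\eta_{1i})} -
#'   \frac{\Phi_2(\hat\eta_{2i}(y_1{=}0), -\hat\eta_{1i}; -\hat\rho)}
#'        {1 - \Phi(\hat\eta_{1i})}\right],}
#' whose two terms are the fitted conditional probabilities
#' \eqn{P(y_2{=}1 \mid y_1{=}1, x_i)} and \eqn{P(y_2{=}1 \mid y_1{=}0,
#' x_i)}. Because the terms condition on the realized treatment, this
#' average conditional contrast differs from the counterfactual
#' (potential-outcome) average
#' \eqn{n^{-1}\sum_i[\Phi(\hat\eta_{2i}(1)) - \Phi(\hat\eta_{2i}(0))]}
#' whenever \eqn{\hat\rho \ne 0}; the latter is also computed and returned
#' as \code{estimate_po}. Both intervals come from the delta method through
#' the posterior covariance \eqn{V_\theta}, with analytic gradients.
#'
#' @param object a recursive \code{"recprobit"} fit (the treatment must
#'   enter the outcome equation).
#' @param level confidence level.
#' @param ... unused.
#' @return an object of class \code{"rp_ate"} with fields \code{estimate},
#'   \code{ci}, \code{se}, \code{estimate_po}, \code{ci_po}, \code{se_po},
#'   \code{method = "SBP"} and \code{scale = "probability difference"}.
#' @export
ate <- function(object, ...) UseMethod("ate")

#' @rdname ate
#' @export
ate.recprobit <- function(object, level = 0.95, ...) {
  ms <- object$ms
  if (!ms$recursive) {
    stop("the fitted model has no endogenous treatment in the outcome equation")
  }
  th <- object$coefficients
  rho <- object$rho
  eps <- object$control$floor_p
  n <- ms$n

  b <- drop(ms$X1 %*% th[ms$i1])             # eta1
  cc <- drop(ms$X2 %*% th[ms$i2])            # eta2 with treatment 0
  a <- cc + th[ms$igam]                      # eta2 with treatment 1
  Pb <- stats::pnorm(b)
  if (any(Pb < eps) || any(Pb > 1 - eps)) {
    warning("some treatment-propensity probabilities were numerically 0 or 1 and were floored")
    Pb <- pmin(pmax(Pb, eps), 1 - eps)
  }

  T1 <- pbinorm(a, b, rho) / Pb
  T2 <- pbinorm(cc, -b, -rho) / (1 - Pb)
  est <- mean(T1 - T2)

  # analytic delta-method gradient through theta
  s <- sqrt(1 - rho^2)
  phi_b <- stats::dnorm(b)
  dT1_da <- .dPhi2_dh(a, b, rho) / Pb
  dT1_db <- (.dPhi2_dh(b, a, rho) * Pb - pbinorm(a, b, rho) * phi_b) / Pb^2
  dT1_dr <- dbinorm(a, b, rho) / Pb
  dT2_dc <- .dPhi2_dh(cc, -b, -rho) / (1 - Pb)
  dT2_db <- (-phi_b * stats::pnorm((cc - rho * b) / s) * (1 - Pb) +
               pbinorm(cc, -b, -rho) * phi_b) / (1 - Pb)^2
  dT2_dr <- -dbinorm(cc, -b, -rho) / (1 - Pb)

  g <- numeric(ms$np)
  g[ms$i1] <- drop(crossprod(ms$X1, dT1_db - dT2_db)) / n
  g[ms$igam] <- sum(dT1_da) / n
  g[ms$i2] <- drop(crossprod(ms$X2, dT1_da - dT2_dc)) / n
  if (ms$free_z) g[ms$iz] <- sum(dT1_dr - dT2_dr) * (1 - rho^2) / n
  se <- sqrt(pmax(drop(g %*% object$V %*% g), 0))

  # counterfactual (potential-outcome) average
  est_po <- mean(stats::pnorm(a) - stats::pnorm(cc))
  gp <- numeric(ms$np)
  da <- stats::dnorm(a); dc <- stats::dnorm(cc)
  gp[ms$igam] <- sum(da) / n
  gp[ms$i2] <- drop(crossprod(ms$X2, da - dc)) / n
  se_po <- sqrt(pmax(drop(gp %*% object$V %*% gp), 0))

  q <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    estimate = est, se = se, ci = est + c(-1, 1) * q * se,
    estimate_po = est_po, se_po = se_po,
    ci_po = est_po + c(-1, 1) * q * se_po,
    gradient = g, gradient_po = gp,
    method = "SBP", level = level, n = n,
    scale = "probability difference"
  ), class = "rp_ate")
}

#' @export
print.rp_ate <- function(x, digits = 4, percent = FALSE, ...) {
  f <- if (percent) 100 else 1
  unit <- if (percent) " (percentage points)" else ""
  cat(sprintf("ATE [%s]%s: %.*g  (%.*g, %.*g)\n", x$method, unit,
              digits, f * x$estimate, digits, f * x$ci[1], digits, f * x$ci[2]))
  if (!is.null(x$estimate_po)) {
    cat(sprintf("  potential-outcome average: %.*g  (%.*g, %.*g)\n",
                digits, f * x$estimate_po, digits, f * x$ci_po[1],
                digits, f * x$ci_po[2]))
  }
  invisible(x)
}

#' Additive-probit (AP) comparison estimator of the ATE
#'
#' Fits the outcome equation alone as a univariate additive probit (the
#' treatment enters as an ordinary regressor; smooths allowed), i.e. a
#' model that adjusts for observed confounders but ignores unobserved ones,
#' and averages \eqn{\Phi(\hat\eta(1)) - \Phi(\hat\eta(0))} over subjects.
#' The interval is a delta-method interval through the fit's Bayesian
#' covariance.
#'
#' @param formula outcome-equation formula including the treatment variable
#'   as a linear term (smooths via \code{s()} are allowed).
#' @param data a data frame.
#' @param treatment name of the binary treatment column.
#' @param level confidence level.
#' @return an object of class \code{"rp_ate"} with \code{method = "AP"}.
#' @export
ate_probit <- function(formula, data, treatment, level = 0.95) {
  if (!treatment %in% all.vars(formula)) {
    stop(sprintf("treatment '%s' does not appear in the formula", treatment))
  }
  bad <- setdiff(unique(data[[treatment]]), c(0, 1))
  if (length(bad)) stop(sprintf("treatment '%s' must be coded {0, 1}", treatment))
  fit <- mgcv::gam(formula, data = data,
                   family = stats::binomial(link = "probit"), method = "GCV.Cp")
  d1 <- data; d1[[treatment]] <- 1
  d0 <- data; d0[[treatment]] <- 0
  X1 <- stats::predict(fit, newdata = d1, type = "lpmatrix")
  X0 <- stats::predict(fit, newdata = d0, type = "lpmatrix")
  e1 <- drop(X1 %*% stats::coef(fit))
  e0 <- drop(X0 %*% stats::coef(fit))
  est <- mean(stats::pnorm(e1) - stats::pnorm(e0))
  n <- nrow(data)
  g <- drop(crossprod(X1, stats::dnorm(e1)) - crossprod(X0, stats::dnorm(e0))) / n
  se <- sqrt(pmax(drop(g %*% stats::vcov(fit) %*% g), 0))
  q <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = est, se = se, ci = est + c(-1, 1) * q * se,
                 estimate_po = NULL, method = "AP", level = level, n = n,
                 scale = "probability difference", fit = fit),
            class = "rp_ate")
}

#' Unadjusted risk-difference estimator of the ATE
#'
#' \eqn{\bar y_2\mid(y_1{=}1) - \bar y_2\mid(y_1{=}0)} with a Wald interval
#' from the two binomial variances; ignores observed and unobserved
#' confounders alike.
#'
#' @param y1 binary treatment vector.
#' @param y2 binary outcome vector.
#' @param level confidence level.
#' @return an object of class \code{"rp_ate"} with
#'   \code{method = "unadjusted"}.
#' @export
ate_unadjusted <- function(y1, y2, level = 0.95) {
  if (length(y1) != length(y2)) stop("'y1' and 'y2' must have equal length")
  if (length(setdiff(unique(c(y1, y2)), c(0, 1)))) {
    stop("'y1' and 'y2' must be coded {0, 1}")
  }
  n1 <- sum(y1 == 1); n0 <- sum(y1 == 0)
  if (n1 == 0 || n0 == 0) stop("both treatment groups must be nonempty")
  p1 <- mean(y2[y1 == 1]); p0 <- mean(y2[y1 == 0])
  est <- p1 - p0
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  q <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(estimate = est, se = se, ci = est + c(-1, 1) * q * se,
                 estimate_po = NULL, method = "unadjusted", level = level,
                 n = n1 + n0, scale = "probability difference"),
            class = "rp_ate")
}

#' Three-estimator ATE comparison table
#'
#' Computes the model-based (SBP), additive-probit (AP) and unadjusted ATE
#' estimates on the data underlying a fit, in the layout of the case-study
#' report (one row per estimator with its interval).
#'
#' @param object a recursive \code{"recprobit"} fit.
#' @param level confidence level.
#' @param percent if \code{TRUE}, report in percentage points.
#' @return a data frame with columns \code{method}, \code{estimate},
#'   \code{ci_low}, \code{ci_high}.
#' @export
ate_table <- function(object, level = 0.95, percent = FALSE) {
  ms <- object$ms
  sbp <- ate(object, level = level)
  # AP: the outcome formula with the treatment as an ordinary regressor
  ap <- ate_probit(ms$formula[[2]], ms$data, treatment = ms$ynames[1],
                   level = level)
  un <- ate_unadjusted(ms$y1, ms$y2, level = level)
  f <- if (percent) 100 else 1
  data.frame(method = c("SBP", "AP", "unadjusted"),
             estimate = f * c(sbp$estimate, ap$estimate, un$estimate),
             ci_low = f * c(sbp$ci[1], ap$ci[1], un$ci[1]),
             ci_high = f * c(sbp$ci[2], ap$ci[2], un$ci[2]))
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood estimate of the latent correlation of two dichotomized
#' standard normal variables: thresholds are fixed at the normal quantiles
#' of the margins (their joint MLE) and \eqn{\rho} solves
#' \eqn{\Phi_2(h, k; \rho) = p_{11}}. This equals the latent correlation of
#' an intercept-only, non-recursive bivariate probit fitted to the same
#' table. The interval is a delta-method interval on the
#' \eqn{\mathrm{atanh}} scale from the observed information of the
#' three-parameter threshold model.
#'
#' @param tab a 2x2 matrix of counts with \code{tab[1,1]} the count of both
#'   indicators equal to 1 and \code{tab[2,2]} both 0, or a length-4 vector
#'   \code{c(n11, n10, n01, n00)}.
#' @param level confidence level.
#' @return a list of class \code{"rp_tetrachoric"} with \code{rho},
#'   \code{se}, \code{ci}, \code{n}.
#' @examples
#' tetrachoric(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
#' @export
tetrachoric <- function(tab, level = 0.95) {
  if (is.matrix(tab) || is.table(tab)) {
    if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be 2x2")
    cnt <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  } else if (length(tab) == 4L) {
    cnt <- as.numeric(tab)
  } else {
    stop("'tab' must be a 2x2 matrix or a length-4 count vector")
  }
  if (any(cnt < 0)) stop("counts must be nonnegative")
  n <- sum(cnt)
  n11 <- cnt[1]; n10 <- cnt[2]; n01 <- cnt[3]; n00 <- cnt[4]
  if ((n11 + n10) == 0 || (n01 + n00) == 0 ||
      (n11 + n01) == 0 || (n10 + n00) == 0) {
    stop("all margins of the 2x2 table must be positive")
  }
  p1 <- (n11 + n10) / n
  p2 <- (n11 + n01) / n
  h <- stats::qnorm(p1)
  k <- stats::qnorm(p2)
  target <- n11 / n
  f <- function(r) pbinorm(h, k, r) - target
  lo <- -1 + 1e-9; hi <- 1 - 1e-9
  if (f(lo) > 0 || f(hi) < 0) {
    stop("the observed table lies on the boundary; the tetrachoric correlation is not identified away from +/-1")
  }
  rho <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root

  # observed information of the (h, k, z) threshold model
  ll <- function(par) {
    p11 <- pbinorm(par[1], par[2], tanh(par[3]))
    P1 <- stats::pnorm(par[1]); P2 <- stats::pnorm(par[2])
    p <- pmax(c(p11, P1 - p11, P2 - p11, 1 - P1 - P2 + p11), 1e-12)
    sum(cnt * log(p))
  }
  par <- c(h, k, atanh(rho))
  Hm <- matrix(0, 3, 3)
  step <- 1e-4
  for (i in 1:3) for (j in 1:3) {
    ei <- ej <- numeric(3); ei[i] <- step * (1 + abs(par[i]))
    ej[j] <- step * (1 + abs(par[j]))
    Hm[i, j] <- (ll(par + ei + ej) - ll(par + ei - ej) -
                   ll(par - ei + ej) + ll(par - ei - ej)) /
      (4 * ei[i] * ej[j])
  }
  V <- solve(-(Hm + t(Hm)) / 2)
  se_z <- sqrt(max(V[3, 3], 0))
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- tanh(atanh(rho) + c(-1, 1) * q * se_z)
  structure(list(rho = rho, se = (1 - rho^2) * se_z, ci = ci, n = n,
                 level = level),
            class = "rp_tetrachoric")
}

#' @export
print.rp_tetrachoric <- function(x, digits = 4, ...) {
  cat(sprintf("tetrachoric correlation: %.*g  (%.*g, %.*g), n = %d\n",
              digits, x$rho, digits, x$ci[1], digits, x$ci[2], x$n))
  invisible(x)
}
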