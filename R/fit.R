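# Penalized maximum likelihood fitting.
#
# Nested scheme: the inner loop maximizes the penalized log-likelihood at
# fixed smoothing parameters by Newton iteration (analytic gradient, Hessian
# by central finite differences of the gradient, ridge fallback when not
# negative definite, step-halving line search so accepted steps are monotone
# ascent). The outer loop selects each smoothing parameter by minimizing a
# deviance-based approximate unbiased risk estimator,
#   UBRE(lambda) = D/n - 1 + 2 edf_total / n,   D = -2 l(theta_hat_lambda),
# over a log-spaced grid followed by golden-section refinement, cycling over
# smooths. Interval inference uses V = (penalized information)^{-1} at
# convergence, the Bayesian posterior covariance of a penalized fit.

#' Control options for [recprobit()]
#'
#' @param inner_tol convergence tolerance: the inner Newton loop stops when
#'   the gradient infinity-norm is below \code{inner_tol * (1 + |l_p|)}.
#' @param max_inner maximum Newton iterations per inner fit.
#' @param max_halving maximum step halvings per Newton step.
#' @param lambda_grid log-spaced candidate smoothing parameters for the
#'   coarse outer search.
#' @param outer_cycles number of coordinate cycles over smooths when more
#'   than one smoothing parameter is selected.
#' @param golden_tol absolute tolerance of the golden-section refinement on
#'   the log10 smoothing-parameter scale.
#' @param floor_p probability floor applied to the four outcome-cell
#'   probabilities before taking logs.
#' @return a list of class \code{"rp_control"}.
#' @export
rp_control <- function(inner_tol = 1e-6, max_inner = 100L, max_halving = 30L,
                       lambda_grid = 10^seq(-4, 9, by = 1),
                       outer_cycles = 2L, golden_tol = 0.1,
                       floor_p = 1e-10) {
  stopifnot(inner_tol > 0, max_inner >= 1, max_halving >= 1,
            length(lambda_grid) >= 2, all(lambda_grid > 0),
            golden_tol > 0, floor_p > 0)
  structure(list(inner_tol = inner_tol, max_inner = as.integer(max_inner),
                 max_halving = as.integer(max_halving),
                 lambda_grid = sort(lambda_grid),
                 outer_cycles = as.integer(outer_cycles),
                 golden_tol = golden_tol, floor_p = floor_p),
            class = "rp_control")
}

# starting values: two univariate probits (eq 2 includes the treatment),
# rho_z = 0; ridge-stabilized Newton fallback under separation
.rp_init <- function(ms) {
  probit_start <- function(X, y, eq) {
    sep <- FALSE
    co <- withCallingHandlers(
      tryCatch(
        stats::glm.fit(X, y, family = stats::binomial("probit"),
                       control = stats::glm.control(epsilon = 1e-10,
                                                    maxit = 100))$coefficients,
        error = function(e) rep(NA_real_, ncol(X))),
      warning = function(w) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || anyNA(co) || any(!is.finite(co))) {
      warning(sprintf(
        "possible separation in the univariate probit start for equation %d; using ridge-stabilized starting values", eq))
      co <- .ridge_probit(X, y)
    }
    co
  }
  X2full <- if (ms$recursive) cbind(ms$treat, ms$X2) else ms$X2
  c1 <- probit_start(ms$X1, ms$y1, 1L)
  c2 <- probit_start(X2full, ms$y2, 2L)
  theta <- numeric(ms$np)
  theta[ms$i1] <- c1
  if (ms$recursive) {
    theta[ms$igam] <- c2[1]
    theta[ms$i2] <- c2[-1]
  } else {
    theta[ms$i2] <- c2
  }
  if (ms$free_z) theta[ms$iz] <- 0
  theta
}

# small ridge-penalized probit Newton, start fallback only
.ridge_probit <- function(X, y, ridge = 1e-2, iter = 25L) {
  b <- numeric(ncol(X))
  b[1] <- stats::qnorm(min(max(mean(y), 0.02), 0.98))
  for (it in seq_len(iter)) {
    eta <- drop(X %*% b)
    p <- pmin(pmax(stats::pnorm(eta), 1e-8), 1 - 1e-8)
    ph <- stats::dnorm(eta)
    g <- drop(crossprod(X, ph * (y - p) / (p * (1 - p)))) - ridge * b
    W <- ph^2 / (p * (1 - p))
    H <- crossprod(X * sqrt(W)) + diag(ridge, ncol(X))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(g)) < 1e-8) break
  }
  b
}

# inner maximization of the penalized log-likelihood at fixed penalty:
# Newton iteration with the exact observed Hessian, ridge fallback when the
# penalized information is not positive definite, and step-halving so that
# accepted steps are monotone ascent
.rp_newton <- function(theta, ms, Spen, ctrl) {
  pll <- .rp_pll(theta, ms, Spen, ctrl$floor_p)
  g <- .rp_grad(theta, ms, Spen, ctrl$floor_p)
  trace <- pll
  converged <- FALSE
  it <- 0L
  A <- NULL
  while (it < ctrl$max_inner) {
    if (any(!is.finite(g)) || !is.finite(pll)) break
    if (max(abs(g)) <= ctrl$inner_tol * (1 + abs(pll))) {
      converged <- TRUE
      break
    }
    it <- it + 1L
    A <- -.rp_hessian_analytic(theta, ms, Spen, ctrl$floor_p)
    tau <- 0
    repeat {
      ch <- tryCatch(chol(A + diag(tau, nrow(A))), error = function(e) NULL)
      if (!is.null(ch)) break
      tau <- if (tau == 0) 1e-6 * max(1, abs(diag(A))) else tau * 10
      if (tau > 1e12 * max(1, abs(diag(A)))) {
        stop("penalized information is numerically singular; consider a stronger penalty or a simpler specification")
      }
    }
    dir <- backsolve(ch, forwardsolve(t(ch), g))
    step <- 1
    improved <- FALSE
    for (hlv in seq_len(ctrl$max_halving)) {
      cand <- theta + step * dir
      # boundary safeguard: |rho| <= 1 - 1.2e-5 keeps the information finite
      if (ms$free_z) cand[ms$iz] <- max(min(cand[ms$iz], 6), -6)
      pll_new <- .rp_pll(cand, ms, Spen, ctrl$floor_p)
      if (is.finite(pll_new) && pll_new > pll - 1e-10 * (1 + abs(pll))) {
        improved <- pll_new >= pll
        theta <- cand
        pll <- pll_new
        break
      }
      step <- step / 2
    }
    if (!improved && step < 1) {
      # no ascent possible along the Newton direction: at numerical optimum
      g <- .rp_grad(theta, ms, Spen, ctrl$floor_p)
      converged <- max(abs(g)) <= ctrl$inner_tol * (1 + abs(pll)) * 10
      break
    }
    g <- .rp_grad(theta, ms, Spen, ctrl$floor_p)
    trace <- c(trace, pll)
  }
  if (it == ctrl$max_inner && max(abs(g)) <= ctrl$inner_tol * (1 + abs(pll))) {
    converged <- TRUE
  }
  list(theta = theta, pll = pll, grad = g, iter = it,
       converged = converged, trace = trace)
}

# UBRE and total edf at a converged inner fit; A = penalized information
.rp_ubre <- function(theta, ms, Spen, A, floor_p) {
  ll <- .rp_loglik(theta, ms, floor_p)
  edf <- ms$np - sum(diag(solve(A, Spen)))
  n <- ms$n
  list(ubre = -2 * ll / n - 1 + 2 * edf / n, edf_total = edf, loglik = ll)
}

#' Fit a semiparametric recursive bivariate probit model
#'
#' Fits the two-equation latent-Gaussian model
#' \deqn{y_{1i}^* = \tilde{x}_{1i}^T\delta_1 + \textstyle\sum_k s_{1k}(x_{1ki})
#'   + \epsilon_{1i}, \qquad
#'   y_{2i}^* = \gamma y_{1i} + \tilde{x}_{2i}^T\delta_2 +
#'   \textstyle\sum_k s_{2k}(x_{2ki}) + \epsilon_{2i},}
#' with \eqn{y_{vi} = 1\{y_{vi}^* > 0\}} and latent errors that are standard
#' bivariate normal with correlation \eqn{\rho}, by penalized maximum
#' likelihood. The first formula is the treatment equation; its response,
#' when it appears on the right-hand side of the second (outcome) formula,
#' is the endogenous treatment whose coefficient is \eqn{\gamma}. Omitting
#' it fits the non-recursive (seemingly unrelated) bivariate probit. Smooth
#' terms are specified with \code{s(x, k = )} and represented by centered
#' cubic regression splines with a second-order roughness penalty; their
#' smoothing parameters are selected by minimizing an approximate unbiased
#' risk estimator unless \code{lambda} fixes them.
#'
#' \eqn{\rho} is estimated on the unconstrained scale \eqn{z =
#' \mathrm{atanh}(\rho)}; its confidence interval is computed by the delta
#' method on that scale and back-transformed. Interval inference for all
#' terms uses the Bayesian posterior covariance \eqn{V_\theta}, the inverse
#' of the penalized information matrix at convergence.
#'
#' @param formula a list of two formulas: treatment equation, then outcome
#'   equation.
#' @param data a data frame; rows with missing values in model variables are
#'   dropped with a message.
#' @param lambda optional fixed smoothing parameters (one per smooth term,
#'   in equation order); \code{NULL} selects them by UBRE.
#' @param fix_rho optional fixed value for the latent correlation (e.g.
#'   \code{0} for an exogeneity-constrained fit); \code{NULL} estimates it.
#' @param control a [rp_control()] list.
#' @param start optional starting vector for the packed parameters; defaults
#'   to two univariate probit fits with \eqn{z = 0}.
#' @return an object of class \code{"recprobit"}; see
#'   [summary.recprobit()], [coef.recprobit()], [vcov.recprobit()],
#'   [predict.recprobit()], [ate()].
#' @examples
#' d <- simulate_stemi(stemi_config(n = 400, seed = 3))
#' fit <- recprobit(list(STres ~ access + age, mortality ~ STres + killip + EF),
#'                  data = d)
#' summary(fit)
#' @export
recprobit <- function(formula, data, lambda = NULL, fix_rho = NULL,
                      control = rp_control(), start = NULL) {
  cl <- match.call()
  if (!inherits(control, "rp_control")) stop("'control' must come from rp_control()")
  if (!is.null(fix_rho) && (length(fix_rho) != 1L || abs(fix_rho) >= 1)) {
    stop("'fix_rho' must be a single value in (-1, 1)")
  }
  ms <- .rp_structure(formula, data, fix_rho = fix_rho)
  nsm <- length(ms$smooth_idx)

  # exclusion-restriction advisory (identification by functional form only)
  if (ms$recursive) {
    v1 <- setdiff(all.vars(stats::delete.response(stats::terms(ms$formula[[1]]))),
                  ms$ynames)
    v2 <- setdiff(all.vars(stats::delete.response(stats::terms(ms$formula[[2]]))),
                  ms$ynames)
    if (length(v1) && all(v1 %in% v2)) {
      warning("the treatment equation contains no covariate excluded from the outcome equation; identification relies on functional form alone")
    }
  }

  theta <- if (is.null(start)) .rp_init(ms) else {
    if (length(start) != ms$np) stop("'start' has the wrong length")
    start
  }
  init <- theta

  if (!is.null(lambda)) {
    if (length(lambda) != nsm) stop("need one 'lambda' per smooth term")
    if (any(lambda < 0)) stop("smoothing parameters must be nonnegative")
  }

  fit_at <- function(lams, th) .rp_newton(th, ms, .rp_Spen(ms, lams), ctrl = control)

  if (nsm == 0L || !is.null(lambda)) {
    lambdas <- if (nsm) lambda else numeric(0)
    inner <- fit_at(lambdas, theta)
  } else {
    lambdas <- rep(1, nsm)
    inner <- fit_at(lambdas, theta)
    ubre_of <- function(lam_j, j, th) {
      lams <- lambdas; lams[j] <- lam_j
      Spen_j <- .rp_Spen(ms, lams)
      f <- .rp_newton(th, ms, Spen_j, control)
      A <- -.rp_hessian_analytic(f$theta, ms, Spen_j, control$floor_p)
      u <- .rp_ubre(f$theta, ms, Spen_j, A, control$floor_p)
      list(ubre = u$ubre, fit = f)
    }
    cycles <- if (nsm > 1L) control$outer_cycles else 1L
    for (cy in seq_len(cycles)) {
      for (j in seq_len(nsm)) {
        grid <- control$lambda_grid
        # coarse pass, warm-starting each candidate from its neighbour
        vals <- numeric(length(grid))
        fits <- vector("list", length(grid))
        th <- inner$theta
        for (gi in seq_along(grid)) {
          r <- ubre_of(grid[gi], j, th)
          vals[gi] <- r$ubre
          fits[[gi]] <- r$fit
          th <- r$fit$theta
        }
        ib <- which.min(vals)
        best <- list(ubre = vals[ib], fit = fits[[ib]], lam = grid[ib])
        lo <- log10(grid[max(ib - 1L, 1L)])
        hi <- log10(grid[min(ib + 1L, length(grid))])
        # golden-section refinement on log10 lambda
        take <- function(lam) {
          r <- ubre_of(lam, j, best$fit$theta)
          if (r$ubre < best$ubre) best <<- list(ubre = r$ubre, fit = r$fit, lam = lam)
          r$ubre
        }
        gr <- (sqrt(5) - 1) / 2
        x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
        f1 <- take(10^x1); f2 <- take(10^x2)
        while ((hi - lo) > control$golden_tol) {
          if (f1 <= f2) {
            hi <- x2; x2 <- x1; f2 <- f1
            x1 <- hi - gr * (hi - lo); f1 <- take(10^x1)
          } else {
            lo <- x1; x1 <- x2; f1 <- f2
            x2 <- lo + gr * (hi - lo); f2 <- take(10^x2)
          }
        }
        lambdas[j] <- best$lam
        inner <- best$fit
      }
    }
  }

  Spen <- .rp_Spen(ms, lambdas)
  A <- -.rp_hessian_analytic(inner$theta, ms, Spen, control$floor_p)
  V <- tryCatch(solve(A), error = function(e) {
    stop("penalized information is singular at convergence; consider a stronger penalty or a simpler specification")
  })
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values)))) {
    warning("posterior covariance had negative eigenvalues; clipped at zero")
    V <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    V <- (V + t(V)) / 2
  }
  dimnames(V) <- list(ms$theta_names, ms$theta_names)

  # per-smooth effective degrees of freedom: tr of (unpenalized information
  # times V) restricted to the smooth's coefficients
  Iu <- A - Spen
  Fdiag <- diag(V %*% Iu)
  edf <- vapply(ms$smooth_idx, function(ii) sum(Fdiag[ii]), 0)
  if (length(edf)) names(edf) <- paste0("eq", ms$smooth_eq, ":", ms$smooth_lab)
  u <- .rp_ubre(inner$theta, ms, Spen, A, control$floor_p)

  theta_hat <- stats::setNames(inner$theta, ms$theta_names)
  rho_hat <- .rp_rho(inner$theta, ms)

  structure(list(
    coefficients = theta_hat,
    rho = rho_hat,
    fix_rho = fix_rho,
    V = V,
    lambda = stats::setNames(lambdas, names(edf)),
    edf = edf,
    edf_total = u$edf_total,
    loglik = u$loglik,
    ploglik = inner$pll,
    deviance = -2 * u$loglik,
    ubre = u$ubre,
    converged = inner$converged,
    iter = inner$iter,
    grad_norm = max(abs(inner$grad)),
    pll_trace = inner$trace,
    init = stats::setNames(init, ms$theta_names),
    n = ms$n,
    n_dropped = ms$n_dropped,
    ms = ms,
    control = control,
    call = cl
  ), class = "recprobit")
}
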