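# Model structure and likelihood of the recursive bivariate probit.
#
# Latent system:
#   y1* = eta1 + e1,  eta1 = X1 delta1 + sum_k s_1k(x_1k)
#   y2* = eta2 + e2,  eta2 = gamma y1 + X2 delta2 + sum_k s_2k(x_2k)
# with (e1, e2) standard bivariate normal with correlation rho and
# y_v = 1{y_v* > 0}.  The four cells have probabilities
#   p11 = Phi2(eta1, eta2; rho),  p10 = Phi(eta1) - p11,
#   p01 = Phi(eta2) - p11,        p00 = 1 - p11 - p10 - p01.
# The parameter vector is packed as theta = (delta1, beta1, gamma, delta2,
# beta2, z) with rho = tanh(z) so optimization is unconstrained.

# ---- model structure ------------------------------------------------------

# Parse the two model formulas, validate the data, build design matrices.
# Smooths default to cubic regression splines ("cr"); mgcv's default thin
# plate spec is coerced to cr (univariate smooths only).
.rp_structure <- function(formula, data, fix_rho = NULL) {
  if (!is.list(formula) || length(formula) != 2L ||
      !all(vapply(formula, inherits, TRUE, "formula"))) {
    stop("'formula' must be a list of two formulas: treatment equation first, outcome equation second")
  }
  ig <- lapply(formula, mgcv::interpret.gam)
  ynames <- vapply(ig, function(g) g$response, "")
  if (anyNA(ynames) || any(ynames == "")) stop("both formulas need a response")

  used <- unique(c(unlist(lapply(ig, function(g) all.vars(g$fake.formula)))))
  miss <- setdiff(used, names(data))
  if (length(miss)) {
    stop("variables not found in 'data': ", paste(miss, collapse = ", "))
  }
  cc <- stats::complete.cases(data[used])
  n_drop <- sum(!cc)
  if (n_drop > 0) {
    message(sprintf("dropped %d row(s) with missing values in model variables", n_drop))
    data <- data[cc, , drop = FALSE]
  }

  y1 <- data[[ynames[1]]]
  y2 <- data[[ynames[2]]]
  for (v in 1:2) {
    y <- if (v == 1) y1 else y2
    bad <- setdiff(unique(y), c(0, 1))
    if (length(bad)) {
      stop(sprintf("outcome '%s' must be coded {0, 1}; found: %s",
                   ynames[v], paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)

  build_eq <- function(g, drop_term = NULL) {
    tt <- stats::delete.response(stats::terms(g$pf))
    X <- stats::model.matrix(tt, data)
    has_treat <- FALSE
    if (!is.null(drop_term) && drop_term %in% colnames(X)) {
      X <- X[, setdiff(colnames(X), drop_term), drop = FALSE]
      has_treat <- TRUE
    }
    sms <- lapply(g$smooth.spec, function(spec) {
      if (spec$dim != 1L) {
        stop("only univariate smooth terms are supported (term ", spec$label, ")")
      }
      if (inherits(spec, "tp.smooth.spec")) class(spec) <- "cr.smooth.spec"
      # the default penalty rescaling keeps lambda ranges comparable across
      # covariate scales; the penalty stays proportional to the integrated
      # squared second derivative, so only the units of lambda change
      mgcv::smoothCon(spec, data = data, absorb.cons = TRUE)[[1]]
    })
    list(X = X, smooths = sms, has_treat = has_treat, terms = tt)
  }

  eq1 <- build_eq(ig[[1]])
  eq2 <- build_eq(ig[[2]], drop_term = ynames[1])
  recursive <- eq2$has_treat

  sm_block <- function(eq) {
    if (!length(eq$smooths)) {
      return(list(X = NULL, S = list(), labels = character(0)))
    }
    Xs <- lapply(eq$smooths, function(s) {
      colnames(s$X) <- paste0(s$label, ".", seq_len(ncol(s$X)))
      s$X
    })
    list(X = do.call(cbind, Xs),
         S = lapply(eq$smooths, function(s) s$S[[1]]),
         labels = vapply(eq$smooths, function(s) s$label, ""))
  }
  b1 <- sm_block(eq1); b2 <- sm_block(eq2)

  X1 <- cbind(eq1$X, b1$X)
  X2 <- cbind(eq2$X, b2$X)
  for (eqi in list(list(X1, 1), list(X2, 2))) {
    qrX <- qr(eqi[[1]])
    if (qrX$rank < ncol(eqi[[1]])) {
      dep <- colnames(eqi[[1]])[qrX$pivot[-seq_len(qrX$rank)]]
      stop(sprintf("model matrix of equation %d is rank deficient; collinear column(s): %s",
                   eqi[[2]], paste(dep, collapse = ", ")))
    }
  }

  p1p <- ncol(eq1$X); p1s <- if (is.null(b1$X)) 0L else ncol(b1$X)
  p2p <- ncol(eq2$X); p2s <- if (is.null(b2$X)) 0L else ncol(b2$X)
  free_z <- is.null(fix_rho)
  p1 <- p1p + p1s
  p2 <- p2p + p2s
  np <- p1 + recursive + p2 + free_z

  i1 <- seq_len(p1)
  igam <- if (recursive) p1 + 1L else integer(0)
  i2 <- p1 + recursive + seq_len(p2)
  iz <- if (free_z) np else integer(0)

  # theta-index blocks of each smooth, and labels
  sm_idx <- list(); sm_lab <- character(0); sm_eq <- integer(0); Slist <- list()
  off <- p1p
  for (j in seq_along(b1$S)) {
    d <- ncol(b1$S[[j]])
    sm_idx[[length(sm_idx) + 1L]] <- off + seq_len(d)
    sm_lab <- c(sm_lab, b1$labels[j]); sm_eq <- c(sm_eq, 1L)
    Slist[[length(Slist) + 1L]] <- b1$S[[j]]
    off <- off + d
  }
  off <- p1 + recursive + p2p
  for (j in seq_along(b2$S)) {
    d <- ncol(b2$S[[j]])
    sm_idx[[length(sm_idx) + 1L]] <- off + seq_len(d)
    sm_lab <- c(sm_lab, b2$labels[j]); sm_eq <- c(sm_eq, 2L)
    Slist[[length(Slist) + 1L]] <- b2$S[[j]]
    off <- off + d
  }

  nms <- c(paste0("eq1:", colnames(X1)),
           if (recursive) paste0("eq2:", ynames[1]),
           paste0("eq2:", colnames(X2)),
           if (free_z) "atanh(rho)")

  list(y1 = y1, y2 = y2, X1 = X1, X2 = X2, treat = y1,
       recursive = recursive, free_z = free_z,
       fix_rho = if (free_z) NULL else fix_rho,
       i1 = i1, igam = igam, i2 = i2, iz = iz,
       p1p = p1p, p2p = p2p, np = np, n = length(y1),
       smooth_idx = sm_idx, smooth_lab = sm_lab, smooth_eq = sm_eq,
       smooth_S = Slist,
       smooth_obj = c(eq1$smooths, eq2$smooths),
       terms1 = eq1$terms, terms2 = eq2$terms,
       ynames = ynames, theta_names = nms,
       formula = formula, data = data, n_dropped = n_drop)
}

.rp_rho <- function(theta, ms) {
  if (ms$free_z) tanh(theta[ms$iz]) else ms$fix_rho
}

.rp_eta <- function(theta, ms) {
  eta1 <- drop(ms$X1 %*% theta[ms$i1])
  eta2 <- drop(ms$X2 %*% theta[ms$i2])
  if (ms$recursive) eta2 <- eta2 + theta[ms$igam] * ms$treat
  list(eta1 = eta1, eta2 = eta2)
}

# block-diagonal penalty matrix sum_k lambda_k S_k embedded in theta space
.rp_Spen <- function(ms, lambdas) {
  S <- matrix(0, ms$np, ms$np)
  if (length(ms$smooth_idx)) {
    if (length(lambdas) != length(ms$smooth_idx)) {
      stop("need one smoothing parameter per smooth term")
    }
    if (any(lambdas < 0)) stop("smoothing parameters must be nonnegative")
    for (j in seq_along(ms$smooth_idx)) {
      ii <- ms$smooth_idx[[j]]
      S[ii, ii] <- S[ii, ii] + lambdas[j] * ms$smooth_S[[j]]
    }
  }
  S
}

# ---- probabilities and likelihood ----------------------------------------

#' Joint cell probabilities of a bivariate probit
#'
#' Computes the probabilities of the four outcome cells
#' \eqn{(y_1, y_2) \in \{1,0\}^2} from the two linear predictors and the
#' latent correlation: \eqn{p_{11} = \Phi_2(\eta_1, \eta_2; \rho)},
#' \eqn{p_{10} = \Phi(\eta_1) - p_{11}}, \eqn{p_{01} = \Phi(\eta_2) - p_{11}},
#' \eqn{p_{00} = 1 - p_{11} - p_{10} - p_{01}}. Cells are floored at
#' \code{floor_p} and renormalized to sum to one, which only matters at
#' pathologically extreme predictors.
#'
#' @param eta1,eta2 numeric vectors of linear predictors.
#' @param rho scalar latent correlation.
#' @param floor_p probability floor (default \code{1e-10}).
#' @return a list with vectors \code{p11}, \code{p10}, \code{p01}, \code{p00}.
#' @examples
#' joint_probs(0, 0, 0.5)   # (1/3, 1/6, 1/6, 1/3)
#' @export
joint_probs <- function(eta1, eta2, rho, floor_p = 1e-10) {
  if (!all(is.finite(eta1)) || !all(is.finite(eta2))) {
    stop("linear predictors must be finite")
  }
  p11 <- pbinorm(eta1, eta2, rho)
  P1 <- stats::pnorm(eta1)
  P2 <- stats::pnorm(eta2)
  p10 <- P1 - p11
  p01 <- P2 - p11
  p00 <- 1 - P1 - P2 + p11
  m <- cbind(p11, p10, p01, p00)
  m[m < floor_p] <- floor_p
  m <- m / rowSums(m)
  list(p11 = unname(m[, 1]), p10 = unname(m[, 2]),
       p01 = unname(m[, 3]), p00 = unname(m[, 4]))
}

# unpenalized log-likelihood
.rp_loglik <- function(theta, ms, floor_p = 1e-10) {
  eta <- .rp_eta(theta, ms)
  p <- joint_probs(eta$eta1, eta$eta2, .rp_rho(theta, ms), floor_p)
  sum(ms$y1 * ms$y2 * log(p$p11) +
      ms$y1 * (1 - ms$y2) * log(p$p10) +
      (1 - ms$y1) * ms$y2 * log(p$p01) +
      (1 - ms$y1) * (1 - ms$y2) * log(p$p00))
}

# penalized log-likelihood  l(theta) - 0.5 beta' S_lambda beta
.rp_pll <- function(theta, ms, Spen, floor_p = 1e-10) {
  .rp_loglik(theta, ms, floor_p) - 0.5 * drop(theta %*% Spen %*% theta)
}

# analytic gradient of the penalized log-likelihood w.r.t. packed theta
.rp_grad <- function(theta, ms, Spen, floor_p = 1e-10) {
  eta <- .rp_eta(theta, ms)
  rho <- .rp_rho(theta, ms)
  p <- joint_probs(eta$eta1, eta$eta2, rho, floor_p)
  y1 <- ms$y1; y2 <- ms$y2

  s <- sqrt(max(1 - rho^2, 1e-16))
  d11_1 <- stats::dnorm(eta$eta1) * stats::pnorm((eta$eta2 - rho * eta$eta1) / s)
  d11_2 <- stats::dnorm(eta$eta2) * stats::pnorm((eta$eta1 - rho * eta$eta2) / s)
  phi1 <- stats::dnorm(eta$eta1)
  phi2v <- stats::dnorm(eta$eta2)
  dens <- dbinorm(eta$eta1, eta$eta2, rho)

  pc <- y1 * y2 * p$p11 + y1 * (1 - y2) * p$p10 +
    (1 - y1) * y2 * p$p01 + (1 - y1) * (1 - y2) * p$p00

  num1 <- y1 * y2 * d11_1 + y1 * (1 - y2) * (phi1 - d11_1) -
    (1 - y1) * y2 * d11_1 + (1 - y1) * (1 - y2) * (d11_1 - phi1)
  num2 <- y1 * y2 * d11_2 - y1 * (1 - y2) * d11_2 +
    (1 - y1) * y2 * (phi2v - d11_2) + (1 - y1) * (1 - y2) * (d11_2 - phi2v)
  sgn <- y1 * y2 - y1 * (1 - y2) - (1 - y1) * y2 + (1 - y1) * (1 - y2)

  w1 <- num1 / pc
  w2 <- num2 / pc
  wr <- dens * sgn / pc

  g <- numeric(ms$np)
  g[ms$i1] <- drop(crossprod(ms$X1, w1))
  if (ms$recursive) g[ms$igam] <- sum(w2 * ms$treat)
  g[ms$i2] <- drop(crossprod(ms$X2, w2))
  if (ms$free_z) g[ms$iz] <- sum(wr) * (1 - rho^2)
  g - drop(Spen %*% theta)
}

# exact observed Hessian of the penalized log-likelihood.
#
# Every second derivative of Phi2 reduces to closed forms in the bivariate
# density: with w1 = (eta2 - rho eta1)/s, s = sqrt(1 - rho^2),
#   d2Phi2/dh2    = -h dPhi2/dh - rho phi2(h,k;rho)
#   d2Phi2/dh dk  =  phi2(h,k;rho)
#   d2Phi2/dh drho= -phi2 (h - rho k)/s^2
#   d2Phi2/drho2  =  phi2 [rho s^2 + h k s^2 - rho Q]/s^4,  Q = h^2-2rho hk+k^2,
# using phi(h) phi((k - rho h)/s)/s = phi2(h,k;rho). The per-observation
# Hessian of log p_cell in (eta1, eta2, rho) is Hp/p - gp gp'/p^2, chained
# through rho = tanh(z), then assembled over the design matrices.
.rp_hessian_analytic <- function(theta, ms, Spen, floor_p = 1e-10) {
  eta <- .rp_eta(theta, ms)
  rho <- .rp_rho(theta, ms)
  e1 <- eta$eta1; e2 <- eta$eta2
  y1 <- ms$y1; y2 <- ms$y2
  p <- joint_probs(e1, e2, rho, floor_p)
  s2 <- max(1 - rho^2, 1e-16)
  s <- sqrt(s2)
  phi1 <- stats::dnorm(e1)
  phi2v <- stats::dnorm(e2)
  d11_1 <- phi1 * stats::pnorm((e2 - rho * e1) / s)
  d11_2 <- phi2v * stats::pnorm((e1 - rho * e2) / s)
  dens <- dbinorm(e1, e2, rho)
  Q <- e1^2 - 2 * rho * e1 * e2 + e2^2

  # second derivatives of p11
  B_hh <- -e1 * d11_1 - rho * dens
  B_kk <- -e2 * d11_2 - rho * dens
  B_hk <- dens
  B_hr <- -dens * (e1 - rho * e2) / s2
  B_kr <- -dens * (e2 - rho * e1) / s2
  B_rr <- dens * (rho * s2 + e1 * e2 * s2 - rho * Q) / s2^2

  # observed-cell probability, gradient and Hessian pieces
  i11 <- y1 * y2; i10 <- y1 * (1 - y2); i01 <- (1 - y1) * y2
  i00 <- (1 - y1) * (1 - y2)
  pc <- i11 * p$p11 + i10 * p$p10 + i01 * p$p01 + i00 * p$p00
  sgn <- i11 - i10 - i01 + i00
  g1 <- i11 * d11_1 + i10 * (phi1 - d11_1) - i01 * d11_1 + i00 * (d11_1 - phi1)
  g2 <- i11 * d11_2 - i10 * d11_2 + i01 * (phi2v - d11_2) + i00 * (d11_2 - phi2v)
  gr <- sgn * dens
  # cell-by-cell assembly (marginal curvature enters cells 10, 01, 00)
  h11 <- i11 * B_hh + i10 * (-e1 * phi1 - B_hh) + i01 * (-B_hh) +
    i00 * (e1 * phi1 + B_hh)
  h22 <- i11 * B_kk + i10 * (-B_kk) + i01 * (-e2 * phi2v - B_kk) +
    i00 * (e2 * phi2v + B_kk)
  h12 <- sgn * B_hk
  h1r <- sgn * B_hr
  h2r <- sgn * B_kr
  hrr <- sgn * B_rr

  a11 <- h11 / pc - (g1 / pc)^2
  a22 <- h22 / pc - (g2 / pc)^2
  a12 <- h12 / pc - g1 * g2 / pc^2
  a1r <- h1r / pc - g1 * gr / pc^2
  a2r <- h2r / pc - g2 * gr / pc^2
  arr <- hrr / pc - (gr / pc)^2
  # chain rho = tanh(z): drho/dz = 1 - rho^2
  a1z <- a1r * s2
  a2z <- a2r * s2
  azz <- arr * s2^2 - 2 * rho * s2 * (gr / pc)

  Xg2 <- if (ms$recursive) cbind(ms$treat, ms$X2) else ms$X2
  ii2 <- c(ms$igam, ms$i2)
  H <- matrix(0, ms$np, ms$np)
  H[ms$i1, ms$i1] <- crossprod(ms$X1, a11 * ms$X1)
  H[ms$i1, ii2] <- crossprod(ms$X1, a12 * Xg2)
  H[ii2, ms$i1] <- t(H[ms$i1, ii2])
  H[ii2, ii2] <- crossprod(Xg2, a22 * Xg2)
  if (ms$free_z) {
    H[ms$i1, ms$iz] <- drop(crossprod(ms$X1, a1z))
    H[ms$iz, ms$i1] <- H[ms$i1, ms$iz]
    H[ii2, ms$iz] <- drop(crossprod(Xg2, a2z))
    H[ms$iz, ii2] <- H[ii2, ms$iz]
    H[ms$iz, ms$iz] <- sum(azz)
  }
  H - Spen
}

# central finite-difference Hessian of the analytic gradient (symmetrized)
.rp_hessian <- function(theta, ms, Spen, step = 1e-4) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- step * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (.rp_grad(tp, ms, Spen) - .rp_grad(tm, ms, Spen)) / (2 * h)
  }
  (H + t(H)) / 2
}
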