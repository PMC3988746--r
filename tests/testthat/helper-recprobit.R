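# Shared fixtures and small oracles, all built in code at test time.

# case-study model formulas
fml_stemi <- list(STres ~ access + age + s(O2B, k = 10),
                  mortality ~ STres + killip + EF)
fml_stemi_nosmooth <- list(STres ~ access + age + O2B,
                           mortality ~ STres + killip + EF)

# independent 1-D conditioning-integral oracle for the bivariate normal CDF:
# P(Z1 <= h, Z2 <= k) = int_{-inf}^{h} phi(x) Phi((k - rho x)/s) dx
bvn_oracle <- function(h, k, rho) {
  stats::integrate(function(x) stats::dnorm(x) *
                     stats::pnorm((k - rho * x) / sqrt(1 - rho^2)),
                   -Inf, h, rel.tol = 1e-13, abs.tol = 1e-15)$value
}

# central finite difference of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    hj <- h * (1 + abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    (f(xp) - f(xm)) / (2 * hj)
  }, 0)
}

# a random parameter vector scaled to the design columns, so the linear
# predictors stay in a sane probit range on raw covariates like age or O2B
scaled_theta <- function(ms, sd = 0.3) {
  sc <- c(apply(abs(ms$X1), 2, max),
          if (ms$recursive) 1,
          apply(abs(ms$X2), 2, max),
          if (ms$free_z) 1)
  rnorm(ms$np, 0, sd) / pmax(sc, 1e-8)
}

# expand a 2x2 count table (n11, n10, n01, n00) into a two-column data frame
table_to_data <- function(cnt) {
  data.frame(
    y1 = rep(c(1, 1, 0, 0), cnt),
    y2 = rep(c(1, 0, 1, 0), cnt)
  )
}

# brute-force profile-likelihood grid search for the tetrachoric correlation
# (thresholds fixed at the normal quantiles of the margins)
tetrachoric_grid <- function(cnt, step = 1e-5) {
  n <- sum(cnt)
  h <- stats::qnorm((cnt[1] + cnt[2]) / n)
  k <- stats::qnorm((cnt[1] + cnt[3]) / n)
  ll_at <- function(r) {
    p11 <- pbinorm(h, k, r)
    p <- pmax(c(p11, stats::pnorm(h) - p11, stats::pnorm(k) - p11,
                1 - stats::pnorm(h) - stats::pnorm(k) + p11), 1e-12)
    sum(cnt * log(p))
  }
  coarse <- seq(-0.999, 0.999, by = 1e-3)
  v <- vapply(coarse, ll_at, 0)
  r0 <- coarse[which.max(v)]
  fine <- seq(max(-0.999, r0 - 2e-3), min(0.999, r0 + 2e-3), by = step)
  v <- vapply(fine, ll_at, 0)
  fine[which.max(v)]
}
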