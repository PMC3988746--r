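# Internal likelihood machinery accessed via ::: — these are the numerical
# contracts the fitter relies on.

toy_structure <- function(n = 60, seed = 31, smooth = TRUE, fix_rho = NULL) {
  d <- simulate_stemi(stemi_config(n = n, seed = seed))
  fml <- if (smooth) list(STres ~ access + age + s(O2B, k = 8),
                          mortality ~ STres + killip + EF)
         else fml_stemi_nosmooth
  recprobit:::.rp_structure(fml, d, fix_rho = fix_rho)
}

test_that("joint_probs matches closed forms and always sums to one", {
  p <- joint_probs(0, 0, 0)
  expect_equal(unlist(p), c(p11 = 0.25, p10 = 0.25, p01 = 0.25, p00 = 0.25),
               tolerance = 1e-12)
  p <- joint_probs(0, 0, 0.5)
  expect_equal(unlist(p), c(p11 = 1/3, p10 = 1/6, p01 = 1/6, p00 = 1/3),
               tolerance = 1e-9)
  set.seed(32)
  e1 <- rnorm(50, 0, 3); e2 <- rnorm(50, 0, 3)
  for (r in c(-0.8, 0, 0.6)) {
    p <- joint_probs(e1, e2, r)
    expect_lt(max(abs(p$p11 + p$p10 + p$p01 + p$p00 - 1)), 1e-12)
    expect_true(all(unlist(p) >= 0))
  }
  expect_error(joint_probs(NA, 0, 0.2), "finite")
})

test_that("log-likelihood matches per-observation oracle and factorizes at rho = 0", {
  # single observation, both outcomes 1, eta = 0, rho = 0
  d1 <- data.frame(y1 = 1, y2 = 1)
  ms1 <- recprobit:::.rp_structure(list(y1 ~ 1, y2 ~ 1), d1)
  expect_equal(recprobit:::.rp_loglik(c(0, 0, 0), ms1), log(0.25),
               tolerance = 1e-12)

  # 4-row toy data covering every cell: direct cell-by-cell summation
  d4 <- data.frame(y1 = c(1, 1, 0, 0), y2 = c(1, 0, 1, 0),
                   x = c(0.5, -1, 2, 0))
  ms4 <- recprobit:::.rp_structure(list(y1 ~ x, y2 ~ y1 + x), d4)
  th <- c(0.2, -0.3, 0.4, -0.1, 0.25, atanh(0.3))
  eta1 <- 0.2 - 0.3 * d4$x
  eta2 <- 0.4 * d4$y1 - 0.1 + 0.25 * d4$x
  p11 <- pbinorm(eta1, eta2, 0.3)
  cellp <- c(p11[1], pnorm(eta1[2]) - p11[2], pnorm(eta2[3]) - p11[3],
             1 - pnorm(eta1[4]) - pnorm(eta2[4]) + p11[4])
  expect_equal(recprobit:::.rp_loglik(th, ms4), sum(log(cellp)),
               tolerance = 1e-12)

  # rho = 0: joint log-likelihood equals the sum of two univariate probits
  ms <- toy_structure(n = 80, smooth = FALSE)
  set.seed(33)
  th <- scaled_theta(ms)
  th[ms$iz] <- 0
  eta <- recprobit:::.rp_eta(th, ms)
  uni <- sum(dbinom(ms$y1, 1, pnorm(eta$eta1), log = TRUE)) +
    sum(dbinom(ms$y2, 1, pnorm(eta$eta2), log = TRUE))
  expect_equal(recprobit:::.rp_loglik(th, ms), uni, tolerance = 1e-10)
})

test_that("log-likelihood is invariant to reordering of observations", {
  ms <- toy_structure(n = 50)
  set.seed(34)
  th <- scaled_theta(ms)
  ll1 <- recprobit:::.rp_loglik(th, ms)
  d <- simulate_stemi(stemi_config(n = 50, seed = 31))
  d2 <- d[sample(nrow(d)), ]
  ms2 <- recprobit:::.rp_structure(list(STres ~ access + age + s(O2B, k = 8),
                                        mortality ~ STres + killip + EF), d2)
  expect_equal(recprobit:::.rp_loglik(th, ms2), ll1, tolerance = 1e-9)
})

test_that("penalty enters the penalized log-likelihood as the block quadratic form", {
  ms <- toy_structure(n = 70)
  set.seed(35)
  th <- scaled_theta(ms, sd = 0.4)
  lam <- c(3.7)
  Spen <- recprobit:::.rp_Spen(ms, lam)
  # zero lambda and zero beta both reduce to the unpenalized value
  expect_identical(recprobit:::.rp_pll(th, ms, recprobit:::.rp_Spen(ms, 0)),
                   recprobit:::.rp_loglik(th, ms))
  th0 <- th; th0[ms$smooth_idx[[1]]] <- 0
  expect_identical(recprobit:::.rp_pll(th0, ms, Spen),
                   recprobit:::.rp_loglik(th0, ms))
  # independently assembled dense quadratic form
  beta <- th[ms$smooth_idx[[1]]]
  expect_equal(recprobit:::.rp_pll(th, ms, Spen),
               recprobit:::.rp_loglik(th, ms) -
                 0.5 * lam * drop(beta %*% ms$smooth_S[[1]] %*% beta),
               tolerance = 1e-12)
  # penalty Hessian contribution is negative semidefinite (concavity in beta)
  ev <- eigen(Spen, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
  expect_error(recprobit:::.rp_Spen(ms, -1), "nonnegative")
})

test_that("analytic gradient matches finite differences, including the rho chain", {
  ms <- toy_structure(n = 50)
  Spen <- recprobit:::.rp_Spen(ms, 2)
  set.seed(36)
  for (rep in 1:3) {
    th <- scaled_theta(ms)
    g <- recprobit:::.rp_grad(th, ms, Spen)
    gfd <- fd_grad(function(t) recprobit:::.rp_pll(t, ms, Spen), th)
    expect_lt(max(abs(g - gfd)) / max(1, max(abs(gfd))), 1e-7)
  }
  # rho derivative at rho = 0 for a single observation with eta1 = eta2 = 0
  d1 <- data.frame(y1 = 1, y2 = 1)
  ms1 <- recprobit:::.rp_structure(list(y1 ~ 1, y2 ~ 1), d1)
  S0 <- recprobit:::.rp_Spen(ms1, numeric(0))
  th1 <- c(0, 0, 0)
  g <- recprobit:::.rp_grad(th1, ms1, S0)
  gfd <- fd_grad(function(t) recprobit:::.rp_pll(t, ms1, S0), th1)
  expect_equal(g[ms1$iz], gfd[ms1$iz], tolerance = 1e-8)
  # closed form: d log p11 / d z at 0 is phi2(0,0;0)/p11 = (1/2pi)/(1/4)
  expect_equal(g[ms1$iz], (1 / (2 * pi)) / 0.25, tolerance = 1e-10)
})

test_that("analytic Hessian matches finite differences of the gradient", {
  ms <- toy_structure(n = 60)
  Spen <- recprobit:::.rp_Spen(ms, 1.5)
  set.seed(37)
  th <- scaled_theta(ms)
  for (r in c(-0.6, 0, 0.85)) {
    th[ms$iz] <- atanh(r)
    Ha <- recprobit:::.rp_hessian_analytic(th, ms, Spen)
    Hf <- recprobit:::.rp_hessian(th, ms, Spen, 1e-5)
    expect_lt(max(abs(Ha - Hf)) / max(abs(Ha)), 1e-6)
  }
})

test_that("outcome coding and rank deficiency are validated", {
  d <- simulate_stemi(stemi_config(n = 60, seed = 38))
  d$bad <- d$STres; d$bad[1] <- 2
  expect_error(
    recprobit:::.rp_structure(list(bad ~ access, mortality ~ bad + EF), d),
    "coded \\{0, 1\\}.*2")
  d$age2 <- d$age
  expect_error(
    recprobit:::.rp_structure(list(STres ~ age + age2,
                                   mortality ~ STres + EF), d),
    "age2")
})
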