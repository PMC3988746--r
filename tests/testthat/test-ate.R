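# Treatment-effect estimators and the tetrachoric correlation.

test_that("the model ATE factorizes at rho = 0 and vanishes without a treatment effect", {
  d <- simulate_stemi(stemi_config(n = 800, seed = 61))
  fit0 <- recprobit(fml_stemi_nosmooth, d, fix_rho = 0)
  a0 <- ate(fit0)
  # with rho = 0 the conditional contrast and the counterfactual average
  # are the same expression
  expect_equal(a0$estimate, a0$estimate_po, tolerance = 1e-10)

  # zero treatment coefficient: the counterfactual average is exactly zero,
  # and at rho = 0 so is the conditional contrast
  fit <- recprobit(fml_stemi_nosmooth, d)
  fitz <- fit
  fitz$coefficients[fit$ms$igam] <- 0
  az <- ate(fitz)
  expect_identical(az$estimate_po, 0)
  fitz0 <- fit0
  fitz0$coefficients[fit0$ms$igam] <- 0
  expect_equal(ate(fitz0)$estimate, 0, tolerance = 1e-12)

  expect_true(az$ci[1] <= az$estimate && az$estimate <= az$ci[2])
  expect_lte(abs(az$estimate), 1)
})

test_that("delta-method gradients of both ATE forms match finite differences", {
  # informative design (common outcome) so rho is interior and the fit
  # converges; boundary fits are exercised elsewhere
  d <- simulate_stemi(stemi_config(n = 800, outcome_intercept = 3, seed = 62))
  fit <- recprobit(fml_stemi_nosmooth, d)
  expect_true(fit$converged)
  expect_lt(abs(fit$rho), 0.95)
  a <- ate(fit)
  est_at <- function(th, what) {
    f <- fit
    f$coefficients <- th
    f$rho <- tanh(th[fit$ms$iz])
    ai <- ate(f)
    if (what == "eq5") ai$estimate else ai$estimate_po
  }
  g_fd <- fd_grad(function(t) est_at(t, "eq5"), coef(fit))
  expect_lt(max(abs(a$gradient - g_fd)) / max(1, max(abs(g_fd))), 1e-6)
  gp_fd <- fd_grad(function(t) est_at(t, "po"), coef(fit))
  expect_lt(max(abs(a$gradient_po - gp_fd)) / max(1, max(abs(gp_fd))), 1e-6)
})

test_that("the counterfactual ATE recovers the generator truth over replicates", {
  res <- t(vapply(1:20, function(r) {
    d <- simulate_stemi(stemi_config(n = 1500, seed = 63000 + r))
    f <- recprobit(fml_stemi_nosmooth, d)
    c(ate(f)$estimate_po, attr(d, "true_ate"))
  }, c(0, 0)))
  mc_se <- sd(res[, 1]) / sqrt(nrow(res))
  expect_lt(abs(mean(res[, 1]) - mean(res[, 2])), 3 * mc_se)
})

test_that("the additive probit estimator nests the unadjusted risk difference", {
  d <- simulate_stemi(stemi_config(n = 1200, gamma = 0, rho = 0, seed = 64))
  ap <- ate_probit(mortality ~ STres, d, treatment = "STres")
  un <- ate_unadjusted(d$STres, d$mortality)
  expect_equal(ap$estimate, un$estimate, tolerance = 1e-8)
  # with gamma = 0 truth and no confounding, AP is centred at zero
  ap2 <- ate_probit(mortality ~ STres + killip + EF, d, treatment = "STres")
  expect_lt(abs(ap2$estimate), 3 * ap2$se)
})

test_that("the unadjusted estimator is the plain risk difference", {
  y1 <- rep(c(1, 0), c(100, 100))
  y2 <- c(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(40, 60)))
  un <- ate_unadjusted(y1, y2)
  expect_equal(un$estimate, -0.10, tolerance = 1e-12)
  # identical proportions give exactly zero
  expect_identical(ate_unadjusted(rep(0:1, 50), rep(0:1, 50) * 0)$estimate, 0)
  # saturated-model equivalence: intercept + treatment probit
  g <- glm(y2 ~ y1, binomial("probit"))
  probit_ate <- pnorm(sum(coef(g))) - pnorm(coef(g)[1])
  expect_equal(un$estimate, unname(probit_ate), tolerance = 1e-8)
  expect_error(ate_unadjusted(rep(1, 10), rep(0:1, 5)), "nonempty")
})

test_that("unobserved confounding biases the naive estimators but not the joint model", {
  # strong latent correlation, no true effect: one illustrative replicate
  d <- simulate_stemi(stemi_config(n = 3000, gamma = 0, rho = 0.7, seed = 65))
  un <- ate_unadjusted(d$STres, d$mortality)
  expect_gt(abs(un$estimate), 3 * un$se)
  fit <- recprobit(fml_stemi, d)
  g <- coef(fit)[fit$ms$igam]
  se_g <- sqrt(vcov(fit)[fit$ms$igam, fit$ms$igam])
  expect_lt(abs(g), qnorm(0.975) * se_g * 1.5)
})

test_that("tetrachoric estimation matches its oracles and symmetries", {
  # independence: cell proportions equal to the product of the margins
  expect_lt(abs(tetrachoric(c(300, 300, 200, 200))$rho), 1e-6)

  # brute-force profile-likelihood grid oracle
  for (cnt in list(c(40, 10, 10, 40), c(25, 15, 20, 40), c(55, 20, 35, 30))) {
    tt <- tetrachoric(cnt)
    expect_equal(tt$rho, tetrachoric_grid(cnt), tolerance = 1e-4)
  }

  m <- matrix(c(40, 10, 10, 40), 2, byrow = TRUE)
  t0 <- tetrachoric(m)
  # swapping both labels leaves the estimate unchanged
  expect_equal(tetrachoric(m[2:1, 2:1])$rho, t0$rho, tolerance = 1e-10)
  # swapping one label negates it
  expect_equal(tetrachoric(m[2:1, ])$rho, -t0$rho, tolerance = 1e-10)
  expect_error(tetrachoric(c(0, 0, 10, 40)), "margins")
  expect_error(tetrachoric(matrix(1, 3, 3)), "2x2")
})

test_that("tetrachoric equals the intercept-only non-recursive fit", {
  cnt <- c(40, 10, 10, 40)
  d <- table_to_data(cnt)
  fit <- recprobit(list(y1 ~ 1, y2 ~ 1), d)
  expect_equal(fit$rho, tetrachoric(cnt)$rho, tolerance = 1e-4)
  expect_false(fit$ms$recursive)
})

test_that("ate_table reports the three estimators in layout order", {
  d <- simulate_stemi(stemi_config(n = 600, seed = 66))
  fit <- recprobit(fml_stemi_nosmooth, d)
  tab <- ate_table(fit)
  expect_identical(tab$method, c("SBP", "AP", "unadjusted"))
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  tab100 <- ate_table(fit, percent = TRUE)
  expect_equal(tab100$estimate, 100 * tab$estimate)
  # non-recursive fits have no treatment effect to report
  fit_nr <- recprobit(list(STres ~ access, mortality ~ killip), d)
  expect_error(ate(fit_nr), "endogenous treatment")
})
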