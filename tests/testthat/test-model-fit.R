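test_that("log-likelihood matches closed forms and the oracle", {
  p <- ntcp_params(1, 1)
  # y = 1 wherever p = 0.5: four patients at D = D50
  expect_equal(ntcp_loglik(rep(1, 4), rep(1, 4), p), 4 * log(0.5),
               tolerance = 1e-12)
  expect_error(ntcp_loglik(numeric(0), integer(0), p), "empty")
  expect_error(ntcp_loglik(c(1, 2), c(1), p), "mismatch")
  expect_error(ntcp_loglik(c(1, 2), c(1, 2), p), "binary")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    D <- rlnorm(n, 0, 0.6)
    y <- rbinom(n, 1, 0.5)
    d50 <- runif(1, 0.3, 3); g <- runif(1, 0.1, 4)
    expect_equal(ntcp_loglik(D, y, ntcp_params(d50, g)),
                 oracle_loglik(D, y, d50, g), tolerance = 1e-10)
  }
})

test_that("fit recovers generating parameters on a large cohort", {
  set.seed(11)
  co <- make_test_cohort(n = 6000, seed = 11)
  truth <- ntcp_params(1, 1)
  y <- simulate_outcomes(ntcp(co$D_gt, truth))$labels
  f <- fit_ntcp(co$D_gt, y)
  expect_true(f$converged)
  expect_lt(abs(coef(f)["D50"] - 1), 0.06)
  expect_lt(abs(coef(f)["gamma"] - 1), 0.06)
  # log-likelihood at the optimum beats the truth by construction
  expect_gte(f$logLik, ntcp_loglik(co$D_gt, y, truth) - 1e-8)
})

test_that("fit agrees with the exhaustive grid-search oracle", {
  set.seed(5)
  for (rep in 1:10) {
    co <- make_test_cohort(n = 50, seed = 100 + rep)
    y <- simulate_outcomes(ntcp(co$D_gt, ntcp_params(1, 1)))$labels
    if (all(y == y[1])) next
    f <- fit_ntcp(co$D_gt, y)
    g <- oracle_grid_fit(co$D_gt, y)
    # only comparable when the oracle's window contains the optimum interior
    if (g$D50 > 0.5 + g$step_D50 && g$D50 < 1.5 - g$step_D50 &&
        g$gamma < 3 - g$step_gamma) {
      expect_lt(abs(coef(f)["D50"] - g$D50), g$step_D50 * 1.5)
      expect_lt(abs(coef(f)["gamma"] - g$gamma), g$step_gamma * 1.5)
      expect_gte(f$logLik, g$ll - 1e-6)
    }
  }
})

test_that("agreement with logistic regression on non-separated data", {
  # the logistic NTCP MLE is a reparameterized logistic GLM:
  # slope = s, intercept = -s * D50, hence gamma = -intercept / 4
  set.seed(21)
  co <- make_test_cohort(n = 800, seed = 21)
  y <- simulate_outcomes(ntcp(co$D_gt, ntcp_params(1, 0.8)))$labels
  f <- fit_ntcp(co$D_gt, y)
  g <- glm(y ~ D, data = data.frame(D = co$D_gt, y = y), family = binomial)
  expect_equal(unname(coef(f)["s"]), unname(coef(g)[2]), tolerance = 1e-4)
  expect_equal(unname(coef(f)["D50"]), unname(-coef(g)[1] / coef(g)[2]),
               tolerance = 1e-4)
})

test_that("complete separation runs gamma to the bound with a diagnostic", {
  f <- fit_ntcp(c(0.5, 0.6, 1.4, 1.5), c(0, 0, 1, 1))
  expect_true(f$diagnostics$separation)
  expect_true(f$converged)
  expect_equal(unname(coef(f)["gamma"]), f$control$gamma_bounds[2],
               tolerance = 1e-6)
  # likelihood is monotone in gamma under separation: larger gamma never hurts
  d50 <- unname(coef(f)["D50"])
  lls <- vapply(c(1, 5, 20, 50), function(g)
    ntcp_loglik(c(0.5, 0.6, 1.4, 1.5), c(0, 0, 1, 1), ntcp_params(d50, g)),
    numeric(1))
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("degenerate inputs raise typed errors", {
  expect_error(fit_ntcp(c(1, 2, 3), c(1, 1, 1)),
               class = "ntcpsim_degenerate_outcome")
  expect_error(fit_ntcp(c(1, 2, 3), c(0, 0, 0)),
               class = "ntcpsim_degenerate_outcome")
  expect_error(fit_ntcp(c(2, 2, 2), c(0, 1, 0)),
               class = "ntcpsim_constant_dose")
})

test_that("fit is invariant to patient order and parameterization", {
  set.seed(8)
  co <- make_test_cohort(n = 300, seed = 8)
  y <- simulate_outcomes(ntcp(co$D_gt, ntcp_params(1, 1)))$labels
  f1 <- fit_ntcp(co$D_gt, y)
  perm <- sample(300)
  f2 <- fit_ntcp(co$D_gt[perm], y[perm])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  f3 <- fit_ntcp(co$D_gt, y, parameterization = "slope")
  expect_equal(coef(f1), coef(f3), tolerance = 1e-4)
})

test_that("in-sample AUC of the fitted model equals the raw dose AUC", {
  set.seed(14)
  for (g_true in c(0.3, 1.5)) {
    co <- make_test_cohort(n = 250, seed = 14 + g_true * 10)
    y <- simulate_outcomes(ntcp(co$D_gt, ntcp_params(1, g_true)))$labels
    f <- fit_ntcp(co$D_gt, y)
    expect_equal(f$auc, auc(co$D_gt, y), tolerance = 1e-12)
    expect_equal(auc(predict(f, type = "link"), y), auc(co$D_gt, y),
                 tolerance = 1e-12)
  }
})

test_that("model object methods behave coherently", {
  set.seed(3)
  co <- make_test_cohort(n = 200, seed = 3)
  y <- simulate_outcomes(ntcp(co$D_gt, ntcp_params(1, 1)))$labels
  f <- fit_ntcp(co$D_gt, y)
  expect_named(coef(f), c("D50", "gamma", "s"))
  expect_equal(unname(coef(f)["s"]),
               unname(4 * coef(f)["gamma"] / coef(f)["D50"]))
  expect_equal(as.numeric(logLik(f)), f$logLik)
  expect_equal(attr(logLik(f), "df"), 2L)
  pr <- predict(f, newdata = c(0.5, 1, 2))
  expect_true(all(pr >= 0 & pr <= 1) && all(diff(pr) > 0))
  expect_equal(predict(f, newdata = coef(f)["D50"]), 0.5, tolerance = 1e-9,
               ignore_attr = TRUE)
  r <- residuals(f)
  expect_equal(r, y - predict(f), tolerance = 1e-12)
  expect_equal(length(residuals(f, "deviance")), 200L)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(200L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_output(print(f), "D50")
  expect_output(print(summary(f)), "event fraction")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
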