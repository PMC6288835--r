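test_that("fit_slm matches closed forms and flags degenerate fits", {
  set.seed(21)
  y <- rnorm(80, 3, 2)
  f <- fit_slm(y)
  expect_equal(unname(f$coefficients), mean(y))
  expect_equal(f$sigma2, mean((y - mean(y))^2)) # ML variance, not RSS/(n-1)

  x <- rnorm(80)
  f2 <- fit_slm(2 + 3 * x, design = cbind(x = x)) # perfect fit
  expect_true(f2$degenerate)

  expect_error(fit_slm(cbind(x, 2 * x)[, 1], design = cbind(x = x, x2 = 2 * x)),
               "collinear.*x2")
  expect_error(fit_slm(c(1, NA, 3)), "missing")
})

test_that("SLM slope recovery is within sampling error", {
  set.seed(22)
  n <- 500
  a <- sample(0:2, n, replace = TRUE)
  y <- 1 + 2 * a + rnorm(n)
  f <- fit_slm(y, design = cbind(a = a))
  X <- cbind(1, a)
  se <- sqrt(f$sigma2 * solve(crossprod(X))[2, 2])
  expect_lt(abs(f$coefficients["a"] - 2), 3 * se)
})

test_that("DGLM with intercept-only variance design reduces to the SLM", {
  set.seed(23)
  n <- 100
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  slm <- fit_slm(y, design = cbind(x = x))
  dglm <- fit_dglm(y, mean_design = cbind(x = x))
  expect_equal(dglm$mean$coefficients, slm$coefficients, tolerance = 1e-9)
  # exp(2 mu_v) on the log-sigma scale equals the ML variance RSS/n
  expect_equal(exp(2 * unname(dglm$variance$coefficients[1])), slm$rss / n,
               tolerance = 1e-9)
  expect_equal(dglm$loglik, slm$loglik, tolerance = 1e-9)
})

test_that("two-group heteroskedastic data recovers per-group MLEs exactly", {
  y <- c(-1, 1, 8, 12)
  g <- c(0, 0, 1, 1)
  f <- fit_dglm(y, mean_design = cbind(g = g), var_design = cbind(g = g))
  expect_equal(sort(unique(round(f$fitted_mean, 9))), c(0, 10))
  expect_equal(sort(unique(round(exp(2 * f$fitted_logsd), 9))), c(1, 4))
  expect_true(f$converged)
})

test_that("the alternating fitter never decreases the log-likelihood", {
  set.seed(24)
  n <- 60
  a <- sample(0:2, n, replace = TRUE)
  y <- rnorm(n, 0.4 * a, exp(0.5 * (a == 2)))
  X <- cbind(1, a = a, d = as.numeric(a == 1))
  lls <- vapply(1:12, function(k) {
    mvqtlmap:::cpp_dglm_fit(y, X, X, tol = 0, maxit = k)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("DGLM estimates are invariant to shifting and equivariant to scaling", {
  set.seed(25)
  n <- 120
  a <- sample(0:2, n, replace = TRUE)
  d <- as.numeric(a == 1)
  y <- rnorm(n, 0.3 * a, exp(-0.2 * a))
  X <- cbind(a = a, d = d)
  f <- fit_dglm(y, X, X)
  f_shift <- fit_dglm(y + 100, X, X)
  expect_equal(unname(f_shift$mean$coefficients[1] - f$mean$coefficients[1]),
               100, tolerance = 1e-6)
  expect_equal(f_shift$mean$coefficients[-1], f$mean$coefficients[-1],
               tolerance = 1e-6)
  expect_equal(f_shift$variance$coefficients, f$variance$coefficients,
               tolerance = 1e-6)

  f_scale <- fit_dglm(3 * y, X, X)
  expect_equal(unname(f_scale$variance$coefficients[1] -
                        f$variance$coefficients[1]), log(3),
               tolerance = 1e-6)
  expect_equal(f_scale$variance$coefficients[-1], f$variance$coefficients[-1],
               tolerance = 1e-6)

  t1 <- lr_tests(y, a, d)
  t2 <- lr_tests(3 * y + 100, a, d)
  expect_equal(unlist(t1[1:4]), unlist(t2[1:4]), tolerance = 1e-6)
})

test_that("lr_tests handles uninformative loci and respects nesting", {
  set.seed(26)
  y <- rnorm(50)
  t0 <- lr_tests(y, a = rep(1, 50), d = rep(0.5, 50))
  expect_equal(unlist(t0[1:4]), c(lr_mqtl = 0, lr_vqtl = 0, lr_mvqtl = 0,
                                  lod_slm = 0))
  expect_true(all(unlist(t0[5:8])))

  for (i in 1:10) {
    n <- 90
    a <- sample(0:2, n, replace = TRUE)
    d <- as.numeric(a == 1)
    y <- rnorm(n, 0.2 * a, exp(0.2 * d))
    tt <- lr_tests(y, a, d, mean_covariates = cbind(s = rbinom(n, 1, 0.5)))
    expect_gte(tt$lr_mvqtl, tt$lr_mqtl - 1e-6)
    expect_gte(tt$lr_mvqtl, tt$lr_vqtl - 1e-6)
    expect_true(all(unlist(tt[1:4]) >= 0))
  }
})

test_that("DGLM coefficient estimates and SEs are well calibrated at n = 800", {
  set.seed(27)
  n <- 800
  g <- sample.int(3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  a <- g - 1
  d <- as.numeric(g == 2)
  y <- rnorm(n, 0.5 * a, exp(-0.4 * a))
  f <- fit_dglm(y, cbind(a = a, d = d), cbind(a = a, d = d))
  expect_lt(abs(f$mean$coefficients["(Intercept)"] - 0) /
              f$mean$se["(Intercept)"], 3)
  expect_lt(abs(f$mean$coefficients["a"] - 0.5) / f$mean$se["a"], 3)
  expect_lt(abs(f$variance$coefficients["(Intercept)"] - 0) /
              f$variance$se["(Intercept)"], 3)
  expect_lt(abs(f$variance$coefficients["a"] - (-0.4)) / f$variance$se["a"], 3)
})

test_that("Poisson DGLM recovers dispersion structure", {
  set.seed(28)
  y <- rpois(500, 8)
  f <- fit_dglm_poisson(y)
  expect_true(f$converged)
  expect_lt(abs(exp(f$variance$coefficients[1]) - 1), 0.35)

  g <- rbinom(500, 1, 0.5)
  # group 1 is negative-binomial with Pearson dispersion about 4
  y2 <- ifelse(g == 1, rnbinom(500, size = 10 / 3, mu = 10), rpois(500, 10))
  f2 <- fit_dglm_poisson(y2, mean_design = cbind(g = g),
                         var_design = cbind(g = g))
  ratio <- exp(unname(f2$variance$coefficients["g"]))
  expect_gt(ratio, 2)
  expect_lt(ratio, 7)

  expect_error(fit_dglm_poisson(rep(0, 20)), "zero")
  expect_error(fit_dglm_poisson(c(-1, 2, 3)), "non-negative")
})

test_that("pve follows the LOD definition", {
  expect_equal(pve(lod = 0, n = 100), 0)
  expect_equal(pve(lod = 50, n = 100), 90) # LOD = n/2 -> 1 - 10^-1
  expect_equal(pve(lr = 2 * log(10) * 5, n = 200), pve(lod = 5, n = 200))
  expect_error(pve(n = 10), "supply")
})

test_that("tidy and glance expose the fit in broom form", {
  set.seed(29)
  a <- sample(0:2, 100, replace = TRUE)
  f <- fit_dglm(rnorm(100, a), cbind(a = a), cbind(a = a))
  td <- tidy(f)
  expect_named(td, c("submodel", "term", "estimate", "std.error",
                     "statistic", "p.value"))
  expect_equal(nrow(td), 4)
  expect_equal(unique(td$submodel), c("mean", "variance"))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 100)
  js <- jsonlite::fromJSON(dglm_to_json(f))
  expect_equal(js$loglik, f$loglik)
})
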