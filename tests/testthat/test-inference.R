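perm_fixture <- function(n = 100, seed = 41) {
  cr <- simulate_f2(sim_config(n = n, chromosomes = 2, markers_per_chr = 3,
                               spacing = 15, seed = seed))
  pr <- calc_genoprob(cr, error_prob = 1e-4)
  list(cr = cr, pr = pr)
}

test_that("gev distribution functions are mutually consistent", {
  q <- qgev(c(0.1, 0.5, 0.9), 3, 2, 0.15)
  expect_equal(pgev(q, 3, 2, 0.15), c(0.1, 0.5, 0.9))
  q0 <- qgev(c(0.1, 0.5, 0.9), 3, 2, 0)
  expect_equal(pgev(q0, 3, 2, 0), c(0.1, 0.5, 0.9))
  # density integrates to the cdf increment
  expect_equal(integrate(dgev, -5, 5, loc = 0, scale = 1, shape = 0.2)$value,
               pgev(5, 0, 1, 0.2) - pgev(-5, 0, 1, 0.2), tolerance = 1e-5)
  # support endpoint behavior
  expect_equal(pgev(-100, 0, 1, 0.2), 0)
  expect_equal(pgev(100, 0, 1, -0.2), 1)
})

test_that("fit_gev recovers parameters and rejects degenerate input", {
  set.seed(42)
  g <- fit_gev(rgev(3000, 10, 2, 0))
  expect_lt(abs(g$loc - 10), 0.2)
  expect_lt(abs(g$scale - 2), 0.2)
  expect_lt(abs(g$shape), 0.08)
  g2 <- fit_gev(rgev(3000, 0, 1, 0.2))
  expect_lt(abs(g2$shape - 0.2), 0.08)
  expect_error(fit_gev(rep(3, 100)), "constant")
  expect_named(tidy(g)[1:2], c("term", "estimate"))
})

test_that("permutation maxima are reproducible under a fixed seed", {
  fx <- perm_fixture()
  n1 <- suppressWarnings(permute_scan(fx$pr, fx$cr$pheno$y, test = "mqtl",
                                      n_perm = 120, seed = 7))
  n2 <- suppressWarnings(permute_scan(fx$pr, fx$cr$pheno$y, test = "mqtl",
                                      n_perm = 120, seed = 7))
  expect_identical(n1$maxima, n2$maxima)
  n3 <- suppressWarnings(permute_scan(fx$pr, fx$cr$pheno$y, test = "mqtl",
                                      n_perm = 120, seed = 8))
  expect_false(identical(n1$maxima, n3$maxima))
  expect_error(permute_scan(fx$pr, fx$cr$pheno$y, test = "banana"),
               "should be one of")
})

test_that("structured permutation maxima match direct recomputation", {
  fx <- perm_fixture(n = 60)
  y <- fx$cr$pheno$y
  sex <- fx$cr$pheno$sex
  n <- length(y)
  n_perm <- 3
  seed <- 99
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), \(i) sample.int(n), integer(n))
  })
  cod <- mvqtlmap:::coding_matrices(fx$pr)
  Xc <- cbind(1, sex = sex)

  oracle_max <- function(test) {
    vapply(seq_len(n_perm), function(p) {
      idx <- perms[, p]
      stats <- vapply(seq_len(ncol(cod$A)), function(l) {
        a <- cod$A[, l]; d <- cod$D[, l]
        ap <- a[idx];    dp <- d[idx]
        if (test == "slm") {
          f0 <- fit_slm(y, cbind(sex = sex))
          f1 <- fit_slm(y, cbind(sex = sex, a = ap, d = dp))
          0.5 * n * log10(f0$rss / f1$rss)
        } else if (test == "mqtl") {
          full <- fit_dglm(y, cbind(sex = sex, a = ap, d = dp),
                           cbind(sex = sex, a = a, d = d))
          null <- fit_dglm(y, cbind(sex = sex),
                           cbind(sex = sex, a = a, d = d))
          2 * (full$loglik - null$loglik)
        } else if (test == "vqtl") {
          full <- fit_dglm(y, cbind(sex = sex, a = a, d = d),
                           cbind(sex = sex, a = ap, d = dp))
          null <- fit_dglm(y, cbind(sex = sex, a = a, d = d),
                           cbind(sex = sex))
          2 * (full$loglik - null$loglik)
        } else {
          full <- fit_dglm(y, cbind(sex = sex, a = ap, d = dp),
                           cbind(sex = sex, a = ap, d = dp))
          null <- fit_dglm(y, cbind(sex = sex), cbind(sex = sex))
          2 * (full$loglik - null$loglik)
        }
      }, numeric(1))
      max(stats)
    }, numeric(1))
  }

  for (test in c("slm", "mqtl", "vqtl", "mvqtl")) {
    got <- suppressWarnings(
      permute_scan(fx$pr, y, covariates = fx$cr$pheno["sex"], test = test,
                   n_perm = n_perm, seed = seed))
    expect_equal(got$maxima, oracle_max(test), tolerance = 1e-6,
                 label = paste("maxima for", test))
  }
})

test_that("null maxima grow with the number of scanned loci", {
  set.seed(43)
  cr_small <- simulate_f2(sim_config(n = 120, chromosomes = 1,
                                     markers_per_chr = 10, seed = 44))
  cr_big <- simulate_f2(sim_config(n = 120, chromosomes = 10,
                                   markers_per_chr = 10, seed = 44))
  pr_small <- calc_genoprob(cr_small, error_prob = 1e-4)
  pr_big <- calc_genoprob(cr_big, error_prob = 1e-4)
  m_small <- permute_scan(pr_small, cr_small$pheno$y, test = "slm",
                          n_perm = 200, seed = 45)
  m_big <- permute_scan(pr_big, cr_big$pheno$y, test = "slm",
                        n_perm = 200, seed = 45)
  expect_gt(median(m_big$maxima), median(m_small$maxima))
})

test_that("fwer_adjust yields monotone, clamped, GEV-consistent p-values", {
  fx <- perm_fixture(n = 120)
  sc <- scan_genome(fx$pr, fx$cr$pheno$y)
  null <- permute_scan(fx$pr, fx$cr$pheno$y, test = "mqtl", n_perm = 200,
                       seed = 46)
  adj <- fwer_adjust(sc, null)
  expect_true("p_mqtl" %in% names(adj))
  ord <- order(adj$lr_mqtl)
  expect_true(all(diff(adj$p_mqtl[ord]) <= 1e-12))
  expect_true(all(adj$p_mqtl >= 1e-12 & adj$p_mqtl <= 1))

  g <- attr(adj, "gev")$mqtl
  expect_s3_class(g, "gev_fit")
  # a statistic at the fitted median has adjusted p 1/2; far below the
  # support the p-value clamps to 1
  med <- qgev(0.5, g$loc, g$scale, g$shape)
  sc2 <- sc
  sc2$lr_mqtl[1] <- med
  sc2$lr_mqtl[2] <- -50
  adj2 <- fwer_adjust(sc2, null)
  expect_equal(adj2$p_mqtl[1], 0.5, tolerance = 1e-6)
  expect_equal(adj2$p_mqtl[2], 1)

  expect_error(fwer_adjust(scan_genome(fx$pr, fx$cr$pheno$y, tests = "slm"),
                           null), "does not contain")

  thr <- perm_thresholds(null)
  expect_equal(thr$alpha, c(0.05, 0.01))
  expect_true(all(diff(thr$threshold) > 0))
  # GEV 95th percentile agrees with the empirical percentile of the maxima
  emp <- quantile(null$maxima, 0.95, names = FALSE)
  band <- quantile(null$maxima, c(0.90, 0.99), names = FALSE)
  expect_gt(thr$threshold[1], band[1])
  expect_lt(thr$threshold[1], band[2])
})

test_that("permutation nulls serialize to JSON with their GEV fit", {
  fx <- perm_fixture(n = 80)
  null <- suppressWarnings(permute_scan(fx$pr, fx$cr$pheno$y, test = "slm",
                                        n_perm = 120, seed = 47))
  tf <- withr::local_tempfile(fileext = ".json")
  perm_null_to_json(null, tf)
  back <- jsonlite::fromJSON(tf)
  expect_equal(back$test, "slm")
  expect_equal(back$n_perm, 120)
  expect_equal(back$maxima, null$maxima, tolerance = 1e-12)
  expect_true(back$gev$scale > 0)
})

test_that("bootstrap intervals are deterministic and collapse for huge effects", {
  cr <- simulate_f2(sim_config(
    n = 200, chromosomes = 2, markers_per_chr = 6, spacing = 12,
    qtl = list(chr = "1", pos = 24, beta_a = 3), mu_v = -2, seed = 48))
  pr <- calc_genoprob(cr, error_prob = 1e-4)
  ci1 <- bootstrap_interval(pr, cr$pheno$y, chromosome = "1", test = "mqtl",
                            n_boot = 150, seed = 49)
  ci2 <- bootstrap_interval(pr, cr$pheno$y, chromosome = "1", test = "mqtl",
                            n_boot = 150, seed = 49)
  expect_equal(ci1, ci2)
  # a near-noiseless large effect pins every resample's peak to the QTL
  expect_equal(ci1$lower, 24)
  expect_equal(ci1$upper, 24)

  expect_warning(bootstrap_interval(pr, cr$pheno$y, chromosome = "1",
                                    n_boot = 99, seed = 1), "unstable")
  expect_error(bootstrap_interval(pr, cr$pheno$y, chromosome = "9",
                                  n_boot = 150, seed = 1), "not found")
})

test_that("nominal 90% bootstrap intervals cover the causal position", {
  covered <- 0
  for (i in 1:25) {
    cr <- simulate_f2(sim_config(
      n = 200, chromosomes = 1, markers_per_chr = 11, spacing = 10,
      qtl = list(chr = "1", pos = 50, beta_a = 1), seed = 4900 + i))
    pr <- calc_genoprob(cr, error_prob = 1e-4)
    ci <- bootstrap_interval(pr, cr$pheno$y, chromosome = "1", test = "mqtl",
                             n_boot = 200, level = 0.9, seed = 50 + i)
    if (ci$lower <= 50 && ci$upper >= 50) covered <- covered + 1
  }
  expect_gte(covered, 20) # >= 80% observed for a nominal 90% interval
})
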