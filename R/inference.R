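# Genome-wide significance: structured permutations, generalized extreme
# value (GEV) tail fitting, FWER-adjusted p-values, and bootstrap QTL
# localization.

#' Generalized extreme value distribution
#'
#' Density, distribution function, quantile function, and random generation
#' for the three-parameter GEV distribution with location `loc`, scale
#' `scale` (> 0), and shape `shape` (`shape = 0` is the Gumbel limit).
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param loc,scale,shape GEV parameters.
#' @param log,lower.tail Usual distribution-function conventions.
#' @return Numeric vector.
#' @name gev
NULL

#' @rdname gev
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-10) {
    ld <- -z - exp(-z) - base::log(scale)
  } else {
    t <- 1 + shape * z
    ld <- ifelse(t > 0,
                 -(1 / shape + 1) * base::log(pmax(t, 1e-300)) -
                   pmax(t, 1e-300)^(-1 / shape) - base::log(scale),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' @rdname gev
#' @export
pgev <- function(q, loc = 0, scale = 1, shape = 0, lower.tail = TRUE) {
  stopifnot(scale > 0)
  z <- (q - loc) / scale
  if (abs(shape) < 1e-10) {
    p <- exp(-exp(-z))
  } else {
    t <- 1 + shape * z
    # beyond the finite endpoint the cdf is 0 (shape > 0) or 1 (shape < 0)
    p <- ifelse(t <= 0, as.numeric(shape < 0), exp(-pmax(t, 1e-300)^(-1 / shape)))
  }
  if (lower.tail) p else 1 - p
}

#' @rdname gev
#' @export
qgev <- function(p, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0, all(p > 0 & p < 1))
  if (abs(shape) < 1e-10) {
    loc - scale * base::log(-base::log(p))
  } else {
    loc + scale * ((-base::log(p))^(-shape) - 1) / shape
  }
}

#' @rdname gev
#' @export
rgev <- function(n, loc = 0, scale = 1, shape = 0) {
  qgev(runif(n), loc, scale, shape)
}

#' Fit a generalized extreme value distribution by maximum likelihood
#'
#' Used on permutation genome-wide maxima so that FWER-adjusted p-values
#' can be computed beyond the permutation support. Initialization uses
#' Gumbel moment estimates (`scale = sd * sqrt(6)/pi`,
#' `loc = mean - 0.5772 * scale`, `shape = 0`); if the three-parameter ML
#' fit fails to converge the Gumbel submodel is returned with
#' `gumbel_fallback = TRUE`.
#'
#' @param maxima Numeric vector of maxima (length >= 50 recommended).
#' @return A `gev_fit` object: `loc`, `scale`, `shape`, `loglik`,
#'   `converged`, `gumbel_fallback`, `n`.
#' @examples
#' fit_gev(rgev(500, 10, 2, 0.1))
#' @export
fit_gev <- function(maxima) {
  maxima <- maxima[is.finite(maxima)]
  if (length(maxima) < 2 || sd(maxima) == 0) {
    bail("`maxima` is (near-)constant; cannot fit a GEV distribution.")
  }
  s0 <- sd(maxima) * sqrt(6) / pi
  m0 <- mean(maxima) - 0.5772 * s0
  negll <- function(par) {
    ll <- sum(dgev(maxima, par[1], exp(par[2]), par[3], log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- tryCatch(
    optim(c(m0, log(s0), 0.05), negll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  ok <- !is.null(opt) && opt$convergence == 0 && is.finite(opt$value) &&
    opt$value < 1e9
  if (ok) {
    structure(list(loc = opt$par[1], scale = exp(opt$par[2]),
                   shape = opt$par[3], loglik = -opt$value,
                   converged = TRUE, gumbel_fallback = FALSE,
                   n = length(maxima)),
              class = "gev_fit")
  } else {
    negll_g <- function(par) {
      ll <- sum(dgev(maxima, par[1], exp(par[2]), 0, log = TRUE))
      if (!is.finite(ll)) 1e10 else -ll
    }
    optg <- optim(c(m0, log(s0)), negll_g, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    structure(list(loc = optg$par[1], scale = exp(optg$par[2]), shape = 0,
                   loglik = -optg$value, converged = optg$convergence == 0,
                   gumbel_fallback = TRUE, n = length(maxima)),
              class = "gev_fit")
  }
}

#' @export
print.gev_fit <- function(x, ...) {
  cat("GEV fit: loc =", signif(x$loc, 5), " scale =", signif(x$scale, 5),
      " shape =", signif(x$shape, 4),
      if (x$gumbel_fallback) "[Gumbel fallback]", "\n")
  invisible(x)
}

#' @method tidy gev_fit
#' @export
tidy.gev_fit <- function(x, ...) {
  tibble::tibble(term = c("loc", "scale", "shape"),
                 estimate = c(x$loc, x$scale, x$shape))
}

#' Structured permutation null for a genome scan
#'
#' Estimates the null distribution of the genome-wide maximum statistic by
#' permutation. Each permutation draws one random relabeling of individuals
#' and applies it to the whole-genome genotype information, preserving each
#' individual's multilocus genotype vector (and thus linkage among loci);
#' phenotypes and covariates are never permuted. The relabeling is applied
#' to different parts of the model depending on the test:
#' \itemize{
#'   \item `slm`, `mvqtl`: all genotype terms are relabeled;
#'   \item `mqtl`: only the locus terms in the mean submodel of the full
#'     model (the variance-submodel locus terms stay unpermuted, in the
#'     full and null models alike);
#'   \item `vqtl`: the converse.
#' }
#' The genome-wide maximum of the test's statistic is recorded per
#' permutation; loci whose fits fail or degenerate are excluded from the
#' maxima.
#'
#' @inheritParams scan_genome
#' @param test One of `"slm"`, `"mqtl"`, `"vqtl"`, `"mvqtl"`.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A `perm_null` object: `test`, `maxima` (length `n_perm`),
#'   `n_perm`, `seed`.
#' @export
permute_scan <- function(probs, phenotype, covariates = NULL,
                         test = c("slm", "mqtl", "vqtl", "mvqtl"),
                         n_perm = 1000, seed = 1, covariate_roles = NULL,
                         tol = 1e-8, maxit = 50) {
  test <- match.arg(test)
  seed <- assert_seed(seed)
  if (n_perm < 100) {
    warning("n_perm < 100 gives a poorly estimated null; ",
            ">= 100 recommended", call. = FALSE)
  }
  inp <- prepare_scan_inputs(probs, phenotype, covariates, covariate_roles)
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), \(i) sample.int(inp$n), integer(inp$n))
  })
  maxima <- cpp_perm_max(inp$y, inp$Xc, inp$Zc, inp$A, inp$D,
                         perms - 1L, match(test, .all_tests) - 1L,
                         tol, maxit)
  maxima[!is.finite(maxima)] <- NA_real_
  if (anyNA(maxima)) {
    warning(sum(is.na(maxima)), " permutation(s) had no valid locus fit",
            call. = FALSE)
  }
  structure(list(test = test, maxima = as.numeric(maxima),
                 n_perm = n_perm, seed = seed),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat("permutation null (", x$test, "): ", x$n_perm, " genome-wide maxima, ",
      "seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Significance thresholds from a permutation null
#'
#' Genome-wide statistic thresholds at the given FWER levels, from the GEV
#' fit to the permutation maxima.
#'
#' @param null A [permute_scan()] `perm_null`.
#' @param alpha FWER levels.
#' @return Tibble with `alpha` and `threshold`.
#' @export
perm_thresholds <- function(null, alpha = c(0.05, 0.01)) {
  g <- fit_gev(null$maxima)
  tibble::tibble(test = null$test, alpha = alpha,
                 threshold = qgev(1 - alpha, g$loc, g$scale, g$shape))
}

#' FWER-adjusted p-values for a genome scan
#'
#' Converts per-locus statistics into family-wise-error-rate-adjusted
#' p-values: each statistic is referred to the upper tail of a GEV
#' distribution fitted to the permutation genome-wide maxima for the same
#' test, `p = 1 - GEV_cdf(LR)` (LOD statistics are compared on the LOD
#' scale). Such a p-value is the estimated probability of seeing a
#' statistic this large anywhere in a genome scan of a phenotype with no
#' true associations. P-values are computed from the fitted tail even
#' beyond the permutation support and clamped to `[1e-12, 1]`.
#'
#' @param scan An `mvqtl_scan`.
#' @param nulls A `perm_null` or list of them (one per test to adjust).
#' @return The scan with a `p_<test>` column added per null; the GEV fits
#'   are stored in `attr(, "gev")`.
#' @export
fwer_adjust <- function(scan, nulls) {
  if (inherits(nulls, "perm_null")) nulls <- list(nulls)
  gevs <- attr(scan, "gev") %||% list()
  for (null in nulls) {
    stat_col <- if (null$test == "slm") "lod_slm" else paste0("lr_", null$test)
    if (!stat_col %in% names(scan)) {
      bail("scan does not contain the ", null$test, " test.")
    }
    g <- fit_gev(null$maxima)
    p <- pgev(scan[[stat_col]], g$loc, g$scale, g$shape, lower.tail = FALSE)
    scan[[paste0("p_", null$test)]] <- pmin(pmax(p, 1e-12), 1)
    gevs[[null$test]] <- g
  }
  attr(scan, "gev") <- gevs
  scan
}

#' Serialize a permutation null (with GEV fit) to JSON
#' @param null A `perm_null`.
#' @param path Optional path to write to.
#' @return JSON string, invisibly when `path` is given.
#' @export
perm_null_to_json <- function(null, path = NULL) {
  g <- fit_gev(null$maxima)
  js <- jsonlite::toJSON(list(
    test = null$test, n_perm = null$n_perm, seed = null$seed,
    maxima = null$maxima,
    gev = list(loc = g$loc, scale = g$scale, shape = g$shape,
               gumbel_fallback = g$gumbel_fallback)),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Bootstrap confidence interval for QTL position
#'
#' Nonparametric bootstrap localization of a QTL on one chromosome:
#' individuals are resampled with replacement, the single-chromosome scan
#' is rerun on each resample, the position of the maximal statistic is
#' recorded, and the interval is formed from the
#' `(1-level)/2` and `1-(1-level)/2` percentiles of those positions.
#'
#' @inheritParams permute_scan
#' @param chromosome Chromosome holding the QTL peak.
#' @param test Statistic to maximize (the test that identified the QTL).
#' @param n_boot Number of bootstrap resamples.
#' @param level Coverage level in (0, 1).
#' @return A one-row `qtl_interval` tibble: `chr`, `lower`, `upper`,
#'   `level`, `n_boot`, `test`, `seed`.
#' @export
bootstrap_interval <- function(probs, phenotype, covariates = NULL,
                               chromosome, test = "mqtl", n_boot = 1000,
                               level = 0.9, seed = 1,
                               covariate_roles = NULL,
                               tol = 1e-8, maxit = 50) {
  test <- match.arg(test, .all_tests)
  seed <- assert_seed(seed)
  stopifnot(level > 0, level < 1)
  if (n_boot < 100) {
    warning("n_boot < 100 gives an unstable interval", call. = FALSE)
  }
  pr_chr <- subset_genoprob(probs, chromosome)
  inp <- prepare_scan_inputs(pr_chr, phenotype, covariates, covariate_roles)
  boots <- withr::with_seed(seed, {
    matrix(sample.int(inp$n, inp$n * n_boot, replace = TRUE), nrow = inp$n)
  })
  pos <- pr_chr$map$pos
  peaks <- cpp_boot_peak(inp$y, inp$Xc, inp$Zc, inp$A, inp$D, pos,
                         boots - 1L, match(test, .all_tests) - 1L,
                         tol, maxit)
  peaks <- peaks[is.finite(peaks)]
  if (length(peaks) == 0) bail("no bootstrap resample produced a valid scan.")
  qs <- quantile(peaks, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  out <- tibble::tibble(chr = as.character(chromosome), lower = qs[1],
                        upper = qs[2], level = level,
                        n_boot = n_boot, test = test, seed = seed)
  class(out) <- c("qtl_interval", class(out))
  out
}
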