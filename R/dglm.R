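# Single-locus model fitting: standard linear model (SLM), Gaussian double
# generalized linear model (DGLM), Poisson DGLM, and the four test
# statistics. The heavy lifting is in src/dglm_core.cpp; these wrappers add
# design construction, naming, and broom-style accessors.

# build a design matrix with intercept from NULL / vector / matrix / df
build_design <- function(x, n, label = "covariate") {
  if (is.null(x)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  if (is.vector(x) && !is.list(x)) x <- matrix(x, ncol = 1,
                                               dimnames = list(NULL, label))
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0(label, seq_len(ncol(x)))
  }
  if (nrow(x) != n) bail("design has ", nrow(x), " rows; expected ", n, ".")
  cbind("(Intercept)" = 1, x)
}

check_full_rank <- function(X, what = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    bail("rank-deficient ", what, "; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the standard linear model by maximum likelihood
#'
#' Gaussian linear model with a single residual variance shared by all
#' individuals, the engine of traditional interval mapping. The variance is
#' the maximum-likelihood estimate RSS/n (not RSS/(n-p)), so that
#' log-likelihoods are directly comparable with [fit_dglm()].
#'
#' @param y Numeric response vector (no missing values).
#' @param design Covariate matrix/data frame for the mean; an intercept is
#'   always added. `NULL` for intercept-only.
#' @return An `slm_fit` object: coefficients, `sigma2`, `rss`, `loglik`,
#'   `n`, and a `degenerate` flag (fitted variance at the 1e-12 floor).
#' @examples
#' f <- fit_slm(rnorm(50))
#' f$coefficients
#' @export
fit_slm <- function(y, design = NULL) {
  if (anyNA(y)) bail("`y` has missing values; drop them before fitting.")
  X <- build_design(design, length(y))
  if (length(y) <= ncol(X)) bail("need n > number of coefficients.")
  check_full_rank(X, "mean design")
  f <- cpp_slm_fit(y, X)
  structure(list(coefficients = setNames(drop(f$coef), colnames(X)),
                 sigma2 = f$sigma2, rss = f$rss, loglik = f$loglik,
                 n = length(y), degenerate = f$degenerate),
            class = "slm_fit")
}

#' @export
print.slm_fit <- function(x, ...) {
  cat("SLM fit (ML): n =", x$n, " logLik =", format(x$loglik), "\n")
  print(x$coefficients)
  cat("sigma2 (ML):", x$sigma2, if (x$degenerate) "[degenerate]", "\n")
  invisible(x)
}

#' Fit the Gaussian double generalized linear model
#'
#' Jointly models the phenotype mean and the log residual standard
#' deviation of each individual:
#' \deqn{y_i \sim N(m_i, \sigma_i^2), \quad m_i = x_i'\beta, \quad
#'       \sigma_i = \exp(v_i), \quad v_i = z_i'\gamma.}
#' Fitting is full maximum likelihood by block coordinate ascent: weighted
#' least squares for the mean coefficients with weights
#' \eqn{1/\sigma_i^2}, then a gamma GLM with log link (dispersion 2) on the
#' squared residuals for the variance coefficients, iterated until the
#' log-likelihood changes by less than `tol`. The log-likelihood is
#' non-decreasing across iterations, and with an intercept-only variance
#' design the fit reduces exactly to [fit_slm()].
#'
#' Internally the variance submodel is parameterized on the
#' \eqn{\log\sigma^2} scale; reported variance coefficients and standard
#' errors follow the \eqn{\log\sigma} convention above (i.e. halved).
#'
#' @param y Numeric response (no missing values).
#' @param mean_design,var_design Covariate matrices/data frames for the two
#'   submodels; an intercept is always added; `NULL` for intercept-only.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param maxit Maximum number of outer iterations.
#' @return A `dglm_fit` object with elements `mean` and `variance` (each
#'   coefficients + standard errors), `fitted_mean`, `fitted_logsd`,
#'   `loglik`, `iterations`, `converged`, `degenerate`, `n`.
#' @examples
#' y <- rnorm(100, sd = exp(0.3 * rbinom(100, 1, 0.5)))
#' fit_dglm(y)
#' @export
fit_dglm <- function(y, mean_design = NULL, var_design = NULL,
                     tol = 1e-8, maxit = 50) {
  if (anyNA(y)) bail("`y` has missing values; drop them before fitting.")
  n <- length(y)
  X <- build_design(mean_design, n)
  Z <- build_design(var_design, n)
  if (n <= ncol(X) || n <= ncol(Z)) {
    bail("need n larger than each submodel's coefficient count.")
  }
  check_full_rank(X, "mean design")
  check_full_rank(Z, "variance design")
  f <- cpp_dglm_fit(y, X, Z, tol, maxit)
  if (!f$converged) {
    warning("DGLM fit did not converge in ", maxit, " iterations",
            call. = FALSE)
  }
  structure(list(
    mean = list(coefficients = setNames(drop(f$beta), colnames(X)),
                se = setNames(drop(f$se_beta), colnames(X))),
    # log sigma^2 -> log sigma
    variance = list(coefficients = setNames(drop(f$phi) / 2, colnames(Z)),
                    se = setNames(drop(f$se_phi) / 2, colnames(Z))),
    fitted_mean = drop(f$fitted_mean),
    fitted_logsd = drop(f$fitted_logvar) / 2,
    loglik = f$loglik, iterations = f$iterations,
    converged = f$converged, degenerate = f$degenerate, n = n),
    class = "dglm_fit")
}

#' @export
print.dglm_fit <- function(x, ...) {
  cat("DGLM fit (ML): n =", x$n, " logLik =", format(x$loglik),
      " iterations =", x$iterations,
      if (!x$converged) "[not converged]",
      if (x$degenerate) "[degenerate]", "\n")
  cat("mean submodel:\n")
  print(x$mean$coefficients)
  cat("variance submodel (log sigma):\n")
  print(x$variance$coefficients)
  invisible(x)
}

#' @method tidy dglm_fit
#' @export
tidy.dglm_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(submodel = "mean",
                   term = names(x$mean$coefficients),
                   estimate = unname(x$mean$coefficients),
                   std.error = unname(x$mean$se)),
    tibble::tibble(submodel = "variance",
                   term = names(x$variance$coefficients),
                   estimate = unname(x$variance$coefficients),
                   std.error = unname(x$variance$se))
  ) |>
    dplyr::mutate(statistic = .data$estimate / .data$std.error,
                  p.value = 2 * pnorm(-abs(.data$statistic)))
}

#' @method glance dglm_fit
#' @export
glance.dglm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged, degenerate = x$degenerate,
                 nobs = x$n)
}

#' @method tidy slm_fit
#' @export
tidy.slm_fit <- function(x, ...) {
  tibble::tibble(submodel = "mean", term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance slm_fit
#' @export
glance.slm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, sigma2 = x$sigma2,
                 degenerate = x$degenerate, nobs = x$n)
}

#' Serialize a DGLM fit to JSON
#' @param fit A `dglm_fit`.
#' @return JSON string with coefficients, standard errors, log-likelihood,
#'   and convergence metadata.
#' @export
dglm_to_json <- function(fit) {
  stopifnot(inherits(fit, "dglm_fit"))
  jsonlite::toJSON(list(
    mean = list(coefficients = as.list(fit$mean$coefficients),
                se = as.list(fit$mean$se)),
    variance = list(coefficients = as.list(fit$variance$coefficients),
                    se = as.list(fit$variance$se)),
    loglik = fit$loglik, iterations = fit$iterations,
    converged = fit$converged, degenerate = fit$degenerate, n = fit$n),
    auto_unbox = TRUE, digits = NA)
}

# gamma-GLM IRLS with log link and unit working weights (exact score
# equations for a log-linear dispersion model); stable when d has zeros
gamma_irls <- function(Z, d, phi_init, tol = 1e-11, maxit = 50) {
  phi <- phi_init
  eta <- drop(Z %*% phi)
  for (j in seq_len(maxit)) {
    mu <- exp(eta)
    z <- eta + (d - mu) / mu
    phi_new <- qr.solve(Z, z)
    delta <- max(abs(phi_new - phi))
    phi <- phi_new
    eta <- pmin(pmax(drop(Z %*% phi), log(1e-12)), 700)
    if (delta < tol) break
  }
  phi
}

#' Fit a Poisson double generalized linear model
#'
#' Mean submodel: Poisson regression with canonical log link. Dispersion
#' submodel: log-linear model for a per-individual dispersion
#' \eqn{\phi_i}, fitted as a gamma GLM on the squared Pearson residuals.
#' The two are alternated, with the mean submodel using prior weights
#' \eqn{1/\phi_i}. Model comparison uses the extended quasi-likelihood
#' \deqn{Q = -\tfrac12 \sum_i \left[ d_i/\phi_i +
#'   \log(2\pi \phi_i V(\tilde y_i)) \right],}
#' with \eqn{d_i} the unit Poisson deviance, \eqn{V(y) = y}, and
#' \eqn{\tilde y_i = \max(y_i, 1/6)} so zero counts contribute a finite
#' constant.
#'
#' @inheritParams fit_dglm
#' @param y Non-negative integer counts.
#' @return A `dglm_fit`-like object of class `c("dglm_poisson_fit",
#'   "dglm_fit")`; `loglik` holds the extended quasi-likelihood and the
#'   variance submodel coefficients are on the \eqn{\log\phi} scale.
#' @export
fit_dglm_poisson <- function(y, mean_design = NULL, var_design = NULL,
                             tol = 1e-8, maxit = 50) {
  if (anyNA(y)) bail("`y` has missing values; drop them before fitting.")
  if (any(y < 0) || any(y != floor(y))) bail("`y` must be non-negative counts.")
  if (all(y == 0)) bail("all counts are zero; the Poisson DGLM is degenerate.")
  n <- length(y)
  X <- build_design(mean_design, n)
  Z <- build_design(var_design, n)
  check_full_rank(X, "mean design")
  check_full_rank(Z, "variance design")

  phi_coef <- numeric(ncol(Z))
  w <- rep(1, n)
  eql_old <- -Inf
  converged <- FALSE
  yt <- pmax(y, 1 / 6)
  it <- 0
  beta <- NULL
  for (it in seq_len(maxit)) {
    mfit <- suppressWarnings(
      glm.fit(X, y, weights = w, family = poisson(),
              start = beta))
    beta <- mfit$coefficients
    mu <- mfit$fitted.values
    pearson2 <- (y - mu)^2 / mu
    phi_coef <- gamma_irls(Z, pearson2, phi_coef)
    phi <- exp(pmin(pmax(drop(Z %*% phi_coef), log(1e-12)), 700))
    w <- 1 / phi
    dev_unit <- poisson()$dev.resids(y, mu, rep(1, n))
    eql <- -0.5 * sum(dev_unit / phi + log(2 * pi * phi * yt))
    if (abs(eql - eql_old) < tol) { converged <- TRUE; break }
    eql_old <- eql
  }
  if (!converged) {
    warning("Poisson DGLM did not converge in ", maxit, " iterations",
            call. = FALSE)
  }
  # asymptotic SEs from the working information of each submodel
  W <- mu * w
  cb <- tryCatch(chol2inv(chol(crossprod(X * sqrt(W)))),
                 error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  cp <- tryCatch(2 * chol2inv(chol(crossprod(Z))),
                 error = function(e) matrix(NA_real_, ncol(Z), ncol(Z)))
  structure(list(
    mean = list(coefficients = setNames(beta, colnames(X)),
                se = setNames(sqrt(diag(cb)), colnames(X))),
    variance = list(coefficients = setNames(phi_coef, colnames(Z)),
                    se = setNames(sqrt(diag(cp)), colnames(Z))),
    fitted_mean = mu, fitted_dispersion = phi,
    loglik = eql, iterations = it, converged = converged,
    degenerate = any(phi <= 1e-12), n = n),
    class = c("dglm_poisson_fit", "dglm_fit"))
}

#' Single-locus QTL test statistics
#'
#' Computes the four statistics used in a mean-variance genome scan at one
#' locus, each a comparison of nested maximum-likelihood fits of the DGLM
#' (or SLM):
#' \itemize{
#'   \item `lr_mqtl`: full DGLM vs. the null omitting the locus effects on
#'     the mean (`beta_a = beta_d = 0`); 2 df.
#'   \item `lr_vqtl`: vs. the null omitting the locus effects on the
#'     variance (`gamma_a = gamma_d = 0`); 2 df.
#'   \item `lr_mvqtl`: vs. the null omitting both; 4 df.
#'   \item `lod_slm`: the traditional LOD score,
#'     `(n/2) log10(RSS0/RSS1)`.
#' }
#' Constant locus codings (no genotype information) are dropped from the
#' designs, so a completely uninformative locus yields all statistics 0.
#'
#' @param y Numeric phenotype (no missing values).
#' @param a,d Expected additive / dominance codings per individual (from
#'   [qtl_coding()], or exact 0/1/2 and 0/1 values).
#' @param mean_covariates,var_covariates Covariates for the two submodels
#'   (an intercept is always included); `NULL` for none.
#' @param tol,maxit Passed to the DGLM fitter.
#' @return A one-row tibble of class `qtl_tests`: `lr_mqtl`, `lr_vqtl`,
#'   `lr_mvqtl`, `lod_slm` and validity flags `valid_*`.
#' @export
lr_tests <- function(y, a, d, mean_covariates = NULL, var_covariates = NULL,
                     tol = 1e-8, maxit = 50) {
  if (anyNA(y)) bail("`y` has missing values; drop them before fitting.")
  n <- length(y)
  stopifnot(length(a) == n, length(d) == n)
  Xc <- build_design(mean_covariates, n)
  Zc <- build_design(var_covariates, n)
  locus <- cbind(a = a, d = d)
  keep <- apply(locus, 2, \(v) sd(v) > 0)
  G <- locus[, keep, drop = FALSE]
  # drop locus columns collinear with the covariates or with each other
  while (ncol(G) > 0 && qr(cbind(Xc, G))$rank < ncol(Xc) + ncol(G)) {
    G <- G[, -ncol(G), drop = FALSE]
  }
  if (ncol(G) == 0) {
    out <- tibble::tibble(lr_mqtl = 0, lr_vqtl = 0, lr_mvqtl = 0, lod_slm = 0,
                          valid_mqtl = TRUE, valid_vqtl = TRUE,
                          valid_mvqtl = TRUE, valid_slm = TRUE)
    class(out) <- c("qtl_tests", class(out))
    return(out)
  }
  Xf <- cbind(Xc, G)
  Zf <- cbind(Zc, G)
  fits <- list(
    full = cpp_dglm_fit(y, Xf, Zf, tol, maxit),
    null_m = cpp_dglm_fit(y, Xc, Zf, tol, maxit),
    null_v = cpp_dglm_fit(y, Xf, Zc, tol, maxit),
    null_mv = cpp_dglm_fit(y, Xc, Zc, tol, maxit))
  ok <- vapply(fits, \(f) f$converged && !f$degenerate, logical(1))
  lr <- function(nm) {
    if (!ok["full"] || !ok[nm]) return(NA_real_)
    max(0, 2 * (fits$full$loglik - fits[[nm]]$loglik))
  }
  s0 <- cpp_slm_fit(y, Xc)
  s1 <- cpp_slm_fit(y, Xf)
  lod <- if (s1$degenerate) NA_real_ else
    max(0, 0.5 * n * log10(s0$rss / s1$rss))
  out <- tibble::tibble(
    lr_mqtl = lr("null_m"), lr_vqtl = lr("null_v"), lr_mvqtl = lr("null_mv"),
    lod_slm = lod,
    valid_mqtl = ok["full"] && ok["null_m"],
    valid_vqtl = ok["full"] && ok["null_v"],
    valid_mvqtl = ok["full"] && ok["null_mv"],
    valid_slm = !s1$degenerate)
  class(out) <- c("qtl_tests", class(out))
  out
}

#' Percent variance explained by a QTL
#'
#' The traditional definition for an experimental cross,
#' \eqn{100 (1 - 10^{-2 \mathrm{LOD}/n})}. Supply either a LOD score or a
#' likelihood-ratio statistic (`lr = 2 ln(10) lod`).
#'
#' @param lod LOD score (ignored when `lr` is given).
#' @param n Sample size.
#' @param lr Likelihood-ratio statistic alternative to `lod`.
#' @return Percentage in \[0, 100).
#' @examples
#' pve(lod = 4.5, n = 244)
#' @export
pve <- function(lod = NULL, n, lr = NULL) {
  if (!is.null(lr)) lod <- lr / (2 * log(10))
  if (is.null(lod)) bail("supply `lod` or `lr`.")
  stopifnot(all(lod >= 0), n >= 1)
  100 * (1 - 10^(-2 * lod / n))
}
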