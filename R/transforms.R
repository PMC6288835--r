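#' Phenotype transformation specification
#'
#' A small record describing a deterministic phenotype transformation,
#' applied with [apply_transform()]. Supported kinds: `identity`, `log`,
#' `sqrt`, `power` (Box-Cox form `(y^lambda - 1)/lambda`, `log` at
#' `lambda = 0`), and `rint` (rank-based inverse normal). `shift` is added
#' to the data before `log`/`sqrt`/`power`, for count phenotypes with zeros.
#'
#' @param kind One of `"identity"`, `"log"`, `"sqrt"`, `"power"`, `"rint"`.
#' @param lambda Exponent for `kind = "power"`.
#' @param shift Non-negative offset applied before log/sqrt/power.
#' @return A `transform_spec` object.
#' @examples
#' apply_transform(c(1, exp(1)), transform_spec("log"))
#' @export
transform_spec <- function(kind = c("identity", "log", "sqrt", "power", "rint"),
                           lambda = NULL, shift = 0) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (is.null(lambda) || !is.finite(lambda)) {
      bail("`lambda` must be a finite number for a power transform.")
    }
  } else {
    lambda <- NULL
  }
  if (!is.numeric(shift) || shift < 0) bail("`shift` must be >= 0.")
  structure(list(kind = kind, lambda = lambda, shift = shift),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("transform:", x$kind,
      if (!is.null(x$lambda)) paste0("(lambda = ", signif(x$lambda, 4), ")"),
      if (x$shift != 0) paste0("[shift ", x$shift, "]"), "\n")
  invisible(x)
}

#' Serialize / deserialize a transform specification
#' @param spec A [transform_spec()].
#' @return `transform_to_json()`: a JSON string; `transform_from_json()`:
#'   a `transform_spec`.
#' @export
transform_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, null = "null")
}

#' @param json JSON string produced by `transform_to_json()`.
#' @rdname transform_to_json
#' @export
transform_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  transform_spec(kind = x$kind, lambda = x$lambda, shift = x$shift %||% 0)
}

#' Rank-based inverse normal transform
#'
#' Replaces each value by the normal quantile of its offset rank,
#' \eqn{\Phi^{-1}((r_i - 0.5)/n)}, with average ranks for ties and `n` the
#' number of non-missing values. The result depends on the data only
#' through its ranks, so it is invariant under strictly monotone
#' transformations of the input and limits the influence of outliers.
#' Missing values are passed through.
#'
#' @param y Numeric vector, length >= 2 after removing missing values.
#' @return Numeric vector of normal scores, same length as `y`.
#' @examples
#' rank_inverse_normal(c(3, 1, 2))
#' @export
rank_inverse_normal <- function(y) {
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < 2) bail("need at least 2 non-missing values.")
  if (n > 2 && diff(range(y[ok])) == 0) {
    bail("`y` is constant; ranks are undefined up to ties covering all data.")
  }
  out <- rep(NA_real_, length(y))
  r <- rank(y[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / n)
  out
}

#' Select a Box-Cox power transform by profile likelihood
#'
#' Profiles the Box-Cox log-likelihood (including the Jacobian term) of the
#' Gaussian linear model `y^(lambda) ~ design` over a grid of exponents and
#' returns the maximizing transform as a [transform_spec()]. The selection
#' design should contain covariates only (e.g. sex), not QTL terms, so the
#' choice of scale does not peek at genotype effects. The profile is
#' computed with [MASS::boxcox()].
#'
#' @param y Positive numeric vector (after adding `shift`).
#' @param design Covariate matrix or data frame for the mean model; an
#'   intercept is always included. `NULL` for intercept-only.
#' @param grid Candidate lambda values.
#' @param shift Non-negative offset added to `y` before transformation.
#' @return A `transform_spec` of kind `"power"` (or `"log"` when the
#'   selected lambda is 0), with the selected `lambda` and `shift`.
#' @examples
#' y <- exp(rnorm(200))
#' boxcox_select(y)$lambda # close to 0
#' @export
boxcox_select <- function(y, design = NULL, grid = seq(-2, 2, by = 0.05),
                          shift = 0) {
  if (length(grid) == 0) bail("`grid` must be non-empty.")
  ok <- !is.na(y)
  ys <- y[ok] + shift
  if (any(ys <= 0)) {
    bail("`y` has non-positive values after shift; supply a larger `shift`.")
  }
  if (is.null(design)) {
    X <- matrix(1, length(ys), 1)
  } else {
    X <- cbind(1, as.matrix(design)[ok, , drop = FALSE])
  }
  prof <- MASS::boxcox(ys ~ X - 1, lambda = grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  if (lambda == 0) {
    transform_spec("log", shift = shift)
  } else {
    transform_spec("power", lambda = lambda, shift = shift)
  }
}

#' Apply a transform specification to a phenotype
#'
#' Deterministic elementwise application; missing values are preserved.
#' `power` uses the Box-Cox form `((y + shift)^lambda - 1)/lambda`.
#'
#' @param y Numeric vector.
#' @param spec A [transform_spec()].
#' @return Transformed numeric vector.
#' @export
apply_transform <- function(y, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  ok <- !is.na(y)
  ys <- y[ok] + spec$shift
  out <- rep(NA_real_, length(y))
  out[ok] <- switch(
    spec$kind,
    identity = y[ok],
    log = {
      if (any(ys <= 0)) bail("log transform needs positive values; ",
                             "supply a larger `shift`.")
      log(ys)
    },
    sqrt = {
      if (any(ys < 0)) bail("sqrt transform needs non-negative values.")
      sqrt(ys)
    },
    power = if (spec$lambda == 0) log(ys) else (ys^spec$lambda - 1) / spec$lambda,
    rint = return(rank_inverse_normal(y))
  )
  out
}
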