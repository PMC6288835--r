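#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() without the call, with paste0 semantics
bail <- function(...) stop(paste0(...), call. = FALSE)

#' Haldane map function
#'
#' Convert a genetic distance in centimorgans to a recombination fraction
#' under the Haldane (no-interference) map function,
#' \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d Genetic distance in cM (vectorized, non-negative).
#' @return Recombination fraction(s) in \[0, 0.5).
#' @examples
#' haldane(20)
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d / 100)) / 2
}

# F2 genotype transition matrix between two loci at recombination fraction r
# (two independent meioses). Rows/cols ordered AA, AB, BB.
f2_transition <- function(r) {
  matrix(c(
    (1 - r)^2,     2 * r * (1 - r), r^2,
    r * (1 - r),   (1 - r)^2 + r^2, r * (1 - r),
    r^2,           2 * r * (1 - r), (1 - r)^2
  ), nrow = 3, byrow = TRUE)
}

# natural chromosome order: 1..19 numerically, then X, Y, others last
chrom_order <- function(chr) {
  u <- unique(as.character(chr))
  num <- suppressWarnings(as.numeric(u))
  ord <- order(is.na(num), num, match(u, c("X", "Y")), u)
  factor(as.character(chr), levels = u[ord])
}

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    bail("`seed` must be a single integer.")
  }
  as.integer(seed)
}
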