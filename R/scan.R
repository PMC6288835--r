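# Genome scan: apply the single-locus tests at every evaluation position.

.all_tests <- c("slm", "mqtl", "vqtl", "mvqtl")

# Align phenotype/covariates with the genotype probabilities, drop
# incomplete cases once (the same individuals are used at every locus),
# and build the covariate design matrices for the two submodels.
prepare_scan_inputs <- function(probs, phenotype, covariates = NULL,
                                covariate_roles = NULL) {
  stopifnot(inherits(probs, "genoprob"))
  n <- dim(probs$probs)[1]
  if (length(phenotype) != n) {
    bail("phenotype has length ", length(phenotype),
         " but probabilities cover ", n, " individuals.")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) bail("covariates must have one row per individual.")
  }
  cc <- !is.na(phenotype)
  if (!is.null(covariates)) cc <- cc & complete.cases(covariates)
  y <- phenotype[cc]
  mean_cov <- var_cov <- NULL
  if (!is.null(covariates) && ncol(covariates) > 0) {
    cv <- covariates[cc, , drop = FALSE]
    roles <- covariate_roles %||%
      setNames(rep("both", ncol(cv)), names(cv))
    bad <- setdiff(names(roles), names(cv))
    if (length(bad) > 0) bail("covariate_roles names not in covariates: ",
                              paste(bad, collapse = ", "))
    bad_role <- setdiff(unique(roles), c("mean", "variance", "both"))
    if (length(bad_role) > 0) bail("covariate roles must be mean/variance/both.")
    mc <- names(roles)[roles %in% c("mean", "both")]
    vc <- names(roles)[roles %in% c("variance", "both")]
    if (length(mc) > 0) mean_cov <- as.matrix(cv[mc])
    if (length(vc) > 0) var_cov <- as.matrix(cv[vc])
  }
  Xc <- build_design(mean_cov, length(y))
  Zc <- build_design(var_cov, length(y))
  cod <- coding_matrices(probs)
  list(y = y, Xc = Xc, Zc = Zc,
       A = cod$A[cc, , drop = FALSE], D = cod$D[cc, , drop = FALSE],
       n = length(y), keep = cc)
}

#' Mean-variance QTL genome scan
#'
#' Fits the single-locus models at every evaluation position and records,
#' per locus, the likelihood-ratio statistics for the mQTL, vQTL, and mvQTL
#' tests and the traditional SLM LOD score (see [lr_tests()] for the model
#' comparisons). Covariates enter both submodels by default; individuals
#' with a missing phenotype or covariate are dropped once, so the same
#' sample is used at every locus.
#'
#' @param probs A [calc_genoprob()] `genoprob` object.
#' @param phenotype Numeric vector, one value per individual in `probs`.
#' @param covariates Optional data frame of covariates (e.g. `sex` coded
#'   0/1), one row per individual.
#' @param tests Subset of `c("slm", "mqtl", "vqtl", "mvqtl")`.
#' @param covariate_roles Optional named character vector assigning each
#'   covariate to `"mean"`, `"variance"`, or `"both"` (default both).
#' @param phenotype_name Label stored in the scan metadata.
#' @param tol,maxit DGLM fitter controls.
#' @return An `mvqtl_scan` tibble: one row per locus with `chr`, `pos`,
#'   `locus`, the requested statistics, and `valid_*` flags; metadata
#'   (phenotype name, covariates, n, tests) in `attr(, "meta")`.
#' @examples
#' cr <- simulate_f2(sim_config(n = 60, seed = 2))
#' pr <- calc_genoprob(cr, error_prob = 0.0001)
#' scan_genome(pr, cr$pheno$y, covariates = cr$pheno["sex"])
#' @export
scan_genome <- function(probs, phenotype, covariates = NULL,
                        tests = .all_tests, covariate_roles = NULL,
                        phenotype_name = "phenotype",
                        tol = 1e-8, maxit = 50) {
  tests <- match.arg(tests, .all_tests, several.ok = TRUE)
  inp <- prepare_scan_inputs(probs, phenotype, covariates, covariate_roles)
  if (inp$n < ncol(inp$Xc) + ncol(inp$Zc) + 4 + 2) {
    bail("only ", inp$n, " complete-case individuals; too few to fit the ",
         "locus models.")
  }
  flags <- .all_tests %in% tests
  sc <- cpp_scan(inp$y, inp$Xc, inp$Zc, inp$A, inp$D, flags, tol, maxit)
  out <- tibble::tibble(
    chr = probs$map$chr, pos = probs$map$pos, locus = probs$map$locus)
  if ("slm" %in% tests) {
    out$lod_slm <- drop(sc$lod_slm)
    out$valid_slm <- sc$valid[, 1] == 1
  }
  if ("mqtl" %in% tests) {
    out$lr_mqtl <- drop(sc$lr_mqtl)
    out$valid_mqtl <- sc$valid[, 2] == 1
  }
  if ("vqtl" %in% tests) {
    out$lr_vqtl <- drop(sc$lr_vqtl)
    out$valid_vqtl <- sc$valid[, 3] == 1
  }
  if ("mvqtl" %in% tests) {
    out$lr_mvqtl <- drop(sc$lr_mvqtl)
    out$valid_mvqtl <- sc$valid[, 4] == 1
  }
  out <- out[order(chrom_order(out$chr), out$pos), ]
  attr(out, "meta") <- list(
    phenotype = phenotype_name,
    covariates = if (is.null(covariates)) character(0) else names(covariates),
    tests = tests, n = inp$n)
  class(out) <- c("mvqtl_scan", class(out))
  out
}

#' Top marker of a scan
#'
#' The locus with the strongest evidence for the chosen test: maximal LR
#' (or LOD), or minimal FWER-adjusted p-value when [fwer_adjust()] has
#' added one. Exact ties are broken by the earlier genome position (lowest
#' chromosome, then position).
#'
#' @param scan An `mvqtl_scan`.
#' @param test One of `"slm"`, `"mqtl"`, `"vqtl"`, `"mvqtl"`.
#' @return The one-row tibble for the top locus.
#' @export
top_marker <- function(scan, test = "mqtl") {
  test <- match.arg(test, .all_tests)
  stat_col <- if (test == "slm") "lod_slm" else paste0("lr_", test)
  if (!stat_col %in% names(scan)) bail("scan does not contain the ", test,
                                       " test.")
  p_col <- paste0("p_", test)
  valid_col <- paste0("valid_", test)
  ok <- scan[[valid_col]] & !is.na(scan[[stat_col]])
  if (!any(ok)) bail("no valid loci for the ", test, " test.")
  key <- if (p_col %in% names(scan)) -scan[[p_col]] else scan[[stat_col]]
  key[!ok] <- -Inf
  ord <- order(-key, chrom_order(scan$chr), scan$pos)
  scan[ord[1], ]
}

#' Write / read a genome scan as TSV
#'
#' One row per locus; scan metadata is stored in a `#`-prefixed JSON header
#' line and restored by `read_scan()`.
#'
#' @param scan An `mvqtl_scan`.
#' @param path File path.
#' @return `write_scan()`: `path`, invisibly; `read_scan()`: the scan.
#' @export
write_scan <- function(scan, path) {
  meta <- attr(scan, "meta")
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)), path)
  readr::write_tsv(tibble::as_tibble(scan), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  first <- readLines(path, n = 1)
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           chr = readr::col_character(),
                           locus = readr::col_character(),
                           .default = readr::col_guess()))
  if (startsWith(first, "# ")) {
    attr(out, "meta") <- jsonlite::fromJSON(sub("^# ", "", first))
  }
  class(out) <- c("mvqtl_scan", class(out))
  out
}

#' @export
print.mvqtl_scan <- function(x, ...) {
  meta <- attr(x, "meta")
  if (!is.null(meta)) {
    cat("mean-variance QTL scan of '", meta$phenotype, "' (n = ", meta$n,
        "), tests: ", paste(meta$tests, collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Plot a genome scan
#'
#' One panel per chromosome; when FWER-adjusted p-values are present the
#' vertical axis shows `-log10(p)` per test, otherwise the raw LR/LOD
#' statistics.
#'
#' @param object An `mvqtl_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvqtl_scan
#' @export
autoplot.mvqtl_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p_cols <- grep("^p_", names(df), value = TRUE)
  if (length(p_cols) > 0) {
    long <- tidyr::pivot_longer(df, dplyr::all_of(p_cols),
                                names_to = "test", names_prefix = "p_",
                                values_to = "p")
    long$yval <- -log10(long$p)
    ylab <- expression(-log[10] ~ "FWER-adjusted p")
  } else {
    stat_cols <- intersect(c("lod_slm", "lr_mqtl", "lr_vqtl", "lr_mvqtl"),
                           names(df))
    long <- tidyr::pivot_longer(df, dplyr::all_of(stat_cols),
                                names_to = "test", values_to = "yval")
    long$test <- sub("^(lod|lr)_", "", long$test)
    ylab <- "LR statistic (LOD for slm)"
  }
  long$chr <- chrom_order(long$chr)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$yval,
                                     color = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = ylab, color = "test") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
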