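#' Genotype probabilities along the genome
#'
#' Computes, for every individual and every evaluation locus, the posterior
#' probability of each F2 genotype (AA, AB, BB) given all observed marker
#' genotypes on that chromosome. The calculation is the standard three-state
#' hidden Markov forward-backward pass for an intercross: the prior at the
#' first locus is (1/4, 1/2, 1/4), transitions between adjacent loci come
#' from the Haldane recombination fraction for two independent meioses, and
#' emissions allow a per-marker genotyping error rate (a wrong code is
#' observed with probability `error_prob`, split evenly between the two
#' incorrect genotypes).
#'
#' @param cross An [new_cross()] `f2cross`.
#' @param step Pseudomarker spacing in cM; `0` (default) evaluates at the
#'   genotyped markers only.
#' @param error_prob Genotyping error probability, in \[0, 0.5).
#' @return A `genoprob` object: list with `probs` (array, individuals x
#'   loci x 3 genotype states), `map` (tibble of loci: `locus`, `chr`,
#'   `pos`, `at_marker`), and `ids`.
#' @examples
#' cr <- simulate_f2(sim_config(n = 10, seed = 1))
#' pr <- calc_genoprob(cr, error_prob = 0)
#' dim(pr$probs)
#' @export
calc_genoprob <- function(cross, step = 0, error_prob = 1e-4) {
  stopifnot(inherits(cross, "f2cross"))
  if (step < 0) bail("`step` must be non-negative.")
  if (error_prob < 0 || error_prob >= 0.5) {
    bail("`error_prob` must be in [0, 0.5).")
  }
  chrs <- unique(cross$map$chr)
  if (any(toupper(chrs) == "X")) {
    warning("X chromosome treated as an autosome", call. = FALSE)
  }
  n <- nrow(cross$geno)
  obs_all <- matrix(match(cross$geno, c("AA", "AB", "BB")), nrow = n)
  obs_all[is.na(obs_all)] <- 0L

  pieces <- purrr::map(chrs, function(ch) {
    midx <- which(cross$map$chr == ch)
    if (length(midx) == 0) bail("chromosome ", ch, " has no markers.")
    mpos <- cross$map$pos[midx]
    loci <- tibble::tibble(locus = cross$map$marker[midx], pos = mpos,
                           at_marker = TRUE, obs_col = midx)
    if (step > 0 && diff(range(mpos)) > 0) {
      grid <- seq(min(mpos), max(mpos), by = step)
      grid <- grid[!grid %in% mpos]
      if (length(grid) > 0) {
        loci <- dplyr::bind_rows(loci, tibble::tibble(
          locus = sprintf("c%s.loc%g", ch, grid), pos = grid,
          at_marker = FALSE, obs_col = NA_integer_))
      }
    }
    loci <- dplyr::arrange(loci, .data$pos, dplyr::desc(.data$at_marker))
    L <- nrow(loci)

    emis <- function(l) {
      if (!loci$at_marker[l]) return(matrix(1, n, 3))
      o <- obs_all[, loci$obs_col[l]]
      E <- matrix(1, n, 3)
      typed <- o > 0
      if (any(typed)) {
        E[typed, ] <- error_prob / 2
        E[cbind(which(typed), o[typed])] <- 1 - error_prob
      }
      E
    }

    trans <- purrr::map(seq_len(max(L - 1, 0)), function(l) {
      f2_transition(haldane(loci$pos[l + 1] - loci$pos[l]))
    })

    prior <- c(0.25, 0.5, 0.25)
    slice <- function(arr, l) matrix(arr[, , l], n, 3)
    alpha <- array(0, c(n, 3, L))
    a <- sweep(emis(1), 2, prior, `*`)
    alpha[, , 1] <- a / rowSums(a)
    if (L > 1) {
      for (l in 2:L) {
        a <- (slice(alpha, l - 1) %*% trans[[l - 1]]) * emis(l)
        alpha[, , l] <- a / rowSums(a)
      }
    }
    beta <- array(0, c(n, 3, L))
    beta[, , L] <- 1
    if (L > 1) {
      for (l in (L - 1):1) {
        b <- (slice(beta, l + 1) * emis(l + 1)) %*% t(trans[[l]])
        beta[, , l] <- b / rowSums(b)
      }
    }
    post <- array(0, c(n, L, 3))
    for (l in seq_len(L)) {
      pp <- slice(alpha, l) * slice(beta, l)
      post[, l, ] <- pp / rowSums(pp)
    }
    list(map = dplyr::mutate(loci[c("locus", "pos", "at_marker")],
                             chr = ch, .after = "locus"),
         probs = post)
  })

  probs <- array(NA_real_, c(n, sum(purrr::map_int(pieces, \(p) nrow(p$map))), 3),
                 dimnames = list(NULL, NULL, c("AA", "AB", "BB")))
  off <- 0
  for (p in pieces) {
    probs[, off + seq_len(nrow(p$map)), ] <- p$probs
    off <- off + nrow(p$map)
  }
  map <- dplyr::bind_rows(purrr::map(pieces, "map"))
  dimnames(probs)[[2]] <- map$locus
  structure(list(probs = probs, map = map, ids = cross$pheno$id),
            class = "genoprob")
}

#' @export
print.genoprob <- function(x, ...) {
  cat("genotype probabilities:", dim(x$probs)[1], "individuals x",
      dim(x$probs)[2], "loci on", length(unique(x$map$chr)),
      "chromosome(s)\n")
  invisible(x)
}

#' @method as_tibble genoprob
#' @export
as_tibble.genoprob <- function(x, ...) {
  L <- nrow(x$map)
  n <- length(x$ids)
  tibble::tibble(
    id = rep(x$ids, times = L),
    chr = rep(x$map$chr, each = n),
    pos = rep(x$map$pos, each = n),
    locus = rep(x$map$locus, each = n),
    pAA = as.vector(x$probs[, , "AA"]),
    pAB = as.vector(x$probs[, , "AB"]),
    pBB = as.vector(x$probs[, , "BB"])
  )
}

#' Export genotype probabilities as long-format TSV
#' @param probs A `genoprob` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genoprob <- function(probs, path) {
  readr::write_tsv(tibble::as_tibble(probs), path)
  invisible(path)
}

#' Restrict genotype probabilities to selected chromosomes
#' @param probs A `genoprob` object.
#' @param chr Character vector of chromosome names to keep.
#' @return A `genoprob` object covering only `chr`.
#' @export
subset_genoprob <- function(probs, chr) {
  keep <- probs$map$chr %in% chr
  if (!any(keep)) bail("chromosome(s) not found: ", paste(chr, collapse = ", "))
  structure(list(probs = probs$probs[, keep, , drop = FALSE],
                 map = probs$map[keep, ], ids = probs$ids),
            class = "genoprob")
}

#' Expected QTL design coding at a locus
#'
#' Converts posterior genotype probabilities into the additive/dominance
#' coding used in the scan models: the expected count of the B allele,
#' `a = 2*pBB + pAB` (in \[0, 2\]), and the expected heterozygosity,
#' `d = pAB` (in \[0, 1\]). For a known genotype these reduce to
#' a in \{0, 1, 2\} and d in \{0, 1\}.
#'
#' @param probs A `genoprob` object.
#' @param locus Locus name or index.
#' @return Tibble with columns `id`, `a`, `d`.
#' @export
qtl_coding <- function(probs, locus) {
  if (is.character(locus)) locus <- match(locus, probs$map$locus)
  if (is.na(locus) || locus < 1 || locus > nrow(probs$map)) {
    bail("locus out of range.")
  }
  p <- probs$probs[, locus, , drop = TRUE]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, c("AA", "AB", "BB")))
  tibble::tibble(id = probs$ids,
                 a = unname(2 * p[, "BB"] + p[, "AB"]),
                 d = unname(p[, "AB"]))
}

# n x L matrices of the expected additive / dominance codings for all loci
coding_matrices <- function(probs) {
  n <- dim(probs$probs)[1]
  L <- dim(probs$probs)[2]
  list(A = matrix(2 * probs$probs[, , "BB"] + probs$probs[, , "AB"], n, L),
       D = matrix(probs$probs[, , "AB"], n, L))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
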