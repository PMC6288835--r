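#' Construct an F2 cross object
#'
#' Bundles genotypes, the marker map, and the phenotype table for one
#' mapping population. Most users will create one via [read_cross()] or
#' [simulate_f2()] rather than calling this directly.
#'
#' @param geno Character matrix, individuals x markers, with entries in
#'   `"AA"`, `"AB"`, `"BB"` or `NA` for missing.
#' @param map Data frame with columns `marker`, `chr`, `pos` (cM), one row
#'   per marker, in genome order. Positions must be non-decreasing within
#'   each chromosome and chromosomes must form contiguous blocks.
#' @param pheno Data frame of per-individual phenotypes and covariates, one
#'   row per individual. A column named `id` holds individual identifiers
#'   (created as `"1"`, `"2"`, ... when absent). Sex, when used as a
#'   covariate, should be coded 0/1.
#' @return An object of class `f2cross`: a list with elements `geno`,
#'   `map` (tibble), and `pheno` (tibble).
#' @export
new_cross <- function(geno, map, pheno) {
  map <- tibble::as_tibble(map)
  pheno <- tibble::as_tibble(pheno)
  if (!all(c("marker", "chr", "pos") %in% names(map))) {
    bail("`map` must have columns marker, chr, pos.")
  }
  map$chr <- as.character(map$chr)
  map$pos <- as.numeric(map$pos)
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map)) {
    bail("genotype matrix has ", ncol(geno), " columns but map has ",
          nrow(map), " markers.")
  }
  if (nrow(pheno) != nrow(geno)) {
    bail("phenotype table has ", nrow(pheno), " rows but genotype matrix has ",
          nrow(geno), " individuals.")
  }
  if (anyDuplicated(map$marker)) {
    bail("duplicated marker names: ",
          paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  }
  rl <- rle(map$chr)
  if (anyDuplicated(rl$values)) {
    bail("chromosomes must form contiguous blocks in the map.")
  }
  bad_pos <- map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad_pos) > 0) {
    bail("marker positions decrease within chromosome(s): ",
          paste(bad_pos$chr, collapse = ", "))
  }
  bad <- setdiff(unique(geno[!is.na(geno)]), c("AA", "AB", "BB"))
  if (length(bad) > 0) {
    bail("unknown genotype code(s): ", paste(bad, collapse = ", "))
  }
  if (!"id" %in% names(pheno)) {
    pheno <- dplyr::mutate(pheno, id = as.character(seq_len(nrow(pheno))),
                           .before = 1)
  }
  pheno$id <- as.character(pheno$id)
  colnames(geno) <- map$marker
  rownames(geno) <- NULL
  structure(list(geno = geno, map = map, pheno = pheno), class = "f2cross")
}

#' @export
print.f2cross <- function(x, ...) {
  cat("F2 cross:", nrow(x$geno), "individuals,", nrow(x$map), "markers on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  ph <- setdiff(names(x$pheno), "id")
  cat("phenotypes/covariates:", paste(ph, collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals in a cross
#' @param cross An `f2cross`.
#' @return Integer count.
#' @export
n_individuals <- function(cross) nrow(cross$geno)

# genotype-code dialects accepted on input
.geno_dialects <- list(
  c(AA = "A", AB = "H", BB = "B"),
  c(AA = "AA", AB = "AB", BB = "BB"),
  c(AA = "1", AB = "2", BB = "3")
)

normalize_geno_codes <- function(g, na_tokens = c("-", "NA", "")) {
  g[g %in% na_tokens | is.na(g)] <- NA_character_
  seen <- unique(g[!is.na(g)])
  for (dial in .geno_dialects) {
    if (all(seen %in% dial)) {
      lookup <- setNames(names(dial), dial)
      out <- g
      out[!is.na(g)] <- lookup[g[!is.na(g)]]
      return(out)
    }
  }
  bad <- setdiff(seen, unlist(.geno_dialects))
  if (length(bad) == 0) bad <- seen # codes mix dialects
  bail("unknown genotype code(s): ", paste(utils::head(bad, 5), collapse = ", "))
}

#' Read a cross from an R/qtl-style CSV file
#'
#' Parses the rotated-header CSV layout used by R/qtl and the public mouse
#' cross archives: row 1 holds phenotype names followed by marker names,
#' row 2 is blank under phenotypes and holds the chromosome under each
#' marker, row 3 likewise holds the cM position, and each subsequent row is
#' one individual. Genotype codes `{A,H,B}`, `{AA,AB,BB}`, or `{1,2,3}` are
#' accepted and normalized to `AA`/`AB`/`BB`; `-`, `NA`, and empty cells are
#' treated as missing.
#'
#' @param path Path to the CSV file.
#' @param na_tokens Strings interpreted as missing genotypes.
#' @return An [new_cross()] `f2cross` object.
#' @examples
#' cr <- simulate_f2(sim_config(n = 20, seed = 1))
#' tf <- tempfile(fileext = ".csv")
#' write_cross(cr, tf)
#' read_cross(tf)
#' @export
read_cross <- function(path, na_tokens = c("-", "NA", "")) {
  if (!file.exists(path)) bail("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         strip.white = TRUE)
  if (nrow(raw) < 4) bail("malformed cross file: need header, chromosome, ",
                           "position rows plus at least one individual.")
  header <- as.character(raw[1, ])
  chr_row <- as.character(raw[2, ])
  pos_row <- as.character(raw[3, ])
  is_marker <- !(chr_row %in% c("", NA))
  if (!any(is_marker)) bail("malformed header: no marker columns found ",
                             "(chromosome row is empty).")
  if (!any(!is_marker)) bail("malformed header: no phenotype columns found.")
  if (any(header[is_marker] %in% c("", NA))) {
    bail("malformed header: unnamed marker column at position ",
          which(is_marker & header %in% c("", NA))[1])
  }
  pos <- suppressWarnings(as.numeric(pos_row[is_marker]))
  if (anyNA(pos)) {
    bad <- which(is_marker)[which(is.na(pos))[1]]
    bail("non-numeric position '", pos_row[bad], "' in position row, column ",
          bad, " (marker ", header[bad], ")")
  }
  body <- raw[-(1:3), , drop = FALSE]
  map <- tibble::tibble(marker = header[is_marker],
                        chr = chr_row[is_marker], pos = pos)
  geno <- as.matrix(body[, is_marker, drop = FALSE])
  geno <- matrix(normalize_geno_codes(geno, na_tokens), nrow = nrow(body),
                 dimnames = list(NULL, map$marker))
  pheno <- body[, !is_marker, drop = FALSE]
  names(pheno) <- header[!is_marker]
  pheno <- tibble::as_tibble(pheno)
  id_col <- which(tolower(names(pheno)) %in% c("id", "index"))
  if (length(id_col) > 0) names(pheno)[id_col[1]] <- "id"
  pheno <- dplyr::mutate(pheno, dplyr::across(
    -dplyr::any_of("id"),
    \(x) {
      x[x %in% c("", "NA", "-")] <- NA
      num <- suppressWarnings(as.numeric(x))
      if (all(is.na(num) == is.na(x))) num else x
    }
  ))
  new_cross(geno, map, pheno)
}

#' Write a cross to an R/qtl-style CSV file
#'
#' Inverse of [read_cross()]: the written file round-trips losslessly,
#' including missing genotype cells (serialized as `-`).
#'
#' @param cross An `f2cross`.
#' @param path Output path.
#' @param codes Length-3 character vector used for AA/AB/BB on disk.
#' @return `path`, invisibly.
#' @export
write_cross <- function(cross, path, codes = c("A", "H", "B")) {
  stopifnot(inherits(cross, "f2cross"))
  ph <- setdiff(names(cross$pheno), "id")
  if (length(ph) == 0) bail("cross has no phenotype columns; at least one ",
                             "phenotype is required to write a cross file.")
  lookup <- setNames(codes, c("AA", "AB", "BB"))
  g <- cross$geno
  g[] <- ifelse(is.na(g), "-", lookup[g])
  pheno_cols <- c("id", ph)
  header <- c(pheno_cols, cross$map$marker)
  chr_row <- c(rep("", length(pheno_cols)), cross$map$chr)
  pos_row <- c(rep("", length(pheno_cols)), as.character(cross$map$pos))
  body <- cbind(as.matrix(dplyr::mutate(cross$pheno[pheno_cols],
                                        dplyr::across(dplyr::everything(),
                                                      as.character))), g)
  body[is.na(body)] <- "NA"
  out <- rbind(header, chr_row, pos_row, body)
  con <- tryCatch(file(path, "w"), error = function(e) {
    bail("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
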