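test_that("read_cross parses the rotated-header dialect and maps codes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(tf)
  cr <- read_cross(tf)
  expect_s3_class(cr, "f2cross")
  expect_equal(n_individuals(cr), 4)
  expect_equal(cr$map$marker, c("m1", "m2"))
  expect_equal(cr$map$pos, c(0, 20))
  expect_equal(cr$geno[, "m1"], c("AA", "AB", "BB", "AA"))
  expect_true(is.na(cr$geno[3, "m2"]))
  expect_equal(sort(setdiff(names(cr$pheno), "id")), c("bw", "sex"))
  expect_true(is.na(cr$pheno$bw[4]))

  # numeric 1/2/3 dialect normalizes to the same cross
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(tf2, codes = c("1", "2", "3", "NA"))
  expect_equal(read_cross(tf2)$geno, cr$geno)
})

test_that("read_cross rejects malformed files without partial output", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,bw,m1", ",,1", ",,abc", "1,5,A", "2,6,H"), tf)
  expect_error(read_cross(tf), "non-numeric position.*abc.*m1")

  writeLines(c("id,bw,m1", ",,1", ",,0", "1,5,Q", "2,6,H"), tf)
  expect_error(read_cross(tf), "unknown genotype code.*Q")

  writeLines(c("id,bw", ",", ",", "1,5"), tf)
  expect_error(read_cross(tf), "no marker columns")
})

test_that("write_cross / read_cross round-trips losslessly", {
  cr <- simulate_f2(sim_config(n = 10, chromosomes = 2, markers_per_chr = 4,
                               seed = 5))
  cr$geno[c(1, 7, 23)] <- NA # missing genotypes survive the round trip
  cr$pheno$y[3] <- NA
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cross(cr, tf)
  back <- read_cross(tf)
  expect_equal(back$geno, cr$geno)
  expect_equal(back$map, cr$map)
  expect_equal(back$pheno$y, cr$pheno$y)
  expect_equal(back$pheno$sex, cr$pheno$sex)
  expect_equal(back$pheno$id, cr$pheno$id)

  cr$pheno <- cr$pheno["id"]
  expect_error(write_cross(cr, tf), "at least one phenotype")
})

test_that("new_cross enforces its invariants", {
  g <- matrix("AA", 2, 2)
  map <- data.frame(marker = c("a", "b"), chr = "1", pos = c(0, 10))
  ph <- data.frame(y = c(1, 2))
  expect_s3_class(new_cross(g, map, ph), "f2cross")
  expect_error(new_cross(g, map[1, ], ph), "2 columns but map has 1")
  expect_error(new_cross(g, map, ph[1, , drop = FALSE]), "1 rows")
  expect_error(
    new_cross(g, data.frame(marker = c("a", "a"), chr = "1", pos = c(0, 1)),
              ph), "duplicated marker")
  expect_error(
    new_cross(g, data.frame(marker = c("a", "b"), chr = "1", pos = c(10, 0)),
              ph), "decrease")
  g2 <- g; g2[1] <- "XX"
  expect_error(new_cross(g2, map, ph), "unknown genotype")
  # interleaved chromosome blocks are rejected
  map3 <- data.frame(marker = c("a", "b", "c"), chr = c("1", "2", "1"),
                     pos = c(0, 0, 5))
  expect_error(new_cross(matrix("AA", 2, 3), map3, ph), "contiguous")
})

test_that("genotype posteriors are degenerate at typed markers and revert to the F2 prior", {
  cr <- one_ind_cross(c(1, 0), pos = c(0, 20))
  pr <- calc_genoprob(cr, error_prob = 0)
  expect_equal(unname(pr$probs[1, 1, ]), c(1, 0, 0))

  cr2 <- one_ind_cross(c(0, 0), pos = c(0, 20))
  pr2 <- calc_genoprob(cr2, error_prob = 0)
  expect_equal(unname(pr2$probs[1, 1, ]), c(0.25, 0.5, 0.25))
  expect_equal(unname(pr2$probs[1, 2, ]), c(0.25, 0.5, 0.25))
})

test_that("forward-backward equals brute-force enumeration on short chromosomes", {
  set.seed(401)
  for (rep in 1:25) {
    M <- sample(2:4, 1)
    pos <- sort(runif(M, 0, 60))
    ep <- sample(c(0, 1e-4, 0.02), 1)
    obs <- sample(0:3, M, replace = TRUE)
    pr <- calc_genoprob(one_ind_cross(obs, pos), error_prob = ep)
    expect_lt(max(abs(pr$probs[1, , ] - brute_force_posterior(obs, pos, ep))),
              1e-9)
  }
})

test_that("posteriors normalize and collapse when a typed marker is added", {
  cr <- simulate_f2(sim_config(n = 40, chromosomes = 2, markers_per_chr = 6,
                               seed = 6))
  cr$geno[sample(length(cr$geno), 40)] <- NA
  pr <- calc_genoprob(cr, step = 5, error_prob = 1e-4)
  sums <- apply(pr$probs, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)

  # monotone information: with error_prob = 0 a typed marker pins the state
  pr0 <- calc_genoprob(cr, error_prob = 0)
  typed <- which(!is.na(cr$geno), arr.ind = TRUE)
  code <- match(cr$geno[typed], c("AA", "AB", "BB"))
  picked <- cbind(typed[, 1], typed[, 2], code)
  expect_equal(unname(pr0$probs[picked]), rep(1, nrow(picked)))
})

test_that("pseudomarker posteriors match enumeration over the two meioses", {
  # flanking AA and AB, 20 cM apart, queried at the midpoint
  cr <- one_ind_cross(c(1, 2), pos = c(0, 20))
  pr <- calc_genoprob(cr, step = 10, error_prob = 0)
  mid <- which(pr$map$locus == "c1.loc10")
  # oracle: insert an untyped locus and enumerate
  oracle <- brute_force_posterior(c(1, 0, 2), c(0, 10, 20), 0)[2, ]
  expect_equal(unname(pr$probs[1, mid, ]), oracle, tolerance = 1e-12)
})

test_that("calc_genoprob validates inputs and flags the X chromosome", {
  cr <- simulate_f2(sim_config(n = 10, seed = 1))
  expect_error(calc_genoprob(cr, step = -1), "non-negative")
  expect_error(calc_genoprob(cr, error_prob = 0.7), "0.5")
  crx <- cr
  crx$map$chr <- rep("X", nrow(crx$map))
  expect_warning(calc_genoprob(crx), "X chromosome")
})

test_that("qtl_coding is the expected allele count and heterozygosity", {
  cr <- one_ind_cross(c(1, 0), pos = c(0, 20))
  pr <- calc_genoprob(cr, error_prob = 0)
  expect_equal(qtl_coding(pr, 1)$a, 0)
  expect_equal(qtl_coding(pr, 1)$d, 0)

  cr2 <- one_ind_cross(c(2, 0), pos = c(0, 20))
  pr2 <- calc_genoprob(cr2, error_prob = 0)
  expect_equal(qtl_coding(pr2, 1)$a, 1)
  expect_equal(qtl_coding(pr2, 1)$d, 1)

  cr3 <- one_ind_cross(c(0, 0), pos = c(0, 20))
  pr3 <- calc_genoprob(cr3, error_prob = 0)
  expect_equal(qtl_coding(pr3, "m1")$a, 1)     # linear in the prior
  expect_equal(qtl_coding(pr3, "m1")$d, 0.5)
  expect_error(qtl_coding(pr3, 99), "out of range")
})

test_that("genoprob exports to long-format TSV", {
  cr <- simulate_f2(sim_config(n = 5, chromosomes = 1, markers_per_chr = 3,
                               seed = 2))
  pr <- calc_genoprob(cr)
  tab <- as_tibble(pr)
  expect_equal(nrow(tab), 5 * 3)
  expect_named(tab, c("id", "chr", "pos", "locus", "pAA", "pAB", "pBB"))
  expect_lt(max(abs(tab$pAA + tab$pAB + tab$pBB - 1)), 1e-9)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_genoprob(pr, tf)
  expect_equal(nrow(readr::read_tsv(tf, show_col_types = FALSE)), 15)
})
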