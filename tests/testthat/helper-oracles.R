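# Independent oracles used across tests.

# Brute-force F2 genotype posterior for one individual: enumerate all 3^M
# hidden genotype sequences, weight by prior x Haldane transitions x
# emissions, and marginalize. obs codes: 0 missing, 1 AA, 2 AB, 3 BB.
brute_force_posterior <- function(obs, pos, error_prob) {
  M <- length(obs)
  seqs <- as.matrix(expand.grid(rep(list(1:3), M)))
  prior <- c(0.25, 0.5, 0.25)
  emis <- function(o, s) {
    if (o == 0) 1 else if (o == s) 1 - error_prob else error_prob / 2
  }
  w <- apply(seqs, 1, function(s) {
    p <- prior[s[1]] * emis(obs[1], s[1])
    if (M > 1) {
      for (m in 2:M) {
        r <- haldane(pos[m] - pos[m - 1])
        p <- p * f2_transition(r)[s[m - 1], s[m]] * emis(obs[m], s[m])
      }
    }
    p
  })
  post <- vapply(seq_len(M), function(m) {
    vapply(1:3, function(st) sum(w[seqs[, m] == st]), numeric(1))
  }, numeric(3))
  pm <- t(post) # loci x states
  pm / rowSums(pm)
}

# single-individual cross at given observed codes / positions
one_ind_cross <- function(obs, pos) {
  geno <- matrix(c(NA, "AA", "AB", "BB")[obs + 1], nrow = 1)
  new_cross(geno,
            data.frame(marker = paste0("m", seq_along(pos)), chr = "1",
                       pos = pos),
            data.frame(y = 1))
}

# a small cross CSV in the rotated-header dialect, written to a temp file
write_toy_csv <- function(path, codes = c("A", "H", "B", "-")) {
  lines <- c(
    "id,bw,sex,m1,m2",
    ",,,1,1",
    ",,,0,20",
    paste0("1,10.2,0,", codes[1], ",", codes[2]),
    paste0("2,11.5,1,", codes[2], ",", codes[3]),
    paste0("3,9.8,0,", codes[3], ",", codes[4]),
    paste0("4,NA,1,", codes[1], ",", codes[1])
  )
  writeLines(lines, path)
  path
}

f2_transition <- mvqtlmap:::f2_transition
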