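# Shared in-code fixtures and independent oracles.

# Straight CA trace along x with uniform confidence.
line_model <- function(n, b = 90, chain = "A", resno = seq_len(n), step = 3.8) {
  predicted_model(tibble::tibble(
    atom = "CA", resid = "ALA", chain = chain, resno = resno,
    x = step * seq_len(n), y = 0, z = 0, occ = 1, b = b
  ))
}

# CA model from explicit coordinates / confidences.
ca_model <- function(xyz, b, chain = "A", resno = seq_len(nrow(xyz)),
                     resid = "ALA") {
  predicted_model(tibble::tibble(
    atom = "CA", resid = resid, chain = chain, resno = resno,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = b
  ))
}

# Two compact CA blobs with well-separated centroids.
two_blob_model <- function(n_per = 60, sep = 50, seed = 1, b = 90) {
  withr::with_seed(seed, {
    xyz <- rbind(
      matrix(rnorm(3 * n_per, sd = 3), ncol = 3),
      sweep(matrix(rnorm(3 * n_per, sd = 3), ncol = 3), 2, c(sep, 0, 0), "+")
    )
    ca_model(xyz, b = b)
  })
}

# Noise-free block PAE matrix.
block_pae <- function(sizes, intra = 2, inter = 25) {
  lab <- rep(seq_along(sizes), sizes)
  m <- ifelse(outer(lab, lab, "=="), intra, inter)
  diag(m) <- 0
  pae_matrix(m)
}

# Independent ARI oracle: classify every residue pair by agreement in the
# two labelings and apply the pair-count form of the index directly.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- identical(a[i], a[j])
      sb <- identical(b[i], b[j])
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) return(1)
  2 * (s11 * s00 - s10 * s01) / den
}

# A 2-residue hand-written PDB fragment (CA B values 88.0 and 42.0).
pdb_fragment <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 88.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 88.00           C",
  "ATOM      3  CA  GLY A   2      12.345   9.123  -2.000  1.00 42.00           C",
  "END"
)
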