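# shared fixture builders for the test suite

# quasi-uniform points on a sphere (golden-spiral lattice)
sphere_shell <- function(n, radius, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  sweep(radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                       cos(phi)), 2, center, "+")
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# minimal Structure from an atom spec: data.frame with name, element,
# resname, resno, chain, x, y, z (single model)
make_structure <- function(df, is_het = FALSE) {
  atoms <- data.frame(
    serial = seq_len(nrow(df)),
    name = df$name,
    altloc = " ",
    resname = df$resname,
    chain = if (is.null(df$chain)) "A" else df$chain,
    resno = df$resno,
    inscode = if (is.null(df$inscode)) "" else df$inscode,
    element = df$element,
    occupancy = 1, bfactor = 0,
    is_het = if (length(is_het) == 1) rep(is_het, nrow(df)) else is_het,
    stringsAsFactors = FALSE)
  Structure(atoms, as.matrix(df[, c("x", "y", "z")]))
}

# a tiny three-residue peptide-like structure used across parser tests
toy_pdb_lines <- function() {
  c("HEADER    TOY FIXTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.000   2.800   0.000  1.00  0.00           C",
    "ATOM      6  N   SER A   3       5.400   2.900   0.100  1.00  0.00           N",
    "ATOM      7  CA  SER A   3       6.200   4.100   0.200  1.00  0.00           C",
    "ATOM      8  OG  SER A   3       7.500   3.900   0.900  1.00  0.00           O",
    "END")
}

# brute-force residue neighbour search (independent of select_within)
brute_force_within <- function(s, center, cutoff) {
  xyz <- model_coords(s, 1)
  heavy <- s$atoms$element != "H"
  hit_res <- character(0)
  key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$inscode, sep = "|")
  for (i in which(heavy)) {
    for (j in seq_len(nrow(center))) {
      if (sqrt(sum((xyz[i, ] - center[j, ])^2)) <= cutoff) {
        hit_res <- c(hit_res, key[i])
        break
      }
    }
  }
  unique(hit_res)
}

# independent quaternion-based superposition RMSD (Horn's method)
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- t(A0) %*% B0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lambda) / nrow(A)
  sqrt(max(msd, 0))
}
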