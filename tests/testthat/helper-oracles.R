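# Shared fixtures and independent oracles used across the test files.

# Hand-written PDB text: three residues with CA at (0,0,0), (3.8,0,0),
# (7.6,0,0) Angstrom on chain A, plus a chain B residue.
tiny_pdb <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  LEU A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  SER B   1       1.000   2.000   3.000  1.00  0.00           C",
    sep = "\n")
}

# Brute-force minimum RMSD over rigid rotations: multi-start Nelder-
# Mead over Euler angles on centered point sets.  Independent of the
# SVD-based Kabsch path under test.
brute_rmsd <- function(x, y, n_starts = 40) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  rotmat <- function(a) {
    rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
                c(0, sin(a[1]), cos(a[1])))
    ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
                c(-sin(a[2]), 0, cos(a[2])))
    rz <- rbind(c(cos(a[3]), -sin(a[3]), 0),
                c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
    rx %*% ry %*% rz
  }
  obj <- function(a) sqrt(mean(rowSums((xc - yc %*% rotmat(a))^2)))
  best <- Inf
  set.seed(999)
  for (s in seq_len(n_starts)) {
    a0 <- runif(3, -pi, pi)
    o <- stats::optim(a0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Direct double-loop contact-type counter (oracle for the vectorized
# contact_frequency): one structure, open interval (0.3, 1.0) nm.
brute_contact_freq <- function(struct, lo = 0.3, hi = 1.0) {
  s <- strsplit(struct$sequence, "")[[1]]
  x <- struct$coords
  n <- nrow(x)
  types <- contact_types()
  npq <- setNames(numeric(length(types)), types)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (d > lo && d < hi) {
        tp <- paste0(sort(c(s[i], s[j]))[1], sort(c(s[i], s[j]))[2])
        if (tp %in% types) npq[tp] <- npq[tp] + 1
      }
    }
  }
  nres <- table(s)
  f <- setNames(numeric(length(types)), types)
  for (tp in names(npq[npq > 0])) {
    p <- substr(tp, 1, 1); q <- substr(tp, 2, 2)
    f[tp] <- npq[tp] / (as.numeric(nres[p]) * as.numeric(nres[q]))
  }
  f
}

# Small random folded-ish chain with a fixed seed (for geometry tests)
random_test_chain <- function(n, seed) {
  set.seed(seed)
  x <- matrix(0, n, 3)
  d <- c(1, 0, 0)
  for (i in 2:n) {
    d <- d + rnorm(3, 0, 0.6)
    d <- d / sqrt(sum(d^2))
    x[i, ] <- x[i - 1, ] + 0.38 * d
  }
  x
}

random_test_structure <- function(n, seed) {
  set.seed(seed + 1)
  ca_structure(paste0("rnd", seed),
               paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                            n, replace = TRUE), collapse = ""),
               random_test_chain(n, seed))
}
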