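# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they validate: the alignment
# oracle is a full Gotoh dynamic-programming table, the superposition
# oracle uses the quaternion eigendecomposition method, and the energy
# and pocket oracles are explicit double loops.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Optimal global alignment score under affine gaps where a gap of
# length L costs open + L * ext (full three-state DP).
gotoh_score <- function(a, b, submat = blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  if (m >= 1) for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext,
                      Iy[i - 1, j] - open - ext,
                      Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext,
                      Ix[i, j - 1] - open - ext,
                      Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# Quaternion-method superposition RMSD of P onto Q (n x 3 matrices).
quaternion_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  R <- crossprod(Pc, Qc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- R[1, 1] + R[2, 2] + R[3, 3]
  K[1, 2] <- K[2, 1] <- R[2, 3] - R[3, 2]
  K[1, 3] <- K[3, 1] <- R[3, 1] - R[1, 3]
  K[1, 4] <- K[4, 1] <- R[1, 2] - R[2, 1]
  K[2, 2] <- R[1, 1] - R[2, 2] - R[3, 3]
  K[2, 3] <- K[3, 2] <- R[1, 2] + R[2, 1]
  K[2, 4] <- K[4, 2] <- R[1, 3] + R[3, 1]
  K[3, 3] <- -R[1, 1] + R[2, 2] - R[3, 3]
  K[3, 4] <- K[4, 3] <- R[2, 3] + R[3, 2]
  K[4, 4] <- -R[1, 1] - R[2, 2] + R[3, 3]
  lambda_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda_max) / n
  sqrt(max(0, msd))
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Explicit double-loop receptor-ligand cross-interaction energy.
cross_energy_oracle <- function(A, B, params) {
  if (inherits(A, "structure3d")) A <- A$atoms
  if (inherits(B, "structure3d")) B <- B$atoms
  tot <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dx <- A$x[i] - B$x[j]; dy <- A$y[i] - B$y[j]; dz <- A$z[i] - B$z[j]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      if (r > params$cutoff) next
      sig <- (params$sigma[[A$elesy[i]]] + params$sigma[[B$elesy[j]]]) / 2
      eps <- sqrt(params$epsilon[[A$elesy[i]]] *
                    params$epsilon[[B$elesy[j]]])
      tot <- tot + 4 * eps * ((sig / r)^12 - (sig / r)^6) +
        332.06 * A$charge[i] * B$charge[j] /
        (params$dielectric_factor * r * r)
    }
  }
  tot
}

# Brute-force pocket scan: every receptor residue with any (heavy)
# atom within the cutoff of any probe atom.
brute_pocket <- function(receptor, probe, cutoff, heavy_only = TRUE) {
  a <- receptor$atoms
  if (heavy_only) a <- a[a$elesy != "H", ]
  pb <- if (inherits(probe, "structure3d")) {
    pa <- probe$atoms
    if (heavy_only) pa <- pa[pa$elesy != "H", ]
    as.matrix(pa[, c("x", "y", "z")])
  } else rbind(probe)
  hits <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(pb))) {
      r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - pb[j, ])^2))
      if (r <= cutoff) hits <- c(hits, paste(a$chain[i], a$resno[i]))
    }
  }
  sort(unique(hits))
}

# A random protein-like blob as a structure3d.  Atoms are rejection-
# sampled to a physically sane minimum separation: overlapping atoms
# would give astronomically large intra energies whose floating-point
# cancellation masks the identities under test.
random_structure <- function(n, seed = NULL, id = "rand", chain = "A",
                             spread = 8, elements = c("C", "N", "O"),
                             charges = 0, min_sep = 2.8) {
  if (!is.null(seed)) set.seed(seed)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    repeat {
      p <- stats::runif(3, -spread, spread)
      if (i == 1L || min(sqrt(rowSums(sweep(
        xyz[seq_len(i - 1L), , drop = FALSE], 2, p)^2))) >= min_sep) {
        xyz[i, ] <- p
        break
      }
    }
  }
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(n),
    elety = paste0("X", seq_len(n)),
    resid = "GLY", chain = chain, resno = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0,
    elesy = sample(elements, n, replace = TRUE),
    charge = if (length(charges) == 1L && charges == 0) 0 else
      sample(charges, n, replace = TRUE),
    stringsAsFactors = FALSE)
  structure3d(atoms, id = id)
}

# A CA-chain structure from a coordinate matrix.
ca_structure <- function(xyz, id = "ca", chain = "A") {
  n <- nrow(xyz)
  structure3d(data.frame(
    type = "ATOM", eleno = seq_len(n), elety = "CA", resid = "ALA",
    chain = chain, resno = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, elesy = "C", charge = 0,
    stringsAsFactors = FALSE), id = id)
}

# Replace the binding energies of a scored pose set (for ranking tests
# that need controlled score patterns, including ties).
with_binding_energies <- function(ps, be) {
  ps$scores$binding_energy <- be
  ps
}
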