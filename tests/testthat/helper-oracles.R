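# Independent oracles and shared builders used across the suite.

# Horn quaternion-method superposition RMSD: independent of the SVD path
# in kabsch_superpose()
quaternion_rmsd <- function(ref, mob) {
  Pc <- scale(mob, scale = FALSE)
  Qc <- scale(ref, scale = FALSE)
  M <- t(Pc) %*% Qc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(Pc^2) + sum(Qc^2) - 2 * lmax) / nrow(ref))
}

# plain double-loop 12-6 sum, independent of the vectorised lj_energy()
brute_lj <- function(A, B, ca, cb, params, exclusions = NULL) {
  e <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (!is.null(exclusions) &&
            any(exclusions[, 1] == i & exclusions[, 2] == j)) next
      r <- sqrt(sum((A[i, ] - B[j, ])^2))
      eps <- sqrt(params$classes$epsilon[ca[i]] *
                    params$classes$epsilon[cb[j]])
      rm <- params$classes$rmin_half[ca[i]] + params$classes$rmin_half[cb[j]]
      e <- e + eps * ((rm / r)^12 - 2 * (rm / r)^6)
    }
  }
  e
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotate_structure <- function(model, R, t = c(0, 0, 0)) {
  at <- tibble::as_tibble(model)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + t[1]; at$y <- xyz[, 2] + t[2]; at$z <- xyz[, 3] + t[3]
  new_structure(at, header_id = attr(model, "header_id"))
}

# minimal single-glycine PDB text
MINIMAL_GLY <- c(
  "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   GLY A   1      12.247   7.410  -4.778  1.00  0.00           C",
  "ATOM      4  O   GLY A   1      12.323   8.308  -5.620  1.00  0.00           O",
  "END")

sheet_with_triad <- function(d = 1.33, n = 8, with_cat = TRUE, seed = 1) {
  m <- make_two_strand_parallel(n, 2.9, seed = seed)
  plant_triad(m, lys = list(chain = "A", res_seq = 4),
              acceptor = list(chain = "B", res_seq = 5),
              catalytic = if (with_cat) list(chain = "A", res_seq = 6),
              triad_nz_cg = d)
}

split_topology <- function(cs) {
  new_structure(dplyr::bind_rows(tibble::as_tibble(cs$catcher),
                                 tibble::as_tibble(cs$tag)),
                header_id = "split")
}
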