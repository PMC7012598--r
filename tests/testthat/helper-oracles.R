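# Independent oracles used to cross-check the package's implementations.

# Horn's closed-form quaternion superposition: returns the minimal RMSD
# between two point sets under proper rigid motion. Independent of the
# package's SVD-based Kabsch implementation.
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       Syy - Sxx - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       Szz - Sxx - Syy),
    nrow = 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(P)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# random rigid motion (uniform rotation via normalized quaternion)
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Monte-Carlo volume of a union of spheres
mc_union_volume <- function(spheres, n_samples = 1e6) {
  ctr <- t(vapply(spheres, function(s) s$center, numeric(3)))
  rad <- vapply(spheres, function(s) s$radius, numeric(1))
  lo <- apply(ctr - rad, 2, min); hi <- apply(ctr + rad, 2, max)
  pts <- cbind(runif(n_samples, lo[1], hi[1]),
               runif(n_samples, lo[2], hi[2]),
               runif(n_samples, lo[3], hi[3]))
  inside <- rep(FALSE, n_samples)
  for (i in seq_along(rad)) {
    d2 <- (pts[, 1] - ctr[i, 1])^2 + (pts[, 2] - ctr[i, 2])^2 +
      (pts[, 3] - ctr[i, 3])^2
    inside <- inside | (d2 <= rad[i]^2)
  }
  mean(inside) * prod(hi - lo)
}

# small synthetic polypeptide-like structure for I/O tests
make_tiny_structure <- function(n_res = 5, chain = "A", res_start = 1,
                                atom_names = c("N", "CA", "C", "O"),
                                seed = 42) {
  set.seed(seed)
  n <- n_res * length(atom_names)
  df <- data.frame(
    serial = seq_len(n),
    name = rep(atom_names, n_res),
    element = substr(rep(atom_names, n_res), 1, 1),
    res_name = "ALA",
    res_seq = rep(res_start:(res_start + n_res - 1),
                  each = length(atom_names)),
    chain = chain, altloc = "", occupancy = 1,
    x = round(rnorm(n, sd = 5), 3), y = round(rnorm(n, sd = 5), 3),
    z = round(rnorm(n, sd = 5), 3), stringsAsFactors = FALSE)
  new_structure("tiny", df)
}

# backbone reduction mirroring the PCA path, via exported selection tools
reduce_backbone_for_test <- function(s, backbone_atoms = BACKBONE_ATOMS) {
  idx <- select_atoms(s, atom_selection(atom_names = backbone_atoms))
  idx <- idx[toupper(s$atoms$element[idx]) != "H"]
  s$atoms <- s$atoms[idx, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

# rebuild the superposed, concatenated data matrix exactly as fit_pc_model
# consumes it (backbone reduction + per-frame Kabsch onto the reference)
fitted_data_matrix <- function(ensemble, reference,
                               backbone_atoms = BACKBONE_ATOMS) {
  topo <- reduce_backbone_for_test(ensemble$topology, backbone_atoms)
  ref <- reduce_backbone_for_test(reference, backbone_atoms)
  idx <- select_atoms(ensemble$topology,
                      atom_selection(atom_names = backbone_atoms))
  idx <- idx[toupper(ensemble$topology$atoms$element[idx]) != "H"]
  ref_xyz <- coords(ref)
  rows <- lapply(ensemble$frames, function(fr) {
    fr <- fr[idx, , drop = FALSE]
    sup <- kabsch_superpose(fr, ref_xyz)
    as.vector(t(apply_superposition(sup, fr)))
  })
  do.call(rbind, rows)
}
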