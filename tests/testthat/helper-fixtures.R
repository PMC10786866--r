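# Shared fixtures, built once per test run, and independent oracle
# implementations used to cross-check the package's numerics.

.fixture_cache <- new.env(parent = emptyenv())

toy_structure <- function() {
  if (is.null(.fixture_cache$st))
    .fixture_cache$st <- build_toy_crystal()
  .fixture_cache$st
}

toy_map <- function() {
  if (is.null(.fixture_cache$map))
    .fixture_cache$map <- simulate_map(toy_structure(), grid = 0.25)
  .fixture_cache$map
}

p212121_ops <- function() spacegroup_ops("P 21 21 21")

# chi1 target guaranteed to change the rotamer class of a toy residue
toy_flip_target <- function(resno) {
  if (is.null(.fixture_cache$rot))
    .fixture_cache$rot <- rotamer_assignments(toy_structure())
  ra <- .fixture_cache$rot
  unname(c(p = 180, t = -65, m = 180)[ra$chi1_class[ra$resno == resno]])
}

# independent dihedral formulation (projection / atan2 of rejected vectors)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  b1u <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1u) * b1u
  w <- b2 - sum(b2 * b1u) * b1u
  x <- sum(v * w)
  cr <- c(b1u[2] * v[3] - b1u[3] * v[2],
          b1u[3] * v[1] - b1u[1] * v[3],
          b1u[1] * v[2] - b1u[2] * v[1])
  y <- sum(cr * w)
  atan2(y, x) * 180 / pi
}

# quaternion (Horn) superposition: independent of the Kabsch path
quaternion_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- sweep(X, 2, cx); B <- sweep(Y, 2, cy)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  e2 <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(X)
  sqrt(max(0, e2))
}

# brute-force trilinear interpolation at a single fractional point
trilinear_oracle <- function(arr, frac) {
  dims <- dim(arr)
  u <- (frac %% 1) * dims
  i0 <- floor(u); w <- u - i0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- ((i0[1] + dx) %% dims[1]) + 1
    iy <- ((i0[2] + dy) %% dims[2]) + 1
    iz <- ((i0[3] + dz) %% dims[3]) + 1
    wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    val <- val + wt * arr[ix, iy, iz]
  }
  val
}

# exhaustive symmetry-aware minimum distance (scalar loops)
sym_min_dist_oracle <- function(q_frac, others_frac, cell, ops, shell = 1) {
  M <- orth_matrix(cell)
  qx <- as.numeric(M %*% q_frac)
  best <- Inf
  for (op in ops) for (tx in -shell:shell) for (ty in -shell:shell)
    for (tz in -shell:shell)
      for (i in seq_len(nrow(others_frac))) {
        img <- as.numeric(op$R %*% others_frac[i, ]) + op$t + c(tx, ty, tz)
        d <- sqrt(sum((as.numeric(M %*% img) - qx)^2))
        if (d < best) best <- d
      }
  best
}

# small two-chain mmCIF snippet written on the fly
write_mini_mmcif <- function(path) {
  writeLines(c(
    "data_toy",
    "_cell.length_a    30.000",
    "_cell.length_b    34.000",
    "_cell.length_c    40.000",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  90.00",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 21 21 21'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "ATOM   N N  . SER A 1 ? 10.000 10.000 10.000 1.00 15.0",
    "ATOM   C CA . SER A 1 ? 11.458 10.000 10.000 1.00 15.0",
    "ATOM   C CB A SER A 1 ? 12.000 11.400 10.000 0.60 15.0",
    "ATOM   C CB B SER A 1 ? 12.000 11.200 10.600 0.40 15.0",
    "HETATM O O  . HOH S 1 ? 20.000 20.000 20.000 1.00 20.0",
    "HETATM O O  . HOH S 2 ? 24.000 20.000 20.000 1.00 20.0"
  ), path)
  path
}

polymer_atoms_of <- function(st) st$atoms[st$atoms$kind == "polymer", , drop = FALSE]
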