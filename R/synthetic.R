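## Synthetic crystal systems with known ground truth: an ideal-geometry
## peptide in a P212121 cell, clash-free ordered waters, Gaussian-atom
## density maps obeying the space-group symmetry, and controlled
## perturbations (rotamer flips, loop shifts, water moves, B inflation).

#' Place an atom from internal coordinates (NeRF)
#'
#' Position `d` such that `|d - c| = bond`, the angle b-c-d equals
#' `angle` and the dihedral a-b-c-d equals `torsion` (degrees).
#'
#' @param a,b,c Cartesian 3-vectors of the three reference atoms.
#' @param bond Bond length in Angstrom.
#' @param angle Bond angle in degrees.
#' @param torsion Dihedral angle in degrees.
#' @return Cartesian 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d2)
}

## side-chain internal-coordinate templates: one row per atom beyond CB.
## refs name the three previously placed atoms; tor is "chiK" optionally
## with +offset, or a number
.sidechain_templates <- list(
  SER = list(list("OG", "O", c("N","CA","CB"), 1.417, 110.8, "chi1")),
  CYS = list(list("SG", "S", c("N","CA","CB"), 1.808, 114.4, "chi1")),
  THR = list(list("OG1", "O", c("N","CA","CB"), 1.433, 109.6, "chi1"),
             list("CG2", "C", c("N","CA","CB"), 1.521, 110.5, "chi1-120")),
  VAL = list(list("CG1", "C", c("N","CA","CB"), 1.527, 110.7, "chi1"),
             list("CG2", "C", c("N","CA","CB"), 1.527, 110.4, "chi1+122")),
  LEU = list(list("CG", "C", c("N","CA","CB"), 1.530, 116.3, "chi1"),
             list("CD1", "C", c("CA","CB","CG"), 1.524, 110.7, "chi2"),
             list("CD2", "C", c("CA","CB","CG"), 1.525, 110.4, "chi2+122")),
  ILE = list(list("CG1", "C", c("N","CA","CB"), 1.530, 110.4, "chi1"),
             list("CG2", "C", c("N","CA","CB"), 1.521, 110.5, "chi1-122"),
             list("CD1", "C", c("CA","CB","CG1"), 1.513, 113.8, "chi2")),
  MET = list(list("CG", "C", c("N","CA","CB"), 1.520, 114.1, "chi1"),
             list("SD", "S", c("CA","CB","CG"), 1.803, 112.7, "chi2"),
             list("CE", "C", c("CB","CG","SD"), 1.791, 100.9, "chi3")),
  ASP = list(list("CG", "C", c("N","CA","CB"), 1.516, 112.6, "chi1"),
             list("OD1", "O", c("CA","CB","CG"), 1.249, 118.4, "chi2"),
             list("OD2", "O", c("CA","CB","CG"), 1.249, 118.4, "chi2+180")),
  ASN = list(list("CG", "C", c("N","CA","CB"), 1.516, 112.6, "chi1"),
             list("OD1", "O", c("CA","CB","CG"), 1.231, 120.8, "chi2"),
             list("ND2", "N", c("CA","CB","CG"), 1.328, 116.4, "chi2+180")),
  GLU = list(list("CG", "C", c("N","CA","CB"), 1.520, 114.1, "chi1"),
             list("CD", "C", c("CA","CB","CG"), 1.516, 112.6, "chi2"),
             list("OE1", "O", c("CB","CG","CD"), 1.249, 118.4, "chi3"),
             list("OE2", "O", c("CB","CG","CD"), 1.249, 118.4, "chi3+180")),
  GLN = list(list("CG", "C", c("N","CA","CB"), 1.520, 114.1, "chi1"),
             list("CD", "C", c("CA","CB","CG"), 1.516, 112.6, "chi2"),
             list("OE1", "O", c("CB","CG","CD"), 1.231, 120.8, "chi3"),
             list("NE2", "N", c("CB","CG","CD"), 1.328, 116.4, "chi3+180")),
  LYS = list(list("CG", "C", c("N","CA","CB"), 1.520, 114.1, "chi1"),
             list("CD", "C", c("CA","CB","CG"), 1.520, 111.3, "chi2"),
             list("CE", "C", c("CB","CG","CD"), 1.520, 111.3, "chi3"),
             list("NZ", "N", c("CG","CD","CE"), 1.489, 111.9, "chi4")),
  ALA = list(), GLY = list()
)

parse_torsion_spec <- function(spec, chis) {
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^chi([0-9])([+-][0-9.]+)?$", spec))[[1]]
  stopifnot(length(m) >= 2)
  val <- chis[as.integer(m[2])]
  if (m[3] != "" && !is.na(m[3])) val <- val + as.numeric(m[3])
  val
}

#' Configuration for a synthetic toy crystal
#'
#' Defaults describe a 14-residue mixed peptide (gamma-branched side
#' chains throughout) in a 30 x 34 x 40 Angstrom P212121 cell with 20
#' ordered waters, B = 20 Angstrom^2, a 0.25 Angstrom map grid and no
#' map noise.
#'
#' @param sequence Character vector of 3-letter residue codes.
#' @param cell A [unit_cell()].
#' @param spacegroup Space-group symbol.
#' @param n_waters Number of ordered waters.
#' @param grid Map grid spacing in Angstrom.
#' @param b B-factor applied to every atom (Angstrom^2).
#' @param noise_sigma Map noise level in sigma units of the noiseless map.
#' @param seed Random seed; fully determines the output.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(sequence = c("MET", "SER", "LEU", "GLU", "CYS",
                                          "LYS", "THR", "VAL", "ASP", "SER",
                                          "ILE", "GLN", "LEU", "ASN"),
                             cell = unit_cell(30, 34, 40),
                             spacegroup = "P 21 21 21",
                             n_waters = 20, grid = 0.25, b = 20,
                             noise_sigma = 0, seed = 20240112) {
  structure(list(sequence = toupper(sequence), cell = cell,
                 spacegroup = spacegroup, n_waters = n_waters,
                 grid = grid, b = b, noise_sigma = noise_sigma, seed = seed),
            class = "synthetic_config")
}

## deterministic rotamer choice per residue from the mode table
pick_chis <- function(restype, rng_index) {
  modes <- .rotamer_modes[[restype]]
  if (is.null(modes)) return(numeric())
  modes[[1 + (rng_index %% length(modes))]]
}

## place the side chain for the deterministically chosen rotamer,
## advancing to the next mode when any atom beyond CB comes within
## 2.0 A of a previously built residue
place_sidechain_clash_free <- function(res, restype, rng_index, prev_xyz) {
  modes <- .rotamer_modes[[restype]]
  n_modes <- if (is.null(modes)) 1L else length(modes)
  backbone <- c("N", "CA", "C", "O", "CB")
  for (k in 0:(n_modes - 1)) {
    chis <- pick_chis(restype, rng_index + k)
    cand <- res
    for (tmpl in .sidechain_templates[[restype]]) {
      refs <- lapply(tmpl[[3]], function(nm) cand[[nm]])
      cand[[tmpl[[1]]]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                      tmpl[[4]], tmpl[[5]],
                                      parse_torsion_spec(tmpl[[6]], chis))
    }
    side <- setdiff(names(cand), backbone)
    if (is.null(prev_xyz) || !length(side))
      return(list(res = cand, chis = chis))
    sxyz <- do.call(rbind, cand[side])
    ok <- TRUE
    for (j in seq_len(nrow(sxyz))) {
      d2 <- (prev_xyz[, 1] - sxyz[j, 1])^2 + (prev_xyz[, 2] - sxyz[j, 2])^2 +
        (prev_xyz[, 3] - sxyz[j, 3])^2
      if (min(d2) < 4) { ok <- FALSE; break }
    }
    if (ok) return(list(res = cand, chis = chis))
  }
  stop("no clash-free rotamer for ", restype, " at build position")
}

#' Build a deterministic toy crystal structure
#'
#' Constructs an ideal-geometry alpha-helical peptide from the
#' configuration's sequence with rotamers assigned from the built-in
#' mode table, places it in the asymmetric unit, and adds ordered waters
#' at least 2.4 Angstrom from the protein, from each other, and from all
#' crystal-symmetry images.
#'
#' @param config A [synthetic_config()].
#' @return A [crystal_structure()] with extra fields `assigned_chis`
#'   (list per residue) and `config`.
#' @export
build_toy_crystal <- function(config = synthetic_config()) {
  set.seed(config$seed)
  seq3 <- config$sequence
  nres <- length(seq3)
  phi <- rep(-57, nres); psi <- rep(-47, nres)
  # backbone ideal internal coordinates
  atoms <- list()
  add_atom <- function(name, element, xyz, resno, resid)
    atoms[[length(atoms) + 1]] <<- data.frame(
      element = element, name = name, altloc = "", occ = 1, b = config$b,
      x = xyz[1], y = xyz[2], z = xyz[3], chain = "A", resno = resno,
      icode = "", resid = resid, kind = "polymer", stringsAsFactors = FALSE)
  coords <- list()   # per residue named list
  assigned <- vector("list", nres)
  for (i in seq_len(nres)) {
    if (i == 1) {
      n <- c(0, 0, 0)
      ca <- c(1.458, 0, 0)
      ang <- 111.2 * pi / 180
      cc <- ca + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
    } else {
      prev <- coords[[i - 1]]
      n <- place_atom(prev$N, prev$CA, prev$C, 1.329, 116.2, psi[i - 1])
      ca <- place_atom(prev$CA, prev$C, n, 1.458, 121.7, 180)
      cc <- place_atom(prev$C, n, ca, 1.525, 111.2, phi[i])
    }
    res <- list(N = n, CA = ca, C = cc)
    res$O <- place_atom(res$N, res$CA, res$C, 1.231, 120.8, psi[i] + 180)
    if (seq3[i] != "GLY")
      res$CB <- place_atom(res$N, res$C, res$CA, 1.530, 110.5, 122.6)
    prev_xyz <- do.call(rbind, lapply(coords, function(r)
      do.call(rbind, r)))
    built <- place_sidechain_clash_free(res, seq3[i], i + config$seed,
                                        prev_xyz)
    assigned[[i]] <- built$chis
    coords[[i]] <- built$res
  }
  # assemble and center the peptide in the asymmetric unit
  for (i in seq_len(nres)) {
    res <- coords[[i]]
    for (nm in names(res)) {
      el <- if (nm %in% c("N", "NZ", "ND2", "NE2")) "N"
            else if (startsWith(nm, "O")) "O"
            else if (startsWith(nm, "S")) "S" else "C"
      add_atom(nm, el, res[[nm]], i, seq3[i])
    }
  }
  at <- do.call(rbind, atoms)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  target <- frac_to_orth(c(0.25, 0.25, 0.22), config$cell)
  xyz <- sweep(xyz, 2, as.numeric(target) - colMeans(xyz), `+`)
  at[, c("x", "y", "z")] <- xyz
  st <- crystal_structure(at, config$cell, config$spacegroup,
                          label = "toy")
  # symmetry clash check: all non-identity images >= 2.0 A away
  d <- protein_symmetry_min_dist(st)
  if (d < 2.0)
    stop(sprintf("cell too small: symmetry images clash at %.2f A", d))
  # waters
  ops <- st$ops
  prot_frac <- orth_to_frac(xyz, config$cell)
  wat_frac <- matrix(numeric(), 0, 3)
  tries <- 0
  while (nrow(wat_frac) < config$n_waters) {
    tries <- tries + 1
    if (tries > 20000) stop("could not place waters without clashes")
    cand <- stats::runif(3)
    dp <- min_symmetry_distance(cand, prot_frac, config$cell, ops, shell = 1)
    if (dp < 2.4 || dp > 6.0) next    # keep waters near the protein surface
    if (nrow(wat_frac)) {
      dw <- min_symmetry_distance(cand, wat_frac, config$cell, ops, shell = 1)
      if (dw < 3.0) next
    }
    # also self-image distance
    img <- symmetry_expand(matrix(cand, 1), ops, 1)
    d_self <- sort(sqrt(rowSums(sweep(frac_to_orth(img, config$cell), 2,
                                      as.numeric(frac_to_orth(cand, config$cell)))^2)))
    if (d_self[2] < 3.0) next
    wat_frac <- rbind(wat_frac, cand)
  }
  wxyz <- frac_to_orth(wat_frac, config$cell)
  wat <- data.frame(element = "O", name = "O", altloc = "", occ = 1,
                    b = config$b, x = wxyz[, 1], y = wxyz[, 2], z = wxyz[, 3],
                    chain = "S", resno = seq_len(nrow(wxyz)), icode = "",
                    resid = "HOH", kind = "water", stringsAsFactors = FALSE)
  st <- crystal_structure(rbind(at, wat), config$cell, config$spacegroup,
                          label = "toy")
  st$assigned_chis <- assigned
  st$config <- config
  st
}

## minimum distance between the protein and its non-identity symmetry
## images (shell 1), exhaustive over atoms
protein_symmetry_min_dist <- function(structure) {
  xyz <- atom_xyz(structure, structure$atoms$kind == "polymer")
  frac <- orth_to_frac(xyz, structure$cell)
  ops <- structure$ops
  best <- Inf
  r <- -1:1
  trans <- as.matrix(expand.grid(r, r, r))
  for (k in seq_along(ops)) {
    for (t in seq_len(nrow(trans))) {
      if (k == 1 && all(trans[t, ] == 0)) next
      img <- sweep(apply_sym_op(ops[[k]], frac), 2, trans[t, ], `+`)
      ixyz <- frac_to_orth(img, structure$cell)
      # min cross distance
      for (i in seq_len(nrow(xyz))) {
        d2 <- min((ixyz[, 1] - xyz[i, 1])^2 + (ixyz[, 2] - xyz[i, 2])^2 +
                    (ixyz[, 3] - xyz[i, 3])^2)
        if (d2 < best) best <- d2
      }
    }
  }
  sqrt(best)
}

.z_eff <- c(C = 6, N = 7, O = 8, S = 16)

#' Simulate a symmetry-obeying Gaussian-atom density map
#'
#' Each atom (and every one of its space-group images) contributes a
#' normalized 3D Gaussian with variance `B/(8 pi^2) + (grid/2)^2` and
#' integrated weight `occupancy x Z_eff` (C 6, N 7, O 8, S 16). Optional
#' white noise is added with standard deviation `noise_sigma` times the
#' rms of the noiseless map.
#'
#' @param structure A [crystal_structure()].
#' @param grid Grid spacing in Angstrom; must not exceed half the
#'   smallest atomic Gaussian width.
#' @param noise_sigma Noise level in sigma units (0 = noiseless).
#' @param seed Seed for the noise (default: derived from no seed; pass
#'   one for reproducibility).
#' @return A [density_map()].
#' @export
simulate_map <- function(structure, grid = 0.25, noise_sigma = 0,
                         seed = NULL) {
  cell <- structure$cell
  at <- structure$atoms
  sig2 <- at$b / (8 * pi^2) + (grid / 2)^2
  if (grid > 0.5 * sqrt(min(sig2)))
    stop("grid spacing exceeds half the smallest atomic Gaussian width")
  dims <- pmax(8L, as.integer(round(c(cell$a, cell$b, cell$c) / grid)))
  vals <- array(0, dims)
  M <- orth_matrix(cell)
  step_len <- sqrt(colSums(M^2)) / dims      # Angstrom per grid step per axis
  frac <- orth_to_frac(as.matrix(at[, c("x", "y", "z")]), cell)
  z <- .z_eff[at$element]; z[is.na(z)] <- 6
  for (i in seq_len(nrow(at))) {
    images <- do.call(rbind, lapply(structure$ops, apply_sym_op,
                                    frac = frac[i, , drop = FALSE])) %% 1
    s2 <- sig2[i]
    amp <- at$occ[i] * z[i] / (2 * pi * s2)^1.5
    half <- ceiling(4 * sqrt(s2) / step_len)
    for (r in seq_len(nrow(images))) {
      ctr <- images[r, ] * dims               # 0-based grid coordinate
      i0 <- floor(ctr)
      ax <- (i0[1] - half[1]):(i0[1] + half[1])
      ay <- (i0[2] - half[2]):(i0[2] + half[2])
      az <- (i0[3] - half[3]):(i0[3] + half[3])
      # fractional deltas of each grid line to the center
      dfx <- (ax - ctr[1]) / dims[1]; dfy <- (ay - ctr[2]) / dims[2]
      dfz <- (az - ctr[3]) / dims[3]
      # Cartesian squared distance via the orthogonalization matrix
      gx <- outer(M[1, 1] * dfx, M[1, 2] * dfy, `+`)
      gx <- outer(gx, M[1, 3] * dfz, `+`)
      gy <- outer(M[2, 1] * dfx, M[2, 2] * dfy, `+`)
      gy <- outer(gy, M[2, 3] * dfz, `+`)
      gz <- outer(M[3, 1] * dfx, M[3, 2] * dfy, `+`)
      gz <- outer(gz, M[3, 3] * dfz, `+`)
      d2 <- gx^2 + gy^2 + gz^2
      contrib <- amp * exp(-d2 / (2 * s2))
      ix <- wrap_index(ax + 1, dims[1])
      iy <- wrap_index(ay + 1, dims[2])
      iz <- wrap_index(az + 1, dims[3])
      vals[ix, iy, iz] <- vals[ix, iy, iz] + contrib
    }
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    m0 <- mean(vals)
    rms0 <- sqrt(mean((vals - m0)^2))
    vals <- vals + stats::rnorm(length(vals), 0, noise_sigma * rms0)
  }
  density_map(vals, cell)
}

#' Apply controlled perturbations with recorded ground truth
#'
#' Supported perturbation kinds:
#' \describe{
#'   \item{rotamer-flip}{`list(kind = "rotamer-flip", resno =, target_chi1 =)`:
#'     rotates the side chain beyond CB about the CA-CB axis so chi1
#'     equals the target, preserving ideal geometry.}
#'   \item{loop-shift}{`list(kind = "loop-shift", from =, to =, distance =)`
#'     (or an explicit `vector`): rigidly translates a residue range.}
#'   \item{water-move}{`list(kind = "water-move", water =, distance =)`:
#'     displaces the water with residue number `water` by the stated
#'     distance in a clash-free direction.}
#'   \item{b-inflate}{`list(kind = "b-inflate", factor =, from =, to =)`:
#'     multiplies B-factors in a residue range.}
#' }
#'
#' @param structure A [crystal_structure()] from [build_toy_crystal()].
#' @param requests List of perturbation request lists.
#' @param seed Seed for random directions.
#' @return List with `structure` (perturbed) and `truth` (data.frame:
#'   kind, target, magnitude).
#' @export
perturb <- function(structure, requests, seed = 1) {
  set.seed(seed)
  st <- structure
  truth <- list()
  record <- function(kind, target, magnitude)
    truth[[length(truth) + 1]] <<- data.frame(kind = kind, target = target,
                                              magnitude = magnitude,
                                              stringsAsFactors = FALSE)
  for (rq in requests) {
    st <- switch(rq$kind,
      "rotamer-flip" = {
        out <- flip_rotamer(st, rq$resno, rq$target_chi1)
        record("rotamer-flip", rq$resno, rq$target_chi1)
        out
      },
      "loop-shift" = {
        vec <- if (!is.null(rq$vector)) rq$vector else {
          u <- stats::rnorm(3); rq$distance * u / sqrt(sum(u^2))
        }
        sel <- st$atoms$kind == "polymer" & st$atoms$resno >= rq$from &
          st$atoms$resno <= rq$to
        st$atoms$x[sel] <- st$atoms$x[sel] + vec[1]
        st$atoms$y[sel] <- st$atoms$y[sel] + vec[2]
        st$atoms$z[sel] <- st$atoms$z[sel] + vec[3]
        for (r in rq$from:rq$to)
          record("loop-shift", r, sqrt(sum(vec^2)))
        st
      },
      "water-move" = {
        st2 <- move_water(st, rq$water, rq$distance)
        record("water-move", rq$water, rq$distance)
        st2
      },
      "b-inflate" = {
        sel <- st$atoms$kind == "polymer" & st$atoms$resno >= rq$from &
          st$atoms$resno <= rq$to
        st$atoms$b[sel] <- st$atoms$b[sel] * rq$factor
        record("b-inflate", rq$from, rq$factor)
        st
      },
      stop("unknown perturbation kind: ", rq$kind))
  }
  st$label <- paste0(structure$label, "-perturbed")
  list(structure = st, truth = do.call(rbind, truth))
}

## rotate every side-chain atom beyond CB about the CA-CB axis so chi1
## hits the target; errors on steric clash (< 2 A to any other atom)
flip_rotamer <- function(structure, resno, target_chi1) {
  at <- structure$atoms
  sel_res <- at$kind == "polymer" & at$resno == resno
  res <- at[sel_res, , drop = FALSE]
  n <- get_atom_coord(res, "N"); ca <- get_atom_coord(res, "CA")
  cb <- get_atom_coord(res, "CB")
  gname <- gamma_atom_name(res)
  if (is.null(cb) || is.null(gname))
    stop("residue ", resno, " has no rotatable side chain")
  chi_now <- dihedral(n, ca, cb, get_atom_coord(res, gname))
  delta <- target_chi1 - chi_now
  u <- cb - ca; u <- u / sqrt(sum(u^2))
  move <- sel_res & !(at$name %in% c("N", "CA", "C", "O", "CB"))
  idx <- which(move)
  for (i in idx) {
    p <- rotate_about_axis(as.numeric(at[i, c("x", "y", "z")]), cb, u, delta)
    at[i, c("x", "y", "z")] <- p
  }
  # clash check against all unmoved atoms
  moved_xyz <- as.matrix(at[idx, c("x", "y", "z")])
  other_xyz <- as.matrix(at[-idx, c("x", "y", "z")])
  other_sel <- !(seq_len(nrow(at)) %in% idx) &
    !(at$kind == "polymer" & at$resno == resno)
  other_xyz <- as.matrix(at[other_sel, c("x", "y", "z")])
  for (i in seq_len(nrow(moved_xyz))) {
    d2 <- (other_xyz[, 1] - moved_xyz[i, 1])^2 +
      (other_xyz[, 2] - moved_xyz[i, 2])^2 +
      (other_xyz[, 3] - moved_xyz[i, 3])^2
    if (min(d2) < 4)
      stop(sprintf("rotamer flip of residue %d clashes (%.2f A)",
                   resno, sqrt(min(d2))))
  }
  structure$atoms <- at
  structure
}

## displace one water by `distance`, rejection-sampling a direction that
## stays clash-free with respect to protein and other waters (and their
## symmetry images)
move_water <- function(structure, water_resno, distance) {
  at <- structure$atoms
  wi <- which(at$kind == "water" & at$resno == water_resno)
  if (!length(wi)) stop("no water with residue number ", water_resno)
  wi <- wi[1]
  cell <- structure$cell
  prot_frac <- orth_to_frac(as.matrix(at[at$kind == "polymer",
                                         c("x", "y", "z")]), cell)
  other_w <- at$kind == "water" & seq_len(nrow(at)) != wi
  oth_frac <- orth_to_frac(as.matrix(at[other_w, c("x", "y", "z")]), cell)
  old <- as.numeric(at[wi, c("x", "y", "z")])
  for (try in 1:500) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    cand <- old + distance * u
    cf <- orth_to_frac(cand, cell)
    if (min_symmetry_distance(cf, prot_frac, cell, structure$ops) < 2.4) next
    if (nrow(oth_frac) &&
        min_symmetry_distance(cf, oth_frac, cell, structure$ops) <
          max(2.6, distance + 0.1)) next
    at[wi, c("x", "y", "z")] <- cand
    structure$atoms <- at
    return(structure)
  }
  stop("could not find a clash-free direction for water ", water_resno)
}
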