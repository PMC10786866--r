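## Volume analytics: grid-based protein molecular volume, percent changes,
## and Welch's t-test on pocket-volume tables.

## built-in van der Waals radii (Angstrom)
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10,
                P = 1.80, SE = 1.90)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.70   # fall back to carbon for exotic elements
  unname(r)
}

#' Protein molecular volume by grid flood fill
#'
#' Solvent-excluded molecular volume: the protein interior is every grid
#' voxel that a spherical probe rolling in from outside cannot cover.
#' Probe centers are flood-filled from the bounding-box boundary through
#' voxels farther than (vdW radius + probe radius) from every atom; the
#' reachable region dilated by the probe radius is "solvent", and the
#' volume is the voxel count of its complement times the voxel volume.
#' Interior cavities too small for the probe are therefore included.
#'
#' @param structure A [crystal_structure()]; waters and het atoms are
#'   excluded unless `include_waters` is set.
#' @param grid Grid spacing in Angstrom, in `[0.2, 1.0]`.
#' @param probe Probe radius in Angstrom (1.4 = water).
#' @param include_waters Include ordered waters as part of the molecule.
#' @param altloc_policy Conformer selection, passed to
#'   [strip_to_single_conformer()] when alternate locations are present.
#' @return Volume in cubic Angstrom, with attributes `grid` and `probe`.
#' @export
protein_volume <- function(structure, grid = 0.3, probe = 1.4,
                           include_waters = FALSE,
                           altloc_policy = "highest-occupancy") {
  if (grid < 0.2 - 1e-9 || grid > 1.0 + 1e-9)
    stop("grid spacing must lie in [0.2, 1.0] Angstrom")
  st <- strip_to_single_conformer(structure, altloc_policy)
  at <- polymer_atoms(st)
  if (include_waters) at <- rbind(at, water_atoms(st))
  if (!nrow(at)) stop("structure has no polymer atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- vdw_radius(at$element)

  margin <- max(radii) + probe + 2 * grid
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / grid) + 1L, 4L)
  # per-voxel squared distance to nearest atom surface offset is not needed:
  # we only need two masks
  blocked <- array(FALSE, dims)   # probe center cannot sit here
  # the quarter-voxel shrink compensates the center-sampling bias of the
  # discrete blocked set (calibrated on the closed-form single-sphere case)
  for (i in seq_len(nrow(xyz))) {
    r <- radii[i] + probe - grid / 4
    ctr <- (xyz[i, ] - lo) / grid
    i1 <- pmax(floor(ctr - r / grid), 0); i2 <- pmin(ceiling(ctr + r / grid), dims - 1)
    ax <- (i1[1]:i2[1]); ay <- (i1[2]:i2[2]); az <- (i1[3]:i2[3])
    dx2 <- (ax - ctr[1])^2; dy2 <- (ay - ctr[2])^2; dz2 <- (az - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`) * grid^2
    blk <- blocked[ax + 1, ay + 1, az + 1, drop = FALSE]
    blocked[ax + 1, ay + 1, az + 1] <- blk | (d2 <= r^2)
  }
  reach <- flood_fill_from_boundary(!blocked)
  covered <- dilate_by_ball(reach, probe / grid)
  vol <- sum(!covered) * grid^3
  attr(vol, "grid") <- grid
  attr(vol, "probe") <- probe
  vol
}

## reachable voxels: connected (6-neighborhood) to the array boundary
## through `free`; propagation by repeated axis sweeps until stable
flood_fill_from_boundary <- function(free) {
  d <- dim(free)
  reach <- array(FALSE, d)
  reach[1, , ] <- free[1, , ]; reach[d[1], , ] <- free[d[1], , ]
  reach[, 1, ] <- reach[, 1, ] | free[, 1, ]; reach[, d[2], ] <- reach[, d[2], ] | free[, d[2], ]
  reach[, , 1] <- reach[, , 1] | free[, , 1]; reach[, , d[3]] <- reach[, , d[3]] | free[, , d[3]]
  repeat {
    before <- sum(reach)
    for (i in 2:d[1]) reach[i, , ] <- reach[i, , ] | (reach[i - 1, , ] & free[i, , ])
    for (i in (d[1] - 1):1) reach[i, , ] <- reach[i, , ] | (reach[i + 1, , ] & free[i, , ])
    for (j in 2:d[2]) reach[, j, ] <- reach[, j, ] | (reach[, j - 1, ] & free[, j, ])
    for (j in (d[2] - 1):1) reach[, j, ] <- reach[, j, ] | (reach[, j + 1, ] & free[, j, ])
    for (k in 2:d[3]) reach[, , k] <- reach[, , k] | (reach[, , k - 1] & free[, , k])
    for (k in (d[3] - 1):1) reach[, , k] <- reach[, , k] | (reach[, , k + 1] & free[, , k])
    if (sum(reach) == before) break
  }
  reach
}

## binary dilation by a discrete ball of given radius (in voxels)
dilate_by_ball <- function(mask, radius_vox) {
  r <- floor(radius_vox)
  offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  offs <- offs[rowSums(offs^2) <= radius_vox^2, , drop = FALSE]
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    sx <- pmax(1, 1 + o[1]):pmin(d[1], d[1] + o[1])
    sy <- pmax(1, 1 + o[2]):pmin(d[2], d[2] + o[2])
    sz <- pmax(1, 1 + o[3]):pmin(d[3], d[3] + o[3])
    tx <- sx - o[1]; ty <- sy - o[2]; tz <- sz - o[3]
    out[sx, sy, sz] <- out[sx, sy, sz] | mask[tx, ty, tz]
  }
  out
}

#' Signed percent change relative to a reference
#'
#' @param reference,other Positive reference value and comparison value.
#' @param digits Decimal places for the returned value (default 1, the
#'   convention used when reporting volume changes).
#' @return `100 * (other - reference) / reference`, rounded.
#' @examples
#' percent_change(340527.7, 353769.9)  # +3.9
#' @export
percent_change <- function(reference, other, digits = 1) {
  if (any(reference <= 0)) stop("reference must be positive")
  round(100 * (other - reference) / reference, digits)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' as used to compare per-pocket volume distributions between conditions.
#' Wraps [stats::t.test()].
#'
#' @param group_a,group_b Numeric vectors (e.g. pocket volumes in
#'   cubic Angstrom); each needs at least two values and nonzero variance.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || stats::var(group_a) == 0)
    stop("group_a needs >= 2 values with nonzero variance")
  if (length(group_b) < 2 || stats::var(group_b) == 0)
    stop("group_b needs >= 2 values with nonzero variance")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Read a pocket-volume table
#'
#' CSV with columns `structure`, `pocket_id`, `volume_A3`, as produced by
#' an external pocket-detection tool.
#'
#' @param path CSV file path.
#' @return data.frame with those columns.
#' @export
read_pocket_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "pocket_id", "volume_A3")
  if (!all(need %in% names(tab)))
    stop("pocket table must have columns ", paste(need, collapse = ", "))
  if (any(tab$volume_A3 < 0)) stop("pocket volumes must be non-negative")
  tab
}
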