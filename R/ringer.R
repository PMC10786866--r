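## Ringer-style chi1 density sampling: rotate the gamma atom of a side
## chain about the Calpha-Cbeta axis and sample the (sigma-scaled)
## electron density at each candidate gamma position.

## gamma-atom name priority per the documented convention:
## CG > OG/SG > CG1/OG1
.gamma_priority <- c("CG", "OG", "SG", "CG1", "OG1")

gamma_atom_name <- function(res_atoms) {
  present <- intersect(.gamma_priority, res_atoms$name)
  if (length(present)) present[1] else NULL
}

## rotate point p about the axis through `origin` with unit direction u
## by `ang` degrees (Rodrigues)
rotate_about_axis <- function(p, origin, u, ang) {
  v <- p - origin
  th <- ang * pi / 180
  vr <- v * cos(th) + cross3(u, v) * sin(th) + u * sum(u * v) * (1 - cos(th))
  origin + vr
}

#' Ringer chi1 density curve for one residue
#'
#' For each angle theta in `{0, step, ..., 360-step}` the residue's gamma
#' atom is swung about the Calpha->Cbeta axis so that the chi1 dihedral
#' (N-CA-CB-gamma) equals theta, preserving the model's CB-gamma bond
#' length and CA-CB-gamma angle, and the map is sampled at that point.
#' When the gamma atom is missing it is constructed with ideal geometry
#' (1.52 Angstrom, 114 degrees).
#'
#' @param map A [density_map()] sharing the structure's crystal frame.
#' @param structure A [crystal_structure()] (use
#'   [strip_to_single_conformer()] first if it carries altlocs).
#' @param resno Author residue number (with `chain`/`icode` to
#'   disambiguate).
#' @param chain,icode Optional residue qualifiers.
#' @param step Angular step in degrees; must divide 360 (default 10).
#' @param mode Interpolation kernel for [map_value_at()].
#' @param scale `"sigma"` (default) or `"raw"`.
#' @return Object of class `ringer_curve`: list with `angle` (degrees),
#'   `density`, residue metadata and `step`.
#' @export
ringer_curve <- function(map, structure, resno, chain = NULL, icode = "",
                         step = 10, mode = "trilinear", scale = "sigma") {
  if (360 %% step != 0) stop("step must divide 360")
  at <- polymer_atoms(structure)
  sel <- at$resno == resno & at$icode == icode
  if (!is.null(chain)) sel <- sel & at$chain == chain
  res <- at[sel, , drop = FALSE]
  if (!nrow(res)) stop("residue ", resno, " not found")
  restype <- res$resid[1]
  if (restype %in% c("GLY", "ALA")) {
    message(restype, " ", resno, " has no chi1; skipped")
    return(NULL)
  }
  n <- get_atom_coord(res, "N"); ca <- get_atom_coord(res, "CA")
  cb <- get_atom_coord(res, "CB")
  if (is.null(n) || is.null(ca) || is.null(cb))
    stop("residue ", resno, " is missing N/CA/CB")
  gname <- gamma_atom_name(res)
  if (!is.null(gname)) {
    g <- get_atom_coord(res, gname)
  } else {
    # ideal-geometry gamma: 1.52 A from CB, 114 deg CA-CB-gamma, chi1 = 180
    g <- place_atom(n, ca, cb, 1.52, 114, 180)
    gname <- "CG*"
  }
  chi_now <- dihedral(n, ca, cb, g)
  u <- cb - ca; u <- u / sqrt(sum(u^2))
  angles <- seq(0, 360 - step, by = step)
  pts <- t(vapply(angles, function(th)
    rotate_about_axis(g, cb, u, th - chi_now), numeric(3)))
  dens <- map_value_at(map, pts, mode = mode, scale = scale)
  structure(list(angle = angles, density = dens,
                 chain = res$chain[1], resno = resno, icode = icode,
                 restype = restype, gamma_atom = gname, chi = 1,
                 step = step),
            class = "ringer_curve")
}

#' @export
print.ringer_curve <- function(x, ...) {
  cat(sprintf("Ringer curve %s %s%d: chi1 sampled every %d deg, max %.2f sigma at %d deg\n",
              x$restype, x$chain, x$resno, x$step,
              max(x$density), x$angle[which.max(x$density)]))
  invisible(x)
}

#' @export
plot.ringer_curve <- function(x, ...) {
  plot(x$angle, x$density, type = "l", xlab = "chi1 (degrees)",
       ylab = "density (sigma)",
       main = sprintf("%s %s%d", x$restype, x$chain, x$resno), ...)
  invisible(x)
}

#' Ringer curves for all eligible residues of a structure
#'
#' @inheritParams ringer_curve
#' @return Named list of [ringer_curve()] objects keyed by
#'   `"chain|resno|icode"`.
#' @export
ringer_curves <- function(map, structure, step = 10, mode = "trilinear",
                          scale = "sigma") {
  at <- polymer_atoms(structure)
  keys <- unique(residue_key(at))
  out <- list()
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    chain <- parts[1]; resno <- as.integer(parts[2])
    icode <- if (length(parts) >= 3) parts[3] else ""
    res <- at[residue_key(at) == k, , drop = FALSE]
    if (res$resid[1] %in% c("GLY", "ALA")) next
    if (is.null(get_atom_coord(res, "CB"))) next
    out[[k]] <- ringer_curve(map, structure, resno, chain, icode,
                             step = step, mode = mode, scale = scale)
  }
  out
}

#' Pearson correlation between two Ringer curves
#'
#' @param c1,c2 [ringer_curve()] objects on identical angle grids.
#' @return Pearson correlation coefficient; `NA` (with attribute
#'   `undefined = TRUE`) when either curve is flat.
#' @export
curve_cc <- function(c1, c2) {
  if (length(c1$angle) != length(c2$angle) || any(c1$angle != c2$angle))
    stop("curves are on different angle grids")
  flat <- function(v)            # tolerate interpolation round-off
    stats::sd(v) <= 1e-10 * max(1, abs(mean(v)))
  if (flat(c1$density) || flat(c2$density)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(c1$density, c2$density)
}

#' Compare Ringer curve sets and flag changed residues
#'
#' @param curves_a,curves_b Named lists from [ringer_curves()].
#' @param threshold CC below which a residue is flagged (default 0.5).
#' @param exclude Residue ranges excluded from flagging (see
#'   [rotamer_diff()] for the format).
#' @return Object of class `ringer_comparison`: data.frame `table`
#'   (chain, resno, icode, restype, cc, changed), `flagged` subset,
#'   counts/percentages over residues with defined CC, and the list of
#'   undefined (flat-curve) residues.
#' @export
flag_changed_residues <- function(curves_a, curves_b, threshold = 0.5,
                                  exclude = NULL) {
  shared <- intersect(names(curves_a), names(curves_b))
  rows <- list()
  for (k in shared) {
    cc <- curve_cc(curves_a[[k]], curves_b[[k]])
    cv <- curves_a[[k]]
    rows[[length(rows) + 1]] <- data.frame(
      chain = cv$chain, resno = cv$resno, icode = cv$icode,
      restype = cv$restype, cc = as.numeric(cc),
      undefined = isTRUE(attr(cc, "undefined")),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  excl <- parse_residue_ranges(exclude)
  tab <- tab[!in_ranges(tab$resno, excl), , drop = FALSE]
  defined <- tab[!tab$undefined, , drop = FALSE]
  defined$changed <- defined$cc < threshold
  flagged <- defined[defined$changed, , drop = FALSE]
  structure(list(table = defined, flagged = flagged,
                 undefined = tab[tab$undefined, , drop = FALSE],
                 threshold = threshold,
                 count = nrow(flagged), n_evaluated = nrow(defined),
                 percent = round(100 * nrow(flagged) /
                                   max(1, nrow(defined)), 1)),
            class = "ringer_comparison")
}

#' @export
print.ringer_comparison <- function(x, ...) {
  cat(sprintf("Ringer CC comparison: %d of %d residues with CC < %.2f (%.1f%%)\n",
              x$count, x$n_evaluated, x$threshold, x$percent))
  if (nrow(x$undefined))
    cat(nrow(x$undefined), "residue(s) with flat curves excluded\n")
  invisible(x)
}

#' Circular peak detection on a Ringer curve
#'
#' Local maxima on the periodic angle grid above a density floor,
#' returned sorted by height (dominant peak first).
#'
#' @param curve A [ringer_curve()].
#' @param min_sigma Minimum peak height in sigma units (default 0.3).
#' @return data.frame with columns `angle` and `height`.
#' @export
find_peaks <- function(curve, min_sigma = 0.3) {
  v <- curve$density
  n <- length(v)
  prev <- v[c(n, 1:(n - 1))]
  nxt <- v[c(2:n, 1)]
  is_peak <- v > prev & v >= nxt & v >= min_sigma
  out <- data.frame(angle = curve$angle[is_peak], height = v[is_peak])
  out[order(-out$height), , drop = FALSE]
}
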