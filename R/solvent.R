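## Symmetry-aware comparison of ordered solvent between structures.
##
## Frame reconciliation: isomorphous crystals under different conditions
## have cells differing by a few percent. By default each structure's
## water coordinates are fractionalized in its own cell and
## re-orthogonalized in the reference cell, so "the same" lattice
## position maps onto itself. A superposition-based Cartesian mode is
## available as an alternative.

## fractional water coordinates of a structure (own cell), one row per
## water atom; altloc copies count as distinct positions
water_frac <- function(structure) {
  w <- water_atoms(structure)
  if (!nrow(w)) return(matrix(numeric(), 0, 3))
  orth_to_frac(as.matrix(w[, c("x", "y", "z")]), structure$cell)
}

water_ids <- function(structure) {
  w <- water_atoms(structure)
  paste0(w$chain, w$resno, w$icode,
         ifelse(w$altloc == "", "", paste0(".", w$altloc)))
}

#' Minimum symmetry-aware distance from a point to a water set
#'
#' Minimum Euclidean distance from a query position to any
#' crystal-symmetry image (all operators times lattice translations
#' within `shell`) of any water in `others_frac`.
#'
#' @param query_frac Fractional coordinates of the query position(s)
#'   (3-vector or n x 3 matrix), expressed in `cell`.
#' @param others_frac n x 3 matrix of fractional water coordinates of the
#'   comparison set, expressed in the same `cell`.
#' @param cell Reference [unit_cell()] used to measure distances.
#' @param ops Symmetry operators of the crystal.
#' @param shell Lattice translation shell (default 1 = 27 neighbor cells,
#'   exhaustive for thresholds far below the cell edges).
#' @return Numeric vector: one minimum distance (Angstrom) per query row.
#' @export
min_symmetry_distance <- function(query_frac, others_frac, cell, ops,
                                  shell = 1) {
  query_frac <- rbind(query_frac)
  others_frac <- rbind(others_frac)
  if (!nrow(others_frac)) stop("comparison structure has no waters")
  images <- symmetry_expand(others_frac, ops, shell)
  img_xyz <- frac_to_orth(images, cell)
  q_xyz <- frac_to_orth(query_frac, cell)
  out <- numeric(nrow(q_xyz))
  for (i in seq_len(nrow(q_xyz))) {
    d2 <- (img_xyz[, 1] - q_xyz[i, 1])^2 + (img_xyz[, 2] - q_xyz[i, 2])^2 +
      (img_xyz[, 3] - q_xyz[i, 3])^2
    out[i] <- sqrt(min(d2))
  }
  out
}

#' Classify waters as unique or shared between structures
#'
#' A water of `query` is unique when its minimum symmetry-aware distance
#' to the waters of every reference structure exceeds `threshold`.
#'
#' @param query A [crystal_structure()] whose waters are classified.
#' @param references A [crystal_structure()] or list of them.
#' @param threshold Distance threshold in Angstrom (default 2.0).
#' @param frame `"fractional"` (default): coordinates are compared as
#'   fractional points re-orthogonalized in the query's cell;
#'   `"superposed"`: each reference is rigid-body superposed onto the
#'   query by shared C-alpha atoms before comparison.
#' @param shell Lattice translation shell for symmetry images.
#' @return Object of class `water_comparison`: list with `table`
#'   (data.frame: water_id, min_dist_A, unique), `threshold`, `counts`
#'   (unique, shared, total), labels, and `cell_deltas` (percent cell
#'   edge differences vs the query).
#' @export
unique_waters <- function(query, references, threshold = 2.0,
                          frame = c("fractional", "superposed"), shell = 1) {
  frame <- match.arg(frame)
  if (inherits(references, "crystal_structure")) references <- list(references)
  if (!length(references)) stop("at least one reference structure is required")
  qw <- water_frac(query)
  if (!nrow(qw)) stop("query structure has no waters")
  cell <- query$cell
  mind <- rep(Inf, nrow(qw))
  cell_deltas <- list()
  for (ref in references) {
    cell_deltas[[ref$label]] <- round(100 * (unlist(ref$cell[c("a", "b", "c")]) -
      unlist(cell[c("a", "b", "c")])) / unlist(cell[c("a", "b", "c")]), 2)
    if (frame == "fractional") {
      rw <- water_frac(ref)
    } else {
      fit <- superpose(ref, query)
      w <- water_atoms(ref)
      xyz <- sweep(as.matrix(w[, c("x", "y", "z")]) %*% t(fit$rotation), 2,
                   fit$translation, `+`)
      rw <- orth_to_frac(xyz, cell)
    }
    d <- min_symmetry_distance(qw, rw, cell, query$ops, shell)
    mind <- pmin(mind, d)
  }
  uniq <- mind > threshold
  tab <- data.frame(water_id = water_ids(query),
                    min_dist_A = mind, unique = uniq,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, threshold = threshold,
                 query_label = query$label,
                 reference_labels = vapply(references, `[[`, "", "label"),
                 counts = c(unique = sum(uniq), shared = sum(!uniq),
                            total = length(uniq)),
                 frame = frame, cell_deltas = cell_deltas),
            class = "water_comparison")
}

#' @export
print.water_comparison <- function(x, ...) {
  cat(sprintf("Water comparison: %s vs {%s} at %.2f A (%s frame)\n",
              x$query_label, paste(x$reference_labels, collapse = ", "),
              x$threshold, x$frame))
  cat(sprintf("  unique %d / %d (%.1f%%), shared %d\n",
              x$counts["unique"], x$counts["total"],
              100 * x$counts["unique"] / x$counts["total"],
              x$counts["shared"]))
  invisible(x)
}
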