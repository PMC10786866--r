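## CrystalStructure container: atoms + unit cell + space-group operators.

.atom_cols <- c("element", "name", "altloc", "occ", "b",
                "x", "y", "z", "chain", "resno", "icode", "resid", "kind")

#' Construct a crystal structure object
#'
#' @param atoms data.frame with columns `element`, `name`, `altloc`, `occ`,
#'   `b`, `x`, `y`, `z`, `chain`, `resno`, `icode`, `resid` (3-letter code)
#'   and `kind` (one of `"polymer"`, `"water"`, `"het"`).
#' @param cell A [unit_cell()].
#' @param spacegroup Hermann-Mauguin space-group symbol.
#' @param label Free-text label for the structure (e.g. `"LoTP"`).
#' @param ops Optional list of symmetry operators; derived from
#'   `spacegroup` when omitted.
#' @return Object of class `crystal_structure`.
#' @export
crystal_structure <- function(atoms, cell, spacegroup = "P 1",
                              label = "structure", ops = NULL) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(atoms$occ < -1e-9 | atoms$occ > 1 + 1e-9))
    stop("occupancies must lie in [0,1]")
  if (any(atoms$b < 0)) stop("B-factors must be non-negative")
  if (is.null(ops)) ops <- spacegroup_ops(spacegroup)
  st <- structure(list(label = label,
                       atoms = atoms[, .atom_cols],
                       cell = cell,
                       spacegroup = normalize_spacegroup_symbol(spacegroup),
                       ops = ops,
                       warnings = character()),
                  class = "crystal_structure")
  st$warnings <- check_altloc_occupancy(st)
  st
}

#' @export
print.crystal_structure <- function(x, ...) {
  n_poly <- sum(x$atoms$kind == "polymer")
  n_wat <- sum(x$atoms$kind == "water")
  cat(sprintf("<crystal_structure '%s'>  %d atoms (%d polymer, %d water, %d het)\n",
              x$label, nrow(x$atoms), n_poly, n_wat,
              nrow(x$atoms) - n_poly - n_wat))
  print(x$cell)
  cat("Space group:", x$spacegroup, sprintf("(%d operators)\n", length(x$ops)))
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

## residue identity key: chain | resno | icode
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
}

## total occupancy per altloc group must not exceed 1 (tolerance 0.01);
## blank altloc is common to all conformers and not summed with them
check_altloc_occupancy <- function(structure) {
  at <- structure$atoms[structure$atoms$kind == "polymer" &
                          structure$atoms$altloc != "", , drop = FALSE]
  if (!nrow(at)) return(character())
  warnings <- character()
  key <- paste(residue_key(at), at$name)
  tot <- tapply(at$occ, key, sum)
  bad <- names(tot)[tot > 1 + 0.01]
  if (length(bad))
    warnings <- sprintf("altloc occupancy sum > 1 at %d atom site(s), e.g. %s (%.2f)",
                        length(bad), bad[1], tot[bad[1]])
  warnings
}

atom_xyz <- function(structure, subset = NULL) {
  at <- structure$atoms
  if (!is.null(subset)) at <- at[subset, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

water_atoms <- function(structure) {
  structure$atoms[structure$atoms$kind == "water", , drop = FALSE]
}

polymer_atoms <- function(structure) {
  structure$atoms[structure$atoms$kind == "polymer", , drop = FALSE]
}

#' Reduce a structure to a single conformer per residue
#'
#' Keeps, for every residue, either the highest-occupancy conformer or a
#' named alternate-location label; blank-altloc atoms (common to all
#' conformers) are always retained. Occupancies of retained atoms are set
#' to 1 and the choice is recorded in the structure's `conformer_choice`
#' field.
#'
#' @param structure A [crystal_structure()].
#' @param policy `"highest-occupancy"`, or an altloc label such as `"B"`
#'   (falls back to highest occupancy where that label is absent).
#' @return A [crystal_structure()] with one conformer per residue.
#' @export
strip_to_single_conformer <- function(structure, policy = "highest-occupancy") {
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  choice <- character()
  keys <- residue_key(at)
  for (k in unique(keys[at$altloc != ""])) {
    idx <- which(keys == k & at$altloc != "")
    labels <- unique(at$altloc[idx])
    if (length(labels) <= 1) { choice[k] <- labels; next }
    pick <- if (policy != "highest-occupancy" && policy %in% labels) policy
            else labels[which.max(vapply(labels, function(l)
              mean(at$occ[idx][at$altloc[idx] == l]), numeric(1)))]
    keep[idx[at$altloc[idx] != pick]] <- FALSE
    choice[k] <- pick
  }
  at <- at[keep, , drop = FALSE]
  at$occ <- 1
  at$altloc <- ""
  out <- crystal_structure(at, structure$cell, structure$spacegroup,
                           structure$label, structure$ops)
  out$conformer_choice <- choice
  out
}

## per-residue list of conformer atom tables; blank altloc merged into each
residue_conformers <- function(res_atoms) {
  labels <- setdiff(unique(res_atoms$altloc), "")
  if (!length(labels)) return(list(" " = res_atoms))
  common <- res_atoms[res_atoms$altloc == "", , drop = FALSE]
  out <- lapply(labels, function(l)
    rbind(common, res_atoms[res_atoms$altloc == l, , drop = FALSE]))
  names(out) <- labels
  out
}

## named coordinate lookup within one residue/conformer table
get_atom_coord <- function(res_atoms, name) {
  i <- which(res_atoms$name == name)
  if (!length(i)) return(NULL)
  as.numeric(res_atoms[i[1], c("x", "y", "z")])
}
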