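## Reduced-dimensionality torsion-angle embedding of a structure set:
## backbone (phi, psi) and side-chain (chi1..chi4) torsions, vectorized
## as (sin, cos) pairs and decomposed by PCA.

#' Extract backbone and side-chain torsions from a structure
#'
#' Phi and psi are computed for every residue with intact peptide-bonded
#' neighbors (a C-N distance above 2 Angstrom is treated as a chain
#' break and masked); chi angles follow the residue type. Alternate
#' conformers are reduced by the given policy first.
#'
#' @param structure A [crystal_structure()].
#' @param policy Conformer policy for [strip_to_single_conformer()].
#' @return data.frame with columns `key` (`chain|resno|icode|torsion`),
#'   `torsion` (`phi`, `psi`, `chi1`..`chi4`) and `angle` (degrees);
#'   missing torsions are absent rather than NA.
#' @export
extract_torsions <- function(structure, policy = "highest-occupancy") {
  st <- strip_to_single_conformer(structure, policy)
  at <- polymer_atoms(st)
  if (!nrow(at)) stop("structure has no polymer atoms")
  keys <- residue_key(at)
  ukeys <- unique(keys)
  res_list <- lapply(ukeys, function(k) at[keys == k, , drop = FALSE])
  names(res_list) <- ukeys
  get3 <- function(i, nm) if (i >= 1 && i <= length(res_list))
    get_atom_coord(res_list[[i]], nm) else NULL
  rows <- list()
  add <- function(key, torsion, angle)
    rows[[length(rows) + 1]] <<- data.frame(key = paste(key, torsion, sep = "|"),
                                            torsion = torsion, angle = angle,
                                            stringsAsFactors = FALSE)
  bonded <- function(c_prev, n_next)
    !is.null(c_prev) && !is.null(n_next) &&
      sqrt(sum((c_prev - n_next)^2)) < 2.0
  for (i in seq_along(res_list)) {
    res <- res_list[[i]]
    k <- ukeys[i]
    n <- get_atom_coord(res, "N"); ca <- get_atom_coord(res, "CA")
    cc <- get_atom_coord(res, "C")
    # phi: C(i-1)-N-CA-C
    cp <- get3(i - 1, "C")
    if (!is.null(n) && !is.null(ca) && !is.null(cc) && bonded(cp, n))
      add(k, "phi", dihedral(cp, n, ca, cc))
    # psi: N-CA-C-N(i+1)
    nn <- get3(i + 1, "N")
    if (!is.null(n) && !is.null(ca) && !is.null(cc) && bonded(cc, nn))
      add(k, "psi", dihedral(n, ca, cc, nn))
    chis <- residue_chis(res, res$resid[1])
    for (j in seq_along(chis))
      if (!is.na(chis[j])) add(k, paste0("chi", j), chis[j])
  }
  out <- do.call(rbind, rows)
  attr(out, "label") <- structure$label
  out
}

#' PCA embedding of structures in torsion-angle space
#'
#' Torsions present in every structure (the complete-case mask) are each
#' encoded as (sin, cos); features are centered on their mean and
#' decomposed by singular-value decomposition. The sign of each
#' component is fixed by making its largest-magnitude loading positive.
#'
#' @param torsion_list List of data.frames from [extract_torsions()]
#'   (>= 3 structures).
#' @param n_components Number of components to report (default 2).
#' @param weights Optional named per-torsion weight vector (names
#'   `phi`, `psi`, `chi1`..; default uniform).
#' @return Object of class `torsion_embedding`: `scores` (structure x
#'   component), `explained` (variance fractions, non-increasing),
#'   `loadings` (feature x component), `labels`, `mask` (torsion keys
#'   used).
#' @export
embed_torsions <- function(torsion_list, n_components = 2, weights = NULL) {
  if (length(torsion_list) < 3)
    stop("need at least 3 structures for a torsion embedding")
  labels <- vapply(seq_along(torsion_list), function(i) {
    l <- attr(torsion_list[[i]], "label")
    if (is.null(l)) paste0("structure", i) else l
  }, character(1))
  mask <- Reduce(intersect, lapply(torsion_list, `[[`, "key"))
  if (!length(mask)) stop("no torsions shared by all structures")
  ang <- vapply(torsion_list, function(tv)
    tv$angle[match(mask, tv$key)], numeric(length(mask)))
  ang <- t(ang) * pi / 180                     # structures x torsions
  w <- rep(1, length(mask))
  if (!is.null(weights)) {
    tnames <- sub("^.*\\|", "", mask)
    w <- ifelse(tnames %in% names(weights), weights[tnames], 1)
  }
  sw <- sqrt(w)
  X <- cbind(sweep(sin(ang), 2, sw, `*`), sweep(cos(ang), 2, sw, `*`))
  X <- sweep(X, 2, colMeans(X))
  s <- svd(X)
  total_var <- sum(s$d^2)
  k <- min(n_components, length(s$d))
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                      # deterministic sign
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- labels
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- c(paste0("sin:", mask), paste0("cos:", mask))
  colnames(loadings) <- colnames(scores)
  structure(list(scores = scores,
                 explained = if (total_var > 0) s$d[seq_len(k)]^2 / total_var
                             else rep(0, k),
                 singular_values = s$d,
                 loadings = loadings, labels = labels, mask = mask),
            class = "torsion_embedding")
}

#' @export
print.torsion_embedding <- function(x, ...) {
  cat(sprintf("Torsion embedding: %d structures, %d shared torsions\n",
              length(x$labels), length(x$mask)))
  cat("Explained variance:",
      paste(sprintf("%s %.1f%%", colnames(x$scores), 100 * x$explained),
            collapse = ", "), "\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' @export
plot.torsion_embedding <- function(x, ...) {
  plot(x$scores[, 1], x$scores[, 2],
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  text(x$scores[, 1], x$scores[, 2], labels = x$labels, pos = 3, cex = 0.8)
  invisible(x)
}
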