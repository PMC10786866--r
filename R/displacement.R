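## Backbone displacement analytics: rigid superposition, per-residue
## C-alpha distance profiles, multi-structure RMSF, and intra-structure
## alternate-conformer separations.

## per-(residue, altloc) C-alpha coordinate table
ca_table <- function(structure) {
  at <- polymer_atoms(structure)
  ca <- at[at$name == "CA", , drop = FALSE]
  data.frame(chain = ca$chain, resno = ca$resno, icode = ca$icode,
             altloc = ca$altloc, occ = ca$occ,
             x = ca$x, y = ca$y, z = ca$z,
             key = residue_key(ca), stringsAsFactors = FALSE)
}

## representative (highest-occupancy) C-alpha per residue
ca_representative <- function(structure) {
  tab <- ca_table(structure)
  tab <- tab[order(tab$key, -tab$occ), ]
  tab[!duplicated(tab$key), , drop = FALSE]
}

#' Rigid-body least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the C-alpha RMSD
#' of `mobile` onto `reference` over shared residues.
#'
#' @param mobile,reference [crystal_structure()] objects.
#' @param selection Optional character vector of residue keys
#'   (`"chain|resno|icode"`) to fit on; default all shared residues.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `n` (atoms fitted). Apply as
#'   `x %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  cm <- ca_representative(mobile)
  cr <- ca_representative(reference)
  shared <- intersect(cm$key, cr$key)
  if (!is.null(selection)) shared <- intersect(shared, selection)
  if (length(shared) < 3)
    stop("need at least 3 shared C-alpha atoms to superpose (have ",
         length(shared), ")")
  X <- as.matrix(cm[match(shared, cm$key), c("x", "y", "z")])
  Y <- as.matrix(cr[match(shared, cr$key), c("x", "y", "z")])
  fit <- kabsch(X, Y)
  Xf <- sweep(X %*% t(fit$rotation), 2, fit$translation, `+`)
  fit$rmsd <- sqrt(mean(rowSums((Xf - Y)^2)))
  fit$n <- length(shared)
  fit
}

## Kabsch algorithm: rotation/translation mapping X onto Y
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, translation = as.numeric(cy - R %*% cx))
}

transform_structure <- function(structure, rotation, translation) {
  xyz <- atom_xyz(structure)
  xyz <- sweep(xyz %*% t(rotation), 2, translation, `+`)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Per-residue C-alpha distance profile between two structures
#'
#' For every residue shared by `a` and `b`, the Euclidean C-alpha
#' distance, optionally after global rigid superposition. With alternate
#' conformers, altloc labels are paired like-with-like (A with A); a
#' conformer with no partner falls back to the partner structure's
#' highest-occupancy conformer, so e.g. a dual-conformation loop in one
#' structure yields one profile row per conformer.
#'
#' @param a,b [crystal_structure()] objects (`b` is the reference).
#' @param mode `"superposed"` (default; `a` is fitted onto `b` over all
#'   shared residues first) or `"crystal-frame"` (raw coordinates).
#' @param fit_exclude Optional residue keys excluded from the
#'   superposition fit (still profiled).
#' @return Object of class `displacement_profile`: data.frame with
#'   columns chain, resno, icode, altloc, ca_dist_A, plus attributes
#'   `mode`, `only_a`, `only_b` (residues present in one structure).
#' @export
ca_distance_profile <- function(a, b, mode = c("superposed", "crystal-frame"),
                                fit_exclude = NULL) {
  mode <- match.arg(mode)
  ta <- ca_table(a); tb <- ca_table(b)
  shared <- intersect(unique(ta$key), unique(tb$key))
  if (!length(shared)) stop("no shared residues between structures")
  if (mode == "superposed") {
    sel <- setdiff(shared, fit_exclude)
    fit <- superpose(a, b, selection = sel)
    xyz <- as.matrix(ta[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(fit$rotation), 2, fit$translation, `+`)
    ta[, c("x", "y", "z")] <- xyz
  }
  rows <- list()
  for (k in shared) {
    ra <- ta[ta$key == k, , drop = FALSE]
    rb <- tb[tb$key == k, , drop = FALSE]
    rb_best <- rb[which.max(rb$occ), , drop = FALSE]
    for (i in seq_len(nrow(ra))) {
      partner <- rb[rb$altloc == ra$altloc[i], , drop = FALSE]
      if (!nrow(partner)) partner <- rb_best
      d <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                     as.numeric(partner[1, c("x", "y", "z")]))^2))
      rows[[length(rows) + 1]] <- data.frame(
        chain = ra$chain[i], resno = ra$resno[i], icode = ra$icode[i],
        altloc = ra$altloc[i], ca_dist_A = d, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resno, out$icode, out$altloc), ]
  rownames(out) <- NULL
  structure(out, class = c("displacement_profile", "data.frame"),
            mode = mode,
            only_a = setdiff(unique(ta$key), shared),
            only_b = setdiff(unique(tb$key), shared))
}

#' Per-residue C-alpha RMSF over a set of structures
#'
#' Root-mean-square fluctuation of each residue's C-alpha about its mean
#' position across the structures, after superposing all structures onto
#' the first (highest-occupancy conformers).
#'
#' @param structures List of >= 2 [crystal_structure()] objects.
#' @param superpose_first Superpose all structures onto the first before
#'   measuring (default TRUE).
#' @return data.frame with chain, resno, icode, rmsf_A for residues
#'   shared by all structures.
#' @export
ca_rmsf <- function(structures, superpose_first = TRUE) {
  if (length(structures) < 2) stop("need at least 2 structures for RMSF")
  tabs <- lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    if (superpose_first && i > 1) {
      fit <- superpose(s, structures[[1]])
      s <- transform_structure(s, fit$rotation, fit$translation)
    }
    ca_representative(s)
  })
  shared <- Reduce(intersect, lapply(tabs, `[[`, "key"))
  coords <- lapply(tabs, function(t) as.matrix(
    t[match(shared, t$key), c("x", "y", "z")]))
  arr <- simplify2array(coords)              # residue x 3 x structure
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply(arr, 3, function(m) rowSums((m - mean_pos)^2))
  rmsf <- sqrt(rowMeans(rbind(dev2)))
  ref <- tabs[[1]][match(shared, tabs[[1]]$key), ]
  data.frame(chain = ref$chain, resno = ref$resno, icode = ref$icode,
             rmsf_A = as.numeric(rmsf), stringsAsFactors = FALSE)
}

#' C-alpha separation between alternate conformers of one residue
#'
#' @param structure A [crystal_structure()].
#' @param resno Author residue number.
#' @param chain Optional chain id (required when ambiguous).
#' @param icode Insertion code (default blank).
#' @return data.frame with columns altloc_1, altloc_2, dist_A, one row
#'   per conformer pair; zero rows (with a message) for single-conformer
#'   residues.
#' @export
altloc_ca_separation <- function(structure, resno, chain = NULL, icode = "") {
  tab <- ca_table(structure)
  sel <- tab$resno == resno & tab$icode == icode
  if (!is.null(chain)) sel <- sel & tab$chain == chain
  tab <- tab[sel, , drop = FALSE]
  if (length(unique(tab$chain)) > 1)
    stop("residue ", resno, " is present in multiple chains; specify `chain`")
  empty <- data.frame(altloc_1 = character(), altloc_2 = character(),
                      dist_A = numeric(), stringsAsFactors = FALSE)
  if (nrow(tab) < 2) {
    message("residue ", resno, " has a single C-alpha conformer")
    return(empty)
  }
  pairs <- utils::combn(nrow(tab), 2)
  data.frame(altloc_1 = tab$altloc[pairs[1, ]],
             altloc_2 = tab$altloc[pairs[2, ]],
             dist_A = apply(pairs, 2, function(p)
               sqrt(sum((as.numeric(tab[p[1], c("x", "y", "z")]) -
                         as.numeric(tab[p[2], c("x", "y", "z")]))^2))),
             stringsAsFactors = FALSE)
}
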