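## Side-chain torsion angles and rotamer classification.

#' Signed dihedral angle of four points
#'
#' IUPAC-signed torsion angle, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Cartesian 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("collinear points: dihedral undefined")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## chi-angle atom quadruples per residue type; `symm_last` marks a
## two-fold-symmetric terminal torsion (folded into (-90, 90] for
## mode matching)
.chi_atoms <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

.chi_symm_last <- c(ASP = TRUE, GLU = TRUE, PHE = TRUE, TYR = TRUE)

## canonical chi-class modes for combinatorially named residue types
.cls_modes <- c(p = 62, t = 180, m = -65)

combi_modes <- function(nchi, last = .cls_modes) {
  grids <- c(rep(list(.cls_modes), nchi - 1), list(last))
  combos <- do.call(expand.grid, lapply(grids, names))
  out <- lapply(seq_len(nrow(combos)), function(i)
    mapply(function(g, nm) g[[nm]], grids, as.character(unlist(combos[i, ]))))
  names(out) <- apply(combos, 1, paste0, collapse = "")
  out
}

## built-in modal chi values per rotamer per residue type, following the
## penultimate/MolProbity-style p/t/m nomenclature
.rotamer_modes <- local({
  tab <- list(
    SER = list(p = 64, t = 178, m = -65),
    CYS = list(p = 62, t = 178, m = -65),
    VAL = list(p = 64, t = 175, m = -60),
    THR = list(p = 59, t = 175, m = -61),
    LEU = list(pp = c(62, 80), tp = c(177, 65), tt = c(-172, 147),
               mt = c(-65, 175), mp = c(-85, 65)),
    ILE = list(pt = c(62, 170), pp = c(62, 100), tt = c(-167, 166),
               tp = c(-167, 66), mt = c(-65, 170), mm = c(-57, -60),
               mp = c(-65, 100)),
    ASP = list("p" = c(62, -10), "t" = c(-177, 0), "m" = c(-70, -20)),
    ASN = list("p10" = c(62, -10), "p30" = c(62, 30), "t0" = c(-174, 0),
               "t60" = c(-177, 60), "m20" = c(-65, -20), "m80" = c(-65, -75),
               "m120" = c(-65, 120)),
    PHE = list("p90" = c(62, 90), "t80" = c(177, 80), "m30" = c(-65, -30),
               "m85" = c(-65, 85)),
    TYR = list("p90" = c(62, 90), "t80" = c(177, 80), "m30" = c(-65, -30),
               "m85" = c(-65, 85)),
    TRP = list("p90" = c(62, 90), "p-90" = c(62, -90), "t105" = c(-177, -105),
               "t90" = c(-177, 90), "m0" = c(-65, -5), "m95" = c(-65, 95)),
    HIS = list("p80" = c(62, -75), "p90" = c(62, 80), "t60" = c(-177, 60),
               "t80" = c(-177, -80), "m70" = c(-65, -70), "m90" = c(-65, 90))
  )
  tab$MET <- combi_modes(3, c(p = 75, t = 180, m = -75))
  tab$LYS <- combi_modes(4)
  tab$ARG <- combi_modes(4, c(p = 85, t = 180, m = -85))
  tab$GLU <- combi_modes(3, c(p = 20, t = 0, m = -20))
  tab$GLN <- combi_modes(3, c(p = 40, t = 0, m = -40))
  tab
})

#' Number of chi angles expected for a residue type
#' @param restype Three-letter residue code.
#' @return Integer (0 for GLY/ALA and unknown types).
#' @export
n_chi <- function(restype) {
  def <- .chi_atoms[[toupper(restype)]]
  if (is.null(def)) 0L else length(def)
}

## wrapped angular difference in degrees, in [0, 180]
ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

## fold a two-fold-symmetric torsion into (-90, 90]
fold_symmetric <- function(a) {
  a <- ((a + 90) %% 180) - 90
  ifelse(a <= -90, a + 180, a)
}

#' Chi-1 rotamer class
#'
#' `p` near +60 (chi1 in [0, 120)), `t` near 180 ([120, 240)), `m` near
#' -60 ([240, 360), i.e. (-120, 0)).
#'
#' @param chi1 Chi-1 angle in degrees.
#' @return `"p"`, `"t"` or `"m"`.
#' @export
chi1_class <- function(chi1) {
  a <- chi1 %% 360
  ifelse(a < 120, "p", ifelse(a < 240, "t", "m"))
}

#' Assign a rotamer name from chi angles
#'
#' Nearest mode in the built-in modal-value table under wrapped angular
#' distance; `"OUTLIER"` when any chi deviates more than `outlier_cut`
#' degrees from its nearest mode. Terminal torsions with two-fold
#' symmetry (Asp, Glu, Phe, Tyr) are folded before matching.
#'
#' @param restype Three-letter residue code.
#' @param chis Numeric vector of chi angles in degrees.
#' @param outlier_cut Per-chi deviation limit in degrees (default 40).
#' @return Rotamer name, with attribute `chi1_class`.
#' @export
name_rotamer <- function(restype, chis, outlier_cut = 40) {
  restype <- toupper(restype)
  modes <- .rotamer_modes[[restype]]
  if (is.null(modes)) stop("no rotamer table for residue type ", restype)
  expected <- n_chi(restype)
  if (length(chis) != expected)
    stop(restype, " expects ", expected, " chi angle(s), got ", length(chis))
  symm <- isTRUE(.chi_symm_last[restype])
  dev_to <- function(mode) {
    d <- ang_diff(chis, mode)
    if (symm) {
      k <- length(chis)
      d[k] <- abs(fold_symmetric(chis[k]) - fold_symmetric(mode[k]))
      d[k] <- min(d[k], 180 - d[k])
    }
    d
  }
  devs <- vapply(modes, function(m) max(dev_to(m)), numeric(1))
  best <- which.min(devs)
  name <- if (devs[best] > outlier_cut) "OUTLIER" else names(modes)[best]
  attr(name, "chi1_class") <- chi1_class(chis[1])
  name
}

## chi angles for one residue conformer table; NA where atoms missing
residue_chis <- function(res_atoms, restype) {
  def <- .chi_atoms[[toupper(restype)]]
  if (is.null(def)) return(numeric())
  vapply(def, function(quad) {
    pts <- lapply(quad, get_atom_coord, res_atoms = res_atoms)
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }, numeric(1))
}

#' Rotamer assignments for every residue of a structure
#'
#' @param structure A [crystal_structure()].
#' @return data.frame with one row per residue conformer: chain, resno,
#'   icode, altloc, resid, rotamer, chi1_class, chi1..chi4 (NA beyond the
#'   type's count). Residues without chi angles (Gly/Ala, incomplete
#'   side chains, unknown types) are omitted.
#' @export
rotamer_assignments <- function(structure) {
  at <- polymer_atoms(structure)
  keys <- residue_key(at)
  rows <- list()
  for (k in unique(keys)) {
    res <- at[keys == k, , drop = FALSE]
    restype <- res$resid[1]
    if (n_chi(restype) == 0) next
    for (lab in names(conf <- residue_conformers(res))) {
      chis <- residue_chis(conf[[lab]], restype)
      if (!length(chis) || any(is.na(chis))) next
      nm <- name_rotamer(restype, chis)
      rows[[length(rows) + 1]] <- data.frame(
        chain = res$chain[1], resno = res$resno[1], icode = res$icode[1],
        altloc = ifelse(lab == " ", "", lab), resid = restype,
        rotamer = as.character(nm), chi1_class = attr(nm, "chi1_class"),
        chi1 = chis[1],
        chi2 = if (length(chis) >= 2) chis[2] else NA_real_,
        chi3 = if (length(chis) >= 3) chis[3] else NA_real_,
        chi4 = if (length(chis) >= 4) chis[4] else NA_real_,
        # conformer occupancy: the altloc atoms' occupancy, not the
        # full-occupancy shared atoms'
        occ = min(conf[[lab]]$occ),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

#' Census of rotamer changes between two structures
#'
#' A shared residue is counted as changed when no conformer rotamer name
#' in `a` matches any conformer name in `b` (`policy = "any-match"`,
#' default) or when the highest-occupancy conformers differ
#' (`policy = "primary"`). Residues in the excluded ranges are dropped
#' from the census.
#'
#' @param a,b [crystal_structure()] objects.
#' @param exclude Residue ranges to exclude: list of `c(lo, hi)` pairs or
#'   strings like `"375-383"`.
#' @param policy `"any-match"` or `"primary"`.
#' @return Object of class `rotamer_diff`: list with `changed`
#'   (data.frame of changed residues with names on both sides), `count`,
#'   `n_evaluated`, `percent`, `multi_rotamer` (per-structure counts of
#'   residues whose own altlocs have different rotamers), `policy`.
#' @export
rotamer_diff <- function(a, b, exclude = NULL, policy = c("any-match", "primary")) {
  policy <- match.arg(policy)
  ra <- rotamer_assignments(a)
  rb <- rotamer_assignments(b)
  if (!nrow(ra) || !nrow(rb)) stop("no rotamer-bearing residues in one structure")
  ra$key <- paste(ra$chain, ra$resno, ra$icode, sep = "|")
  rb$key <- paste(rb$chain, rb$resno, rb$icode, sep = "|")
  excl <- parse_residue_ranges(exclude)
  keep <- function(tab) tab[!in_ranges(tab$resno, excl), , drop = FALSE]
  ra <- keep(ra); rb <- keep(rb)
  shared <- intersect(unique(ra$key), unique(rb$key))
  if (!length(shared)) stop("no shared residues to compare")
  changed <- list()
  for (k in shared) {
    na_ <- ra[ra$key == k, , drop = FALSE]
    nb_ <- rb[rb$key == k, , drop = FALSE]
    if (policy == "primary") {
      names_a <- na_$rotamer[which.max(na_$occ)]
      names_b <- nb_$rotamer[which.max(nb_$occ)]
    } else {
      names_a <- unique(na_$rotamer)
      names_b <- unique(nb_$rotamer)
    }
    if (!length(intersect(names_a, names_b)))
      changed[[length(changed) + 1]] <- data.frame(
        chain = na_$chain[1], resno = na_$resno[1], icode = na_$icode[1],
        resid = na_$resid[1],
        rotamers_a = paste(names_a, collapse = "/"),
        rotamers_b = paste(names_b, collapse = "/"),
        stringsAsFactors = FALSE)
  }
  changed <- if (length(changed)) do.call(rbind, changed) else
    data.frame(chain = character(), resno = integer(), icode = character(),
               resid = character(), rotamers_a = character(),
               rotamers_b = character(), stringsAsFactors = FALSE)
  multi <- c(a = count_multi_rotamer(ra), b = count_multi_rotamer(rb))
  names(multi) <- c(a$label, b$label)
  structure(list(changed = changed, count = nrow(changed),
                 n_evaluated = length(shared),
                 percent = round(100 * nrow(changed) / length(shared), 1),
                 multi_rotamer = multi, policy = policy,
                 exclude = excl),
            class = "rotamer_diff")
}

count_multi_rotamer <- function(assign_tab) {
  sum(tapply(assign_tab$rotamer, assign_tab$key,
             function(v) length(unique(v)) > 1))
}

#' @export
print.rotamer_diff <- function(x, ...) {
  cat(sprintf("Rotamer census (%s policy): %d of %d shared residues changed (%.1f%%)\n",
              x$policy, x$count, x$n_evaluated, x$percent))
  if (length(x$multi_rotamer))
    cat("Multi-rotamer altloc residues:",
        paste(sprintf("%s=%d", names(x$multi_rotamer), x$multi_rotamer),
              collapse = ", "), "\n")
  invisible(x)
}

## parse residue ranges given as list(c(lo,hi), ...) or "375-383" strings
parse_residue_ranges <- function(exclude) {
  if (is.null(exclude)) return(list())
  if (is.character(exclude)) {
    exclude <- lapply(exclude, function(s) {
      p <- as.integer(strsplit(s, "-")[[1]])
      if (length(p) == 1) c(p, p) else p
    })
  }
  if (is.numeric(exclude)) exclude <- list(range(exclude))
  exclude
}

in_ranges <- function(resno, ranges) {
  if (!length(ranges)) return(rep(FALSE, length(resno)))
  Reduce(`|`, lapply(ranges, function(r) resno >= r[1] & resno <= r[2]))
}
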