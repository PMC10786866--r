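## Space-group symmetry in fractional coordinates.
## An operator is list(R = 3x3 matrix, t = length-3 translation in [0,1)).

#' Parse a symmetry operator from triplet notation
#'
#' Accepts strings such as `"x,y,z"` or `"-x+1/2,-y,z+1/2"`.
#'
#' @param triplet A single symmetry triplet string.
#' @return list with `R` (3x3 rotation in fractional coordinates) and `t`
#'   (translation vector with components wrapped into `[0,1)`).
#' @export
sym_op <- function(triplet) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry triplet must have three components: ", triplet)
  R <- matrix(0, 3, 3)
  tvec <- numeric(3)
  for (i in seq_len(3)) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        tvec[i] <- tvec[i] + sign * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tvec[i] <- tvec[i] + sign * as.numeric(body)
      } else stop("cannot parse symmetry term '", tm, "' in ", triplet)
    }
  }
  list(R = R, t = tvec %% 1)
}

## built-in operator triplets for the space groups this package needs
.spacegroup_triplets <- list(
  "P 1"          = c("x,y,z"),
  "P 1 21 1"     = c("x,y,z", "-x,y+1/2,-z"),
  "P 21 21 2"    = c("x,y,z", "-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z"),
  "P 21 21 21"   = c("x,y,z", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2", "-x+1/2,-y,z+1/2"),
  "C 1 2 1"      = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z")
)

normalize_spacegroup_symbol <- function(symbol) {
  s <- toupper(gsub("[[:space:]]+", " ", trimws(symbol)))
  compact <- gsub(" ", "", s)
  aliases <- c("P1" = "P 1", "P21" = "P 1 21 1", "P121 1" = "P 1 21 1",
               "P1211" = "P 1 21 1", "P21212" = "P 21 21 2",
               "P212121" = "P 21 21 21", "C2" = "C 1 2 1", "C121" = "C 1 2 1")
  if (s %in% names(.spacegroup_triplets)) return(s)
  if (compact %in% names(aliases)) return(unname(aliases[compact]))
  stop("unsupported space group symbol: ", symbol)
}

#' Symmetry operators for a space group
#'
#' @param symbol Hermann-Mauguin symbol, e.g. `"P 21 21 21"` (spacing and
#'   case are normalized; `"P212121"` also works).
#' @return List of operators, each `list(R, t)`. The identity is first.
#' @export
spacegroup_ops <- function(symbol) {
  sym <- normalize_spacegroup_symbol(symbol)
  lapply(.spacegroup_triplets[[sym]], sym_op)
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op Operator from [sym_op()] or [spacegroup_ops()].
#' @param frac Fractional coordinates (3-vector or n x 3 matrix).
#' @return n x 3 matrix of transformed fractional coordinates (no
#'   wrapping applied).
#' @export
apply_sym_op <- function(op, frac) {
  frac <- rbind(frac)
  sweep(frac %*% t(op$R), 2, op$t, `+`)
}

#' Symmetry-equivalent images of a fractional point
#'
#' Applies every space-group operator and every integer lattice translation
#' with components in `[-shell, shell]` to a point. The result has
#' `length(ops) * (2*shell+1)^3` rows and no wrapping is applied.
#'
#' @param point Fractional coordinate 3-vector.
#' @param ops List of symmetry operators from [spacegroup_ops()].
#' @param shell Non-negative integer; number of neighbor-cell translations
#'   per axis.
#' @return Matrix of fractional coordinates, one image per row.
#' @export
symmetry_images <- function(point, ops, shell = 1) {
  stopifnot(length(point) == 3, shell >= 0)
  base <- do.call(rbind, lapply(ops, apply_sym_op, frac = matrix(point, 1)))
  r <- seq(-shell, shell)
  trans <- as.matrix(expand.grid(x = r, y = r, z = r))
  out <- matrix(NA_real_, nrow(base) * nrow(trans), 3)
  k <- 0L
  for (i in seq_len(nrow(trans))) {
    out[k + seq_len(nrow(base)), ] <- sweep(base, 2, trans[i, ], `+`)
    k <- k + nrow(base)
  }
  out
}

## all symmetry+lattice images of an n x 3 fractional matrix, as a big matrix
symmetry_expand <- function(frac, ops, shell = 1) {
  frac <- rbind(frac)
  base <- do.call(rbind, lapply(ops, apply_sym_op, frac = frac))
  r <- seq(-shell, shell)
  trans <- as.matrix(expand.grid(x = r, y = r, z = r))
  do.call(rbind, lapply(seq_len(nrow(trans)), function(i)
    sweep(base, 2, trans[i, ], `+`)))
}
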