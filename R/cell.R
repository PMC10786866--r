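#' Construct a crystallographic unit cell
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; must lie in (0, 180).
#'
#' @return An object of class `unit_cell`: a named list with fields
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' unit_cell(39.67, 63.51, 135.16)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = a, b = b, c = c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("unit cell edge lengths must be positive and finite")
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie strictly between 0 and 180 degrees")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Unit-cell volume
#'
#' Volume of a general triclinic cell,
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'   +2\cos\alpha\cos\beta\cos\gamma}}.
#' For orthorhombic cells this reduces to \eqn{abc}.
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @examples
#' cell_volume(unit_cell(39.67, 63.51, 135.16))  # 340527.7
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  rad <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (rad <= 0)
    stop("degenerate unit cell: angle combination gives non-positive volume radicand")
  cell$a * cell$b * cell$c * sqrt(rad)
}

#' Orthogonalization matrix (fractional -> Cartesian)
#'
#' Standard PDB convention: `a` along x, `b` in the xy-plane.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 matrix `M` such that `x_cart = M %*% x_frac`.
#' @export
orth_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- cell_volume(cell)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           v / (cell$a * cell$b * sg)),
         nrow = 3, byrow = TRUE)
}

#' Fractionalization matrix (Cartesian -> fractional)
#'
#' @param cell A [unit_cell()].
#' @return The inverse of [orth_matrix()].
#' @export
frac_matrix <- function(cell) solve(orth_matrix(cell))

## row-wise coordinate transforms for n x 3 matrices
frac_to_orth <- function(xyz_frac, cell) {
  xyz_frac <- rbind(xyz_frac)
  t(orth_matrix(cell) %*% t(xyz_frac))
}

orth_to_frac <- function(xyz, cell) {
  xyz <- rbind(xyz)
  t(frac_matrix(cell) %*% t(xyz))
}
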