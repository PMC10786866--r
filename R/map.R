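## Real-space density maps on a cell-spanning periodic grid.
## Grid index i (1-based) along an axis of n points corresponds to
## fractional coordinate (i-1)/n; the grid wraps periodically.

#' Construct a density map
#'
#' @param values 3D numeric array covering exactly one unit cell, X,Y,Z
#'   axis order, periodic.
#' @param cell The [unit_cell()] the grid spans.
#' @return Object of class `density_map` with cached `mean` and `rms`
#'   (root-mean-square deviation about the mean) over the grid.
#' @export
density_map <- function(values, cell) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  m <- mean(values)
  structure(list(values = values, cell = cell, mean = m,
                 rms = sqrt(mean((values - m)^2))),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map>  grid %dx%dx%d  mean %.4g  rms %.4g\n",
              d[1], d[2], d[3], x$mean, x$rms))
  print(x$cell)
  invisible(x)
}

## periodic 1-based index
wrap_index <- function(i, n) ((i - 1) %% n) + 1

#' Interpolate map density at Cartesian points
#'
#' Points are converted to fractional coordinates, wrapped into the cell,
#' and interpolated on the periodic grid. With `scale = "sigma"` values
#' are returned as (rho - mean)/rms in map-sigma units.
#'
#' @param map A [density_map()].
#' @param xyz Cartesian coordinates in Angstrom: a 3-vector or an n x 3
#'   matrix.
#' @param mode `"trilinear"` (default) or `"tricubic"` (separable
#'   Catmull-Rom).
#' @param scale `"sigma"` (default) or `"raw"`.
#' @return Numeric vector of density values, one per point.
#' @export
map_value_at <- function(map, xyz, mode = c("trilinear", "tricubic"),
                         scale = c("sigma", "raw")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (scale == "sigma" && map$rms <= 0)
    stop("sigma scaling is undefined for a constant map")
  xyz <- rbind(xyz)
  frac <- orth_to_frac(xyz, map$cell) %% 1
  dims <- dim(map$values)
  u <- sweep(frac, 2, dims, `*`)        # grid coordinate, 0-based
  vals <- if (mode == "trilinear") interp_trilinear(map$values, u, dims)
          else interp_tricubic(map$values, u, dims)
  if (scale == "sigma") (vals - map$mean) / map$rms else vals
}

interp_trilinear <- function(arr, u, dims) {
  i0 <- floor(u)
  w <- u - i0
  out <- numeric(nrow(u))
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (k in seq_len(nrow(corners))) {
    c3 <- corners[k, ]
    ix <- wrap_index(i0[, 1] + c3[1] + 1, dims[1])
    iy <- wrap_index(i0[, 2] + c3[2] + 1, dims[2])
    iz <- wrap_index(i0[, 3] + c3[3] + 1, dims[3])
    wt <- ((if (c3[1] == 1) w[, 1] else 1 - w[, 1]) *
           (if (c3[2] == 1) w[, 2] else 1 - w[, 2]) *
           (if (c3[3] == 1) w[, 3] else 1 - w[, 3]))
    out <- out + wt * arr[cbind(ix, iy, iz)]
  }
  out
}

## Catmull-Rom kernel weights for fractional offset t in [0,1)
catmull_rom_w <- function(t) {
  cbind(-0.5 * t^3 + t^2 - 0.5 * t,
        1.5 * t^3 - 2.5 * t^2 + 1,
        -1.5 * t^3 + 2 * t^2 + 0.5 * t,
        0.5 * t^3 - 0.5 * t^2)
}

interp_tricubic <- function(arr, u, dims) {
  i0 <- floor(u)
  t <- u - i0
  wx <- catmull_rom_w(t[, 1]); wy <- catmull_rom_w(t[, 2]); wz <- catmull_rom_w(t[, 3])
  out <- numeric(nrow(u))
  for (a in -1:2) for (b in -1:2) for (c3 in -1:2) {
    ix <- wrap_index(i0[, 1] + a + 1, dims[1])
    iy <- wrap_index(i0[, 2] + b + 1, dims[2])
    iz <- wrap_index(i0[, 3] + c3 + 1, dims[3])
    out <- out + wx[, a + 2] * wy[, b + 2] * wz[, c3 + 2] * arr[cbind(ix, iy, iz)]
  }
  out
}
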