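# Shared planar geometry helpers.
#
# Coordinate conventions used throughout:
#  * a slice is a matrix indexed [row, col]; voxel centres sit at
#    ((i - 1) * spacing, (j - 1) * spacing) mm, row running "down" the image;
#  * angles are measured from the image "up" direction (decreasing row),
#    increasing counter-clockwise as displayed (apex view), in degrees [0, 360).

#' @keywords internal
#' @noRd
deg2rad <- function(x) x * pi / 180

#' @keywords internal
#' @noRd
rad2deg <- function(x) x * 180 / pi

# angle of displacement (d_col, d_row) under the convention above
#' @keywords internal
#' @noRd
angle_of <- function(d_col, d_row) {
  (rad2deg(atan2(-d_col, -d_row))) %% 360
}

# unit direction (d_col, d_row) of a ray at angle theta (degrees)
#' @keywords internal
#' @noRd
angle_dir <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  cbind(d_col = -sin(t), d_row = -cos(t))
}

# bilinear interpolation of matrix `m` at fractional (row, col) voxel indices
# (1-based); points outside the grid evaluate to 0
#' @keywords internal
#' @noRd
bilinear <- function(m, row_idx, col_idx) {
  nr <- nrow(m)
  nc <- ncol(m)
  i0 <- floor(row_idx)
  j0 <- floor(col_idx)
  fi <- row_idx - i0
  fj <- col_idx - j0

  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    out <- numeric(length(ii))
    out[ok] <- m[cbind(ii[ok], jj[ok])]
    out
  }
  val(i0, j0) * (1 - fi) * (1 - fj) +
    val(i0 + 1, j0) * fi * (1 - fj) +
    val(i0, j0 + 1) * (1 - fi) * fj +
    val(i0 + 1, j0 + 1) * fi * fj
}

# number of 4-connected components of TRUE cells in a logical matrix;
# frontier-expansion flood fill, vectorised over the frontier
#' @keywords internal
#' @noRd
count_components4 <- function(mask) {
  nr <- nrow(mask)
  remaining <- which(mask)
  comp <- 0L
  seen <- logical(length(mask))
  while (length(remaining) > 0L) {
    comp <- comp + 1L
    frontier <- remaining[1L]
    seen[frontier] <- TRUE
    while (length(frontier) > 0L) {
      i <- ((frontier - 1L) %% nr) + 1L
      nb <- c(frontier[i > 1L] - 1L,
              frontier[i < nr] + 1L,
              frontier - nr,
              frontier + nr)
      nb <- nb[nb >= 1L & nb <= length(mask)]
      nb <- unique(nb[mask[nb] & !seen[nb]])
      seen[nb] <- TRUE
      frontier <- nb
    }
    remaining <- remaining[!seen[remaining]]
  }
  comp
}

# most counter-clockwise angle of a set of angles assumed to span an arc
# narrower than 180 degrees (handles wrap-around via the circular mean)
#' @keywords internal
#' @noRd
ccw_edge_angle <- function(angles_deg) {
  a <- deg2rad(angles_deg)
  centre <- rad2deg(atan2(mean(sin(a)), mean(cos(a)))) %% 360
  dev <- ((angles_deg - centre + 180) %% 360) - 180
  (centre + max(dev)) %% 360
}

#' @keywords internal
#' @noRd
stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
}
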