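# Wall-thickness measurement from short-axis label masks.
#
# The thickness operator is radial ray-casting from the cavity centroid: for
# each ray the myocardium indicator is sampled along the ray with bilinear
# interpolation and thickness is the distance from the first endocardial
# crossing to the end of the first contiguous myocardial run (the epicardial
# crossing), with sub-voxel linear refinement of both crossings. A per-segment
# MAXIMUM over rays is then taken on the AHA 16-segment parcellation.

#' Area centroid of the LV cavity on one slice
#'
#' @param slice_mask integer label matrix `[row, col]`.
#' @param in_plane_spacing voxel size in mm.
#' @param label_map named label map (needs `cavity`).
#' @return named numeric `c(col, row)`: the centroid in mm (voxel centre of
#'   `[1,1]` is `(0, 0)`, row increasing "down" the image).
#' @details Errors if the slice has no cavity or more than one 4-connected
#'   cavity component.
#' @export
cavity_centroid <- function(slice_mask, in_plane_spacing = 1,
                            label_map = c(cavity = 1L)) {
  cav <- slice_mask == label_map[["cavity"]]
  if (!any(cav)) stop("slice contains no cavity label", call. = FALSE)
  ncomp <- count_components4(cav)
  if (ncomp != 1L) {
    stop(sprintf("expected exactly one cavity component, found %d", ncomp),
         call. = FALSE)
  }
  w <- which(cav, arr.ind = TRUE)
  c(col = (mean(w[, 2]) - 1) * in_plane_spacing,
    row = (mean(w[, 1]) - 1) * in_plane_spacing)
}

#' Anterior RV insertion angle from an RV label
#'
#' Finds epicardial myocardium voxels 4-adjacent to the RV label and returns
#' the most counter-clockwise of their angles about the cavity centroid
#' (0 degrees = image "up", counter-clockwise viewed from the apex) — the
#' anterior RV-LV junction, which anchors AHA segment 1.
#'
#' @param slice_mask integer label matrix.
#' @param in_plane_spacing voxel size in mm.
#' @param label_map named label map (needs `cavity`, `myocardium`, `rv`).
#' @return angle in degrees `[0, 360)`.
#' @details Errors if no RV label is present: supply `rv_insertion_angle` in
#'   the stack metadata instead.
#' @export
rv_insertion_angle <- function(slice_mask, in_plane_spacing = 1,
                               label_map = c(cavity = 1L, myocardium = 2L,
                                             rv = 3L)) {
  if (!("rv" %in% names(label_map)) ||
      !any(slice_mask == label_map[["rv"]])) {
    stop(paste("no RV label present; supply `rv_insertion_angle` in the",
               "stack metadata"), call. = FALSE)
  }
  rv <- slice_mask == label_map[["rv"]]
  myo <- slice_mask == label_map[["myocardium"]]
  # myocardium voxels with an RV 4-neighbour
  nr <- nrow(rv)
  nc <- ncol(rv)
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nr, nc)
    ri <- seq_len(nr) + di
    cj <- seq_len(nc) + dj
    ok_i <- ri >= 1 & ri <= nr
    ok_j <- cj >= 1 & cj <= nc
    out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
    out
  }
  adj <- myo & (shift(rv, 1, 0) | shift(rv, -1, 0) |
                  shift(rv, 0, 1) | shift(rv, 0, -1))
  if (!any(adj)) {
    stop("RV label does not touch the LV epicardial border", call. = FALSE)
  }
  ctr <- cavity_centroid(slice_mask, in_plane_spacing, label_map)
  w <- which(adj, arr.ind = TRUE)
  ang <- angle_of((w[, 2] - 1) * in_plane_spacing - ctr[["col"]],
                  (w[, 1] - 1) * in_plane_spacing - ctr[["row"]])
  ccw_edge_angle(ang)
}

#' Allocate short-axis slices to AHA levels
#'
#' Splits the stack's base-to-apex extent into three contiguous groups —
#' basal, mid, apical — with as-equal-as-possible counts; remainders go to
#' the basal level first, then mid (10 slices -> 4/3/3, 11 -> 4/4/3). The
#' stack is assumed cropped to the ventricle's coverage; a slice whose
#' myocardium is missing (e.g. a failed segmentation) still occupies its
#' anatomical level.
#'
#' @param x an [lv_mask_stack()] or an integer slice count.
#' @return character vector (`"basal"`, `"mid"`, `"apical"`), one entry per
#'   slice in base-to-apex order.
#' @export
allocate_slices <- function(x) {
  n <- if (inherits(x, "lv_mask_stack")) {
    dim(x$volume)[3L]
  } else {
    as.integer(x)
  }
  if (n < 3L) {
    stop("need at least 3 slices to form AHA levels", call. = FALSE)
  }
  base <- n %/% 3L
  rem <- n %% 3L
  counts <- c(basal = base + (rem >= 1L), mid = base + (rem >= 2L),
              apical = base)
  rep(c("basal", "mid", "apical"), times = counts)
}

#' Radial wall thickness along rays from the cavity centroid
#'
#' Casts a ray from `centroid` at each requested angle, samples the myocardium
#' indicator by bilinear interpolation at `in_plane_spacing / 4` steps, and
#' measures the distance from the first endocardial boundary crossing to the
#' end of that contiguous myocardial run. Both crossings are refined by linear
#' interpolation of the sampled indicator (threshold 0.5), giving sub-voxel
#' boundary placement.
#'
#' @param slice_mask integer label matrix.
#' @param centroid named `c(col, row)` point in mm (see [cavity_centroid()]).
#' @param angles_deg angles to sample, degrees.
#' @param in_plane_spacing voxel size in mm.
#' @param label_map named label map (needs `cavity`, `myocardium`).
#' @return numeric vector of thicknesses (mm), `NaN` where a ray meets no
#'   myocardium.
#' @export
radial_thickness <- function(slice_mask, centroid,
                             angles_deg = seq(0, 359, by = 1),
                             in_plane_spacing = 1,
                             label_map = c(cavity = 1L, myocardium = 2L)) {
  s <- in_plane_spacing
  ci <- centroid[["row"]] / s + 1     # fractional voxel indices
  cj <- centroid[["col"]] / s + 1
  ci0 <- round(ci)
  cj0 <- round(cj)
  if (ci0 < 1 || ci0 > nrow(slice_mask) || cj0 < 1 || cj0 > ncol(slice_mask) ||
      slice_mask[ci0, cj0] != label_map[["cavity"]]) {
    stop("centroid does not lie inside the cavity", call. = FALSE)
  }
  myo <- (slice_mask == label_map[["myocardium"]]) * 1

  step <- s / 4
  r_max <- sqrt((nrow(slice_mask) * s)^2 + (ncol(slice_mask) * s)^2)
  radii <- seq(0, r_max, by = step)
  dir <- angle_dir(angles_deg)
  n_a <- length(angles_deg)
  n_r <- length(radii)
  # sample all rays at once: row = ray, col = radius
  row_idx <- ci + outer(dir[, "d_row"], radii) / s
  col_idx <- cj + outer(dir[, "d_col"], radii) / s
  v <- matrix(bilinear(myo, as.vector(row_idx), as.vector(col_idx)), n_a, n_r)
  inside <- v >= 0.5

  measure_ray <- function(i) {
    ins <- inside[i, ]
    k_in <- which(ins)[1L]
    if (is.na(k_in)) return(NaN)
    after <- which(!ins & seq_len(n_r) > k_in)[1L]
    k_out <- if (is.na(after)) n_r else after - 1L   # last sample of the run
    refine <- function(k_lo, k_hi) {
      dv <- v[i, k_hi] - v[i, k_lo]
      frac <- if (abs(dv) < 1e-12) 0.5 else (0.5 - v[i, k_lo]) / dv
      radii[k_lo] + max(0, min(1, frac)) * step
    }
    r_enter <- if (k_in == 1L) radii[1L] else refine(k_in - 1L, k_in)
    r_exit <- if (k_out == n_r) radii[n_r] else refine(k_out, k_out + 1L)
    r_exit - r_enter
  }
  vapply(seq_len(n_a), measure_ray, numeric(1))
}

#' Per-segment maximal wall thickness on the AHA 16-segment model
#'
#' Runs the full measurement on a stack: slices are allocated to AHA levels,
#' rays are cast on every myocardium-bearing slice, each ray is assigned to an
#' AHA segment by its angle relative to the anterior RV insertion (6 sectors
#' of 60 degrees on basal and mid levels, 4 of 90 degrees apically, segment
#' numbering counter-clockwise viewed from the apex), and each segment's value
#' is the MAXIMUM ray thickness over all rays of all slices of its level.
#'
#' @param stack an [lv_mask_stack()].
#' @param angle_step ray angular step in degrees (default 1).
#' @param subject_id identifier carried into the output.
#' @return a [segmental_wt_profile()]: 16 maximal thicknesses in mm, `NaN`
#'   for segments with no valid ray.
#' @export
segment_wt <- function(stack, angle_step = 1, subject_id = "subject") {
  if (!inherits(stack, "lv_mask_stack")) {
    stop("`stack` must be an lv_mask_stack", call. = FALSE)
  }
  lm <- stack$label_map
  ord <- base_to_apex_order(stack)
  # AHA levels are thirds of the stack's base-to-apex extent: a slice whose
  # myocardium is missing still occupies its anatomical level, it just
  # contributes no measurements (so its segments can come back NaN)
  levels <- allocate_slices(length(ord))
  myo_here <- myocardium_slices(stack)[ord]

  insertion <- stack$rv_insertion_angle
  if (is.na(insertion)) {
    # measure from the RV label on the most basal myocardium-bearing slice
    insertion <- rv_insertion_angle(stack$volume[, , ord[myo_here][1L]],
                                    stack$in_plane_spacing, lm)
  }

  # rays at angular bin centres: a ray exactly along a sector discontinuity
  # is degenerate (it runs along the thickness step), so sampling at
  # half-step offsets is both unbiased and robust
  angles <- seq(0, 360 - angle_step, by = angle_step) + angle_step / 2
  wt <- rep(NaN, 16L)
  s <- stack$in_plane_spacing
  bg <- if ("background" %in% names(lm)) lm[["background"]] else 0L
  for (si in seq_along(ord)) {
    if (!myo_here[si]) next
    slice <- stack$volume[, , ord[si]]
    ctr <- cavity_centroid(slice, s, lm)
    # assign each myocardium voxel to its sector by the angle of its centre
    # about the cavity centroid; each sector is then measured against its own
    # wall only, so a thickness step in the neighbouring sector cannot leak
    # into the interpolated boundary
    d_col <- outer(rep(1, nrow(slice)), (seq_len(ncol(slice)) - 1) * s) -
      ctr[["col"]]
    d_row <- outer((seq_len(nrow(slice)) - 1) * s, rep(1, ncol(slice))) -
      ctr[["row"]]
    vox_seg <- aha_segment_of(angle_of(d_col, d_row), levels[si], insertion)
    ray_seg <- aha_segment_of(angles, levels[si], insertion)
    myo_mask <- slice == lm[["myocardium"]]
    for (g in unique(ray_seg)) {
      slice_g <- slice
      slice_g[myo_mask & vox_seg != g] <- bg
      th <- radial_thickness(slice_g, ctr, angles[ray_seg == g], s, lm)
      vals <- th[is.finite(th)]
      if (length(vals) > 0L) {
        wt[g] <- max(wt[g], max(vals), na.rm = TRUE)
      }
    }
  }
  segmental_wt_profile(wt, subject_id = subject_id)
}
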