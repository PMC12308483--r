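#' Specify an analytic left-ventricular annulus phantom
#'
#' A phantom is a stack of short-axis slices in which each slice is an annulus:
#' LV cavity inside `endo_radius`, myocardium out to a per-angle epicardial
#' radius. The epicardial radius is piecewise constant over the AHA angular
#' sectors of the slice's level (6 basal, 6 mid, 4 apical), stepped so that
#' segment `s` has design wall thickness `sector_thickness[s]`. Because the
#' design thickness of every sector is known exactly, the phantom is an oracle
#' for the wall-thickness measurement pipeline.
#'
#' @param n_slices number of short-axis slices (>= 3 so that basal, mid and
#'   apical levels are all populated).
#' @param slice_thickness slice spacing in mm.
#' @param in_plane_spacing isotropic in-plane voxel size in mm.
#' @param endo_radius endocardial (cavity) radius in mm.
#' @param sector_thickness numeric vector of 16 design wall thicknesses in mm,
#'   one per AHA segment (1-6 basal, 7-12 mid, 13-16 apical). A single value
#'   is recycled to all 16 segments.
#' @param rv_insertion_angle angle of the anterior RV-LV insertion in degrees
#'   (0 = image "up", counter-clockwise viewed from the apex). Stored in the
#'   stack metadata; segment 1 starts here.
#' @param grid_size in-plane grid side length in voxels.
#' @param rv_blob optional list `list(centre_angle=, angular_width=,
#'   radial_extent=)` describing an RV marker painted against the epicardium
#'   (label 3), used to exercise RV-insertion detection. `NULL` (default)
#'   paints no RV; the insertion angle then lives only in metadata.
#'
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(n_slices = 9,
                         slice_thickness = 8,
                         in_plane_spacing = 1,
                         endo_radius = 20,
                         sector_thickness = 8,
                         rv_insertion_angle = 60,
                         grid_size = NULL,
                         rv_blob = NULL) {
  stopifnot_scalar_pos(slice_thickness, "slice_thickness")
  stopifnot_scalar_pos(in_plane_spacing, "in_plane_spacing")
  stopifnot_scalar_pos(endo_radius, "endo_radius")
  if (length(sector_thickness) == 1L) {
    sector_thickness <- rep(sector_thickness, 16L)
  }
  if (length(sector_thickness) != 16L || any(!is.finite(sector_thickness)) ||
      any(sector_thickness <= 0)) {
    stop("`sector_thickness` must be 16 positive values (or one, recycled)",
         call. = FALSE)
  }
  if (!is.numeric(n_slices) || n_slices < 3) {
    stop("`n_slices` must be >= 3 so all AHA levels are populated",
         call. = FALSE)
  }
  if (is.null(grid_size)) {
    # default: epicardium plus a 6 mm margin on each side
    grid_size <- 2L * ceiling((endo_radius + max(sector_thickness) + 6) /
                                in_plane_spacing) + 1L
  }
  max_epi <- endo_radius + max(sector_thickness)
  half_extent <- (grid_size - 1) / 2 * in_plane_spacing
  if (max_epi >= half_extent) {
    worst <- which.max(sector_thickness)
    stop(sprintf(
      "epicardium of segment %d (radius %.1f mm) exceeds the grid half-extent %.1f mm; enlarge `grid_size`",
      worst, max_epi, half_extent), call. = FALSE)
  }
  structure(
    list(n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness,
         in_plane_spacing = in_plane_spacing,
         endo_radius = endo_radius,
         sector_thickness = as.numeric(sector_thickness),
         rv_insertion_angle = rv_insertion_angle %% 360,
         grid_size = as.integer(grid_size),
         rv_blob = rv_blob),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("LV annulus phantom spec\n")
  cat(sprintf("  %d slices, %.2g mm in-plane, %.2g mm slice thickness\n",
              x$n_slices, x$in_plane_spacing, x$slice_thickness))
  cat(sprintf("  endo radius %.1f mm, wall %.1f-%.1f mm, RV insertion %g deg\n",
              x$endo_radius, min(x$sector_thickness), max(x$sector_thickness),
              x$rv_insertion_angle))
  invisible(x)
}

#' Construct a short-axis label-mask stack
#'
#' Container for a 3-D integer label volume with its voxel geometry and the
#' metadata the AHA segmentation needs. Slices run base to apex along the
#' third array dimension when `slice_order = "base_to_apex"`.
#'
#' @param volume 3-D integer array `[row, col, slice]` of labels.
#' @param in_plane_spacing,slice_thickness voxel geometry in mm.
#' @param slice_order `"base_to_apex"` or `"apex_to_base"`.
#' @param rv_insertion_angle anterior RV insertion angle in degrees, or `NA`
#'   if it must be measured from an RV label.
#' @param label_map named integer vector mapping roles to label values;
#'   must name `cavity` and `myocardium`, optionally `rv` and `background`.
#' @param meta free-form metadata list (e.g. the generating [phantom_spec()]).
#'
#' @return an object of class `lv_mask_stack`.
#' @export
lv_mask_stack <- function(volume,
                          in_plane_spacing,
                          slice_thickness,
                          slice_order = c("base_to_apex", "apex_to_base"),
                          rv_insertion_angle = NA_real_,
                          label_map = c(background = 0L, cavity = 1L,
                                        myocardium = 2L, rv = 3L),
                          meta = list()) {
  slice_order <- match.arg(slice_order)
  if (length(dim(volume)) != 3L) {
    stop("`volume` must be a 3-D array [row, col, slice]", call. = FALSE)
  }
  stopifnot_scalar_pos(in_plane_spacing, "in_plane_spacing")
  stopifnot_scalar_pos(slice_thickness, "slice_thickness")
  if (!all(c("cavity", "myocardium") %in% names(label_map))) {
    stop("`label_map` must name at least `cavity` and `myocardium`",
         call. = FALSE)
  }
  x <- structure(
    list(volume = volume,
         in_plane_spacing = in_plane_spacing,
         slice_thickness = slice_thickness,
         slice_order = slice_order,
         rv_insertion_angle = rv_insertion_angle,
         label_map = label_map,
         meta = meta),
    class = "lv_mask_stack")
  n_myo <- sum(myocardium_slices(x))
  if (n_myo < 3L) {
    stop("stack must contain myocardium on at least 3 slices", call. = FALSE)
  }
  x
}

#' @export
print.lv_mask_stack <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("lv_mask_stack: %d x %d x %d, %.2g mm in-plane, %.2g mm slices (%s)\n",
              d[1], d[2], d[3], x$in_plane_spacing, x$slice_thickness,
              x$slice_order))
  cat(sprintf("  myocardium on %d slices; RV insertion: %s\n",
              sum(myocardium_slices(x)),
              if (is.na(x$rv_insertion_angle)) "from RV label"
              else sprintf("%g deg (metadata)", x$rv_insertion_angle)))
  invisible(x)
}

# logical vector: which slices carry myocardium
#' @keywords internal
#' @noRd
myocardium_slices <- function(stack) {
  myo <- stack$label_map[["myocardium"]]
  apply(stack$volume == myo, 3L, any)
}

# slices reordered so index 1 is basal
#' @keywords internal
#' @noRd
base_to_apex_order <- function(stack) {
  n <- dim(stack$volume)[3L]
  if (stack$slice_order == "base_to_apex") seq_len(n) else rev(seq_len(n))
}

# AHA segment id for angles (degrees) at a given level
#' @keywords internal
#' @noRd
aha_segment_of <- function(theta_deg, level, rv_insertion_angle) {
  rel <- (theta_deg - rv_insertion_angle) %% 360
  switch(level,
         basal  = 1L + (rel %/% 60) %% 6L,
         mid    = 7L + (rel %/% 60) %% 6L,
         apical = 13L + (rel %/% 90) %% 4L,
         stop("unknown level: ", level))
}

#' Generate an analytic annulus phantom
#'
#' Rasterises a [phantom_spec()] into a labelled short-axis stack. Voxels are
#' classified by the radius and angle of their centre: cavity inside
#' `endo_radius`, myocardium between `endo_radius` and
#' `endo_radius + sector_thickness[segment]` where the segment is determined by
#' the slice's AHA level and the voxel's angle relative to the RV insertion.
#'
#' @param spec a [phantom_spec()].
#' @return an [lv_mask_stack()]; the generating spec is kept in `$meta$spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(endo_radius = 20, sector_thickness = 8))
#' ph
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec", call. = FALSE)
  }
  g <- spec$grid_size
  s <- spec$in_plane_spacing
  centre <- (g + 1) / 2                     # voxel index of the grid centre
  idx <- seq_len(g)
  d_row <- (idx - centre) * s
  d_col <- (idx - centre) * s
  dr <- matrix(d_row, g, g)                 # row offset, mm
  dc <- matrix(d_col, g, g, byrow = TRUE)   # col offset, mm
  r <- sqrt(dr^2 + dc^2)
  theta <- angle_of(dc, dr)

  levels <- allocate_slices(spec$n_slices)
  vol <- array(0L, dim = c(g, g, spec$n_slices))
  for (k in seq_len(spec$n_slices)) {
    seg <- aha_segment_of(theta, levels[k], spec$rv_insertion_angle)
    epi <- spec$endo_radius + spec$sector_thickness[seg]
    slice <- matrix(0L, g, g)
    slice[r < spec$endo_radius] <- 1L
    slice[r >= spec$endo_radius & r < epi] <- 2L
    if (!is.null(spec$rv_blob)) {
      b <- spec$rv_blob
      width <- if (is.null(b$angular_width)) 30 else b$angular_width
      ext <- if (is.null(b$radial_extent)) 6 else b$radial_extent
      dev <- ((theta - b$centre_angle + 180) %% 360) - 180
      in_arc <- abs(dev) <= width / 2
      rv <- in_arc & r >= epi & r < epi + ext & slice == 0L
      slice[rv] <- 3L
    }
    vol[, , k] <- slice
  }
  lv_mask_stack(vol,
                in_plane_spacing = s,
                slice_thickness = spec$slice_thickness,
                slice_order = "base_to_apex",
                rv_insertion_angle = spec$rv_insertion_angle,
                meta = list(spec = spec))
}

#' Write / read a label stack as NIfTI
#'
#' Phantoms and segmentation masks are exchanged as NIfTI label volumes
#' (0 background, 1 LV cavity, 2 LV myocardium, 3 RV) with the voxel spacing
#' in the header; stack metadata that NIfTI cannot carry (RV insertion angle,
#' slice order, label map) is echoed to a JSON sidecar next to the volume.
#'
#' @param stack an [lv_mask_stack()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `write_mask_nifti()` returns `path` invisibly; `read_mask_nifti()`
#'   returns an [lv_mask_stack()].
#' @export
write_mask_nifti <- function(stack, path) {
  img <- RNifti::asNifti(stack$volume)
  RNifti::pixdim(img) <- c(stack$in_plane_spacing, stack$in_plane_spacing,
                           stack$slice_thickness)
  RNifti::writeNifti(img, path)
  sidecar <- list(slice_order = stack$slice_order,
                  rv_insertion_angle = stack$rv_insertion_angle,
                  label_map = as.list(stack$label_map))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    list()
  }
  label_map <- if (!is.null(sidecar$label_map)) {
    unlist(sidecar$label_map)
  } else {
    c(background = 0L, cavity = 1L, myocardium = 2L, rv = 3L)
  }
  lv_mask_stack(array(as.integer(img), dim = dim(img)),
                in_plane_spacing = pd[1],
                slice_thickness = pd[3],
                slice_order = if (is.null(sidecar$slice_order))
                  "base_to_apex" else sidecar$slice_order,
                rv_insertion_angle = if (is.null(sidecar$rv_insertion_angle))
                  NA_real_ else sidecar$rv_insertion_angle,
                label_map = label_map)
}
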