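#' Construct a 3-D binary label mask
#'
#' A segmentation mask is a 3-D binary raster with physical voxel
#' spacing in mm per axis, ordered (x, y, z) = (column, row, slice), and
#' an origin giving the physical position of the corner of voxel
#' (1,1,1). All volume computations use the spacing metadata, so no
#' axis convention leaks into measured volumes.
#'
#' @param voxels 3-D array coercible to logical (nonzero = foreground).
#' @param spacing Numeric length-3, mm per voxel along (x, y, z).
#' @param origin Numeric length-3, mm (default zeros).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) {
    stop("label_mask: voxels must be a 3-D array", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("label_mask: spacing must be 3 positive numbers (mm)", call. = FALSE)
  }
  storage.mode(voxels) <- "integer"
  voxels[voxels != 0L] <- 1L
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_mask %dx%dx%d @ (%.3g, %.3g, %.3g) mm, %d foreground voxels\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L],
              sum(x$voxels)))
  invisible(x)
}

#' Measure the volume of a label mask
#'
#' Foreground voxel count times the physical volume of one voxel --
#' the voxel-volume feature used by segmentation-based CT volumetry.
#' Disconnected components all count (no component filtering).
#'
#' @param mask A [label_mask()].
#' @return A list of class `volume_measurement` with `voxel_volume`
#'   (mm^3), `voxel_count` and `spacing_used`.
#' @export
measure_volume <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  count <- sum(mask$voxels)
  structure(list(voxel_volume = count * prod(mask$spacing),
                 voxel_count = as.integer(count),
                 spacing_used = mask$spacing),
            class = "volume_measurement")
}

#' @export
print.volume_measurement <- function(x, ...) {
  cat(sprintf("volume %.2f mm^3 (%d voxels at %s mm)\n", x$voxel_volume,
              x$voxel_count, paste(signif(x$spacing_used, 3), collapse = "x")))
  invisible(x)
}

#' Resample a label mask to isotropic spacing
#'
#' Nearest-neighbour resampling onto an isotropic grid (default 0.5 mm),
#' the preprocessing step that removes slice-thickness differences
#' between serial scans before volumetry. Nearest-neighbour keeps the
#' mask binary; each output voxel takes the label of the input voxel
#' whose centre is closest to its own centre. Voxel centres sit at
#' `origin + (i - 1/2) * spacing`.
#'
#' @param mask A [label_mask()].
#' @param target_spacing Isotropic output spacing in mm (> 0).
#' @return A resampled `label_mask` with spacing
#'   `rep(target_spacing, 3)` covering the same physical extent.
#' @export
resample_isotropic <- function(mask, target_spacing = 0.5) {
  stopifnot(inherits(mask, "label_mask"))
  if (!is.finite(target_spacing) || target_spacing <= 0) {
    stop("resample_isotropic: target_spacing must be > 0", call. = FALSE)
  }
  din <- dim(mask$voxels)
  extent <- din * mask$spacing
  dout <- pmax(1L, as.integer(round(extent / target_spacing)))
  idx <- lapply(1:3, function(a) {
    centres <- (seq_len(dout[a]) - 0.5) * target_spacing
    i <- ceiling(centres / mask$spacing[a])
    pmin(pmax(i, 1L), din[a])
  })
  out <- mask$voxels[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  label_mask(out, rep(target_spacing, 3), mask$origin)
}

#' Digital ellipsoid phantom
#'
#' Rasterises an axis-aligned ellipsoid by centre-inclusion: a voxel is
#' foreground when its centre lies inside the analytic surface. Serves
#' as a reproducible stand-in for manual lesion contours; its analytic
#' volume `4/3*pi*a*b*c` is the oracle for discretisation error.
#'
#' @param semi_axes Length-3 semi-axes (a, b, c) in mm (> 0).
#' @param spacing Length-3 voxel spacing in mm (> 0).
#' @param margin_mm Background padding around the ellipsoid.
#' @return A `label_mask` containing the ellipsoid.
#' @export
make_ellipsoid_mask <- function(semi_axes, spacing, margin_mm = 2) {
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("make_ellipsoid_mask: semi_axes must be 3 positive numbers",
         call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("make_ellipsoid_mask: spacing must be 3 positive numbers",
         call. = FALSE)
  }
  if (any(2 * semi_axes < spacing)) {
    warning("make_ellipsoid_mask: ellipsoid smaller than one voxel along ",
            "some axis; mask may be degenerate")
  }
  half <- semi_axes + margin_mm
  dims <- pmax(1L, as.integer(ceiling(2 * half / spacing)))
  centre <- dims * spacing / 2   # physical centre of the raster
  coord <- lapply(1:3, function(a) {
    ((seq_len(dims[a]) - 0.5) * spacing[a] - centre[a]) / semi_axes[a]
  })
  q <- outer(outer(coord[[1L]]^2, coord[[2L]]^2, `+`), coord[[3L]]^2, `+`)
  label_mask(array(q <= 1, dims), spacing)
}

#' Write / read a label mask
#'
#' `write_mask()` writes NIfTI (`.nii`/`.nii.gz`, via the RNifti
#' package, spacing stored in the header) or a plain-text JSON format
#' (dims, spacing, origin and the linear indices of foreground voxels),
#' chosen by file extension. `read_mask()` reverses either.
#'
#' @param mask A [label_mask()].
#' @param path Output path; `.nii`/`.nii.gz` selects NIfTI, anything
#'   else the JSON text format.
#' @return `write_mask()`: `path`, invisibly. `read_mask()`: a
#'   `label_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("write_mask: NIfTI output needs the RNifti package", call. = FALSE)
    }
    img <- RNifti::asNifti(array(as.numeric(mask$voxels), dim(mask$voxels)))
    RNifti::pixdim(img) <- mask$spacing
    RNifti::writeNifti(img, path)
  } else {
    payload <- list(dims = dim(mask$voxels), spacing = mask$spacing,
                    origin = mask$origin,
                    foreground = which(mask$voxels != 0L))
    jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_mask: no such file: %s", path), call. = FALSE)
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("read_mask: NIfTI input needs the RNifti package", call. = FALSE)
    }
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    label_mask(array(as.integer(img != 0), dim(img)[1:3]), spacing)
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    vox <- array(0L, unlist(payload$dims))
    vox[unlist(payload$foreground)] <- 1L
    label_mask(vox, unlist(payload$spacing), unlist(payload$origin))
  }
}

#' Volume of a mask after standard isotropic preprocessing
#'
#' Convenience wrapper reproducing the full measurement path: resample
#' to isotropic spacing (default 0.5 mm), then count voxels. The
#' pre-resampling volume is returned alongside for comparison; the
#' resampled value is the primary measurement.
#'
#' @inheritParams resample_isotropic
#' @return List with `volume` (mm^3, after resampling),
#'   `volume_native` (before), and the `volume_measurement` object.
#' @export
mask_volume_isotropic <- function(mask, target_spacing = 0.5) {
  native <- measure_volume(mask)
  res <- measure_volume(resample_isotropic(mask, target_spacing))
  list(volume = res$voxel_volume, volume_native = native$voxel_volume,
       measurement = res)
}
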