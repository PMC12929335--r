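#' Labeled CT-like volume
#'
#' Container for a 3D scalar image in Hounsfield units plus an integer label
#' mask of identical shape (0 = background, 1 = liver, 2 = spleen) and voxel
#' spacing in mm. An affine is carried for NIfTI round trips; attenuation
#' extraction uses only voxel-space geometry.
#'
#' @param image 3D numeric array (HU)
#' @param mask 3D integer array, same dim as `image`, values in {0, 1, 2}
#' @param spacing numeric length-3, mm per axis
#' @param affine optional 4x4 voxel-to-world matrix; default diagonal spacing
#' @return object of class `phantom_volume`
#' @export
phantom_volume <- function(image, mask, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(image)) == 3, identical(dim(image), dim(mask)))
  if (!all(mask %in% c(0L, 1L, 2L))) stop("mask values must be in {0, 1, 2}")
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(
    list(image = image, mask = mask, spacing = as.numeric(spacing), affine = affine),
    class = "phantom_volume"
  )
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf(
    "phantom_volume: %s voxels @ %s mm; labels: %s\n",
    paste(dim(x$image), collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    paste(sort(unique(as.integer(x$mask))), collapse = ", ")
  ))
  invisible(x)
}

#' Mean attenuation over a labeled organ
#'
#' Arithmetic mean of image values across all voxels carrying the given mask
#' label — the volumetric analogue of a pooled ROI mean. For scans that
#' truncate the organ (partial organ volume), the mean is simply over the
#' visible labeled voxels.
#'
#' @param volume a [phantom_volume()]
#' @param label integer mask label (1 = liver, 2 = spleen)
#' @return list with `mean_hu` and `n_voxels`
#' @export
masked_mean <- function(volume, label) {
  stopifnot(inherits(volume, "phantom_volume"))
  sel <- volume$mask == label
  n <- sum(sel)
  if (n == 0) stop(sprintf("label %d not present in mask", label))
  list(mean_hu = mean(volume$image[sel]), n_voxels = n)
}

#' Circular region-of-interest specification
#'
#' A 2D disc on a single axial slice: pixels whose in-plane centre lies
#' within `radius_mm` of the ROI centre belong to the ROI. The radius is
#' converted to voxel units with the in-plane spacing.
#'
#' @param center numeric length-3 voxel coordinates (x, y, z); z selects the
#'   axial slice
#' @param radius_mm disc radius in mm (> 0)
#' @return object of class `roi_spec`
#' @export
roi_spec <- function(center, radius_mm) {
  stopifnot(length(center) == 3, radius_mm > 0)
  structure(list(center = as.numeric(center), radius_mm = radius_mm),
            class = "roi_spec")
}

#' Pooled mean attenuation over circular ROIs
#'
#' Mean over the pooled pixel list of all in-disc pixels across all ROIs —
#' "all pixels across all ROIs", not the mean of per-ROI means, so larger
#' discs carry proportionally more weight. Pixels covered by overlapping
#' discs are pooled once per disc they belong to.
#'
#' @param volume a [phantom_volume()]
#' @param rois list of [roi_spec()] objects (>= 1)
#' @return list with `mean_hu` and `n_pixels` (pooled, with multiplicity)
#' @export
roi_mean <- function(volume, rois) {
  stopifnot(inherits(volume, "phantom_volume"), length(rois) >= 1)
  dims <- dim(volume$image)
  sx <- volume$spacing[1]; sy <- volume$spacing[2]
  total <- 0
  n_total <- 0L
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    stopifnot(inherits(roi, "roi_spec"))
    cx <- roi$center[1]; cy <- roi$center[2]
    z <- as.integer(round(roi$center[3]))
    rx <- roi$radius_mm / sx
    ry <- roi$radius_mm / sy
    if (z < 1 || z > dims[3] ||
        cx - rx < 1 || cx + rx > dims[1] ||
        cy - ry < 1 || cy + ry > dims[2]) {
      stop(sprintf("ROI %d extends outside the image bounds", i))
    }
    xs <- seq.int(max(1L, floor(cx - rx)), min(dims[1], ceiling(cx + rx)))
    ys <- seq.int(max(1L, floor(cy - ry)), min(dims[2], ceiling(cy + ry)))
    dx2 <- ((xs - cx) * sx)^2
    dy2 <- ((ys - cy) * sy)^2
    inside <- outer(dx2, dy2, `+`) <= roi$radius_mm^2
    vals <- volume$image[xs, ys, z][inside]
    total <- total + sum(vals)
    n_total <- n_total + length(vals)
  }
  if (n_total == 0L) stop("no pixels fell inside any ROI")
  list(mean_hu = total / n_total, n_pixels = n_total)
}

#' Per-subject, per-phase attenuation record
#'
#' Bundles liver and spleen mean attenuation for one scan phase with the two
#' derived steatosis markers: the liver-spleen difference L-S and the
#' liver/spleen ratio L/S. The ratio is undefined (NA, with a warning) when
#' the spleen mean is within 1 HU of zero, where the ratio blows up without
#' physical meaning; the difference is always computed.
#'
#' @param subject_id identifier
#' @param phase `"non-contrast"`, `"arterial"`, `"venous"` or `"delayed"`
#' @param liver_hu,spleen_hu mean attenuations (HU)
#' @return one-row data.frame with `subject_id`, `phase`, `liver_hu`,
#'   `spleen_hu`, `liver_minus_spleen`, `liver_spleen_ratio`
#' @export
derive_record <- function(subject_id, phase, liver_hu, spleen_hu) {
  phase <- match.arg(phase, c("non-contrast", "arterial", "venous", "delayed"))
  stopifnot(is.finite(liver_hu), is.finite(spleen_hu))
  ratio <- if (abs(spleen_hu) <= 1) {
    warning(sprintf(
      "spleen mean %.3f HU within 1 HU of zero; liver/spleen ratio undefined",
      spleen_hu
    ))
    NA_real_
  } else {
    liver_hu / spleen_hu
  }
  data.frame(
    subject_id = subject_id,
    phase = phase,
    liver_hu = liver_hu,
    spleen_hu = spleen_hu,
    liver_minus_spleen = liver_hu - spleen_hu,
    liver_spleen_ratio = ratio
  )
}

#' Write / read a phantom volume as paired NIfTI files
#'
#' The image and mask are written as two NIfTI files with identical spacing
#' and affine, plus a sidecar JSON documenting the label scheme
#' (0 background, 1 liver, 2 spleen).
#'
#' @param volume a [phantom_volume()]
#' @param image_path,mask_path output NIfTI paths (`.nii`)
#' @return `read_phantom_nifti` returns a [phantom_volume()]
#' @export
write_phantom_nifti <- function(volume, image_path, mask_path) {
  stopifnot(inherits(volume, "phantom_volume"))
  img <- RNifti::asNifti(volume$image, pixdim = volume$spacing)
  msk <- RNifti::asNifti(array(as.integer(volume$mask), dim(volume$mask)),
                         pixdim = volume$spacing)
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".labels.json", mask_path)
  jsonlite::write_json(
    list(labels = list(`0` = "background", `1` = "liver", `2` = "spleen")),
    sidecar, auto_unbox = TRUE
  )
  invisible(c(image = image_path, mask = mask_path, sidecar = sidecar))
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  phantom_volume(
    image = array(as.numeric(img), dim(img)),
    mask = array(as.integer(round(as.numeric(msk))), dim(msk)),
    spacing = spacing,
    affine = structure(RNifti::xform(img), class = NULL)
  )
}
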