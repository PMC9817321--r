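#' HU range of calibrated CT data
#'
#' Calibrated CT attenuation is bounded below by air (-1024 HU) and above by
#' the 12-bit scanner ceiling (3071 HU). Values outside this range are
#' calibration artifacts and are clipped on construction.
#' @keywords internal
HU_MIN <- -1024L
HU_MAX <- 3071L

#' Lobe label encoding
#'
#' Integer labels used in lobe label maps: 0 is background, then the five
#' lobes in the fixed order right upper (RUL), right middle (RML), right
#' lower (RLL), left upper (LUL), left lower (LLL).
#'
#' @return A named integer vector mapping lobe abbreviation to label.
#' @examples
#' lobe_labels()
#' @export
lobe_labels <- function() {
  c(RUL = 1L, RML = 2L, RLL = 3L, LUL = 4L, LLL = 5L)
}

#' CT volume in canonical orientation
#'
#' A 3-D grid of Hounsfield-unit values with physical voxel spacing. The
#' canonical axis order is (superior-inferior, anterior-posterior,
#' right-left): slice `voxels[1, , ]` is the lung apex. All downstream
#' operations (airway seeding, slice-wise leak guards) assume this order.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing Numeric length-3, physical voxel size in mm per axis
#'   (SI, AP, RL). All entries must be positive; spacing is never defaulted.
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param clip Clip HU values into \[-1024, 3071\] (with a warning) instead of
#'   erroring. Default `TRUE`: out-of-range values in real scans are
#'   calibration artifacts, not data.
#'
#' @return An object of class `ct_volume`: a list with elements `voxels`,
#'   `spacing`, `origin`.
#' @examples
#' vol <- ct_volume(array(-750, dim = c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), clip = TRUE) {
  check_grid(voxels)
  spacing <- check_spacing(spacing)
  origin <- check_origin(origin)
  if (anyNA(voxels)) {
    abort("`voxels` must not contain missing HU values.", class = "lungflv_format_error")
  }
  out_of_range <- voxels < HU_MIN | voxels > HU_MAX
  if (any(out_of_range)) {
    if (!clip) {
      abort(
        sprintf("%d voxel(s) outside the HU range [%d, %d].", sum(out_of_range), HU_MIN, HU_MAX),
        class = "lungflv_format_error"
      )
    }
    warn(sprintf("Clipped %d HU value(s) into [%d, %d].", sum(out_of_range), HU_MIN, HU_MAX))
    voxels[voxels < HU_MIN] <- HU_MIN
    voxels[voxels > HU_MAX] <- HU_MAX
  }
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin),
    class = "ct_volume"
  )
}

#' Binary mask on a CT grid
#'
#' @param voxels 3-D logical array (or 0/1 numeric, coerced).
#' @inheritParams ct_volume
#' @return An object of class `mask_volume`.
#' @examples
#' m <- mask_volume(array(TRUE, dim = c(2, 2, 2)), spacing = c(1, 1, 1))
#' @export
mask_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  check_grid(voxels)
  spacing <- check_spacing(spacing)
  origin <- check_origin(origin)
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) {
      abort("Mask voxels must be logical or 0/1.", class = "lungflv_format_error")
    }
    voxels <- array(as.logical(voxels), dim = dim(voxels))
  }
  if (anyNA(voxels)) abort("Mask voxels must not be NA.", class = "lungflv_format_error")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin),
    class = "mask_volume"
  )
}

#' Lobe label map on a CT grid
#'
#' Integer labels 0 (background) and 1..5 for the five lobes; see
#' [lobe_labels()] for the encoding.
#'
#' @param voxels 3-D integer array with values in `c(0, lobe_labels())`.
#' @inheritParams ct_volume
#' @param legend Named integer vector mapping lobe names to labels.
#' @return An object of class `lobe_label_map`.
#' @export
lobe_label_map <- function(voxels, spacing, origin = c(0, 0, 0),
                           legend = lobe_labels()) {
  check_grid(voxels)
  spacing <- check_spacing(spacing)
  origin <- check_origin(origin)
  if (anyNA(voxels)) abort("Label voxels must not be NA.", class = "lungflv_format_error")
  allowed <- c(0L, as.integer(legend))
  bad <- setdiff(unique(as.integer(voxels)), allowed)
  if (length(bad) > 0) {
    abort(
      sprintf("Labels outside the legend: %s.", paste(bad, collapse = ", ")),
      class = "lungflv_format_error"
    )
  }
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, legend = legend),
    class = "lobe_label_map"
  )
}

check_grid <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3-D array.", class = "lungflv_format_error")
  }
  if (length(voxels) == 0L) {
    abort("`voxels` must be non-empty.", class = "lungflv_format_error")
  }
  invisible(voxels)
}

check_spacing <- function(spacing) {
  if (is.null(spacing) || length(spacing) != 3L || anyNA(spacing)) {
    abort("`spacing` must be a length-3 numeric vector (mm); it is never defaulted.",
      class = "lungflv_format_error"
    )
  }
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) {
    abort("All spacings must be > 0 mm.", class = "lungflv_format_error")
  }
  unname(spacing)
}

check_origin <- function(origin) {
  if (length(origin) != 3L || anyNA(origin)) {
    abort("`origin` must be a length-3 numeric vector.", class = "lungflv_format_error")
  }
  unname(as.numeric(origin))
}

# grids must agree exactly for voxel-wise Boolean work
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    abort(sprintf("Grid shapes of the %s differ.", what), class = "lungflv_grid_error")
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    abort(sprintf("Spacings of the %s differ.", what), class = "lungflv_grid_error")
  }
  invisible(TRUE)
}

voxel_ml <- function(x) prod(x$spacing) / 1000

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> %s voxels, spacing %s mm (SI, AP, RL), HU range [%d, %d]\n",
    paste(dim(x$voxels), collapse = " x "),
    paste(format(x$spacing, trim = TRUE), collapse = " x "),
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf(
    "<mask_volume> %s voxels, %d selected (%.1f mL)\n",
    paste(dim(x$voxels), collapse = " x "),
    sum(x$voxels), sum(x$voxels) * voxel_ml(x)
  ))
  invisible(x)
}

#' @export
print.lobe_label_map <- function(x, ...) {
  tab <- tabulate(x$voxels + 1L, nbins = max(x$legend) + 1L)
  cat(sprintf(
    "<lobe_label_map> %s voxels; labelled: %s\n",
    paste(dim(x$voxels), collapse = " x "),
    paste(sprintf("%s=%d", names(x$legend), tab[x$legend + 1L]), collapse = ", ")
  ))
  invisible(x)
}
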