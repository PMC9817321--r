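#' Read a CT volume from NIfTI
#'
#' Reads a 3-D NIfTI image, reorients it into the canonical
#' (superior-inferior, anterior-posterior, right-left) axis order and
#' reinterprets the stored values as Hounsfield units unchanged. NIfTI stores
#' axes fastest-first as (RL, AP, SI), so the array is transposed and the
#' per-axis spacings reversed: a file with a 0.7 x 0.7 x 1.25 mm grid yields
#' `spacing = c(1.25, 0.7, 0.7)`.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [ct_volume()].
#' @seealso [write_ct()]
#' @export
read_ct <- function(path) {
  raw <- read_nifti_canonical(path)
  ct_volume(raw$voxels, spacing = raw$spacing, origin = raw$origin)
}

#' Write a CT volume to NIfTI
#'
#' Voxels are stored as signed 16-bit integers (the full calibrated HU range
#' fits), so `read_ct(write_ct(v, p))` is voxel-identical and reproduces the
#' spacing to within 1e-6 mm.
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  write_nifti_canonical(vol$voxels, vol$spacing, vol$origin, path, datatype = "int16")
  invisible(path)
}

#' Read/write binary masks as NIfTI
#'
#' Masks are stored as unsigned 8-bit 0/1 volumes on the same canonical grid
#' convention as [read_ct()].
#'
#' @param path NIfTI path.
#' @return `read_mask()` returns a [mask_volume()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  raw <- read_nifti_canonical(path)
  mask_volume(raw$voxels, spacing = raw$spacing, origin = raw$origin)
}

#' @rdname read_mask
#' @param mask A [mask_volume()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  write_nifti_canonical(arr, mask$spacing, mask$origin, path, datatype = "uint8")
  invisible(path)
}

#' Read/write lobe label maps as NIfTI with a JSON legend sidecar
#'
#' The integer labels travel in the NIfTI voxels; the lobe-name legend is
#' written to a `<stem>.labels.json` sidecar next to the image and restored on
#' read (falling back to [lobe_labels()] when the sidecar is absent).
#'
#' @param path NIfTI path.
#' @return `read_lobe_map()` returns a [lobe_label_map()]; `write_lobe_map()`
#'   returns `path` invisibly.
#' @export
read_lobe_map <- function(path) {
  raw <- read_nifti_canonical(path)
  sidecar <- lobe_sidecar_path(path)
  legend <- lobe_labels()
  if (file.exists(sidecar)) {
    leg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    legend <- structure(as.integer(leg), names = names(leg))
  }
  lobe_label_map(raw$voxels, spacing = raw$spacing, origin = raw$origin,
                 legend = legend)
}

#' @rdname read_lobe_map
#' @param lobes A [lobe_label_map()].
#' @export
write_lobe_map <- function(lobes, path) {
  stopifnot(inherits(lobes, "lobe_label_map"))
  write_nifti_canonical(lobes$voxels, lobes$spacing, lobes$origin, path,
                        datatype = "uint8")
  jsonlite::write_json(as.list(lobes$legend), lobe_sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

lobe_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".labels.json", path)
}

read_nifti_canonical <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "lungflv_format_error")
  }
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (length(d) != 3L) {
    abort(
      sprintf("Expected a 3-D NIfTI volume, got %d dimension(s).", length(d)),
      class = "lungflv_format_error"
    )
  }
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || anyNA(pd[1:3]) || any(pd[1:3] <= 0)) {
    abort("NIfTI pixdim does not provide three positive spacings.",
      class = "lungflv_format_error"
    )
  }
  xf <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(xf, "try-error")) c(0, 0, 0) else rev(unname(xf[1:3, 4]))
  arr <- aperm(as.array(img), c(3L, 2L, 1L))
  attributes(arr) <- list(dim = dim(arr))
  list(voxels = arr, spacing = rev(unname(pd[1:3])), origin = orig)
}

write_nifti_canonical <- function(arr, spacing, origin, path, datatype) {
  out <- aperm(arr, c(3L, 2L, 1L))
  attr(out, "pixdim") <- rev(spacing)
  img <- RNifti::asNifti(out, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

cohort_required_cols <- c("id", "group", "pre_fvc", "pre_fev1")
cohort_numeric_cols <- c(
  "pre_fvc", "pre_fev1", "post_fvc", "post_fev1",
  "resected_segment_count", "resected_flv_ml", "total_flv_ml",
  "delta_flv_ratio"
)

#' Read a cohort table from CSV
#'
#' A cohort table holds one row per patient: `id`, `group` (`lobectomy`,
#' `segmentectomy` or `wedge`), preoperative and (optionally) postoperative
#' spirometry in litres (`pre_fvc`, `pre_fev1`, `post_fvc`, `post_fev1`),
#' `resected_lobes` (semicolon-separated lobe abbreviations),
#' `resected_segment_count` (0..19, `NA` when segment counting does not
#' apply), `resected_flv_ml`, `total_flv_ml` and `delta_flv_ratio` in
#' `[0, 1)`. Rows violating these invariants are rejected and the error names
#' the offending row numbers.
#'
#' @param path CSV path.
#' @return A tibble, one row per patient.
#' @seealso [write_cohort()], [simulate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "lungflv_format_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(x)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

validate_cohort <- function(x) {
  missing_cols <- setdiff(cohort_required_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("Cohort table is missing mandatory column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      class = "lungflv_format_error"
    )
  }
  for (col in intersect(cohort_numeric_cols, names(x))) {
    if (!is.numeric(x[[col]])) {
      abort(sprintf("Cohort column `%s` must be numeric.", col),
        class = "lungflv_format_error"
      )
    }
  }
  bad <- rep(FALSE, nrow(x))
  for (col in intersect(c("pre_fvc", "pre_fev1", "post_fvc", "post_fev1"), names(x))) {
    bad <- bad | (!is.na(x[[col]]) & x[[col]] <= 0)
  }
  if ("delta_flv_ratio" %in% names(x)) {
    d <- x$delta_flv_ratio
    bad <- bad | (!is.na(d) & (d < 0 | d >= 1))
  }
  if ("resected_segment_count" %in% names(x)) {
    s <- x$resected_segment_count
    bad <- bad | (!is.na(s) & (s < 0 | s > 19 | s != round(s)))
  }
  if (any(bad)) {
    abort(
      sprintf("Cohort row(s) violate invariants: %s.",
              paste(which(bad), collapse = ", ")),
      class = "lungflv_invariant_error"
    )
  }
  as_tibble(x)
}
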