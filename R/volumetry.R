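#' Volume of a binary mask in mL
#'
#' Selected voxel count times the voxel volume (product of the three mm
#' spacings), divided by 1000.
#'
#' @param mask A [mask_volume()].
#' @return Volume in mL.
#' @examples
#' m <- mask_volume(array(TRUE, dim = c(10, 10, 10)), spacing = c(1, 1, 1))
#' mask_volume_ml(m) # 1 mL
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$voxels) * voxel_ml(mask)
}

#' Per-lobe functional volume
#'
#' Intersects an FLV mask with a lobe label map and reports mL per lobe.
#' FLV voxels with label 0 are reported as `"unassigned"`; they are excluded
#' from lobar sums but still count towards the total, and a warning is
#' emitted when they exceed 5% of the FLV (imperfect fissure coverage).
#'
#' @param flv A [mask_volume()] of functional lung.
#' @param lobes A [lobe_label_map()] on the same grid.
#' @return A tibble with columns `lobe` (five lobes then `"unassigned"`) and
#'   `flv_ml`. The column sums exactly to `mask_volume_ml(flv)`.
#' @export
lobar_flv <- function(flv, lobes) {
  stopifnot(inherits(flv, "mask_volume"), inherits(lobes, "lobe_label_map"))
  check_same_grid(flv, lobes, "FLV mask and lobe map")
  lb <- lobes$legend
  counts <- tabulate(lobes$voxels[flv$voxels] + 1L, nbins = max(lb) + 1L)
  vml <- voxel_ml(flv)
  out <- tibble(
    lobe = c(names(lb), "unassigned"),
    flv_ml = c(counts[lb + 1L], counts[1L]) * vml
  )
  total <- sum(out$flv_ml)
  if (total > 0 && counts[1L] * vml / total > 0.05) {
    warn(sprintf(
      "%.1f%% of the FLV falls outside every lobe label.",
      100 * counts[1L] * vml / total
    ))
  }
  out
}

#' Full volumetry of one scan
#'
#' Combines the TLV and FLV masks with the lobe label map into the standard
#' volumetric report: TLV, total FLV, per-lobe FLV, resected-lobe FLV and
#' the loss ratio for a named resection.
#'
#' @param tlv_mask,flv_mask [mask_volume()]s on the same grid.
#' @param lobes A [lobe_label_map()].
#' @param resected Character vector of resected lobe names (may be empty).
#' @return A list of class `flv_volumetry` with `tlv_ml`, `flv_total_ml`,
#'   `per_lobe` (tibble), `resected`, `resected_flv_ml`, `resected_fraction`
#'   and `mode = "resected-lobe"`. [tidy()] returns the per-lobe tibble,
#'   [glance()] the one-row totals.
#' @export
volumetry <- function(tlv_mask, flv_mask, lobes, resected = character()) {
  check_same_grid(tlv_mask, flv_mask, "TLV and FLV masks")
  if (any(flv_mask$voxels & !tlv_mask$voxels)) {
    abort("FLV mask is not a subset of the TLV mask.", class = "lungflv_invariant_error")
  }
  per_lobe <- lobar_flv(flv_mask, lobes)
  res <- structure(
    list(
      tlv_ml = mask_volume_ml(tlv_mask),
      flv_total_ml = mask_volume_ml(flv_mask),
      per_lobe = per_lobe,
      resected = resected,
      resected_flv_ml = sum(per_lobe$flv_ml[per_lobe$lobe %in% resected]),
      mode = "resected-lobe"
    ),
    class = "flv_volumetry"
  )
  res$resected_fraction <- if (length(resected) > 0) {
    resected_fraction(res, resected)
  } else {
    0
  }
  res
}

#' Fraction of total FLV in the resected lobes
#'
#' The term subtracted inside `(1 - resected FLV / total FLV)` of the
#' FLV prediction method.
#'
#' @param volu An `flv_volumetry` object (or any list with a `per_lobe`
#'   tibble and `flv_total_ml`).
#' @param resected Character vector of lobe names.
#' @return The fraction in `[0, 1]`.
#' @examples
#' v <- list(
#'   per_lobe = tibble::tibble(
#'     lobe = c("RUL", "RML", "RLL", "LUL", "LLL"),
#'     flv_ml = c(844.91, 396.12, 982.97, 999.42, 912.56)
#'   )
#' )
#' v$flv_total_ml <- sum(v$per_lobe$flv_ml)
#' resected_fraction(v, "RUL") # 0.2043
#' @export
resected_fraction <- function(volu, resected) {
  unknown <- setdiff(resected, volu$per_lobe$lobe)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown lobe(s): %s.", paste(unknown, collapse = ", ")),
      class = "lungflv_spec_error"
    )
  }
  if (volu$flv_total_ml <= 0) {
    abort("Total FLV is zero; the resected fraction is undefined.",
      class = "lungflv_invariant_error"
    )
  }
  sum(volu$per_lobe$flv_ml[volu$per_lobe$lobe %in% resected]) / volu$flv_total_ml
}

#' Functional-volume loss ratio ΔFLV/FLV
#'
#' Two definitions are supported, reflecting a genuine ambiguity in how the
#' reduction is measured. `"resected-lobe"`: the preoperative FLV of the
#' resected lobes over the preoperative total FLV. `"pre-post"`: the drop in
#' total FLV between two scans over the preoperative total; when the
#' postoperative FLV exceeds the preoperative one (compensatory expansion of
#' the remaining lung) the ratio clips to 0 and the raw negative value is
#' logged.
#'
#' @param pre Preoperative `flv_volumetry`.
#' @param post Postoperative `flv_volumetry` (required for `"pre-post"`).
#' @param resected Resected lobe names (required for `"resected-lobe"`).
#' @param mode `"resected-lobe"` or `"pre-post"`.
#' @return The loss ratio.
#' @export
delta_flv_ratio <- function(pre, post = NULL, resected = NULL,
                            mode = c("resected-lobe", "pre-post")) {
  mode <- match.arg(mode)
  if (pre$flv_total_ml <= 0) {
    abort("Preoperative total FLV is zero.", class = "lungflv_invariant_error")
  }
  if (mode == "resected-lobe") {
    if (is.null(resected)) {
      abort("`resected` lobes are required in resected-lobe mode.",
        class = "lungflv_spec_error"
      )
    }
    return(resected_fraction(pre, resected))
  }
  if (is.null(post)) {
    abort("A postoperative volumetry is required in pre-post mode.",
      class = "lungflv_spec_error"
    )
  }
  raw <- (pre$flv_total_ml - post$flv_total_ml) / pre$flv_total_ml
  if (raw < 0) {
    inform(sprintf(
      "Postoperative FLV exceeds preoperative (raw ratio %.4f); clipping to 0.",
      raw
    ))
    return(0)
  }
  raw
}

#' @export
print.flv_volumetry <- function(x, ...) {
  cat(sprintf(
    "<flv_volumetry> TLV %.1f mL, FLV %.1f mL; resected {%s}: %.1f mL (fraction %.3f)\n",
    x$tlv_ml, x$flv_total_ml, paste(x$resected, collapse = ","),
    x$resected_flv_ml, x$resected_fraction
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flv_volumetry <- function(x, ...) x$per_lobe

#' @exportS3Method generics::glance
glance.flv_volumetry <- function(x, ...) {
  tibble(
    tlv_ml = x$tlv_ml, flv_total_ml = x$flv_total_ml,
    resected_flv_ml = x$resected_flv_ml,
    resected_fraction = x$resected_fraction, mode = x$mode
  )
}
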