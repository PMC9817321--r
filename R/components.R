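#' Label connected components of a 3-D mask
#'
#' Flood-fill labelling with either face (6) or full (26) neighbourhoods.
#' Airway region growing uses 26-connectivity; exterior-air removal uses
#' face connectivity, so diagonal pinholes in the body wall do not leak.
#'
#' @param mask A [mask_volume()] or a 3-D logical array.
#' @param connectivity 6 or 26.
#' @return An integer array of the same shape: 0 outside the mask, components
#'   numbered from 1 in first-encounter order.
#' @export
label_components <- function(mask, connectivity = 26) {
  arr <- if (inherits(mask, "mask_volume")) mask$voxels else mask
  check_grid(arr)
  if (!is.logical(arr)) arr <- array(as.logical(arr), dim = dim(arr))
  cc_label_cpp(arr, as.integer(dim(arr)), as.integer(connectivity))
}
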