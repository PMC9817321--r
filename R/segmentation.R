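#' HU threshold windows
#'
#' Inclusive Hounsfield-unit windows. The two canonical windows of the
#' pipeline are `tlv_window()` (\[-1024, -500\] HU, total lung) and
#' `flv_window()` (\[-910, -600\] HU, normally aerated functional lung,
#' excluding hyperinflated tissue below -910 HU and consolidated or fibrotic
#' tissue above -600 HU).
#'
#' @param lo,hi Inclusive bounds in HU, `lo < hi`, both within
#'   \[-1024, 3071\].
#' @return A named numeric vector of class `threshold_window`.
#' @examples
#' tlv_window()
#' flv_window()
#' @export
threshold_window <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || is.na(lo) || is.na(hi) || lo >= hi) {
    abort("A threshold window needs numeric bounds with lo < hi.",
      class = "lungflv_spec_error"
    )
  }
  if (lo < HU_MIN || hi > HU_MAX) {
    abort(sprintf("Window bounds must lie within [%d, %d] HU.", HU_MIN, HU_MAX),
      class = "lungflv_spec_error"
    )
  }
  structure(c(lo = lo, hi = hi), class = "threshold_window")
}

#' @rdname threshold_window
#' @export
tlv_window <- function() threshold_window(-1024, -500)

#' @rdname threshold_window
#' @export
flv_window <- function() threshold_window(-910, -600)

#' Select voxels inside an HU window
#'
#' Pure per-voxel selection: a voxel is in the mask iff
#' `lo <= HU <= hi` (closed interval). No morphology is applied.
#'
#' @param vol A [ct_volume()].
#' @param window A [threshold_window()].
#' @return A [mask_volume()] on the same grid.
#' @export
threshold_mask <- function(vol, window) {
  stopifnot(inherits(vol, "ct_volume"), inherits(window, "threshold_window"))
  mask_volume(
    vol$voxels >= window[["lo"]] & vol$voxels <= window[["hi"]],
    spacing = vol$spacing, origin = vol$origin
  )
}

#' Segment the tracheal air column
#'
#' Region growing from a seed through the 26-connected component of voxels
#' with HU at or below `hu_max` (default -950). With `seed = "auto"` the
#' seed is searched in the most superior 10% of slices: an in-plane air
#' component that does not touch the slice border (exterior air always does)
#' and whose centroid lies in the central third of both in-plane axes.
#'
#' A leak guard replaces proprietary airway logic: descending from the apex,
#' if one slice's component area more than triples relative to the previous
#' slice, growth stops at that slice (the overgrown slices are dropped) and
#' a message is logged.
#'
#' @param vol A [ct_volume()] in canonical orientation (slice 1 = apex).
#' @param seed `"auto"` or an integer voxel index triple (SI, AP, RL).
#' @param hu_max Airway air threshold in HU.
#' @param leak_factor Slice-to-slice area growth factor that triggers the
#'   leak guard.
#' @return A [mask_volume()] of the airway. If no qualifying seed exists an
#'   error of class `lungflv_airway_not_found` is raised; callers may catch
#'   it and proceed with an empty airway.
#' @export
segment_airway <- function(vol, seed = "auto", hu_max = -950, leak_factor = 3) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  air <- vol$voxels <= hu_max

  if (identical(seed, "auto")) {
    seed <- find_airway_seed(air, d)
  } else {
    seed <- as.integer(seed)
    if (length(seed) != 3L || any(seed < 1L) || any(seed > d)) {
      abort("Explicit airway seed must be a voxel index triple inside the grid.",
        class = "lungflv_airway_not_found"
      )
    }
    if (!air[seed[1], seed[2], seed[3]]) {
      abort("Explicit airway seed is not an air voxel at the airway threshold.",
        class = "lungflv_airway_not_found"
      )
    }
  }

  labels <- cc_label_cpp(air, as.integer(d), 26L)
  id <- labels[seed[1], seed[2], seed[3]]
  comp <- labels == id

  # leak guard while descending from the apex
  areas <- apply(comp, 1, sum)
  first <- which(areas > 0)[1]
  if (!is.na(first) && first < d[1]) {
    for (si in (first + 1):d[1]) {
      if (areas[si - 1] > 0 && areas[si] > leak_factor * areas[si - 1]) {
        inform(sprintf(
          "Airway leak guard triggered at slice %d (area %d -> %d); growth stopped.",
          si, areas[si - 1], areas[si]
        ))
        comp[si:d[1], , ] <- FALSE
        break
      }
    }
  }

  mask_volume(comp, spacing = vol$spacing, origin = vol$origin)
}

find_airway_seed <- function(air, d) {
  top <- max(1L, ceiling(0.1 * d[1]))
  for (si in seq_len(top)) {
    sl <- air[si, , , drop = TRUE]
    if (!any(sl)) next
    lab <- cc_label_cpp(
      array(sl, dim = c(1L, d[2], d[3])),
      c(1L, d[2], d[3]), 26L
    )[1, , ]
    for (id in seq_len(max(lab))) {
      idx <- which(lab == id, arr.ind = TRUE)
      # exterior air always touches the in-plane border
      if (any(idx[, 1] %in% c(1L, d[2])) || any(idx[, 2] %in% c(1L, d[3]))) next
      ctr <- colMeans(idx)
      if (ctr[1] > d[2] / 3 && ctr[1] < 2 * d[2] / 3 &&
          ctr[2] > d[3] / 3 && ctr[2] < 2 * d[3] / 3) {
        return(c(si, idx[1, 1], idx[1, 2]))
      }
    }
  }
  abort("No qualifying airway seed found in the superior 10% of slices.",
    class = "lungflv_airway_not_found"
  )
}

#' Extract the total-lung (TLV) mask
#'
#' Thresholds with the TLV window (default \[-1024, -500\] HU), removes
#' exterior air (voxels face-connected to the grid boundary), subtracts the
#' airway mask (Boolean difference), and drops connected components smaller
#' than `min_component_ml` (noise islands; default 50 mL, far below any
#' lobe volume).
#'
#' @param vol A [ct_volume()].
#' @param airway A [mask_volume()] on the same grid (possibly empty).
#' @param window TLV [threshold_window()].
#' @param min_component_ml Minimum surviving component volume in mL.
#' @return The TLV [mask_volume()]. Raises `lungflv_empty_lung` if nothing
#'   survives.
#' @export
extract_lungs <- function(vol, airway, window = tlv_window(),
                          min_component_ml = 50) {
  stopifnot(inherits(vol, "ct_volume"), inherits(airway, "mask_volume"))
  check_same_grid(vol, airway, "CT and airway mask")
  m <- threshold_mask(vol, window)$voxels
  d <- dim(m)

  lab6 <- cc_label_cpp(m, as.integer(d), 6L)
  boundary <- unique(c(
    lab6[1, , ], lab6[d[1], , ],
    lab6[, 1, ], lab6[, d[2], ],
    lab6[, , 1], lab6[, , d[3]]
  ))
  boundary <- boundary[boundary > 0]
  if (length(boundary) > 0) m[lab6 %in% boundary] <- FALSE

  m <- m & !airway$voxels

  lab26 <- cc_label_cpp(m, as.integer(d), 26L)
  n_comp <- max(lab26)
  if (n_comp == 0L) {
    abort("No lung component survives thresholding and airway removal.",
      class = "lungflv_empty_lung"
    )
  }
  sizes_ml <- tabulate(lab26[lab26 > 0], nbins = n_comp) * prod(vol$spacing) / 1000
  keep <- which(sizes_ml >= min_component_ml)
  if (length(keep) == 0L) {
    abort(sprintf(
      "No lung component reaches %g mL (largest: %.1f mL).",
      min_component_ml, max(sizes_ml)
    ), class = "lungflv_empty_lung")
  }
  m <- array(lab26 %in% keep, dim = d)
  mask_volume(m, spacing = vol$spacing, origin = vol$origin)
}

#' Extract the functional-lung (FLV) mask
#'
#' Voxels of the TLV mask whose HU lies in the functional window (default
#' \[-910, -600\]). By construction the result is a subset of the lung mask.
#'
#' @param vol A [ct_volume()].
#' @param lungs The TLV [mask_volume()] on the same grid.
#' @param window Functional [threshold_window()].
#' @return A [mask_volume()].
#' @export
functional_mask <- function(vol, lungs, window = flv_window()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(lungs, "mask_volume"))
  check_same_grid(vol, lungs, "CT and lung mask")
  mask_volume(
    lungs$voxels & threshold_mask(vol, window)$voxels,
    spacing = vol$spacing, origin = vol$origin
  )
}
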