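#' Specification of a synthetic thoracic CT phantom
#'
#' The phantom emulates the three radiological HU classes the volumetry
#' pipeline separates: normally aerated parenchyma (HU ~ Normal(-750, 50),
#' inside the functional window), hyperinflated/emphysematous tissue
#' (Normal(-960, 15), below -910 HU) and consolidated tissue
#' (Normal(-100, 60), above -600 HU), embedded in a soft-tissue body
#' cylinder (+40 HU) surrounded by exterior air (-1000 HU), with a tracheal
#' air column entering from the lung apex. Lungs are ellipsoids; fissures are
#' planes (one oblique + one horizontal on the right, one oblique on the
#' left), so lobe membership and all class volumes are analytic ground truth.
#'
#' All geometry is in mm in the canonical (SI, AP, RL) axis order. The
#' default grid is a reduced-scale thorax (each lung about 0.64 L) at 1 mm
#' isotropic spacing, chosen so a full phantom builds in seconds.
#'
#' @param dim Grid shape (SI, AP, RL).
#' @param spacing Voxel size in mm per axis.
#' @param right_lung,left_lung Lists with `center` and `half_axes` (mm).
#'   A half axis of 0 produces no lung (degenerate phantoms).
#' @param body List with in-plane `center` (AP, RL), `half_axes` (AP, RL)
#'   and `hu`.
#' @param trachea List with `radius`, `length` (mm from the superior grid
#'   face), in-plane `center` (AP, RL) and `hu`. `length = 0` omits it.
#' @param parenchyma,emphysema,consolidation Lists with `hu_mean`, `hu_sd`;
#'   the blob classes also carry `n` (count across both lungs) and `radius`
#'   (min, max mm).
#' @param fissures List of plane parameters: `right_oblique` / `left_oblique`
#'   each with `point` (SI, AP mm) and `normal` (SI, AP); voxels on the
#'   positive side belong to the lower lobe. `right_horizontal_si` is the SI
#'   level (mm) splitting the non-lower right lung into RUL (above) and RML.
#' @param background_hu HU of exterior air.
#' @param seed Integer seed; the builder is deterministic given the spec.
#'
#' @return A list of class `phantom_spec`.
#' @seealso [build_phantom()]
#' @export
phantom_spec <- function(dim = c(192L, 128L, 192L),
                         spacing = c(1, 1, 1),
                         right_lung = list(center = c(96, 64, 56),
                                           half_axes = c(80, 50, 36)),
                         left_lung = list(center = c(96, 64, 136),
                                          half_axes = c(80, 50, 36)),
                         body = list(center = c(64, 96),
                                     half_axes = c(60, 92), hu = 40),
                         trachea = list(radius = 8, length = 50,
                                        center = c(64, 96), hu = -1000),
                         parenchyma = list(hu_mean = -750, hu_sd = 50),
                         emphysema = list(n = 6L, radius = c(8, 12),
                                          hu_mean = -960, hu_sd = 15),
                         consolidation = list(n = 3L, radius = c(6, 9),
                                              hu_mean = -100, hu_sd = 60),
                         fissures = list(
                           right_oblique = list(point = c(94, 62),
                                                normal = c(0.8, 0.6)),
                           right_horizontal_si = 84,
                           left_oblique = list(point = c(94, 62),
                                               normal = c(0.8, 0.6))
                         ),
                         background_hu = -1000,
                         seed = 1L) {
  spec <- list(
    dim = as.integer(dim), spacing = as.numeric(spacing),
    right_lung = right_lung, left_lung = left_lung, body = body,
    trachea = trachea, parenchyma = parenchyma, emphysema = emphysema,
    consolidation = consolidation, fissures = fissures,
    background_hu = background_hu, seed = as.integer(seed)
  )
  if (length(spec$dim) != 3L || any(spec$dim < 1L)) {
    abort("Phantom grid must be 3-D and non-empty.", class = "lungflv_spec_error")
  }
  check_spacing(spec$spacing)
  for (lung in list(right_lung, left_lung)) {
    if (length(lung$half_axes) != 3L || any(lung$half_axes < 0)) {
      abort("Lung half axes must be three non-negative lengths.",
        class = "lungflv_spec_error"
      )
    }
  }
  structure(spec, class = "phantom_spec")
}

# voxel-centre coordinate arrays (mm) along each canonical axis
coord_arrays <- function(dim, spacing) {
  ax <- lapply(1:3, function(k) (seq_len(dim[k]) - 0.5) * spacing[k])
  list(
    si = array(rep(ax[[1]], times = dim[2] * dim[3]), dim = dim),
    ap = array(rep(rep(ax[[2]], each = dim[1]), times = dim[3]), dim = dim),
    rl = array(rep(ax[[3]], each = dim[1] * dim[2]), dim = dim)
  )
}

inside_ellipsoid <- function(co, center, half) {
  if (any(half <= 0)) {
    return(array(FALSE, dim = dim(co$si)))
  }
  ((co$si - center[1]) / half[1])^2 +
    ((co$ap - center[2]) / half[2])^2 +
    ((co$rl - center[3]) / half[3])^2 <= 1
}

# Tissue class codes used internally by the builder.
CLS_AIR <- 0L
CLS_BODY <- 1L
CLS_TRACHEA <- 2L
CLS_PARENCHYMA <- 3L
CLS_EMPHYSEMA <- 4L
CLS_CONSOLIDATION <- 5L

#' Build a synthetic thoracic CT phantom
#'
#' Rasterises a [phantom_spec()] into a CT volume, a lobe label map and a
#' ground-truth manifest. Ground-truth counts come from the generative tissue
#' labels directly (which voxel was drawn as parenchyma, emphysema,
#' consolidation or airway), never from HU thresholding, so they are an
#' independent oracle for the segmentation stage. Identical specs (including
#' the seed) produce bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `flv_phantom` with elements:
#' \describe{
#'   \item{ct}{[ct_volume()] of drawn HU values.}
#'   \item{lobes}{[lobe_label_map()] of generative lobe membership.}
#'   \item{truth}{Ground truth: `per_lobe` tibble of voxel counts and mL per
#'     tissue class, `airway_ml`, `analytic_lung_ml` (exact ellipsoid
#'     volumes), `nonfunctional_fraction`, `voxel_ml`.}
#' }
#' @examples
#' ph <- build_phantom(phantom_spec(dim = c(48, 32, 48), spacing = c(4, 4, 4),
#'   right_lung = list(center = c(96, 64, 52), half_axes = c(60, 40, 30)),
#'   left_lung = list(center = c(96, 64, 140), half_axes = c(60, 40, 30)),
#'   trachea = list(radius = 9, length = 40, center = c(64, 96), hu = -1000),
#'   emphysema = list(n = 1L, radius = c(8, 10), hu_mean = -960, hu_sd = 15),
#'   consolidation = list(n = 1L, radius = c(8, 10), hu_mean = -100, hu_sd = 60)))
#' ph$truth$per_lobe
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  co <- coord_arrays(d, spec$spacing)

  body_in <- ((co$ap - spec$body$center[1]) / spec$body$half_axes[1])^2 +
    ((co$rl - spec$body$center[2]) / spec$body$half_axes[2])^2 <= 1
  right_in <- inside_ellipsoid(co, spec$right_lung$center, spec$right_lung$half_axes)
  left_in <- inside_ellipsoid(co, spec$left_lung$center, spec$left_lung$half_axes)
  lung_in <- right_in | left_in
  if (any(lung_in & !body_in)) {
    abort("Lung ellipsoids overlap the body boundary.", class = "lungflv_spec_error")
  }

  cls <- array(CLS_AIR, dim = d)
  cls[body_in] <- CLS_BODY
  cls[lung_in] <- CLS_PARENCHYMA

  lobe <- array(0L, dim = d)
  lb <- lobe_labels()
  fis <- spec$fissures
  if (any(right_in)) {
    obl <- fis$right_oblique$normal[1] * (co$si - fis$right_oblique$point[1]) +
      fis$right_oblique$normal[2] * (co$ap - fis$right_oblique$point[2]) > 0
    lobe[right_in & obl] <- lb[["RLL"]]
    upper <- right_in & !obl
    lobe[upper & co$si <= fis$right_horizontal_si] <- lb[["RUL"]]
    lobe[upper & co$si > fis$right_horizontal_si] <- lb[["RML"]]
  }
  if (any(left_in)) {
    obl <- fis$left_oblique$normal[1] * (co$si - fis$left_oblique$point[1]) +
      fis$left_oblique$normal[2] * (co$ap - fis$left_oblique$point[2]) > 0
    lobe[left_in & obl] <- lb[["LLL"]]
    lobe[left_in & !obl] <- lb[["LUL"]]
  }

  if (spec$trachea$length > 0) {
    trach_in <- (co$si <= spec$trachea$length) &
      ((co$ap - spec$trachea$center[1])^2 +
         (co$rl - spec$trachea$center[2])^2 <= spec$trachea$radius^2)
    if (any(trach_in & lung_in)) {
      abort("Tracheal cylinder intersects a lung ellipsoid.",
        class = "lungflv_spec_error"
      )
    }
    cls[trach_in] <- CLS_TRACHEA
  }

  with_substream(spec$seed, "phantom", {
    cls <- place_blobs(cls, co, spec, right_in, left_in,
      blob = spec$emphysema, code = CLS_EMPHYSEMA
    )
    cls <- place_blobs(cls, co, spec, right_in, left_in,
      blob = spec$consolidation, code = CLS_CONSOLIDATION
    )
    hu <- draw_hu(cls, spec)
  })

  vml <- prod(spec$spacing) / 1000
  per_lobe <- purrr::map_dfr(names(lb), function(nm) {
    in_l <- lobe == lb[[nm]]
    tibble(
      lobe = nm,
      total_voxels = sum(in_l & cls >= CLS_PARENCHYMA),
      functional_voxels = sum(in_l & cls == CLS_PARENCHYMA),
      emphysema_voxels = sum(in_l & cls == CLS_EMPHYSEMA),
      consolidation_voxels = sum(in_l & cls == CLS_CONSOLIDATION)
    )
  })
  per_lobe <- dplyr::mutate(per_lobe,
    total_ml = .data$total_voxels * vml,
    functional_ml = .data$functional_voxels * vml,
    emphysema_ml = .data$emphysema_voxels * vml,
    consolidation_ml = .data$consolidation_voxels * vml
  )
  lung_total <- sum(per_lobe$total_voxels)
  truth <- list(
    per_lobe = per_lobe,
    airway_voxels = sum(cls == CLS_TRACHEA),
    airway_ml = sum(cls == CLS_TRACHEA) * vml,
    analytic_lung_ml = c(
      right = 4 / 3 * pi * prod(spec$right_lung$half_axes) / 1000,
      left = 4 / 3 * pi * prod(spec$left_lung$half_axes) / 1000
    ),
    nonfunctional_fraction = if (lung_total > 0) {
      sum(per_lobe$emphysema_voxels + per_lobe$consolidation_voxels) / lung_total
    } else {
      0
    },
    voxel_ml = vml
  )

  structure(
    list(
      ct = ct_volume(hu, spacing = spec$spacing),
      lobes = lobe_label_map(lobe, spacing = spec$spacing),
      truth = truth,
      spec = spec
    ),
    class = "flv_phantom"
  )
}

# Spheres fully inside a lung ellipsoid: centres sampled (by rejection) in the
# ellipsoid shrunk by the blob radius, which guarantees containment.
place_blobs <- function(cls, co, spec, right_in, left_in, blob, code) {
  n <- blob$n %||% 0L
  if (n < 1L) {
    return(cls)
  }
  lungs <- list(right = spec$right_lung, left = spec$left_lung)
  sides <- names(lungs)[which(c(any(right_in), any(left_in)))]
  if (length(sides) == 0L) {
    abort("Blobs requested but the spec has no lung volume.",
      class = "lungflv_spec_error"
    )
  }
  for (i in seq_len(n)) {
    r <- runif(1, blob$radius[1], blob$radius[2])
    lung <- lungs[[sample(sides, 1L)]]
    shrunk <- lung$half_axes - r
    if (any(shrunk <= 0)) {
      abort("Blob radius exceeds a lung half axis; blob would leave the lung.",
        class = "lungflv_spec_error"
      )
    }
    repeat {
      u <- runif(3, -1, 1)
      if (sum(u^2) <= 1) break
    }
    ctr <- lung$center + u * shrunk
    in_blob <- (co$si - ctr[1])^2 + (co$ap - ctr[2])^2 + (co$rl - ctr[3])^2 <= r^2
    overwrite <- in_blob & (cls == CLS_PARENCHYMA | cls == CLS_EMPHYSEMA)
    cls[overwrite] <- code
  }
  cls
}

draw_hu <- function(cls, spec) {
  hu <- array(as.numeric(spec$background_hu), dim = dim(cls))
  hu[cls == CLS_BODY] <- spec$body$hu
  hu[cls == CLS_TRACHEA] <- spec$trachea$hu
  for (layer in list(
    list(code = CLS_PARENCHYMA, p = spec$parenchyma),
    list(code = CLS_EMPHYSEMA, p = spec$emphysema),
    list(code = CLS_CONSOLIDATION, p = spec$consolidation)
  )) {
    idx <- which(cls == layer$code)
    if (length(idx) > 0) {
      hu[idx] <- round(rnorm(length(idx), layer$p$hu_mean, layer$p$hu_sd))
    }
  }
  hu[hu < HU_MIN] <- HU_MIN
  hu[hu > HU_MAX] <- HU_MAX
  array(as.integer(hu), dim = dim(cls))
}

#' @export
print.flv_phantom <- function(x, ...) {
  cat(sprintf(
    "<flv_phantom> %s voxels at %s mm; lung %.1f mL (%.1f%% non-functional), airway %.1f mL\n",
    paste(dim(x$ct$voxels), collapse = " x "),
    paste(format(x$ct$spacing, trim = TRUE), collapse = " x "),
    sum(x$truth$per_lobe$total_ml),
    100 * x$truth$nonfunctional_fraction,
    x$truth$airway_ml
  ))
  invisible(x)
}
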