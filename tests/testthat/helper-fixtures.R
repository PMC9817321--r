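# Reduced-resolution phantom (2 mm voxels, same mm geometry as the default)
# used by most image tests; builds in about a second.
small_phantom_spec <- function(seed = 1L, ...) {
  defaults <- list(
    dim = c(96L, 64L, 96L), spacing = c(2, 2, 2),
    emphysema = list(n = 4L, radius = c(8, 12), hu_mean = -960, hu_sd = 15),
    consolidation = list(n = 2L, radius = c(6, 9), hu_mean = -100, hu_sd = 60),
    seed = seed
  )
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_phantom(small_phantom_spec())
    cache
  }
})

# Lungs only, constant parenchyma: geometry tests without HU randomness.
lungs_only_spec <- function(half_axes = c(60, 40, 30), spacing = c(1, 1, 1),
                            dim = c(128L, 96L, 96L), hu_sd = 5) {
  phantom_spec(
    dim = dim, spacing = spacing,
    right_lung = list(center = c(64, 48, 48), half_axes = half_axes),
    left_lung = list(center = c(64, 48, 48), half_axes = c(0, 0, 0)),
    body = list(center = c(48, 48), half_axes = c(46, 46), hu = 40),
    trachea = list(radius = 0, length = 0, center = c(48, 48), hu = -1000),
    emphysema = list(n = 0L, radius = c(5, 8), hu_mean = -960, hu_sd = 15),
    consolidation = list(n = 0L, radius = c(5, 8), hu_mean = -100, hu_sd = 60),
    parenchyma = list(hu_mean = -750, hu_sd = hu_sd),
    seed = 1L
  )
}

# fake volumetry objects for ratio arithmetic
fake_volumetry <- function(per_lobe_ml, unassigned = 0) {
  per_lobe <- tibble::tibble(
    lobe = c(names(per_lobe_ml), "unassigned"),
    flv_ml = c(unname(per_lobe_ml), unassigned)
  )
  structure(
    list(
      per_lobe = per_lobe,
      flv_total_ml = sum(per_lobe$flv_ml),
      tlv_ml = sum(per_lobe$flv_ml) * 1.1,
      resected = character(), resected_flv_ml = 0,
      resected_fraction = 0, mode = "resected-lobe"
    ),
    class = "flv_volumetry"
  )
}

table2_lobe_flv <- c(
  RUL = 844.91, RML = 396.12, RLL = 982.97, LUL = 999.42, LLL = 912.56
)
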