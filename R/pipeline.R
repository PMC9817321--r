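#' Configuration of an end-to-end run
#'
#' Bundles stage toggles, input paths, generator specifications and analysis
#' parameters for [run_pipeline()]. Disabled stages must be covered by
#' paths: segmentation needs a CT (from the simulate stage or `paths$ct`),
#' volumetry needs masks and a lobe map, prediction and agreement need a
#' cohort. Validation runs before any stage executes.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; every stochastic stage draws from a named
#'   sub-stream of it, and it is recorded in the run manifest.
#' @param stages Named logical list over
#'   `simulate`, `segment`, `volumetry`, `predict`, `agree`.
#' @param phantom A [phantom_spec()] for the simulate stage.
#' @param cohort A [cohort_sim_params()] for the simulate stage.
#' @param paths Named list of input paths (`ct`, `lobes`, `cohort`,
#'   `tlv_mask`, `flv_mask`) used when the producing stage is disabled.
#' @param resected Lobe names treated as resected in the volumetry stage.
#' @param tlv_window,flv_window [threshold_window()] overrides.
#' @param min_component_ml Minimum lung-component size for [extract_lungs()].
#' @param coefficients [regression_coefficients()] used by the predict stage.
#' @return A list of class `flv_run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = list(simulate = TRUE, segment = TRUE,
                                     volumetry = TRUE, predict = TRUE,
                                     agree = TRUE),
                       phantom = phantom_spec(),
                       cohort = cohort_sim_params(),
                       paths = list(),
                       resected = "RUL",
                       tlv_window = lungflv::tlv_window(),
                       flv_window = lungflv::flv_window(),
                       min_component_ml = 50,
                       coefficients = regression_coefficients()) {
  config <- structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), stages = stages,
      phantom = phantom, cohort = cohort, paths = paths,
      resected = resected, tlv_window = tlv_window,
      flv_window = flv_window, min_component_ml = min_component_ml,
      coefficients = coefficients
    ),
    class = "flv_run_config"
  )
  validate_run_config(config)
  config
}

validate_run_config <- function(config) {
  st <- config$stages
  need_path <- function(stage, keys) {
    have <- vapply(
      keys,
      function(k) !is.null(config$paths[[k]]) && file.exists(config$paths[[k]]),
      logical(1)
    )
    if (!all(have)) {
      abort(
        sprintf(
          "Stage `%s` is enabled without the `%s` stage; paths required: %s.",
          stage, "simulate/segment", paste(keys[!have], collapse = ", ")
        ),
        class = "lungflv_config_error"
      )
    }
  }
  if (isTRUE(st$segment) && !isTRUE(st$simulate)) need_path("segment", "ct")
  if (isTRUE(st$volumetry) && !isTRUE(st$segment)) {
    need_path("volumetry", c("tlv_mask", "flv_mask"))
  }
  if (isTRUE(st$volumetry) && !isTRUE(st$simulate)) need_path("volumetry", "lobes")
  if ((isTRUE(st$predict) || isTRUE(st$agree)) && !isTRUE(st$simulate)) {
    need_path("predict/agree", "cohort")
  }
  invisible(config)
}

#' Run the phantom-to-agreement pipeline
#'
#' Executes the enabled stages in order (simulate, segment, volumetry,
#' predict, agree), writing every artifact under `config$out_dir` and a
#' `manifest.json` listing all files together with the seed, the config
#' hash and the package version. Identical configurations produce
#' byte-identical CSV/JSON outputs. A stage failure aborts with the stage
#' named; artifacts already written are retained.
#'
#' @param config An [run_config()] object.
#' @return The manifest, invisibly.
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile("run"),
#'   phantom = phantom_spec(dim = c(64, 48, 64), spacing = c(3, 3, 3),
#'     right_lung = list(center = c(96, 72, 52), half_axes = c(60, 40, 30)),
#'     left_lung = list(center = c(96, 72, 140), half_axes = c(60, 40, 30)),
#'     body = list(center = c(72, 96), half_axes = c(66, 92), hu = 40),
#'     trachea = list(radius = 8, length = 40, center = c(72, 96), hu = -1000),
#'     emphysema = list(n = 2L, radius = c(6, 10), hu_mean = -960, hu_sd = 15),
#'     consolidation = list(n = 1L, radius = c(6, 8), hu_mean = -100, hu_sd = 60)),
#'   cohort = cohort_sim_params(n = 30))
#' manifest <- run_pipeline(cfg)
#' manifest$files
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "flv_run_config"))
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(path) {
    files <<- c(files, basename(path))
    path
  }
  out <- function(name) file.path(config$out_dir, name)
  st <- config$stages
  run_stage <- function(stage, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
        class = "lungflv_pipeline_error", parent = e
      )
    })
  }

  ct <- NULL
  lobes <- NULL
  truth <- NULL
  cohort <- NULL
  tlv <- NULL
  flv <- NULL

  if (isTRUE(st$simulate)) {
    run_stage("simulate", {
      spec <- config$phantom
      spec$seed <- substream_seed(config$seed, "phantom")
      phantom <- build_phantom(spec)
      ct <- phantom$ct
      lobes <- phantom$lobes
      truth <- phantom$truth
      write_ct(ct, emit(out("phantom_ct.nii.gz")))
      write_lobe_map(lobes, emit(out("lobe_map.nii.gz")))
      emit(out("lobe_map.labels.json"))
      jsonlite::write_json(
        list(
          per_lobe = truth$per_lobe, airway_ml = truth$airway_ml,
          analytic_lung_ml = as.list(truth$analytic_lung_ml),
          nonfunctional_fraction = truth$nonfunctional_fraction
        ),
        emit(out("ground_truth.json")),
        dataframe = "columns", auto_unbox = TRUE, digits = NA
      )
      params <- config$cohort
      params$seed <- substream_seed(config$seed, "cohort")
      cohort <- simulate_cohort(params)
      write_cohort(cohort, emit(out("cohort.csv")))
    })
  }

  if (isTRUE(st$segment)) {
    run_stage("segment", {
      if (is.null(ct)) ct <- read_ct(config$paths$ct)
      airway <- tryCatch(
        segment_airway(ct),
        lungflv_airway_not_found = function(e) {
          warn(paste("Proceeding with an empty airway:", conditionMessage(e)))
          mask_volume(array(FALSE, dim = dim(ct$voxels)),
            spacing = ct$spacing, origin = ct$origin
          )
        }
      )
      tlv <- extract_lungs(ct, airway,
        window = config$tlv_window,
        min_component_ml = config$min_component_ml
      )
      flv <- functional_mask(ct, tlv, window = config$flv_window)
      write_mask(airway, emit(out("airway_mask.nii.gz")))
      write_mask(tlv, emit(out("tlv_mask.nii.gz")))
      write_mask(flv, emit(out("flv_mask.nii.gz")))
      jsonlite::write_json(
        list(
          airway_ml = mask_volume_ml(airway), tlv_ml = mask_volume_ml(tlv),
          flv_ml = mask_volume_ml(flv),
          tlv_window = unclass(config$tlv_window),
          flv_window = unclass(config$flv_window)
        ),
        emit(out("segmentation.json")),
        auto_unbox = TRUE, digits = NA
      )
    })
  }

  if (isTRUE(st$volumetry)) {
    run_stage("volumetry", {
      if (is.null(tlv)) tlv <- read_mask(config$paths$tlv_mask)
      if (is.null(flv)) flv <- read_mask(config$paths$flv_mask)
      if (is.null(lobes)) lobes <- read_lobe_map(config$paths$lobes)
      volu <- volumetry(tlv, flv, lobes, resected = config$resected)
      jsonlite::write_json(
        list(
          tlv_ml = volu$tlv_ml, flv_total_ml = volu$flv_total_ml,
          per_lobe = volu$per_lobe, resected = volu$resected,
          resected_flv_ml = volu$resected_flv_ml,
          resected_fraction = volu$resected_fraction, mode = volu$mode
        ),
        emit(out("volumetry.json")),
        dataframe = "columns", auto_unbox = TRUE, digits = NA
      )
      readr::write_csv(glance(volu), emit(out("volumetry.csv")), progress = FALSE)
    })
  }

  predictions <- NULL
  if (isTRUE(st$predict)) {
    run_stage("predict", {
      if (is.null(cohort)) cohort <- read_cohort(config$paths$cohort)
      predictions <- predict_cohort(cohort, coefficients = config$coefficients)
      readr::write_csv(predictions, emit(out("predictions.csv")), progress = FALSE)
    })
  }

  if (isTRUE(st$agree)) {
    run_stage("agree", {
      if (is.null(predictions)) {
        if (is.null(cohort)) cohort <- read_cohort(config$paths$cohort)
        predictions <- predict_cohort(cohort, coefficients = config$coefficients)
      }
      report <- compare_methods(predictions)
      write_agreement(report, emit(out("agreement.json")))
    })
  }

  manifest <- list(
    package = "lungflv",
    version = as.character(utils::packageVersion("lungflv")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = config$stages[vapply(config$stages, isTRUE, logical(1))],
    files = files
  )
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest$files <- c(manifest$files, "manifest.json")
  invisible(manifest)
}
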