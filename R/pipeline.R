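# Declarative pipeline: one YAML config describes one run (inputs, model,
# parameters, seed); the driver executes color-field rasterization ->
# warp -> tracking -> aggregation (-> display normalization), caches
# stage outputs and records provenance next to them. One auditable file
# per run is what stereotactic-planning reproducibility demands.

#' Load a run configuration
#'
#' Reads a YAML run description and fills in defaults. Recognized keys:
#' `seed`, `model` (`tend`/`dti`), `n_seeds`, `tracking` (step, noise,
#' max_steps, angle_threshold, fa_floor, interp), `normalize_display`,
#' `gradient` (amplitudes, centers, sigma, shape, resolution -- used when
#' no template color file is given) and `paths` (tensors or dwi+bvals+
#' bvecs, color, warp, tracking_mask, region_mask, out_dir). Relative
#' paths are resolved against the config file's directory.
#'
#' @param path YAML file, or a list with the same structure.
#' @return An object of class `run_config`.
#' @export
run_config <- function(path) {
  if (is.character(path)) {
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    src <- normalizePath(path)
  } else {
    cfg <- path
    base <- getwd()
    src <- NA_character_
  }
  defaults <- list(seed = 1L, model = "tend", n_seeds = 500L,
                   tracking = list(), normalize_display = FALSE,
                   gradient = NULL, paths = list())
  cfg <- modifyList(defaults, cfg)
  if (!cfg$model %in% c("tend", "dti"))
    stop("config model must be 'tend' or 'dti'", call. = FALSE)
  cfg$paths <- lapply(cfg$paths, function(p)
    if (is.character(p) && !p %in% c("identity") &&
        !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p)
  cfg$source <- src
  class(cfg) <- "run_config"
  cfg
}

config_tracking_params <- function(cfg) {
  do.call(tracking_params,
          c(cfg$tracking, list(seed = as.integer(cfg$seed))))
}

#' Execute a full run from a configuration
#'
#' Stages: (1) obtain the template color volume (read it, or rasterize
#' the configured gradient); (2) warp it to subject space through the
#' configured deformation field -- a field is mandatory, `warp: identity`
#' must be stated explicitly; (3) obtain tensors (read, or fit from
#' DWI + bvals/bvecs); (4) track and aggregate over the target region;
#' (5) optionally display-normalize. Stage outputs are written to
#' `out_dir` and reused on re-runs when `cache = TRUE`; a provenance
#' record (config, seed, package version, input digests) is written
#' alongside. Any stage failure halts with the stage name.
#'
#' @param cfg A [run_config()] (or path to one).
#' @param cache Reuse existing stage outputs in `out_dir`.
#' @return Invisibly, a list with the `spectre_map` and the output paths.
#' @export
run_pipeline <- function(cfg, cache = TRUE) {
  if (is.character(cfg) || !inherits(cfg, "run_config"))
    cfg <- run_config(cfg)
  p <- cfg$paths
  if (is.null(p$out_dir)) stop("config needs paths$out_dir", call. = FALSE)
  dir.create(p$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- tensors ---------------------------------------------------------
  tensors <- stage("tensors", {
    if (!is.null(p$tensors)) {
      read_tensor_field(p$tensors)
    } else if (!is.null(p$dwi)) {
      sch <- read_bvals_bvecs(p$bvals, p$bvecs)
      raw <- read_nifti_raw(p$dwi)
      fit_tensors(raw$data, sch$bvals, sch$bvecs, raw$affine)
    } else stop("config needs paths$tensors or paths$dwi")
  })
  if (!is.null(p$tracking_mask)) {
    tm <- stage("tensors", read_mask(p$tracking_mask))
    if (!all(dim(tm) == dim(tensors$mask)))
      stop("pipeline stage 'tensors' failed: tracking mask grid does not ",
           "match the tensor grid", call. = FALSE)
    tensors$mask <- array(tm, dim(tensors$mask))
  }

  # -- template color --------------------------------------------------
  color_t <- stage("colorfield", {
    if (!is.null(p$color)) {
      read_color_volume(p$color, space = "template")
    } else if (!is.null(cfg$gradient)) {
      g <- cfg$gradient
      spec <- gradient_spec(do.call(rbind, g$amplitudes),
                            do.call(rbind, g$centers), g$sigma)
      rasterize_gradient(spec, unlist(g$shape),
                         grid_affine(g$resolution %||% 1,
                                     unlist(g$origin %||% c(0, 0, 0))))
    } else stop("config needs paths$color or a gradient block")
  })

  # -- warp to subject space -------------------------------------------
  color_s_path <- file.path(p$out_dir, "color_subject.nii.gz")
  color_s <- stage("warp", {
    if (is.null(p$warp))
      stop("a deformation field is required (set paths$warp, or ",
           "'identity' to state explicitly that spaces coincide)")
    if (cache && file.exists(color_s_path)) {
      read_color_volume(color_s_path, space = "subject")
    } else {
      warp <- if (identical(p$warp, "identity"))
        identity_deformation(dim(tensors$mask), tensors$affine)
      else read_deformation_field(p$warp)
      cs <- warp_colorvolume(color_t, warp)
      write_volume(cs, color_s_path)
      cs
    }
  })

  # -- track + aggregate -----------------------------------------------
  map_path <- file.path(p$out_dir, "spectre_map.nii.gz")
  map <- stage("spectre", {
    if (is.null(p$region_mask)) stop("config needs paths$region_mask")
    rm <- read_mask(p$region_mask)
    region <- target_region(rm, attr(rm, "affine"))
    if (cache && file.exists(map_path)) {
      read_spectre_map(map_path)
    } else {
      m <- compute_spectre(region, direction_model(tensors, cfg$model),
                           color_s, config_tracking_params(cfg),
                           n_seeds = cfg$n_seeds)
      write_volume(m, map_path)
      m
    }
  })

  display_path <- NULL
  if (isTRUE(cfg$normalize_display)) {
    display_path <- file.path(p$out_dir, "spectre_map_display.nii.gz")
    stage("normalize", {
      disp <- normalize_for_display(map)
      disp$data[!is.finite(disp$data)] <- 0   # display export: absent -> 0
      write_volume(disp, display_path)
    })
  }

  prov_path <- file.path(p$out_dir, "provenance.json")
  inputs <- unlist(p[names(p) != "out_dir"])
  inputs <- inputs[vapply(inputs, function(f)
    is.character(f) && file.exists(f), TRUE)]
  prov <- list(package = "spectre",
               version = as.character(utils::packageVersion("spectre")),
               date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = cfg$seed, model = cfg$model, n_seeds = cfg$n_seeds,
               tracking = config_tracking_params(cfg)[
                 c("step", "noise", "max_steps", "angle_threshold",
                   "fa_floor", "interp")],
               config = cfg$source,
               input_md5 = as.list(tools::md5sum(inputs)),
               output_md5 = as.list(tools::md5sum(
                 c(color_s_path, map_path, display_path))))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  invisible(list(map = map, map_path = map_path,
                 color_path = color_s_path, display_path = display_path,
                 provenance_path = prov_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complete phantom run directory
#'
#' Generates a tensor phantom with a two-end cap color field, an explicit
#' identity deformation, tracking and target-region masks, a manifest TSV
#' and a ready-to-run `config.yaml`, so that `run_pipeline(file.path(dir,
#' "config.yaml"))` exercises the whole pipeline with known ground truth.
#' The target region is a small block of output-grid voxels at the
#' corridor center, at half the phantom voxel size (the super-resolution
#' setting).
#'
#' @param dir Output directory (created if needed).
#' @param spec A [phantom_spec()].
#' @param n_seeds Streamlines per voxel for the generated config.
#' @param noise Tracking noise factor for the generated config.
#' @param region_halfwidth Half-extent (mm) of the target block along the
#'   corridor.
#' @return The config path, invisibly.
#' @export
phantom_fixture <- function(dir, spec = phantom_spec(), n_seeds = 100,
                            noise = 0.1, region_halfwidth = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tf <- make_tensor_phantom(spec)
  write_volume(tf, file.path(dir, "tensors.nii.gz"))
  write_volume(tf$mask, file.path(dir, "tracking_mask.nii.gz"),
               affine = tf$affine)
  write_volume(identity_deformation(spec$shape, tf$affine),
               file.path(dir, "warp_identity.nii.gz"))

  extent <- spec$shape * spec$resolution
  out_res <- spec$resolution / 2
  out_dim <- as.integer(floor(extent / out_res))
  out_affine <- grid_affine(out_res)
  centers <- grid_centers(out_dim, out_affine)
  geo <- corridor_geometry(spec, centers)
  ctr <- (spec$shape - 1) / 2 * spec$resolution + spec$offset
  along_axis <- if (spec$geometry == "straight")
    c(sin(spec$angle * pi / 180), cos(spec$angle * pi / 180), 0)
  else c(0, 1, 0)
  along <- as.vector(sweep(centers, 2L, ctr) %*% along_axis)
  region <- geo$inside & abs(along) <= region_halfwidth
  write_volume(array(region, out_dim),
               file.path(dir, "region_mask.nii.gz"), affine = out_affine)

  cv <- make_cap_colorfield(spec$shape, tf$affine, axis = 2,
                            space = "template")
  write_volume(cv, file.path(dir, "color_template.nii.gz"))

  manifest <- data.frame(
    file = c("tensors.nii.gz", "tracking_mask.nii.gz",
             "warp_identity.nii.gz", "region_mask.nii.gz",
             "color_template.nii.gz"),
    kind = c("tensors", "tracking_mask", "deformation", "region_mask",
             "color_template"))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg <- list(seed = spec$seed, model = "tend",
              n_seeds = as.integer(n_seeds),
              tracking = list(noise = noise, max_steps = 100L),
              normalize_display = TRUE,
              paths = list(tensors = "tensors.nii.gz",
                           tracking_mask = "tracking_mask.nii.gz",
                           warp = "warp_identity.nii.gz",
                           region_mask = "region_mask.nii.gz",
                           color = "color_template.nii.gz",
                           out_dir = file.path(dir, "out")))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

#' @importFrom utils read.table write.table
NULL
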