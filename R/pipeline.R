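pipeline_defaults <- function() {
  list(
    seed = 1L,
    verbose = TRUE,
    preprocess = list(median_kernel = 3L, clahe_clip_limit = 2,
                      clahe_tile_grid = c(8L, 8L), gamma_g = 1.2,
                      apply_kirsch = FALSE),
    od_removal = list(margin = 2, fill = "black", rmin_frac = 0.03,
                      rmax_frac = 0.15, sigma = 1, score_floor = 0.25),
    wssh = list(thresh_frac = 0.2, class = "auto", clip_relu = FALSE,
                suppress_od = TRUE, smooth_sigma = 1.5),
    training = list(epochs = 10L, batch_size = 32L, momentum = 0.9,
                    weight_decay = 1e-4, lr_scale = 1),
    synth = list(image_size = 256L, class_probs = c(0.3, 0.2, 0.2, 0.15, 0.15))
  )
}

merge_checked <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration section expected at: ", full, call. = FALSE)
      defaults[[key]] <- merge_checked(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Nested configuration for the full chain (preprocess, od_removal, wssh,
#' training, synth sections plus the global seed). Unknown keys are
#' rejected with the offending path named, so a typo never silently falls
#' back to a default. Round-trips losslessly through YAML.
#'
#' @param ... named overrides of the defaults (nested lists per section),
#'   or nothing for the default configuration.
#' @param file optional YAML file to read overrides from (explicit `...`
#'   values win over the file).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    cfg <- merge_checked(cfg, yaml::read_yaml(file))
  }
  user <- list(...)
  if (length(user)) cfg <- merge_checked(cfg, user)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` to serialize.
#' @param path output YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

roi_to_list <- function(rois) {
  lapply(rois, function(r)
    list(bbox = r$bbox, peak = r$peak, score = r$score))
}

#' Run the full four-stage chain on a set of images
#'
#' For each image: preprocessing, optic-disc detection and excision,
#' classification, and WSSH localization, writing every stage's artifacts
#' (circle JSON, heat-map PNG, ROI JSON, prediction CSV row) under
#' `out_dir`. A manifest records the configuration and seed so a rerun
#' with identical inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param images character vector of image paths, or a list of RGB
#'   `raster_image`s (named or numbered for the artifact files).
#' @param model a trained `wssh_model` (or a checkpoint path); required --
#'   the run fails before any image is touched when it is missing.
#' @param out_dir output directory.
#' @return data frame with one row per image: predicted class, class
#'   probability, detected circle parameters, ROI count.
#' @export
run_pipeline <- function(config, images, model, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(model) || is.null(model))
    stop("a trained model is required for the localization stage", call. = FALSE)
  if (is.character(model)) model <- load_model(model)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  if (is.character(images)) {
    nms <- tools::file_path_sans_ext(basename(images))
    images <- lapply(images, read_image)
  } else {
    nms <- if (!is.null(names(images))) names(images)
           else sprintf("image_%03d", seq_along(images))
  }
  pc <- do.call(preprocess_config, config$preprocess)
  set.seed(config$seed)
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    nm <- nms[i]
    img <- images[[i]]
    stage <- "preprocess"
    res <- tryCatch({
      pre <- run_preprocess(img, pc)
      stage <- "od_removal"
      d <- dim(pre)
      circ <- tryCatch(
        detect_od(pre,
                  radius_range = c(config$od_removal$rmin_frac,
                                   config$od_removal$rmax_frac) * min(d[1:2]),
                  sigma = config$od_removal$sigma,
                  score_floor = config$od_removal$score_floor),
        fundusWSSH_no_disc = function(e) NULL)
      od <- if (!is.null(circ))
        remove_od(pre, circ, config$od_removal$margin,
                  config$od_removal$fill) else NULL
      stage <- "localize"
      od_arg <- if (isTRUE(config$wssh$suppress_od) && !is.null(od))
        od$mask else "none"
      loc <- localize_lesions(model, img, class_id = config$wssh$class,
                              thresh_frac = config$wssh$thresh_frac,
                              od = od_arg, margin = config$od_removal$margin,
                              smooth_sigma = config$wssh$smooth_sigma,
                              clip_relu = isTRUE(config$wssh$clip_relu))
      cls <- loc$class_id
      heat_up <- loc$heat
      rois <- loc$rois
      # artifacts
      if (!is.null(circ))
        jsonlite::write_json(list(a = circ$center_a, b = circ$center_b,
                                  r = circ$radius_r, score = circ$score),
                             file.path(out_dir, paste0(nm, "_circle.json")),
                             auto_unbox = TRUE, digits = NA)
      hv <- heat_values(heat_up)
      if (max(hv) > min(hv)) hv <- (hv - min(hv)) / (max(hv) - min(hv))
      write_image(raster_image(array(hv * 255, c(dim(hv), 1L)), "GRAY"),
                  file.path(out_dir, paste0(nm, "_heat.png")))
      jsonlite::write_json(roi_to_list(rois),
                           file.path(out_dir, paste0(nm, "_roi.json")),
                           auto_unbox = TRUE, digits = NA)
      data.frame(name = nm, class = model$classes[cls],
                 prob = max(loc$probs),
                 od_a = if (is.null(circ)) NA_real_ else circ$center_a,
                 od_b = if (is.null(circ)) NA_real_ else circ$center_b,
                 od_r = if (is.null(circ)) NA_real_ else circ$radius_r,
                 n_roi = length(rois))
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed on image '", nm, "': ",
           conditionMessage(e), call. = FALSE)
    })
    say(sprintf("[%d/%d] %s -> class %s, %d ROI(s)", i, length(images), nm,
                res$class, res$n_roi))
    rows[[i]] <- res
  }
  predictions <- do.call(rbind, rows)
  utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed, config = unclass(config),
                            n_images = length(images),
                            package_version =
                              as.character(utils::packageVersion("fundusWSSH"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  predictions
}
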