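# File interfaces: slides and masks as PNG, score maps as 16-bit TIFF with a
# JSON sidecar, configurations as YAML.

#' Read a slide image from a PNG or TIFF file
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param downsample downsample factor metadata.
#' @return an [slide_image()].
#' @export
read_slide <- function(path, downsample = 1) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  slide_image(img * 255, downsample = downsample,
              source_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a slide image to PNG
#'
#' @param slide an [slide_image()].
#' @param path output path.
#' @export
write_slide <- function(slide, path) {
  png::writePNG(slide$pixels / 255, path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Pixels above half intensity are foreground.
#'
#' @param path file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write a binary mask as a 0/255 single-channel PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write a score map as 16-bit TIFF plus JSON sidecar
#'
#' Scores are stored as `round(score * 65535)`; grid geometry (origin,
#' stride, downscale, patch size) goes to `<path>.json`.  Cells without a
#' patch are written as 0.
#'
#' @param map a `score_map`.
#' @param path output path (`.tif`).
#' @return the path, invisibly.
#' @export
write_score_map <- function(map, path) {
  m <- unclass(map)
  m[is.na(m)] <- 0
  tiff::writeTIFF(round(m * 65535) / 65535, path, bits.per.sample = 16L)
  sidecar <- list(
    grid_origin = c(0, 0), stride = attr(map, "stride"),
    downscale = attr(map, "downscale"), patch_size = attr(map, "patch_size"),
    slide_dim = attr(map, "slide_dim")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a score map written by [write_score_map()]
#'
#' @param path the `.tif` path.
#' @return a `score_map` matrix with grid attributes restored.
#' @export
read_score_map <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(m, stride = meta$stride, patch_size = meta$patch_size,
            downscale = meta$downscale, slide_dim = meta$slide_dim,
            class = c("score_map", "matrix"))
}

#' Serialize / restore a configuration as YAML
#'
#' @param x a configuration object (`train_config`, `refine_config`,
#'   `noise_spec`, `synthetic_slide_spec`, ...).
#' @param path file path.
#' @export
write_config_yaml <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  if (!is.null(cls)) structure(obj, class = cls) else obj
}

#' Save / load a trained MIL model
#'
#' Serializes parameters, scaler and configuration to one JSON file.
#'
#' @param model a `mil_model`.
#' @param path file path (`.json`).
#' @export
write_mil_model <- function(model, path) {
  obj <- list(
    variant = model$variant, d_f = model$d_f,
    cfg = unclass(model$cfg),
    scaler = model$scaler,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mil_model
#' @export
read_mil_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else unlist(p$data)
  })
  structure(list(
    variant = obj$variant, params = params,
    scaler = list(center = unlist(obj$scaler$center),
                  scale = unlist(obj$scaler$scale)),
    d_f = obj$d_f, cfg = structure(as.list(obj$cfg), class = "train_config"),
    log = NULL
  ), class = "mil_model")
}
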