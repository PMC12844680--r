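# On-disk formats: RGB tiles as 8-bit PNG, multispectral tiles as
# 4-band 32-bit float TIFF, masks as single-band PNG {0, 255},
# manifests as CSV, checkpoints as RDS.

#' Write a multimodal sample to a directory
#'
#' Creates `<id>_rgb.png`, `<id>_ms.tif`, `<id>_mask.png`.
#'
#' @param sample a `multimodal_sample`.
#' @param dir output directory (created if needed).
#' @param id file-name stem; defaults to the sample's metadata id.
#' @return invisibly, the three file paths.
#' @export
write_sample <- function(sample, dir, id = sample$meta$id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rgb = file.path(dir, paste0(id, "_rgb.png")),
             ms = file.path(dir, paste0(id, "_ms.tif")),
             mask = file.path(dir, paste0(id, "_mask.png")))
  png::writePNG(sample$rgb, paths["rgb"])
  tiff::writeTIFF(sample$ms, paths["ms"], bits.per.sample = 32L)
  png::writePNG(sample$mask, paths["mask"])
  invisible(paths)
}

#' Read a multimodal sample written by [write_sample()]
#'
#' @param dir directory holding the files.
#' @param id file-name stem.
#' @return a `multimodal_sample` (metadata limited to the id).
#' @export
read_sample <- function(dir, id) {
  rgb <- png::readPNG(file.path(dir, paste0(id, "_rgb.png")))
  # libtiff flags the 4th reflectance band of an RGB-photometric file
  # as an unexpected extra sample; the values are read back intact
  ms <- suppressWarnings(tiff::readTIFF(file.path(dir,
                                                  paste0(id, "_ms.tif"))))
  mask <- png::readPNG(file.path(dir, paste0(id, "_mask.png")))
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  mask <- (mask > 0.5) * 1
  structure(list(rgb = rgb, ms = ms, mask = mask,
                 meta = list(id = id)),
            class = "multimodal_sample")
}

#' Write / read a dataset manifest CSV
#'
#' @param manifest a data.frame (id, seed, coverage, and optionally
#'   split columns).
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a predicted mask as an 8-bit PNG over \{0, 255\}
#'
#' @param mask (H, W) binary matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0.5), nrow(mask), ncol(mask)),
                path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is an RDS file with the configuration snapshot, the
#' model mode, and all parameter arrays.
#'
#' @param model a model from [build_model()].
#' @param path RDS path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, mode = model$mode,
               state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, ck$mode)
  load_state(model, ck$state)
  model
}
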