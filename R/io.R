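# ---- dataset and model persistence -----------------------------------------
#
# Datasets are written as one flat binary array per item (64-bit doubles,
# column-major, shape recorded in the manifest) plus a JSON manifest holding
# the metadata and a configuration echo.

.cfg_echo <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  out <- unclass(cfg)
  lapply(out, function(v) if (is.data.frame(v)) as.list(v) else v)
}

#' Write / read an EEG segment dataset
#'
#' @param segments list of [eeg_segment()] objects.
#' @param dir output directory (created if missing).
#' @param config optional [sim_config()] echoed into the manifest.
#' @return `write_eeg_dataset` invisibly returns the manifest path;
#'   `read_eeg_dataset` returns the list of segments.
#' @export
write_eeg_dataset <- function(segments, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("segment_%04d.bin", seq_along(segments))
  for (i in seq_along(segments))
    writeBin(as.vector(segments[[i]]$samples), file.path(dir, files[i]))
  manifest <- list(
    format = "spectrogan-eeg-v1",
    files = files,
    n_channels = vapply(segments, function(s) nrow(s$samples), 1L),
    n_samples = vapply(segments, function(s) ncol(s$samples), 1L),
    fs = vapply(segments, function(s) s$fs, 1),
    label = vapply(segments, function(s) s$label, ""),
    subject_id = vapply(segments, function(s) s$subject_id, ""),
    t_start = vapply(segments, function(s) s$t_start, 1),
    channel_names = lapply(segments, function(s) s$channel_names),
    config = .cfg_echo(config))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eeg_dataset
#' @export
read_eeg_dataset <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  if (!identical(m$format, "spectrogan-eeg-v1"))
    stop("not a spectrogan EEG dataset: ", dir)
  lapply(seq_along(m$files), function(i) {
    v <- readBin(file.path(dir, m$files[i]), "double",
                 n = m$n_channels[i] * m$n_samples[i])
    eeg_segment(matrix(v, m$n_channels[i], m$n_samples[i]), fs = m$fs[i],
                label = m$label[i],
                channel_names = unlist(m$channel_names[[i]]),
                subject_id = m$subject_id[i], t_start = m$t_start[i])
  })
}

#' Write / read a spectrogram image dataset
#'
#' @param images list of [spectrogram_image()] objects.
#' @param dir directory.
#' @return `write_image_dataset` invisibly returns the manifest path;
#'   `read_image_dataset` returns the list of images.
#' @export
write_image_dataset <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("image_%05d.bin", seq_along(images))
  for (i in seq_along(images))
    writeBin(as.vector(images[[i]]$pixels), file.path(dir, files[i]))
  manifest <- list(
    format = "spectrogan-img-v1",
    files = files,
    size = vapply(images, function(im) dim(im$pixels)[1], 1L),
    label = vapply(images, function(im) im$label, ""),
    source = vapply(images, function(im) im$source, ""),
    subject_id = vapply(images, function(im) im$subject_id, ""),
    t_start = vapply(images, function(im) im$t_start, 1),
    accepted = vapply(images, function(im) im$accepted, NA))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_dataset
#' @export
read_image_dataset <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  if (!identical(m$format, "spectrogan-img-v1"))
    stop("not a spectrogan image dataset: ", dir)
  lapply(seq_along(m$files), function(i) {
    s <- m$size[i]
    v <- readBin(file.path(dir, m$files[i]), "double", n = s * s * 3)
    spectrogram_image(array(v, c(s, s, 3)), label = m$label[i],
                      source = m$source[i], subject_id = m$subject_id[i],
                      t_start = m$t_start[i], accepted = m$accepted[i])
  })
}

#' Save / load a model checkpoint
#'
#' Models (GAN pairs, CESP, selector) are serialized with their
#' configurations and training state; GAN checkpoints additionally write
#' the per-batch loss history to `loss_history.csv`.
#'
#' @param model a `gan_model`, `cesp_model` or `selector_model`.
#' @param dir checkpoint directory.
#' @return `save_checkpoint` invisibly returns `dir`; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  if (inherits(model, "gan_model"))
    utils::write.csv(model$train_state$history,
                     file.path(dir, "loss_history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) readRDS(file.path(dir, "model.rds"))
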