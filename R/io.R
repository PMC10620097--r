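# File interchange: PNG images, WAV audio (minimal RIFF reader/writer for
# 16-bit PCM and float32), JSON model descriptors, and tidy CSV tables.

#' Read an image signal from PNG
#'
#' @param path PNG file. Values are mapped to \[0, 1\].
#' @return An image [signal()].
#' @export
read_image_signal <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  signal(v, "image")
}

#' Write an image signal to PNG
#'
#' Values are clipped to \[0, 1\] on write.
#'
#' @param sig Image [signal()].
#' @param path Output path.
#' @export
write_image_signal <- function(sig, path) {
  v <- pmin(pmax(sig$values, 0), 1)
  if (dim(v)[3] == 1L) v <- v[, , 1]
  png::writePNG(v, path)
  invisible(path)
}

#' Read a WAV file as an audio signal
#'
#' Minimal RIFF reader supporting mono/stereo 16-bit PCM (format 1) and
#' 32-bit float (format 3); multichannel input is averaged to mono.
#'
#' @param path WAV file.
#' @return An audio [signal()] with the file's sample rate.
#' @export
read_wav_signal <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file",
                                      class = "metamerlab_validation_error")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file",
                                      class = "metamerlab_validation_error")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little",
                         signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little",
                           signed = FALSE),
        rate = readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "raw", size - 8))
    } else if (id == "data") {
      if (is.null(fmt)) stopf("data chunk before fmt chunk",
                              class = "metamerlab_validation_error")
      if (fmt$format == 1L) {
        data <- readBin(con, "integer", size / 2, 2, endian = "little",
                        signed = TRUE) / 32768
      } else if (fmt$format == 3L) {
        data <- readBin(con, "double", size / 4, 4, endian = "little")
      } else stopf("unsupported WAV format code %d", fmt$format,
                   class = "metamerlab_validation_error")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(data)) stopf("no data chunk found",
                           class = "metamerlab_validation_error")
  if (fmt$channels > 1L) {
    data <- colMeans(matrix(data, nrow = fmt$channels))
  }
  signal(data, "audio", sample_rate = fmt$rate)
}

#' Write an audio signal to WAV
#'
#' @param sig Audio [signal()].
#' @param path Output path.
#' @param format `"pcm16"` (values clipped to \[-1, 1\]) or `"float32"`.
#' @export
write_wav_signal <- function(sig, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- sig$values
  rate <- as.integer(sig$sample_rate %||% 20000)
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")               # mono
  writeBin(rate, con, 4, endian = "little")
  writeBin(rate * bytes_per, con, 4, endian = "little") # byte rate
  writeBin(bytes_per, con, 2, endian = "little")        # block align
  writeBin(8L * bytes_per, con, 2, endian = "little")   # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(pmin(pmax(x, -1), 1) * 32767)), con, 2,
             endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}

#' JSON descriptor of a staged model
#'
#' Writes the model's metadata (stage names, modality, input shape, class
#' vocabulary, preprocessing) as JSON; weights are not serialized.
#'
#' @param model A `staged_model`.
#' @param path Output path (optional; when `NULL` the JSON string is
#'   returned).
#' @export
write_model_descriptor <- function(model, path = NULL) {
  desc <- list(modality = model$modality, stage_names = stage_names(model),
               input_shape = model$input_shape,
               sample_rate = model$sample_rate,
               classifier_labels = model$classifier_labels,
               preprocessing = model$preprocessing,
               variant = model$variant, seed = model$seed)
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
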