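#' Write a multichannel image as multipage TIFF with a JSON sidecar
#'
#' One TIFF page per channel. TIFF storage is normalised to [0, 1], so the
#' per-image intensity scale, channel names and pixel size are recorded in a
#' sidecar JSON (`<path>.json`) and restored on read.
#'
#' @param image H x W x C array.
#' @param path output TIFF path.
#' @param channel_names length-C character vector.
#' @param pixel_size microns per pixel.
#' @return `path`, invisibly.
#' @export
write_ms_tiff <- function(image, path, channel_names = NULL,
                          pixel_size = DEFAULT_PIXEL_SIZE) {
  stopifnot(length(dim(image)) == 3)
  C <- dim(image)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  scale <- max(image, 1e-12)
  pages <- lapply(seq_len(C), function(k) image[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(channel_names = channel_names, pixel_size_um = pixel_size,
                  intensity_scale = scale, shape = dim(image))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel TIFF written by [write_ms_tiff()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar next to it).
#' @return H x W x C array with attributes `channel_names` and `pixel_size`.
#' @export
read_ms_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("sidecar JSON not found: ", sidecar_path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  img <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    img[, , k] <- pg * sc$intensity_scale
  }
  dimnames(img) <- list(NULL, NULL, sc$channel_names)
  attr(img, "channel_names") <- sc$channel_names
  attr(img, "pixel_size") <- sc$pixel_size_um
  img
}

#' Serialize a spectral library to CSV
#'
#' Rows are acquisition channels, columns are components, header row carries
#' the component names.
#'
#' @param library a [spectral_library()].
#' @param path output CSV path.
#' @export
write_spectral_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  write.csv(as.data.frame(library$matrix), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectral_library
#' @export
read_spectral_library <- function(path) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  spectral_library(m, colnames(m))
}

#' Serialize a marker panel to YAML
#'
#' @param panel a [marker_panel()].
#' @param path output YAML path.
#' @export
write_panel_yaml <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  entries <- lapply(seq_len(nrow(panel)), function(i) as.list(panel[i, ]))
  yaml::write_yaml(list(markers = entries), path)
  invisible(path)
}

#' @rdname write_panel_yaml
#' @export
read_panel_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers)) stop("panel YAML lacks a 'markers' list",
                               call. = FALSE)
  df <- do.call(rbind, lapply(y$markers, function(e) {
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
  marker_panel(markers = df$marker, fluorophores = df$fluorophore,
               primary_compartment = df$primary_compartment,
               p1 = as.numeric(df$p1), p99 = as.numeric(df$p99),
               threshold = as.numeric(df$threshold))
}
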