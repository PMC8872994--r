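#' Spectral library objects
#'
#' A spectral library holds the unit-normalised emission signature of each
#' fluorophore (plus DAPI and tissue autofluorescence) across the acquisition
#' channels. It is the design matrix of linear spectral unmixing: one column
#' per component, one row per channel.
#'
#' @param matrix numeric matrix, channels x components, all entries >= 0.
#' @param component_names character vector naming the columns.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(matrix, component_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (is.null(component_names)) {
    stop("component_names are required", call. = FALSE)
  }
  if (length(component_names) != ncol(matrix)) {
    stop("component_names must match the number of columns", call. = FALSE)
  }
  if (any(matrix < 0)) stop("spectra must be non-negative", call. = FALSE)
  if (any(colSums(matrix) <= 0)) {
    stop("every spectrum must have positive total emission", call. = FALSE)
  }
  matrix <- sweep(matrix, 2, colSums(matrix), "/")
  if (qr(matrix)$rank < ncol(matrix)) {
    stop("spectral library is rank-deficient: components are not ",
         "linearly independent in the given channels", call. = FALSE)
  }
  colnames(matrix) <- component_names
  structure(list(matrix = matrix, component_names = component_names),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("Spectral library: %d channels x %d components (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$component_names, collapse = ", ")))
  invisible(x)
}

#' Build a default synthetic spectral library
#'
#' Generates emission signatures for the six marker fluorophores, DAPI and a
#' broad autofluorescence component as Gaussian emission peaks spread across
#' the acquisition channels, with seeded jitter in peak position and width.
#' Autofluorescence is deliberately broad and flat, as intrinsic tissue
#' fluorescence is spectrally diffuse.
#'
#' @param n_channels number of acquisition channels (>= 8 so that the eight
#'   components can be linearly independent).
#' @param seed integer seed; the same seed yields the identical library.
#' @return A [spectral_library()] with components
#'   `CD8, CD68, CD3, FOXP3, CD56, PD1, DAPI, AF`.
#' @examples
#' lib <- default_spectral_library(n_channels = 10, seed = 1)
#' colSums(lib$matrix)  # each spectrum sums to 1
#' @export
default_spectral_library <- function(n_channels = 10, seed = 1) {
  comps <- c(MARKER_NAMES, "DAPI", "AF")
  if (n_channels < length(comps)) {
    stop(sprintf(
      "n_channels = %d is too small: %d spectral components cannot be linearly independent in fewer channels",
      n_channels, length(comps)), call. = FALSE)
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  ch <- seq_len(n_channels)
  n_peaked <- length(comps) - 1L
  centers <- seq(1, n_channels, length.out = n_peaked) +
    runif(n_peaked, -0.25, 0.25)
  widths <- runif(n_peaked, 0.7, 1.1)
  m <- sapply(seq_len(n_peaked), function(i) {
    exp(-((ch - centers[i])^2) / (2 * widths[i]^2))
  })
  af <- 0.6 + 0.4 * exp(-((ch - n_channels / 2)^2) / (2 * (n_channels / 2)^2)) +
    runif(n_channels, 0, 0.05)
  m <- cbind(m, af)
  spectral_library(m, comps)
}

#' Extract a fluorophore spectrum from a single-stain reference image
#'
#' Averages the spectra of the brightest pixels (by total channel sum) of a
#' single-stain slide, optionally subtracting the mean spectrum of a
#' background (unstained) image per channel, floors at zero and
#' unit-normalises. This is how a spectral library is assembled from
#' single-stain, DAPI-only and unstained library slides.
#'
#' @param reference_image H x W x C array of non-negative intensities.
#' @param background_image optional H x W x C array whose mean spectrum is
#'   subtracted channel-wise (e.g. an unstained autofluorescence slide).
#' @param top_fraction proportion of brightest pixels to average (default
#'   0.05).
#' @return numeric vector of length C summing to 1.
#' @export
extract_spectrum <- function(reference_image, background_image = NULL,
                             top_fraction = 0.05) {
  stopifnot(length(dim(reference_image)) == 3, top_fraction > 0,
            top_fraction <= 1)
  d <- dim(reference_image)
  px <- matrix(reference_image, nrow = d[1] * d[2], ncol = d[3])
  total <- rowSums(px)
  if (max(total) <= 0) {
    stop("degenerate reference: image has no positive signal", call. = FALSE)
  }
  n_top <- max(1L, ceiling(top_fraction * nrow(px)))
  idx <- order(total, decreasing = TRUE)[seq_len(n_top)]
  spec <- colMeans(px[idx, , drop = FALSE])
  if (!is.null(background_image)) {
    bd <- dim(background_image)
    if (!identical(bd[3], d[3])) {
      stop("background image channel count differs from reference",
           call. = FALSE)
    }
    bg <- colMeans(matrix(background_image, ncol = bd[3]))
    spec <- pmax(spec - bg, 0)
  }
  if (sum(spec) <= 0) {
    stop("degenerate spectrum: background subtraction removed all signal",
         call. = FALSE)
  }
  spec / sum(spec)
}

# Seeded-RNG helper: sets the seed and returns a restorer for the caller's
# RNG state, so library/image generation never perturbs the session stream.
.Random.seed_guard <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  prev <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(prev)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", prev, envir = globalenv())
    }
  }
}
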