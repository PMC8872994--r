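#' Linear spectral unmixing of a multispectral image
#'
#' Decomposes each pixel's observed channel spectrum into non-negative
#' abundances of the library components (fluorophores, DAPI and
#' autofluorescence) by per-pixel non-negative least squares. Component
#' quantities are physical abundances, so the non-negativity constraint is the
#' default; an unconstrained ordinary-least-squares mode is available for
#' numerical comparisons.
#'
#' @param image H x W x C array of intensities.
#' @param library a [spectral_library()] with C rows.
#' @param nonneg constrain abundances to be >= 0 (default TRUE).
#' @return list with `planes` (H x W x F abundance array, component names on
#'   the third dimension) and `residual_rms` (root-mean-square reconstruction
#'   residual over all pixels and channels).
#' @examples
#' lib <- default_spectral_library(10, seed = 1)
#' px <- array(lib$matrix[, "CD8"], dim = c(1, 1, 10))
#' unmix_pixelwise(px, lib)$planes[1, 1, "CD8"]  # 1
#' @export
unmix_pixelwise <- function(image, library, nonneg = TRUE) {
  stopifnot(inherits(library, "spectral_library"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != nrow(library$matrix)) {
    stop(sprintf("image has %s channels but the library expects %d",
                 if (length(d) == 3) d[3] else "?", nrow(library$matrix)),
         call. = FALSE)
  }
  A <- library$matrix
  Y <- t(matrix(image, nrow = d[1] * d[2], ncol = d[3]))  # C x npx
  X <- if (nonneg) {
    nnls_multi(A, Y)
  } else {
    solve(crossprod(A), crossprod(A, Y))
  }
  resid <- Y - A %*% X
  planes <- array(t(X), dim = c(d[1], d[2], ncol(A)),
                  dimnames = list(NULL, NULL, library$component_names))
  list(planes = planes, residual_rms = sqrt(mean(resid^2)))
}

#' Stitch a grid of multispectral tiles into one image
#'
#' Row-major abutting concatenation (no blending, no overlap model), as used
#' to assemble the multispectral tiles of one scanned region.
#'
#' @param tiles list of H x W x C arrays in row-major order.
#' @param layout integer (rows, cols) of the tile grid.
#' @return single H_total x W_total x C array.
#' @export
stitch_tiles <- function(tiles, layout) {
  stopifnot(length(layout) == 2)
  nr <- layout[1]; nc <- layout[2]
  if (length(tiles) != nr * nc) {
    stop("tile grid is not fully populated", call. = FALSE)
  }
  dims <- lapply(tiles, dim)
  C <- dims[[1]][3]
  if (any(vapply(dims, function(d) length(d) != 3 || d[3] != C, logical(1)))) {
    stop("all tiles must share the same channel count", call. = FALSE)
  }
  rows_out <- vector("list", nr)
  for (i in seq_len(nr)) {
    row_tiles <- tiles[((i - 1) * nc + 1):(i * nc)]
    hs <- vapply(row_tiles, function(t) dim(t)[1], integer(1))
    if (length(unique(hs)) != 1) {
      stop(sprintf("ragged tile heights in grid row %d", i), call. = FALSE)
    }
    rows_out[[i]] <- row_tiles
  }
  ws <- vapply(seq_len(nc), function(j) dim(tiles[[j]])[2], integer(1))
  for (i in seq_len(nr)) {
    wsi <- vapply(rows_out[[i]], function(t) dim(t)[2], integer(1))
    if (!identical(wsi, ws)) {
      stop(sprintf("ragged tile widths in grid column (row %d)", i),
           call. = FALSE)
    }
  }
  H <- sum(vapply(seq_len(nr), function(i) dim(rows_out[[i]][[1]])[1],
                  integer(1)))
  W <- sum(ws)
  out <- array(0, dim = c(H, W, C))
  r_off <- 0L
  for (i in seq_len(nr)) {
    c_off <- 0L
    h <- dim(rows_out[[i]][[1]])[1]
    for (j in seq_len(nc)) {
      w <- ws[j]
      out[(r_off + 1):(r_off + h), (c_off + 1):(c_off + w), ] <-
        rows_out[[i]][[j]]
      c_off <- c_off + w
    }
    r_off <- r_off + h
  }
  out
}

#' Randomly sample non-overlapping regions of interest
#'
#' Samples up to `n_max` non-overlapping axis-aligned rectangles from a
#' low-resolution overview, uniformly among candidate positions; when a
#' foreground (tissue) mask is given, a candidate is admissible only if at
#' least half of its area lies inside the mask. Seeded and deterministic.
#'
#' @param overview_shape integer (H, W) of the overview image.
#' @param roi_shape integer (h, w) of each ROI.
#' @param n_max maximum number of ROIs (>= 1); fewer are returned when no
#'   more non-overlapping admissible positions are found.
#' @param mask optional logical H x W matrix of tissue foreground.
#' @param seed integer seed.
#' @param max_tries sampling attempts.
#' @return data.frame with columns `roi_id, row0, col0, h, w` (1-based
#'   top-left corners).
#' @export
sample_rois <- function(overview_shape, roi_shape, n_max = 10, mask = NULL,
                        seed = 1, max_tries = 5000) {
  stopifnot(length(overview_shape) == 2, length(roi_shape) == 2)
  if (n_max < 1) stop("n_max must be >= 1", call. = FALSE)
  h <- roi_shape[1]; w <- roi_shape[2]
  if (h > overview_shape[1] || w > overview_shape[2]) {
    stop("ROI larger than the overview image", call. = FALSE)
  }
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), as.integer(overview_shape)) ||
                identical(dim(mask), overview_shape))
    cs <- .integral_image(mask)
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  picked <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(picked) < n_max && tries < max_tries) {
    tries <- tries + 1L
    r0 <- sample.int(overview_shape[1] - h + 1L, 1L)
    c0 <- sample.int(overview_shape[2] - w + 1L, 1L)
    if (!is.null(mask)) {
      inside <- .box_sum(cs, r0, c0, h, w)
      if (inside < 0.5 * h * w) next
    }
    if (nrow(picked) > 0) {
      overlap <- abs(picked[, 1] - r0) < h & abs(picked[, 2] - c0) < w
      if (any(overlap)) next
    }
    picked <- rbind(picked, c(r0, c0))
  }
  data.frame(roi_id = seq_len(nrow(picked)),
             row0 = as.integer(picked[, 1]), col0 = as.integer(picked[, 2]),
             h = h, w = w)
}

.integral_image <- function(mask) {
  apply(apply(mask * 1, 2, cumsum), 1, cumsum)  # transposed cumulative sums
}

.box_sum <- function(cs, r0, c0, h, w) {
  # cs is transposed (col x row) from .integral_image
  r1 <- r0 + h - 1L; c1 <- c0 + w - 1L
  s <- cs[c1, r1]
  if (r0 > 1) s <- s - cs[c1, r0 - 1L]
  if (c0 > 1) s <- s - cs[c0 - 1L, r1]
  if (r0 > 1 && c0 > 1) s <- s + cs[c0 - 1L, r0 - 1L]
  s
}
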