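#' Place non-overlapping ground-truth cells on a synthetic tissue scene
#'
#' Samples cell centroids by rejection so that no two nuclei overlap (with a
#' configurable gap) and every cell, including its cytoplasm ring, lies fully
#' inside the image. Each cell is assigned a phenotype by independent draws
#' from per-marker prevalences, and a per-marker expression level.
#'
#' @param n number of cells.
#' @param shape integer (H, W) in pixels.
#' @param pixel_size microns per pixel.
#' @param radius_um nucleus radius in microns (default 4).
#' @param prevalence named vector of per-marker positivity probabilities;
#'   defaults to 0.2 for each of the six panel markers.
#' @param expression_level mean abundance of an expressed marker (default 1).
#' @param min_gap_px minimum pixel gap between nucleus borders (default 2).
#' @param max_tries placement attempts per cell before failing.
#' @param seed integer seed.
#' @return data.frame with `cell_id`, `row`, `col`, `radius_um` and, per
#'   marker, a logical `<marker>_pos` and numeric `<marker>_level` column.
#' @export
place_cells <- function(n, shape, pixel_size = DEFAULT_PIXEL_SIZE,
                        radius_um = 4,
                        prevalence = setNames(rep(0.2, 6), MARKER_NAMES),
                        expression_level = 1, min_gap_px = 2,
                        max_tries = 2000, seed = 1) {
  stopifnot(n >= 0, length(shape) == 2, pixel_size > 0, radius_um > 0)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  r_px <- radius_um / pixel_size
  margin <- ceiling(r_px + DEFAULT_EXPANSION_UM / pixel_size) + 1
  if (2 * margin >= min(shape)) {
    stop("image too small for the requested cell radius", call. = FALSE)
  }
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r0 <- runif(1, margin + 1, shape[1] - margin)
      c0 <- runif(1, margin + 1, shape[2] - margin)
      if (placed == 0L ||
          all((rows[seq_len(placed)] - r0)^2 + (cols[seq_len(placed)] - c0)^2 >
              (2 * r_px + min_gap_px)^2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "placement error: could not place cell %d of %d without nucleus overlap after %d tries",
        placed + 1L, n, max_tries), call. = FALSE)
    }
    placed <- placed + 1L
    rows[placed] <- r0; cols[placed] <- c0
  }
  cells <- data.frame(cell_id = seq_len(n), row = rows, col = cols,
                      radius_um = rep(radius_um, n))
  for (m in names(prevalence)) {
    pos <- runif(n) < prevalence[[m]]
    cells[[paste0(m, "_pos")]] <- pos
    cells[[paste0(m, "_level")]] <- ifelse(pos, expression_level, 0)
  }
  cells
}

#' Render a multispectral tissue image from ground-truth cells
#'
#' Composes per-component abundance maps (DAPI on nucleus disks, each
#' expressed marker on its primary compartment: the nucleus disk or a ring of
#' configurable width around it, and a spatially uniform autofluorescence
#' plane), mixes them through the spectral library, adds zero-mean Gaussian
#' channel noise and clips at zero. The returned truth table lists every
#' rendered cell with its phenotype, so downstream unmixing, segmentation and
#' scoring can be validated against known ground truth.
#'
#' @param cells data.frame as returned by [place_cells()].
#' @param library a [spectral_library()] whose components include `DAPI`,
#'   `AF` and every marker named in `compartments`.
#' @param shape integer (H, W).
#' @param pixel_size microns per pixel (default 0.496).
#' @param compartments named character vector mapping each marker to
#'   `"ring"` or `"nucleus"`; defaults to `"ring"` for all six markers
#'   (cytoplasmic/membranous staining).
#' @param ring_um ring (cytoplasm) width in microns, default 2.
#' @param dapi_level DAPI abundance on nucleus pixels.
#' @param autofluorescence_level uniform autofluorescence abundance.
#' @param noise_sd standard deviation of additive channel noise.
#' @param seed integer seed (noise only).
#' @return list with `image` (H x W x C array), `abundance`
#'   (H x W x F array of true component abundances) and `truth` (the cells
#'   table).
#' @export
render_tissue_image <- function(cells, library, shape,
                                pixel_size = DEFAULT_PIXEL_SIZE,
                                compartments = setNames(
                                  rep("ring", 6), MARKER_NAMES),
                                ring_um = DEFAULT_EXPANSION_UM,
                                dapi_level = 1,
                                autofluorescence_level = 0.1,
                                noise_sd = 0, seed = 1) {
  stopifnot(inherits(library, "spectral_library"), pixel_size > 0)
  A <- library$matrix
  comps <- library$component_names
  if (!all(c("DAPI", "AF") %in% comps)) {
    stop("library must contain DAPI and AF components", call. = FALSE)
  }
  H <- shape[1]; W <- shape[2]
  F_ <- length(comps)
  abund <- array(0, dim = c(H, W, F_), dimnames = list(NULL, NULL, comps))
  abund[, , "AF"] <- autofluorescence_level

  ring_px <- round(ring_um / pixel_size)
  if (nrow(cells) > 0) {
    if (any(cells$row < 1 | cells$row > H | cells$col < 1 | cells$col > W)) {
      stop("cells must lie inside the image", call. = FALSE)
    }
    for (i in seq_len(nrow(cells))) {
      r0 <- cells$row[i]; c0 <- cells$col[i]
      r_px <- cells$radius_um[i] / pixel_size
      ext <- ceiling(r_px + ring_px)
      rr <- max(1, floor(r0 - ext)):min(H, ceiling(r0 + ext))
      cc <- max(1, floor(c0 - ext)):min(W, ceiling(c0 + ext))
      d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
      nuc <- d2 <= r_px^2
      ring <- d2 <= (r_px + ring_px)^2 & !nuc
      plane <- abund[rr, cc, "DAPI"]
      plane[nuc] <- plane[nuc] + dapi_level
      abund[rr, cc, "DAPI"] <- plane
      for (m in names(compartments)) {
        lev <- cells[[paste0(m, "_level")]][i]
        if (is.null(lev) || lev <= 0) next
        mask <- if (compartments[[m]] == "nucleus") nuc else ring
        plane <- abund[rr, cc, m]
        plane[mask] <- plane[mask] + lev
        abund[rr, cc, m] <- plane
      }
    }
  }
  Y <- matrix(abund, nrow = H * W, ncol = F_) %*% t(A)
  if (noise_sd > 0) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    Y <- Y + rnorm(length(Y), sd = noise_sd)
    Y[Y < 0] <- 0
  }
  img <- array(Y, dim = c(H, W, nrow(A)))
  list(image = img, abundance = abund, truth = cells)
}
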