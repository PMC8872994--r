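#' Segment nuclei from a DAPI component image
#'
#' Thresholds the DAPI abundance plane (Otsu by default), splits touching
#' blobs by a distance-transform watershed, discards components smaller than
#' `min_area_um2` and relabels the survivors 1..N. A blank plane yields an
#' empty labelling, not an error.
#'
#' @param dapi_plane H x W matrix of non-negative DAPI abundances.
#' @param pixel_size microns per pixel.
#' @param min_area_um2 minimum nucleus area in square microns (default 7,
#'   suppressing sub-nuclear debris).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity cut-off when `threshold_method = "fixed"`.
#' @return integer H x W label matrix (0 = background) with attribute
#'   `pixel_size`.
#' @export
segment_nuclei <- function(dapi_plane, pixel_size = DEFAULT_PIXEL_SIZE,
                           min_area_um2 = 7,
                           threshold_method = c("otsu", "fixed"),
                           fixed_threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(dapi_plane), pixel_size > 0, min_area_um2 > 0)
  if (any(dapi_plane < 0)) stop("DAPI plane must be non-negative",
                                call. = FALSE)
  mx <- max(dapi_plane)
  empty <- matrix(0L, nrow(dapi_plane), ncol(dapi_plane))
  attr(empty, "pixel_size") <- pixel_size
  if (threshold_method == "otsu") {
    if (mx <= 0) return(empty)
    th <- EBImage::otsu(dapi_plane / mx, range = c(0, 1)) * mx
  } else {
    if (is.null(fixed_threshold)) {
      stop("fixed_threshold required for threshold_method = 'fixed'",
           call. = FALSE)
    }
    th <- fixed_threshold
  }
  mask <- dapi_plane > th
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  min_px <- min_area_um2 / pixel_size^2
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_px)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- relab[labels[nz]]
  attr(out, "pixel_size") <- pixel_size
  out
}

# round-half-up metric-to-pixel conversion (2 um at 0.496 um/px -> 4 px)
.round_half_up <- function(x) floor(x + 0.5)

#' Expand nuclei into cytoplasm rings
#'
#' Simulates the cytoplasm of each cell as a band of fixed metric width
#' around its nucleus: every background pixel within
#' `round(expansion_um / pixel_size)` pixels of a nucleus is assigned to it;
#' pixels within reach of two nuclei go to the one with the nearer centroid,
#' ties to the lower label. The resulting ring label map is disjoint from the
#' nucleus map and partitions contested territory uniquely.
#'
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param pixel_size microns per pixel; defaults to the `pixel_size`
#'   attribute of `nuclei`.
#' @param expansion_um ring width in microns (default 2).
#' @return integer label matrix of ring pixels (0 elsewhere), attribute
#'   `pixel_size`.
#' @export
expand_cytoplasm <- function(nuclei, pixel_size = attr(nuclei, "pixel_size"),
                             expansion_um = DEFAULT_EXPANSION_UM) {
  stopifnot(expansion_um > 0, !is.null(pixel_size))
  n_px <- .round_half_up(expansion_um / pixel_size)
  H <- nrow(nuclei); W <- ncol(nuclei)
  rings <- matrix(0L, H, W)
  n_cells <- max(nuclei)
  if (n_cells == 0 || n_px == 0) {
    attr(rings, "pixel_size") <- pixel_size
    return(rings)
  }
  best_d <- matrix(Inf, H, W)
  cell_px <- split(which(nuclei > 0), nuclei[nuclei > 0])
  for (k in seq_len(n_cells)) {
    px <- cell_px[[as.character(k)]]
    if (is.null(px)) next
    pr <- ((px - 1) %% H) + 1
    pc <- ((px - 1) %/% H) + 1
    cen_r <- mean(pr); cen_c <- mean(pc)
    r_lo <- max(1L, min(pr) - n_px); r_hi <- min(H, max(pr) + n_px)
    c_lo <- max(1L, min(pc) - n_px); c_hi <- min(W, max(pc) + n_px)
    crop_mask <- nuclei[r_lo:r_hi, c_lo:c_hi] == k
    # distance of every crop pixel to this cell's nucleus pixels
    dm <- EBImage::imageData(EBImage::distmap(!crop_mask))
    cand <- which(dm > 0 & dm <= n_px &
                    nuclei[r_lo:r_hi, c_lo:c_hi] == 0L)
    if (length(cand) == 0) next
    ch <- r_hi - r_lo + 1L
    cr <- r_lo - 1L + ((cand - 1) %% ch) + 1
    cc_ <- c_lo - 1L + ((cand - 1) %/% ch) + 1
    d_cen <- sqrt((cr - cen_r)^2 + (cc_ - cen_c)^2)
    gidx <- cr + (cc_ - 1L) * H
    take <- d_cen < best_d[gidx] - 1e-9
    gidx <- gidx[take]
    rings[gidx] <- k
    best_d[gidx] <- d_cen[take]
  }
  attr(rings, "pixel_size") <- pixel_size
  rings
}

#' Per-cell, per-compartment intensity statistics
#'
#' For every segmented cell and every component plane, computes the mean,
#' minimum, maximum and standard deviation of intensity over the nucleus and
#' over the cytoplasm-ring pixels, together with centroids and compartment
#' areas in square microns. Cells whose ring is fully clipped keep their
#' record with ring statistics set to `NA`.
#'
#' @param components H x W x F abundance array with component names on the
#'   third dimension (from [unmix_pixelwise()]).
#' @param nuclei nucleus label matrix.
#' @param rings ring label matrix from [expand_cytoplasm()].
#' @param pixel_size microns per pixel.
#' @param markers which component planes to measure; defaults to all planes
#'   except `DAPI` and `AF`.
#' @return data.frame, one row per cell, with columns `cell_id, row, col,
#'   nucleus_area_um2, ring_area_um2` and `<marker>_<compartment>_<stat>` for
#'   stat in mean, min, max, sd.
#' @export
compute_cell_stats <- function(components, nuclei, rings,
                               pixel_size = attr(nuclei, "pixel_size"),
                               markers = NULL) {
  stopifnot(length(dim(components)) == 3, !is.null(pixel_size))
  comp_names <- dimnames(components)[[3]]
  if (is.null(markers)) markers <- setdiff(comp_names, c("DAPI", "AF"))
  if (!all(markers %in% comp_names)) {
    stop("markers absent from component stack: ",
         paste(setdiff(markers, comp_names), collapse = ", "), call. = FALSE)
  }
  if (!identical(dim(nuclei), dim(components)[1:2]) ||
      !identical(dim(rings), dim(components)[1:2])) {
    stop("label maps and component planes must share shape", call. = FALSE)
  }
  n_cells <- max(nuclei)
  if (n_cells == 0) {
    return(data.frame(cell_id = integer(0)))
  }
  H <- nrow(nuclei)
  nuc_px <- split(which(nuclei > 0), factor(nuclei[nuclei > 0],
                                            levels = seq_len(n_cells)))
  ring_px <- split(which(rings > 0), factor(rings[rings > 0],
                                            levels = seq_len(n_cells)))
  out <- data.frame(cell_id = seq_len(n_cells))
  out$row <- vapply(nuc_px, function(p) mean(((p - 1) %% H) + 1), numeric(1))
  out$col <- vapply(nuc_px, function(p) mean(((p - 1) %/% H) + 1), numeric(1))
  out$nucleus_area_um2 <- lengths(nuc_px) * pixel_size^2
  out$ring_area_um2 <- lengths(ring_px) * pixel_size^2

  stat_fns <- list(mean = mean, min = min, max = max,
                   sd = function(v) if (length(v) > 1) sd(v) else 0)
  for (m in markers) {
    plane <- components[, , m]
    for (comp in c("nucleus", "ring")) {
      px <- if (comp == "nucleus") nuc_px else ring_px
      vals <- lapply(px, function(p) plane[p])
      for (s in names(stat_fns)) {
        col <- paste(m, comp, s, sep = "_")
        out[[col]] <- vapply(vals, function(v) {
          if (length(v) == 0) NA_real_ else stat_fns[[s]](v)
        }, numeric(1))
      }
    }
  }
  out
}
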