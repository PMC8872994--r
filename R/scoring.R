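#' Marker panel definition
#'
#' A marker panel fixes, for each marker, its fluorophore, the primary
#' compartment in which positivity is assessed, the dataset-wide rescale
#' bounds (1st and 99th intensity percentiles) and a single normalized
#' positivity threshold. Thresholds are dataset-global: one per marker,
#' applied identically to every image so that the same intensity means the
#' same thing everywhere.
#'
#' @param markers character vector of marker names.
#' @param fluorophores character vector of fluorophore labels (defaults to
#'   the marker names, as in the synthetic library).
#' @param primary_compartment `"ring"` (cytoplasmic/membranous) or
#'   `"nucleus"`, recycled.
#' @param p1,p99 rescale bounds (may be NA until fitted).
#' @param threshold normalized threshold in (0, 1), recycled.
#' @return data.frame of class `marker_panel`.
#' @export
marker_panel <- function(markers = MARKER_NAMES,
                         fluorophores = markers,
                         primary_compartment = "ring",
                         p1 = NA_real_, p99 = NA_real_,
                         threshold = 0.3) {
  if (anyDuplicated(markers)) {
    stop("duplicate marker names in panel", call. = FALSE)
  }
  if (!all(primary_compartment %in% c("ring", "nucleus"))) {
    stop("primary_compartment must be 'ring' or 'nucleus'", call. = FALSE)
  }
  if (any(!is.na(threshold) & (threshold <= 0 | threshold >= 1))) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  panel <- data.frame(marker = markers, fluorophore = fluorophores,
                      primary_compartment = primary_compartment,
                      p1 = p1, p99 = p99, threshold = threshold,
                      stringsAsFactors = FALSE)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Fit dataset-wide percentile rescale bounds
#'
#' Computes each marker's 1st and 99th empirical percentiles
#' (linear-interpolation definition) over values pooled across the full
#' dataset, and stores them in the panel. Rescaling every image with the same
#' bounds guarantees that equal intensities are displayed and thresholded
#' identically in all images.
#'
#' @param panel a [marker_panel()].
#' @param intensities named list: per marker, the pooled intensity values
#'   (by default per-cell primary-compartment means across all ROIs; pass
#'   pooled pixel values of the component planes for a literal pixel-based
#'   definition).
#' @param min_n minimum pooled values per marker (default 100).
#' @return the panel with `p1`, `p99` filled in.
#' @export
fit_rescale_bounds <- function(panel, intensities, min_n = 100) {
  stopifnot(inherits(panel, "marker_panel"))
  for (i in seq_len(nrow(panel))) {
    m <- panel$marker[i]
    v <- intensities[[m]]
    if (is.null(v)) stop("no intensities supplied for marker ", m,
                         call. = FALSE)
    v <- v[!is.na(v)]
    if (length(v) < min_n) {
      stop(sprintf("marker %s has %d values; >= %d required", m, length(v),
                   min_n), call. = FALSE)
    }
    q <- quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
    if (q[1] >= q[2]) {
      stop(sprintf("degenerate marker %s: 1st and 99th percentiles coincide",
                   m), call. = FALSE)
    }
    panel$p1[i] <- q[1]
    panel$p99[i] <- q[2]
  }
  panel
}

#' Rescale raw intensity to the [0, 1] percentile range
#'
#' Maps `p1 -> 0` and `p99 -> 1` linearly and clips outside values.
#'
#' @param x raw intensity (vectorised).
#' @param p1,p99 the fitted bounds, `p1 < p99`.
#' @return values in `[0, 1]`.
#' @export
rescale_intensity <- function(x, p1, p99) {
  if (!(p1 < p99)) stop("p1 must be strictly below p99", call. = FALSE)
  pmin(pmax((x - p1) / (p99 - p1), 0), 1)
}

#' Suggest a per-marker positivity threshold from calibration ROIs
#'
#' Proposes a threshold on normalized intensities from a calibration set of
#' regions of interest, either by Otsu's between-class criterion or by the
#' crossing point of a two-component Gaussian mixture. The suggestion is
#' advisory: the threshold stored in the panel is authoritative.
#'
#' @param normalized values in `[0, 1]` from the calibration set.
#' @param method `"otsu"` or `"gmm2"`.
#' @return list with `threshold`, `method`, and `fallback` (TRUE when a
#'   degenerate mixture forced the Otsu fallback).
#' @export
suggest_threshold <- function(normalized, method = c("otsu", "gmm2")) {
  method <- match.arg(method)
  v <- normalized[!is.na(normalized)]
  if (length(unique(v)) < 2) {
    stop("calibration set is degenerate: fewer than 2 distinct values",
         call. = FALSE)
  }
  otsu_th <- function(v) {
    as.numeric(EBImage::otsu(matrix(pmin(pmax(v, 0), 1), ncol = 1),
                             range = c(0, 1), levels = 256))
  }
  if (method == "otsu") {
    return(list(threshold = otsu_th(v), method = "otsu", fallback = FALSE))
  }
  par <- tryCatch({
    bic <- mclust::mclustBIC(v, G = 2, modelNames = "V", verbose = FALSE)
    mclust::summaryMclustBIC(bic, v, G = 2, modelNames = "V")$parameters
  }, error = function(e) NULL)
  if (is.null(par) || length(unique(round(par$mean, 8))) < 2) {
    warning("two-component mixture degenerate; falling back to Otsu")
    return(list(threshold = otsu_th(v), method = "otsu", fallback = TRUE))
  }
  mu <- par$mean
  sg <- sqrt(par$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  pro <- par$pro
  lo <- which.min(mu); hi <- which.max(mu)
  # crossing point of the two weighted component densities between the means
  grid <- seq(mu[lo], mu[hi], length.out = 512)
  d_lo <- pro[lo] * dnorm(grid, mu[lo], sg[lo])
  d_hi <- pro[hi] * dnorm(grid, mu[hi], sg[hi])
  cross_i <- which(d_lo < d_hi)[1]
  cross <- if (is.na(cross_i)) mean(mu) else grid[cross_i]
  list(threshold = as.numeric(cross), method = "gmm2", fallback = FALSE)
}

#' Call per-cell marker positivity
#'
#' A cell is positive for a marker iff the rescaled mean intensity in the
#' marker's primary compartment meets or exceeds the marker's threshold.
#' Cells whose primary compartment is missing (e.g. a fully clipped ring)
#' are negative-by-missing and flagged.
#'
#' @param cell_stats data.frame from [compute_cell_stats()].
#' @param panel fitted [marker_panel()] with bounds and thresholds.
#' @param stat which compartment statistic to threshold (default `"mean"`).
#' @return data.frame with `cell_id`, a logical `<marker>_pos` per marker and
#'   a logical `<marker>_missing` flag.
#' @export
score_cells <- function(cell_stats, panel, stat = "mean") {
  stopifnot(inherits(panel, "marker_panel"))
  if (any(is.na(panel$p1)) || any(is.na(panel$p99))) {
    stop("panel bounds are unfitted; run fit_rescale_bounds() first",
         call. = FALSE)
  }
  out <- data.frame(cell_id = cell_stats$cell_id)
  for (i in seq_len(nrow(panel))) {
    m <- panel$marker[i]
    col <- paste(m, panel$primary_compartment[i], stat, sep = "_")
    if (!col %in% names(cell_stats)) {
      stop("cell statistics lack column ", col, call. = FALSE)
    }
    raw <- cell_stats[[col]]
    missing <- is.na(raw)
    norm <- rescale_intensity(ifelse(missing, panel$p1[i], raw),
                              panel$p1[i], panel$p99[i])
    out[[paste0(m, "_pos")]] <- !missing & norm >= panel$threshold[i]
    out[[paste0(m, "_missing")]] <- missing
  }
  out
}

#' Quantify positive-cell density and fraction per ROI
#'
#' Counts positive cells per marker and reports density over the ROI tissue
#' area (pixel count times squared pixel size, in cells per square
#' millimetre) and the fraction of all segmented cells. With zero segmented
#' cells, counts and densities are 0 and fractions are `NA`.
#'
#' @param calls data.frame from [score_cells()].
#' @param labels nucleus label matrix of the ROI (defines the ROI pixel
#'   area).
#' @param pixel_size microns per pixel.
#' @param roi_id label for the ROI row.
#' @return one-row data.frame: `roi_id, area_mm2, total_cells` and per marker
#'   `<m>_count`, `<m>_density_mm2`, `<m>_fraction`.
#' @export
quantify_roi <- function(calls, labels,
                         pixel_size = attr(labels, "pixel_size"),
                         roi_id = "roi1") {
  stopifnot(!is.null(pixel_size))
  area_mm2 <- length(labels) * pixel_size^2 * 1e-6
  total <- max(0L, max(labels))
  if (total > 0 && nrow(calls) != total) {
    stop("positivity calls must cover all segmented cells", call. = FALSE)
  }
  out <- data.frame(roi_id = roi_id, area_mm2 = area_mm2,
                    total_cells = total, stringsAsFactors = FALSE)
  pos_cols <- grep("_pos$", names(calls), value = TRUE)
  for (pc in pos_cols) {
    m <- sub("_pos$", "", pc)
    n_pos <- if (total == 0) 0L else sum(calls[[pc]])
    out[[paste0(m, "_count")]] <- n_pos
    out[[paste0(m, "_density_mm2")]] <- n_pos / area_mm2
    out[[paste0(m, "_fraction")]] <- if (total == 0) NA_real_ else
      n_pos / total
  }
  out
}
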