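# Shared synthetic fixtures, built in code at test time.

PANEL6 <- c("CD8", "CD68", "CD3", "FOXP3", "CD56", "PD1")

# A small rendered scene with ground truth: returns library, cells, scene.
make_scene <- function(n_cells = 30, shape = c(220, 220), noise_sd = 0,
                       seed = 1, autofluorescence_level = 0.1,
                       prevalence = setNames(rep(0.25, 6), PANEL6)) {
  lib <- default_spectral_library(10, seed = 1)
  cells <- place_cells(n_cells, shape, prevalence = prevalence, seed = seed)
  sc <- render_tissue_image(cells, lib, shape, noise_sd = noise_sd,
                            autofluorescence_level = autofluorescence_level,
                            seed = seed + 1000)
  list(lib = lib, cells = cells, scene = sc)
}

# bare cells table with all markers negative, for geometry-only scenes
bare_cells <- function(rows, cols, radius_um = 4) {
  cells <- data.frame(cell_id = seq_along(rows), row = rows, col = cols,
                      radius_um = rep(radius_um, length.out = length(rows)))
  for (m in PANEL6) {
    cells[[paste0(m, "_pos")]] <- rep(FALSE, nrow(cells))
    cells[[paste0(m, "_level")]] <- rep(0, nrow(cells))
  }
  cells
}

# match each detected cell (rows of stats) to the nearest true cell
match_truth <- function(stats, truth) {
  vapply(seq_len(nrow(stats)), function(i) {
    which.min((truth$row - stats$row[i])^2 + (truth$col - stats$col[i])^2)
  }, integer(1))
}

# run segmentation + stats on a scene's true abundances or unmixed planes
segment_scene <- function(planes, pixel_size = 0.496) {
  nuc <- segment_nuclei(planes[, , "DAPI"], pixel_size)
  rings <- expand_cytoplasm(nuc, pixel_size)
  list(nuclei = nuc, rings = rings,
       stats = compute_cell_stats(planes, nuc, rings, pixel_size))
}
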