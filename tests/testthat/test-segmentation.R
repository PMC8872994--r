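test_that("a blank DAPI plane yields zero cells, not an error", {
  labs <- segment_nuclei(matrix(0, 50, 50), 0.496)
  expect_equal(max(labs), 0)
})

test_that("disjoint synthetic nuclei are recovered exactly with sub-pixel centroids", {
  fx <- make_scene(n_cells = 50, shape = c(300, 300), seed = 2)
  seg <- segment_scene(fx$scene$abundance)
  expect_equal(max(seg$nuclei), 50)
  idx <- match_truth(seg$stats, fx$cells)
  expect_equal(sort(idx), 1:50)  # one-to-one
  d <- sqrt((seg$stats$row - fx$cells$row[idx])^2 +
              (seg$stats$col - fx$cells$col[idx])^2)
  expect_lt(max(d), 1)
})

test_that("two touching nuclei forming a dumbbell are split by the watershed", {
  lib <- default_spectral_library(10, seed = 1)
  cells <- bare_cells(c(40, 40), c(32, 47))  # centers 15 px apart, r ~ 8 px
  sc <- render_tissue_image(cells, lib, c(80, 80), noise_sd = 0)
  labs <- segment_nuclei(sc$abundance[, , "DAPI"], 0.496)
  expect_equal(max(labs), 2)
})

test_that("2 um expansion at 0.496 um/pixel gives a 4-pixel ring matching brute-force pixel counting", {
  lib <- default_spectral_library(10, seed = 1)
  cells <- bare_cells(50, 50, radius_um = 4)
  sc <- render_tissue_image(cells, lib, c(100, 100), noise_sd = 0)
  nuc <- segment_nuclei(sc$abundance[, , "DAPI"], 0.496)
  rings <- expand_cytoplasm(nuc, 0.496, 2)
  ring_px <- which(rings == 1)
  # brute-force oracle: pixels within 4 px of the nucleus pixel set
  nuc_px <- which(nuc == 1)
  nr <- ((nuc_px - 1) %% 100) + 1; nc <- ((nuc_px - 1) %/% 100) + 1
  all_r <- rep(1:100, 100); all_c <- rep(1:100, each = 100)
  mind <- vapply(seq_len(10000), function(i) {
    sqrt(min((nr - all_r[i])^2 + (nc - all_c[i])^2))
  }, numeric(1))
  oracle <- which(mind > 0 & mind <= 4)
  expect_setequal(ring_px, oracle)
  # analytic disk annulus area within discretisation error
  r_px <- 4 / 0.496
  analytic <- pi * ((r_px + 4)^2 - r_px^2)
  expect_lt(abs(length(ring_px) - analytic) / analytic, 0.10)
})

test_that("rings of adjacent nuclei partition contested pixels uniquely", {
  lib <- default_spectral_library(10, seed = 1)
  cells <- bare_cells(c(40, 40), c(30, 50))  # 20 px apart: rings would meet
  sc <- render_tissue_image(cells, lib, c(80, 80), noise_sd = 0)
  nuc <- segment_nuclei(sc$abundance[, , "DAPI"], 0.496)
  rings <- expand_cytoplasm(nuc)
  expect_equal(max(nuc), 2)
  # ring pixels never overlap nucleus pixels of any cell
  expect_equal(sum(rings > 0 & nuc > 0), 0)
  # contested pixels went to the nearer centroid
  cen <- lapply(1:2, function(k) {
    px <- which(nuc == k)
    c(mean(((px - 1) %% 80) + 1), mean(((px - 1) %/% 80) + 1))
  })
  ring_idx <- which(rings > 0)
  rr <- ((ring_idx - 1) %% 80) + 1; cc <- ((ring_idx - 1) %/% 80) + 1
  d1 <- sqrt((rr - cen[[1]][1])^2 + (cc - cen[[1]][2])^2)
  d2 <- sqrt((rr - cen[[2]][1])^2 + (cc - cen[[2]][2])^2)
  lab <- rings[ring_idx]
  expect_true(all((lab == 1) == (d1 <= d2 + 1e-9) |
                    abs(d1 - d2) < 1e-9))
})

test_that("per-cell statistics honour constant planes and ground-truth ring abundances", {
  # wide gaps so neighbouring rings cannot overlap and sum abundances
  lib <- default_spectral_library(10, seed = 1)
  cells <- place_cells(10, c(200, 200),
                       prevalence = setNames(c(1, rep(0, 5)), PANEL6),
                       min_gap_px = 10, seed = 8)
  sc <- render_tissue_image(cells, lib, c(200, 200), noise_sd = 0)
  fx <- list(lib = lib, cells = cells, scene = sc)
  seg <- segment_scene(fx$scene$abundance)
  # every cell is CD8+ at level 1, noiseless: ring mean = 1 exactly
  expect_equal(seg$stats$CD8_ring_mean, rep(1, 10))
  expect_equal(seg$stats$CD8_ring_sd, rep(0, 10))
  expect_true(all(seg$stats$CD8_ring_min <= seg$stats$CD8_ring_mean &
                    seg$stats$CD8_ring_mean <= seg$stats$CD8_ring_max))
  # a constant plane: mean = min = max = v, sd = 0 in both compartments
  comp <- fx$scene$abundance
  comp[, , "CD3"] <- 0.7
  st <- compute_cell_stats(comp, seg$nuclei, seg$rings, 0.496)
  expect_equal(st$CD3_nucleus_mean, rep(0.7, 10))
  expect_equal(st$CD3_ring_min, rep(0.7, 10))
  expect_equal(st$CD3_ring_sd, rep(0, 10))
})

test_that("a cell whose ring is fully clipped keeps its record with missing ring stats", {
  # single nucleus filling the whole frame: no background to expand into
  nuc <- matrix(1L, 20, 20)
  attr(nuc, "pixel_size") <- 0.496
  rings <- expand_cytoplasm(nuc)
  expect_equal(max(rings), 0)
  comp <- array(1, dim = c(20, 20, 1), dimnames = list(NULL, NULL, "CD8"))
  st <- compute_cell_stats(comp, nuc, rings, 0.496, markers = "CD8")
  expect_equal(nrow(st), 1)
  expect_true(is.na(st$CD8_ring_mean))
  expect_false(is.na(st$CD8_nucleus_mean))
})

test_that("areas in square microns are invariant to resolution changes", {
  lib <- default_spectral_library(10, seed = 1)
  res <- lapply(c(1, 2), function(f) {
    cells <- bare_cells(60 * f, 60 * f, radius_um = 4)
    sc <- render_tissue_image(cells, lib, c(120 * f, 120 * f),
                              pixel_size = 0.496 / f, noise_sd = 0)
    nuc <- segment_nuclei(sc$abundance[, , "DAPI"], 0.496 / f)
    rings <- expand_cytoplasm(nuc)
    compute_cell_stats(sc$abundance, nuc, rings, 0.496 / f)
  })
  expect_equal(res[[1]]$nucleus_area_um2, res[[2]]$nucleus_area_um2,
               tolerance = 0.05)
  expect_equal(res[[1]]$ring_area_um2, res[[2]]$ring_area_um2,
               tolerance = 0.05)
})
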