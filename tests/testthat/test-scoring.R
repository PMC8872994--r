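test_that("percentile bounds match the direct quantile formula and reject degenerate markers", {
  panel <- marker_panel("CD8")
  fitted <- fit_rescale_bounds(panel, list(CD8 = 0:100))
  expect_equal(fitted$p1, 1)
  expect_equal(fitted$p99, 99)
  expect_error(fit_rescale_bounds(panel, list(CD8 = rep(5, 200))),
               "degenerate")
  # pooling consistency: concatenated batches equal one pooled stream
  set.seed(1)
  b1 <- rlnorm(500); b2 <- rlnorm(700, meanlog = 1)
  f1 <- fit_rescale_bounds(panel, list(CD8 = c(b1, b2)))
  f2 <- fit_rescale_bounds(panel, list(CD8 = c(b2, b1)))
  expect_equal(f1$p1, f2$p1)
  expect_equal(f1$p99, f2$p99)
})

test_that("rescaling maps bounds to endpoints, clips, and is idempotent on [0,1]", {
  expect_equal(rescale_intensity(c(2, 10), 2, 10), c(0, 1))
  expect_equal(rescale_intensity(6, 2, 10), 0.5)
  expect_equal(rescale_intensity(c(-5, 50), 2, 10), c(0, 1))
  x <- seq(0, 1, 0.05)
  expect_equal(rescale_intensity(x, 0, 1), x)
  expect_error(rescale_intensity(1, 3, 3), "p1")
})

test_that("threshold suggestion separates bimodal data and flags degenerate input", {
  v <- c(rep(0.1, 500), rep(0.9, 500))
  th <- suggest_threshold(v, method = "otsu")
  expect_gt(th$threshold, 0.1)
  expect_lt(th$threshold, 0.9)
  expect_error(suggest_threshold(rep(0.5, 100)), "degenerate")

  # well-separated mixture with 20% positives: called fraction within 0.02
  set.seed(7)
  truth_pos <- runif(2000) < 0.2
  v <- ifelse(truth_pos, rnorm(2000, 0.8, 0.05), rnorm(2000, 0.15, 0.05))
  v <- pmin(pmax(v, 0), 1)
  for (method in c("otsu", "gmm2")) {
    th <- suggest_threshold(v, method = method)
    called <- mean(v >= th$threshold)
    expect_lt(abs(called - 0.2), 0.02)
  }
})

test_that("positivity calls recover noiseless ground-truth phenotypes exactly", {
  fx <- make_scene(n_cells = 40, shape = c(260, 260), seed = 11)
  seg <- segment_scene(fx$scene$abundance)
  pooled <- lapply(setNames(nm = PANEL6),
                   function(m) seg$stats[[paste0(m, "_ring_mean")]])
  panel <- fit_rescale_bounds(marker_panel(), pooled, min_n = 30)
  calls <- score_cells(seg$stats, panel)
  idx <- match_truth(seg$stats, fx$cells)
  for (m in PANEL6) {
    expect_identical(calls[[paste0(m, "_pos")]],
                     fx$cells[[paste0(m, "_pos")]][idx])
  }
})

test_that("raising a threshold never increases the positive count", {
  fx <- make_scene(n_cells = 40, shape = c(260, 260), seed = 12,
                   noise_sd = 0.05)
  seg <- segment_scene(unmix_pixelwise(fx$scene$image, fx$lib)$planes)
  pooled <- lapply(setNames(nm = PANEL6),
                   function(m) seg$stats[[paste0(m, "_ring_mean")]])
  panel <- fit_rescale_bounds(marker_panel(), pooled, min_n = 30)
  for (m in PANEL6) {
    counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
      p <- panel
      p$threshold[p$marker == m] <- th
      sum(score_cells(seg$stats, p)[[paste0(m, "_pos")]])
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("cells missing their primary compartment are negative-by-missing and flagged", {
  nuc <- matrix(1L, 20, 20)
  attr(nuc, "pixel_size") <- 0.496
  rings <- expand_cytoplasm(nuc)
  comp <- array(5, dim = c(20, 20, 1), dimnames = list(NULL, NULL, "CD8"))
  st <- compute_cell_stats(comp, nuc, rings, 0.496, markers = "CD8")
  panel <- marker_panel("CD8", p1 = 0, p99 = 1, threshold = 0.3)
  calls <- score_cells(st, panel)
  expect_false(calls$CD8_pos)
  expect_true(calls$CD8_missing)
  # marker absent from the stats table is a schema error
  panel2 <- marker_panel(c("CD8", "CD3"), p1 = 0, p99 = 1)
  expect_error(score_cells(st, panel2), "CD3_ring_mean")
})

test_that("density and fraction identities hold exactly", {
  calls <- data.frame(cell_id = 1:100,
                      CD8_pos = c(rep(TRUE, 20), rep(FALSE, 80)),
                      CD8_missing = FALSE)
  # label map whose pixel area is exactly 1 mm^2 at 1 um/pixel: 1000x1000
  labels <- matrix(0L, 1000, 1000)
  labels[1:10, 1:10] <- rep(1:100, each = 1)
  q <- quantify_roi(calls, labels, pixel_size = 1)
  expect_equal(q$area_mm2, 1)
  expect_equal(q$CD8_count, 20)
  expect_equal(q$CD8_density_mm2, 20)
  expect_equal(q$CD8_fraction, 0.2)
  expect_equal(q$CD8_density_mm2 * q$area_mm2, q$CD8_count)
  expect_equal(q$CD8_fraction * q$total_cells, q$CD8_count)

  # zero cells: zero counts, missing fractions
  q0 <- quantify_roi(data.frame(cell_id = integer(0),
                                CD8_pos = logical(0)),
                     matrix(0L, 10, 10), pixel_size = 1)
  expect_equal(q0$CD8_count, 0)
  expect_true(is.na(q0$CD8_fraction))
})

test_that("programmed prevalence is recovered within the binomial interval", {
  fx <- make_scene(n_cells = 60, shape = c(320, 320), seed = 13,
                   prevalence = setNames(c(0, 0, 0.3, 0, 0, 0), PANEL6))
  seg <- segment_scene(fx$scene$abundance)
  pooled <- lapply(setNames(nm = "CD3"),
                   function(m) seg$stats[[paste0(m, "_ring_mean")]])
  panel <- fit_rescale_bounds(marker_panel("CD3"), pooled, min_n = 30)
  calls <- score_cells(seg$stats, panel)
  q <- quantify_roi(calls, seg$nuclei)
  ci <- qnorm(0.975) * sqrt(0.3 * 0.7 / 60)
  expect_lt(abs(q$CD3_fraction - 0.3), ci + 0.01)
})
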