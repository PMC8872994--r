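test_that("the default cohort report flags the programmed serum declines", {
  tab <- simulate_cohort(cohort_sim_params(), seed = 1)
  rep <- run_longitudinal_report(tab,
                                 variables = c("weight", "crp", "il6",
                                               "tnfa", "cd8"),
                                 pairs = list("cd8:weight"))
  expect_lt(rep$kw$p[rep$kw$variable == "crp"], 0.05)
  d <- rep$dunn
  crp12 <- d[d$variable == "crp" & d$group1 == "0" & d$group2 == "12", ]
  expect_true(crp12$significant)
  expect_lt(rep$rmcorr$r[1], 0)
})

test_that("an empty pairs list yields a report without a correlation section", {
  tab <- simulate_cohort(cohort_sim_params(), seed = 2)
  rep <- run_longitudinal_report(tab, variables = c("crp", "weight"))
  expect_null(rep$rmcorr)
  expect_equal(nrow(rep$kw), 2)
})

test_that("missing required columns produce a schema error naming them", {
  tab <- simulate_cohort(cohort_sim_params(), seed = 2)
  expect_error(run_longitudinal_report(tab[, -1]), "subject_id")
  expect_error(run_longitudinal_report(tab, variables = "nope"), "nope")
  expect_error(run_longitudinal_report(tab, pairs = list("crp:nothere")),
               "nothere")
})

test_that("configuration validation applies protocol defaults and collects violations", {
  cfg <- validate_config(list())
  expect_equal(cfg$expansion_um, 2.0)
  expect_equal(cfg$pixel_size, 0.496)
  expect_equal(cfg$stats$alpha, 0.05)
  expect_error(validate_config(list(expansion_um = -1)), "expansion_um")
  expect_error(validate_config(list(panel_markers = c("CD8", "CD8"))),
               "duplicate")
  expect_error(validate_config(list(bogus_key = 1)), "unknown keys")
  err <- tryCatch(validate_config(list(expansion_um = -1, n_rois = 99)),
                  error = conditionMessage)
  expect_match(err, "expansion_um")
  expect_match(err, "n_rois")
})

test_that("config files round-trip through YAML", {
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9, n_rois = 2, cells_per_roi = 12), tf)
  cfg <- validate_config(tf)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$n_rois, 2)
  expect_equal(cfg$expansion_um, 2.0)
})

test_that("the full pipeline runs end to end and is reproducible", {
  run_cfg <- function(dir) {
    validate_config(list(seed = 4, out_dir = dir, n_rois = 2,
                         roi_shape = c(150L, 150L), cells_per_roi = 15L,
                         noise_sd = 0.01,
                         stats = list(pairs = list("crp:weight"),
                                      n_boot = 50L)))
  }
  d1 <- file.path(tempdir(), "run_a")
  m1 <- run_pipeline(run_cfg(d1))
  expect_named(m1$stages, c("library", "simulate", "unmix", "segment",
                            "score", "stats"))
  expect_true(all(vapply(m1$stages, function(s) isTRUE(s$completed),
                         logical(1))))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "roi01.tif")))
  expect_true(file.exists(file.path(d1, "quantification.csv")))

  d2 <- file.path(tempdir(), "run_b")
  m2 <- run_pipeline(run_cfg(d2))
  expect_identical(unname(unlist(m1$checksums)),
                   unname(unlist(m2$checksums)))
})

test_that("multichannel TIFF round-trips through the sidecar scale", {
  img <- array(runif(20 * 20 * 4, 0, 7), dim = c(20, 20, 4))
  tf <- tempfile(fileext = ".tif")
  write_ms_tiff(img, tf, channel_names = paste0("c", 1:4), pixel_size = 0.5)
  back <- read_ms_tiff(tf)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 7 / 65535 * 1.01)  # 16-bit quantisation
  expect_equal(attr(back, "pixel_size"), 0.5)
  expect_equal(attr(back, "channel_names"), paste0("c", 1:4))
})

test_that("spectral libraries and marker panels round-trip through CSV/YAML", {
  lib <- default_spectral_library(10, seed = 2)
  tf <- tempfile(fileext = ".csv")
  write_spectral_library(lib, tf)
  lib2 <- read_spectral_library(tf)
  expect_equal(lib$matrix, lib2$matrix, tolerance = 1e-12)

  panel <- marker_panel(p1 = 0, p99 = 2, threshold = 0.4)
  ty <- tempfile(fileext = ".yaml")
  write_panel_yaml(panel, ty)
  panel2 <- read_panel_yaml(ty)
  expect_equal(as.data.frame(panel), as.data.frame(panel2))
})

test_that("spectrum extraction recovers the pure and sparse reference spectra", {
  lib <- default_spectral_library(10, seed = 1)
  s <- lib$matrix[, "CD3"]
  # constant reference image
  img <- array(rep(s, each = 400), dim = c(20, 20, 10))
  expect_equal(extract_spectrum(img), unname(s), tolerance = 1e-12)
  # signal on 1% of pixels only
  img2 <- array(0, dim = c(20, 20, 10))
  img2[1, 1:4, ] <- matrix(s, 4, 10, byrow = TRUE)
  expect_equal(extract_spectrum(img2, top_fraction = 0.01), unname(s),
               tolerance = 1e-12)
  expect_error(extract_spectrum(array(0, dim = c(5, 5, 10))), "degenerate")
})

test_that("autofluorescence background subtraction recovers a single-stain spectrum", {
  lib <- default_spectral_library(10, seed = 1)
  cells <- bare_cells(c(30, 30, 70, 70), c(30, 70, 30, 70))
  cells$CD56_pos <- TRUE
  cells$CD56_level <- 3
  sc <- render_tissue_image(cells, lib, c(100, 100),
                            autofluorescence_level = 0.2, noise_sd = 0.01,
                            seed = 3)
  bg <- render_tissue_image(bare_cells(numeric(0), numeric(0))[0, ], lib,
                            c(100, 100), autofluorescence_level = 0.2,
                            noise_sd = 0.01, seed = 4)
  # rings (level 3) outshine nuclei (DAPI level 1), so the brightest 2% of
  # pixels are CD56 ring pixels and background subtraction removes the AF
  sp <- extract_spectrum(sc$image, bg$image, top_fraction = 0.02)
  expect_lt(sum(abs(sp - lib$matrix[, "CD56"])), 0.05)
})
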