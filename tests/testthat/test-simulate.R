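test_that("zero-spread phenotypes generate perfectly straight hyphae", {
  spec <- phenotype_spec("straight", n_cells = 20, deflection_sigma_deg = 0,
                         seed = 5)
  sim <- generate_cells(spec)
  expect_true(all(sim$truth$d_h == 0))
  expect_true(all(sim$truth$junction_deg == 0))
})

test_that("generation is deterministic given the spec seed", {
  spec <- phenotype_spec("det", n_cells = 15, deflection_sigma_deg = 25,
                         seed = 99)
  a <- generate_cells(spec)
  b <- generate_cells(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cells, b$cells)
  c <- generate_cells(phenotype_spec("det", n_cells = 15,
                                     deflection_sigma_deg = 25, seed = 100))
  expect_false(identical(a$truth$d_h, c$truth$d_h))
})

test_that("analytic truth equals the deformity measurement on the generating polyline", {
  spec <- phenotype_spec("agree", n_cells = 40, deflection_sigma_deg = 30,
                         seed = 17)
  sim <- generate_cells(spec)
  for (i in seq_along(sim$cells)) {
    cell <- sim$cells[[i]]
    if (!cell$included_for_deformity) next
    ds <- compute_deformity(cell, simplify_tol_um = 0, min_kink_deg = 10,
                            merge_radius_um = 0, junction_chord_um = 0)
    expect_equal(ds$d_h, sim$truth$d_h[i], tolerance = 1e-9)
  }
})

test_that("half-normal deflections have the expected mean sine", {
  sigma <- 40
  set.seed(1234)
  k <- 10000
  draws <- hyphometry:::r_deflection(k, sigma)
  emp <- mean(sin(draws * pi / 180))
  se <- sd(sin(draws * pi / 180)) / sqrt(k)
  # oracle: numerical integration of E[sin(X)] for half-normal truncated at 180
  dens <- function(x) 2 * dnorm(x, 0, sigma)
  z <- integrate(dens, 0, 180)$value
  oracle <- integrate(function(x) sin(x * pi / 180) * dens(x) / z, 0, 180)$value
  expect_lt(abs(emp - oracle), 2 * se + 1e-6)
})

test_that("direct deformity sampling matches the polyline generator's truth distribution", {
  set.seed(55)
  direct <- simulate_deformity_values(4000, 40)
  sim <- generate_cells(phenotype_spec("d", n_cells = 800,
                                       deflection_sigma_deg = 40, seed = 56))
  ks <- suppressWarnings(ks.test(direct, sim$truth$d_h))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(direct) - mean(sim$truth$d_h)), 0.03)
})

test_that("rasterization places exact tube support and deterministic noise", {
  spec <- phenotype_spec("r", n_cells = 3, deflection_sigma_deg = 10, seed = 31)
  sim <- generate_cells(spec)
  f1 <- rasterize_cells(sim)
  f2 <- rasterize_cells(sim)
  expect_identical(f1$images, f2$images)
  expect_identical(f1$mask, f2$mask)
  expect_equal(sort(unique(as.vector(f1$mask))), 0:3)

  # noiseless, PSF-free: mask support carries the tube intensity exactly
  f0 <- rasterize_cells(sim, gaussian_sd = 0, poisson_scale = 0,
                        psf_sigma_um = 0, peak_amplitude = 0,
                        background = 10, tube_intensity = 50)
  expect_true(all(f0$images[[1]][f0$mask > 0] >= 60 - 1e-9))
  expect_true(all(f0$images[[1]][f0$mask == 0] == 10))
})

test_that("terminal peaks land at hyphal tips in the rendered image", {
  spec <- phenotype_spec("tip", n_cells = 1, deflection_sigma_deg = 0,
                         kink_count_mean = 0,
                         peak_offsets_um = c(growth = 0), seed = 8)
  sim <- generate_cells(spec)
  f <- rasterize_cells(sim, gaussian_sd = 0, poisson_scale = 0,
                       psf_sigma_um = 0.1)
  cell <- f$cells[[1]]
  # offset 0 places the spot at the distal end of the hypha+bud path
  bp <- as.matrix(cell$bud_path)
  tip <- bp[nrow(bp), ]
  br <- which(f$images$growth == max(f$images$growth), arr.ind = TRUE)[1, ]
  bright_um <- c(br[2] - 1, br[1] - 1) * f$pixel_size_um
  expect_lt(sqrt(sum((bright_um - tip)^2)), 0.15)
})

test_that("added Gaussian noise lowers the measured image SNR monotonically", {
  spec <- phenotype_spec("snr", n_cells = 4, deflection_sigma_deg = 5, seed = 3)
  sim <- generate_cells(spec)
  snrs <- vapply(c(2, 8, 25), function(gs) {
    f <- rasterize_cells(sim, gaussian_sd = gs, poisson_scale = 0)
    snr_estimate(f$images[[1]], f$mask)
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("synthesized profiles encode the true peak offsets", {
  spec <- phenotype_spec("sp", n_cells = 10, deflection_sigma_deg = 5,
                         peak_offsets_um = c(a = 0, b = 0.3), seed = 44)
  sim <- synthesize_profiles(generate_cells(spec), snr = Inf)
  for (cell in sim$cells) {
    pa <- peak_to_tip(cell, "a")
    pb <- peak_to_tip(cell, "b")
    expect_lt(abs(pa$distance_um - 0), 0.051)
    expect_lt(abs(pb$distance_um - 0.3), 0.051)
  }
})

test_that("image TIFF round trip preserves intensities and labels", {
  set.seed(2)
  img <- matrix(runif(400, 0, 4000), 20)
  mask <- matrix(sample(0:5, 400, TRUE), 20)
  ti <- tempfile(fileext = ".tif"); tm <- tempfile(fileext = ".tif")
  write_image_tiff(img, ti)
  write_image_tiff(mask, tm)
  expect_equal(read_image_tiff(ti), img, tolerance = 1)
  expect_identical(read_image_tiff(tm, integer_labels = TRUE),
                   matrix(as.integer(mask), 20))
  unlink(c(ti, tm))
})
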