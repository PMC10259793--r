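test_that("deformity score reproduces closed-form cases", {
  # collinear emergence, no kinks: every sine is 0
  expect_equal(compute_deformity(make_cell(0))$d_h, 0)
  # one right-angle kink, collinear emergence: (0 + 1) / 2
  expect_equal(compute_deformity(make_cell(0, 90))$d_h, 0.5)
  # kinks of 30 and 150 degrees: sin 30 = sin 150 = 1/2, N = 3
  expect_equal(compute_deformity(make_cell(0, c(30, 150)))$d_h, 1 / 3,
               tolerance = 1e-12)
  # pure emergence angle: d_h = sin(junction), N = 1
  ds <- compute_deformity(make_cell(35))
  expect_equal(ds$n_angles, 1L)
  expect_equal(ds$d_h, sin(35 * pi / 180), tolerance = 1e-9)
})

test_that("junction angle measures body-axis-to-hypha turn", {
  body <- polyline_trace(rbind(c(-2, 0), c(0, 0)), "body_axis")
  along <- polyline_trace(rbind(c(0, 0), c(2, 0)), "hypha")
  up <- polyline_trace(rbind(c(0, 0), c(0, 2)), "hypha")
  expect_equal(junction_angle(body, along), 0)
  expect_equal(junction_angle(body, up), 90)
  # random orientations reduce to the deflection-angle oracle
  set.seed(23)
  for (i in 1:30) {
    pole <- rnorm(2)
    axis_dir <- rnorm(2); hyp_dir <- rnorm(2)
    b <- polyline_trace(rbind(pole - 3 * axis_dir, pole), "body_axis")
    h <- polyline_trace(rbind(pole, pole + 2 * hyp_dir), "hypha")
    oracle <- deflection_angle(pole - axis_dir, pole, pole + hyp_dir)
    expect_equal(junction_angle(b, h), oracle, tolerance = 1e-9)
  }
  tiny <- polyline_trace(rbind(c(0, 0), c(1e-12, 0)), "body_axis")
  expect_error(junction_angle(tiny, up), "invalid geometry")
})

test_that("supplement symmetry: alpha and 180 - alpha give identical scores", {
  set.seed(41)
  for (i in 1:200) {
    k <- sample(0:4, 1)
    j <- runif(1, 0, 180)
    a <- runif(k, 0, 180)
    expect_equal(deformity_set(j, a)$d_h, deformity_set(180 - j, 180 - a)$d_h,
                 tolerance = 1e-12)
  }
})

test_that("score is bounded in [0, 1] and zero only for flat angle sets", {
  set.seed(42)
  for (i in 1:200) {
    ds <- deformity_set(runif(1, 0, 180), runif(sample(0:5, 1), 0, 180))
    expect_gte(ds$d_h, 0)
    expect_lte(ds$d_h, 1)
  }
  expect_equal(deformity_set(0, c(0, 180))$d_h, 0, tolerance = 1e-12)
  expect_gt(deformity_set(0, c(0, 1))$d_h, 0)
})

test_that("score is invariant under rigid motions, reflection and scaling", {
  set.seed(77)
  for (i in 1:40) {
    cell <- make_cell(runif(1, 0, 60), runif(sample(0:3, 1), 15, 120))
    base <- compute_deformity(cell, simplify_tol_um = 0)$d_h
    tr <- transform_cell(cell, angle_deg = runif(1, 0, 360),
                         shift = rnorm(2, 0, 5), reflect = i %% 2 == 0)
    expect_equal(compute_deformity(tr, simplify_tol_um = 0)$d_h, base,
                 tolerance = 1e-9)
    sc <- transform_cell(cell, scale = runif(1, 0.5, 3))
    expect_equal(compute_deformity(sc, simplify_tol_um = 0,
                                   merge_radius_um = 0)$d_h, base,
                 tolerance = 1e-9)
  }
})

test_that("single-kink score is nondecreasing in deflection on [0, 90]", {
  # exact geometry (no simplification), grid chosen off the 10-degree
  # detection threshold where the score is discontinuous by design
  angs <- seq(0, 90, by = 6)
  dh <- vapply(angs, function(a) {
    compute_deformity(make_cell(0, a), simplify_tol_um = 0,
                      merge_radius_um = 0)$d_h
  }, numeric(1))
  expect_true(all(diff(dh) >= -1e-12))
})

test_that("inclusion rules are enforced with informative errors", {
  body <- polyline_trace(rbind(c(-2, 0), c(0, 0)), "body_axis")
  hyp <- polyline_trace(rbind(c(0, 0), c(3, 0)), "hypha")
  no_bud <- cell_record("nb", body, list(hyp))
  expect_error(compute_deformity(no_bud), "no initiated or finished bud")
  two <- cell_record("two", body,
                     list(hyp, polyline_trace(rbind(c(-2, 0), c(-4, 1)), "hypha")),
                     bud_path = polyline_trace(rbind(c(3, 0), c(3.5, 0)), "bud_path"))
  expect_error(compute_deformity(two), "2 hyphae")
  br <- cell_record("br", body, list(hyp), branched = TRUE,
                    bud_path = polyline_trace(rbind(c(3, 0), c(3.5, 0)), "bud_path"))
  expect_error(compute_deformity(br), "branched")
  # hyphae below the measurable length are rejected, not scored 0
  short <- cell_record("sh", body,
                       list(polyline_trace(rbind(c(0, 0), c(0.05, 0)), "hypha")),
                       bud_path = polyline_trace(rbind(c(0.05, 0), c(0.3, 0)), "bud_path"))
  expect_error(compute_deformity(short, simplify_tol_um = 0.05), "unmeasurable")
})

test_that("junction inclusion is configurable", {
  cell <- make_cell(30, 90)
  with_j <- compute_deformity(cell)
  expect_equal(with_j$n_angles, 2L)
  without_j <- compute_deformity(cell, include_junction = FALSE)
  expect_equal(without_j$n_angles, 1L)
  expect_equal(without_j$d_h, 1, tolerance = 1e-9)
  kink_free <- compute_deformity(make_cell(30), include_junction = FALSE)
  expect_true(is.na(kink_free$d_h))
})

test_that("deformity tables keep every cell with an exclusion reason", {
  cells <- list(make_cell(0, 90, id = "a"),
                cell_record("b", polyline_trace(rbind(c(-2, 0), c(0, 0)), "body_axis")),
                make_cell(20, id = "c"))
  tab <- deformity_table(cells, group = c("wt", "wt", "mut"))
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(!is.na(tab$d_h)) + sum(!is.na(tab$exclusion_reason)), 3L)
  expect_equal(tab$d_h[tab$cell_id == "a"], 0.5)
  expect_match(tab$exclusion_reason[tab$cell_id == "b"], "no bud")
})

test_that("trace CSVs round-trip cell geometry", {
  cells <- list(make_cell(10, c(40, 70), id = "c01"), make_cell(0, id = "c02"))
  tmp <- tempfile(fileext = ".csv")
  write_traces_csv(cells, tmp)
  back <- read_traces_csv(tmp)
  expect_equal(length(back), 2L)
  for (cell in cells) {
    b <- back[[cell$id]]
    expect_equal(unclass(as.matrix(b$hyphae[[1]])),
                 unclass(as.matrix(cell$hyphae[[1]])), tolerance = 1e-9)
    expect_equal(b$stage, cell$stage)
    expect_equal(compute_deformity(b)$d_h, compute_deformity(cell)$d_h,
                 tolerance = 1e-9)
  }
  unlink(tmp)
})
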