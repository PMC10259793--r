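# Demograph construction and peak-to-tip analysis on profile-bearing cells.

profiled_cell <- function(id, length_um, peak_arc_um, step = 0.05,
                          stage = c("budding", "hypha_no_bud", "no_hypha"),
                          channels = c("ch1")) {
  stage <- match.arg(stage)
  stopifnot(length_um >= 2)
  body <- polyline_trace(rbind(c(0, 0), c(1, 0)), "body_axis")
  hyp <- if (stage != "no_hypha") {
    end <- if (stage == "budding") length_um - 0.5 else length_um
    list(polyline_trace(rbind(c(1, 0), c(end, 0)), "hypha"))
  } else list()
  bud <- if (stage == "budding") {
    polyline_trace(rbind(c(length_um - 0.5, 0), c(length_um, 0)), "bud_path")
  } else NULL
  if (stage == "no_hypha") {
    body <- polyline_trace(rbind(c(0, 0), c(length_um, 0)), "body_axis")
  }
  cell <- cell_record(id, body, hyp, bud_path = bud)
  s <- seq(0, cell$cell_length_um, by = step)
  profs <- lapply(seq_along(channels), function(i) {
    exp(-(s - peak_arc_um)^2 / (2 * 0.1^2))
  })
  names(profs) <- channels
  cell$profiles <- profs
  cell$profile_step_um <- step
  cell
}

test_that("demograph rows are normalized, aligned and sorted by cell length", {
  lens <- c(4, 2, 3)
  cells <- lapply(seq_along(lens), function(i) {
    profiled_cell(paste0("c", i), lens[i], peak_arc_um = lens[i])  # tip peaks
  })
  dg <- build_demograph(cells, "budding", "ch1", bin_step_um = 0.05)
  expect_equal(dg$cell_lengths_um, sort(lens))
  # occupied bins span exactly the cell length
  for (i in seq_len(nrow(dg$matrix))) {
    occ <- which(!is.na(dg$matrix[i, ]))
    expect_equal(occ, seq_len(ceiling(dg$cell_lengths_um[i] / 0.05)))
    v <- dg$matrix[i, occ]
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
    # the tip peak lands within one bin of the row's end
    expect_lte(abs(which.max(v) - length(occ)), 1)
  }
  # column 0 occupied for every row
  expect_true(all(!is.na(dg$matrix[, 1])))
})

test_that("demograph output is invariant to input order and rejects empty groups", {
  cells <- lapply(1:5, function(i) profiled_cell(paste0("c", i), 2 + i / 2, 1))
  dg1 <- build_demograph(cells, "budding", "ch1")
  dg2 <- build_demograph(rev(cells), "budding", "ch1")
  expect_identical(dg1$matrix, dg2$matrix)
  expect_identical(dg1$cell_ids, dg2$cell_ids)
  expect_error(build_demograph(cells, "no_hypha", "ch1"), "empty group")
  expect_error(build_demograph(cells, "budding", "nope"), "empty group")
})

test_that("constant profiles map to all-zero demograph rows", {
  cell <- profiled_cell("flat", 3, 1)
  cell$profiles$ch1 <- rep(4.2, length(cell$profiles$ch1))
  dg <- build_demograph(list(cell), "budding", "ch1")
  occ <- !is.na(dg$matrix[1, ])
  expect_true(all(dg$matrix[1, occ] == 0))
})

test_that("single-cell demographs are valid and writable", {
  cell <- profiled_cell("solo", 3.3, 2)
  dg <- build_demograph(list(cell), "budding", "ch1")
  expect_equal(nrow(dg$matrix), 1L)
  tmp <- tempfile(fileext = ".csv")
  write_demograph_csv(dg, tmp)
  back <- utils::read.csv(tmp, check.names = FALSE)
  expect_equal(nrow(back), 1L)
  expect_true(file.exists(paste0(tmp, ".meta.yaml")))
  unlink(c(tmp, paste0(tmp, ".meta.yaml")))
})

test_that("peak-to-tip distance is measured from the distal tip with tip-ward ties", {
  # maximum at the last sample: distance 0
  cell <- profiled_cell("tip", 4, peak_arc_um = 4)
  expect_equal(peak_to_tip(cell, "ch1")$distance_um, 0, tolerance = 1e-9)
  # peak centred 0.30 um from the tip, noiseless
  cell2 <- profiled_cell("sub", 4, peak_arc_um = 3.7)
  expect_lt(abs(peak_to_tip(cell2, "ch1")$distance_um - 0.3), 0.0501)
  # exact tie between two positions resolves toward the tip
  cell3 <- profiled_cell("tie", 4, peak_arc_um = 3.7)
  p <- cell3$profiles$ch1
  p[] <- 0
  p[61] <- 1   # arc 3.00 um
  p[74] <- 1   # arc 3.65 um, equal height but closer to the tip
  cell3$profiles$ch1 <- p
  expect_equal(peak_to_tip(cell3, "ch1", window_um = 0)$distance_um,
               4 - (74 - 1) * 0.05, tolerance = 1e-9)
  expect_error(peak_to_tip(profiled_cell("nh", 3, 1, stage = "no_hypha"), "ch1"),
               "no hypha")
})

test_that("swapping channel labels swaps peak outputs exactly", {
  cell <- profiled_cell("two", 4, 3.8, channels = c("a", "b"))
  cell$profiles$b <- rev(cell$profiles$b)  # make channels differ
  pa <- peak_to_tip(cell, "a"); pb <- peak_to_tip(cell, "b")
  swapped <- cell
  names(swapped$profiles) <- c("b", "a")
  expect_equal(peak_to_tip(swapped, "b")$distance_um, pa$distance_um)
  expect_equal(peak_to_tip(swapped, "a")$distance_um, pb$distance_um)
})

test_that("paired channel offsets recover a subterminal shift at moderate noise", {
  spec <- phenotype_spec("pair", n_cells = 60, deflection_sigma_deg = 10,
                         peak_offsets_um = c(growth = 0, marker = 0.2),
                         seed = 21)
  sim <- synthesize_profiles(generate_cells(spec), snr = 5)
  pk <- peak_distance_table(sim$cells)
  po <- paired_peak_offsets(pk, "growth", "marker")
  expect_equal(po$n, 60L)
  expect_lt(abs(po$median_offset_um - 0.2), 0.05)
  expect_lt(po$median_a_um, po$median_b_um)
})
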