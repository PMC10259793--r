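#' Phenotype specification for the synthetic cell generator
#'
#' Describes a population of single budding cells with one polar hypha. Kink
#' and emergence angles are drawn from a half-normal distribution truncated
#' to \[0, 180) whose scale `deflection_sigma_deg` is the single spread
#' parameter separating phenotypes: a few degrees gives essentially straight
#' hyphae (wild-type-like), several tens of degrees gives the kinked and
#' buckled hyphae of shape mutants. Kink counts are Poisson distributed.
#'
#' @param name Phenotype label.
#' @param n_cells Number of cells.
#' @param kink_count_mean Poisson mean of the number of kinks per hypha
#'   (default 2).
#' @param deflection_sigma_deg Half-normal scale of kink and emergence
#'   deflections, degrees (default 5).
#' @param hypha_length_um Length-2 vector (mean, sd) of hyphal length
#'   (default 5, 0.8).
#' @param body_length_um,body_width_um Mother-cell axis length and width
#'   (defaults 2.2, 1.2).
#' @param hypha_width_um Hyphal tube width (default 0.25).
#' @param bud_diameter_um Diameter of the nascent bud (default 0.9).
#' @param peak_offsets_um Named numeric vector: per-channel true distance of
#'   the fluorescence peak from the hyphal tip (default
#'   `c(growth = 0, marker = 0.2)`, emulating a terminal cell-wall label and
#'   a subterminally localizing protein).
#' @param stage_probs Probabilities of the three growth stages
#'   (`no_hypha`, `hypha_no_bud`, `budding`); default all budding, the stage
#'   eligible for deformity measurement.
#' @param min_segment_um Minimum arc length between consecutive kinks
#'   (default 0.4).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return Object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name = "wt_like", n_cells = 100,
                           kink_count_mean = 2, deflection_sigma_deg = 5,
                           hypha_length_um = c(5, 0.8),
                           body_length_um = 2.2, body_width_um = 1.2,
                           hypha_width_um = 0.25, bud_diameter_um = 0.9,
                           peak_offsets_um = c(growth = 0, marker = 0.2),
                           stage_probs = c(no_hypha = 0, hypha_no_bud = 0,
                                           budding = 1),
                           min_segment_um = 0.4, seed = 1L) {
  stopifnot(n_cells >= 1, kink_count_mean >= 0, deflection_sigma_deg >= 0,
            length(hypha_length_um) == 2, all(hypha_length_um[1] > 0),
            body_length_um > 0, body_width_um > 0, hypha_width_um > 0,
            bud_diameter_um > 0, min_segment_um > 0,
            length(stage_probs) == 3, sum(stage_probs) > 0)
  structure(list(
    name = name, n_cells = as.integer(n_cells),
    kink_count_mean = kink_count_mean,
    deflection_sigma_deg = deflection_sigma_deg,
    hypha_length_um = unname(hypha_length_um),
    body_length_um = body_length_um, body_width_um = body_width_um,
    hypha_width_um = hypha_width_um, bud_diameter_um = bud_diameter_um,
    peak_offsets_um = peak_offsets_um,
    stage_probs = stage_probs / sum(stage_probs),
    min_segment_um = min_segment_um,
    seed = as.integer(seed)
  ), class = "phenotype_spec")
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat(sprintf("<phenotype_spec> %s: n=%d, sigma=%g deg, kinks~Pois(%g), seed=%d\n",
              x$name, x$n_cells, x$deflection_sigma_deg, x$kink_count_mean,
              x$seed))
  invisible(x)
}

rotate2 <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

## Half-normal deflection, truncated below 180 degrees.
r_deflection <- function(n, sigma) {
  if (sigma == 0 || n == 0) return(rep(0, n))
  x <- abs(stats::rnorm(n, 0, sigma))
  while (any(x >= 180)) {
    bad <- x >= 180
    x[bad] <- abs(stats::rnorm(sum(bad), 0, sigma))
  }
  x
}

#' Generate ground-truthed synthetic cells
#'
#' Builds the medial-axis geometry of `spec$n_cells` cells: a straight body
#' long axis in a uniformly random orientation, a polar hypha whose emergence
#' angle and kink angles are half-normal draws of scale
#' `deflection_sigma_deg` with random turn direction, kink positions
#' partitioning the hyphal length with a minimum segment length, and (for
#' budding cells) a bud path continuing from the hyphal tip. The analytic
#' deformity score of each cell is computed with [deformity_set()] from the
#' generating angles, so generator truth and the measurement formula agree
#' exactly on the noiseless polylines.
#'
#' Geometries that cannot accommodate the drawn kink count are redrawn, with
#' an error after 100 retries.
#'
#' @param spec A [phenotype_spec()].
#' @param min_kink_deg Kink-visibility threshold shared with the analysis
#'   (default 10 degrees): drawn deflections below it are sub-resolution
#'   wiggles, not kinks, and are excluded from the analytic score exactly
#'   as [detect_kinks()] excludes them from the measured score. The
#'   emergence angle is always counted, whatever its size.
#' @return List of class `synthetic_cells` with elements `cells` (list of
#'   [cell_record()]s), `truth` (data frame: per-cell stage, junction angle,
#'   all drawn kink angles, analytic `d_h`, hyphal length, true per-channel
#'   peak-to-tip distances, seed), and `spec`.
#' @export
generate_cells <- function(spec, min_kink_deg = 10) {
  stopifnot(inherits(spec, "phenotype_spec"))
  set.seed(spec$seed)
  stages <- c("no_hypha", "hypha_no_bud", "budding")
  cells <- vector("list", spec$n_cells)
  rows <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    stage <- sample(stages, 1, prob = spec$stage_probs)
    theta <- stats::runif(1, 0, 360)
    u <- rotate2(c(1, 0), theta)
    pole0 <- -u * spec$body_length_um
    pole1 <- c(0, 0)
    body <- polyline_trace(rbind(pole0, pole1), "body_axis")
    id <- sprintf("%s_%04d", spec$name, i)
    if (stage == "no_hypha") {
      cells[[i]] <- cell_record(id, body)
      rows[[i]] <- data.frame(
        cell_id = id, stage = stage, junction_deg = NA_real_,
        kink_degs = NA_character_, n_kinks = NA_integer_, d_h = NA_real_,
        hypha_length_um = NA_real_,
        cell_length_um = cells[[i]]$cell_length_um, stringsAsFactors = FALSE)
      next
    }
    ok <- FALSE
    for (try in seq_len(100L)) {
      L <- stats::rnorm(1, spec$hypha_length_um[1], spec$hypha_length_um[2])
      k <- stats::rpois(1, spec$kink_count_mean)
      if (L >= (k + 1) * spec$min_segment_um && L > 0) { ok <- TRUE; break }
    }
    if (!ok) stop("impossible geometry: hypha cannot accommodate the drawn kink count after 100 retries")
    # kink arc positions with minimum spacing, by sorting uniform draws
    if (k > 0) {
      for (try in seq_len(100L)) {
        pos <- sort(stats::runif(k, spec$min_segment_um, L - spec$min_segment_um))
        if (k == 1 || min(diff(pos)) >= spec$min_segment_um) break
        if (try == 100L) pos <- seq_len(k) * L / (k + 1)
      }
    } else pos <- numeric()
    junction <- r_deflection(1, spec$deflection_sigma_deg)
    kinks <- r_deflection(k, spec$deflection_sigma_deg)
    signs <- sample(c(-1, 1), k + 1, replace = TRUE)
    dir <- rotate2(u, signs[1] * junction)
    verts <- matrix(NA_real_, k + 2, 2)
    verts[1, ] <- pole1
    seg_len <- diff(c(0, pos, L))
    cur <- pole1
    for (j in seq_len(k + 1)) {
      cur <- cur + dir * seg_len[j]
      verts[j + 1, ] <- cur
      if (j <= k) dir <- rotate2(dir, signs[j + 1] * kinks[j])
    }
    hypha <- polyline_trace(verts, "hypha")
    bud <- NULL
    if (stage == "budding") {
      tip <- verts[k + 2, ]
      bud <- polyline_trace(rbind(tip, tip + dir * spec$bud_diameter_um),
                            "bud_path")
    }
    cells[[i]] <- cell_record(id, body, list(hypha), bud_path = bud)
    ds <- deformity_set(junction, kinks[kinks >= min_kink_deg])
    rows[[i]] <- data.frame(
      cell_id = id, stage = stage, junction_deg = junction,
      kink_degs = paste(sprintf("%.6g", kinks), collapse = ";"),
      n_kinks = k, d_h = ds$d_h, hypha_length_um = L,
      cell_length_um = cells[[i]]$cell_length_um, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  for (ch in names(spec$peak_offsets_um)) {
    truth[[paste0("peak_offset_", ch, "_um")]] <-
      ifelse(truth$stage == "no_hypha", NA_real_, spec$peak_offsets_um[[ch]])
  }
  truth$seed <- spec$seed
  structure(list(cells = cells, truth = truth, spec = spec),
            class = "synthetic_cells")
}

#' @export
print.synthetic_cells <- function(x, ...) {
  cat(sprintf("<synthetic_cells> %s: %d cells (seed %d), mean analytic d_h = %.3f\n",
              x$spec$name, length(x$cells), x$spec$seed,
              mean(x$truth$d_h, na.rm = TRUE)))
  invisible(x)
}

#' Draw deformity scores directly from a phenotype model
#'
#' Samples analytic deformity scores without constructing polylines:
#' kink count ~ Poisson, each angle half-normal of scale `sigma`, score =
#' mean sine over the emergence angle and the kinks at or above the
#' visibility threshold. Distributionally identical to the `d_h` truth of
#' [generate_cells()]; used for large statistical power and calibration
#' simulations.
#'
#' @param n Number of hyphae.
#' @param deflection_sigma_deg Half-normal scale, degrees.
#' @param kink_count_mean Poisson mean kink count.
#' @param min_kink_deg Kink-visibility threshold, see [generate_cells()].
#' @return Numeric vector of `n` deformity scores in \[0, 1\].
#' @export
simulate_deformity_values <- function(n, deflection_sigma_deg,
                                      kink_count_mean = 2,
                                      min_kink_deg = 10) {
  k <- stats::rpois(n, kink_count_mean)
  junction <- r_deflection(n, deflection_sigma_deg)
  kinks <- r_deflection(sum(k), deflection_sigma_deg)
  grp <- rep.int(seq_len(n), k)
  vis <- kinks >= min_kink_deg
  ssum <- rep(0, n); cnt <- rep(0L, n)
  if (any(vis)) {
    agg <- tapply(sin(kinks[vis] * pi / 180), grp[vis], sum)
    idx <- as.integer(names(agg))
    ssum[idx] <- agg
    cnt[idx] <- as.integer(tapply(vis[vis], grp[vis], length))
  }
  (sin(junction * pi / 180) + ssum) / (1L + cnt)
}

#' Synthesize fluorescence profiles directly on cell geometry
#'
#' Attaches per-channel intensity profiles to synthetic cells without
#' rasterization: a uniform cytoplasmic baseline plus a Gaussian peak of
#' width `peak_sigma_um` centered at the channel's true arc offset from the
#' distal tip, with additive Gaussian noise scaled to the requested
#' signal-to-noise ratio (peak amplitude / noise SD).
#'
#' @param sim A `synthetic_cells` object from [generate_cells()].
#' @param sample_step_um Profile sampling step (default 0.05).
#' @param snr Signal-to-noise ratio (default 10); `Inf` for noiseless.
#' @param peak_sigma_um Peak width (default 0.15).
#' @param baseline,amplitude Baseline and peak amplitude intensities.
#' @return The `synthetic_cells` object with profiles filled in.
#' @export
synthesize_profiles <- function(sim, sample_step_um = 0.05, snr = 10,
                                peak_sigma_um = 0.15, baseline = 1,
                                amplitude = 5) {
  stopifnot(inherits(sim, "synthetic_cells"))
  offsets <- sim$spec$peak_offsets_um
  noise_sd <- if (is.finite(snr)) amplitude / snr else 0
  sim$cells <- lapply(sim$cells, function(cell) {
    len <- cell$cell_length_um
    s <- seq(0, len, by = sample_step_um)
    profs <- lapply(names(offsets), function(ch) {
      p <- rep(baseline, length(s))
      if (length(cell$hyphae)) {
        p <- p + amplitude * exp(-(s - (len - offsets[[ch]]))^2 /
                                   (2 * peak_sigma_um^2))
      }
      p + stats::rnorm(length(s), 0, noise_sd)
    })
    names(profs) <- names(offsets)
    cell$profiles <- profs
    cell$profile_step_um <- sample_step_um
    cell
  })
  sim
}
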