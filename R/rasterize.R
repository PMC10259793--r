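## Rasterization of synthetic cells into intensity images and label masks.

## Minimum distance from grid points to a polyline (vectorized per segment).
## xx, yy: pixel-center coordinates in um. pts: polyline matrix.
dist_to_polyline <- function(xx, yy, pts) {
  nx <- length(xx); ny <- length(yy)
  X <- matrix(xx, ny, nx, byrow = TRUE)
  Y <- matrix(yy, ny, nx)
  d2 <- matrix(Inf, ny, nx)
  for (j in seq_len(nrow(pts) - 1L)) {
    a <- pts[j, ]; b <- pts[j + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2
    t[t < 0] <- 0; t[t > 1] <- 1
    dx <- X - (a[1] + t * ab[1])
    dy <- Y - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

## Bounding box (um) of a cell's geometry including tube radii.
cell_bbox <- function(cell, spec) {
  pts <- as.matrix(cell$body_axis)
  if (length(cell$hyphae)) {
    pts <- rbind(pts, do.call(rbind, lapply(cell$hyphae, as.matrix)))
  }
  if (cell$has_bud) pts <- rbind(pts, as.matrix(cell$bud_path))
  r <- max(spec$body_width_um, spec$bud_diameter_um) / 2
  c(xmin = min(pts[, 1]) - r, xmax = max(pts[, 1]) + r,
    ymin = min(pts[, 2]) - r, ymax = max(pts[, 2]) + r)
}

#' Rasterize synthetic cells into micrograph-like images
#'
#' Places the cells of a [generate_cells()] population at non-overlapping
#' random positions in a common field, draws the cell body, hypha and bud as
#' tubes/discs of the specified widths, adds one Gaussian fluorescence spot
#' per channel at the channel's true arc offset from the hyphal tip,
#' convolves with a Gaussian point-spread function, and corrupts with
#' signal-dependent (Poisson) and additive Gaussian noise. The label mask is
#' the noiseless tube support.
#'
#' Placement is rejection-sampled with a margin; if a cell cannot be placed
#' after `max_tries` attempts the field is enlarged and placement continues.
#'
#' @param sim A `synthetic_cells` object.
#' @param pixel_size_um Pixel size (default 0.065, a typical 100x camera
#'   sampling).
#' @param psf_sigma_um Gaussian PSF sigma (default 0.1); 0 disables blur.
#' @param gaussian_sd Additive read-noise SD in intensity units (default 4).
#' @param poisson_scale Photon scaling of shot noise; 0 disables (default 1:
#'   intensities are treated as photon counts).
#' @param background Constant background level (default 20).
#' @param tube_intensity Cytoplasmic tube intensity above background
#'   (default 60).
#' @param peak_amplitude Fluorescence spot amplitude (default 200).
#' @param peak_sigma_um Spot sigma before PSF (default 0.1).
#' @param margin_um Placement margin between cell bounding boxes
#'   (default 0.7).
#' @param max_tries Placement attempts per cell before the field is
#'   enlarged (default 100).
#' @return List of class `synthetic_field`: `images` (named list of
#'   intensity matrices, one per channel), `mask` (integer label matrix;
#'   label i is cell i), `cells` (cell records translated to field
#'   coordinates), `truth`, `pixel_size_um`, `spec`.
#' @export
rasterize_cells <- function(sim, pixel_size_um = 0.065, psf_sigma_um = 0.1,
                            gaussian_sd = 4, poisson_scale = 1,
                            background = 20, tube_intensity = 60,
                            peak_amplitude = 200, peak_sigma_um = 0.1,
                            margin_um = 0.7, max_tries = 100L) {
  stopifnot(inherits(sim, "synthetic_cells"), pixel_size_um > 0,
            psf_sigma_um >= 0)
  spec <- sim$spec
  cells <- sim$cells
  n <- length(cells)
  set.seed(spec$seed + 1000003L)

  boxes <- t(vapply(cells, cell_bbox, numeric(4), spec = spec))
  bw <- boxes[, "xmax"] - boxes[, "xmin"]
  bh <- boxes[, "ymax"] - boxes[, "ymin"]
  # field sized for ~4x the summed padded box area
  side <- sqrt(4 * sum((bw + margin_um) * (bh + margin_um)))
  placed <- matrix(NA_real_, n, 4)
  shifts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    repeat {
      done <- FALSE
      for (try in seq_len(max_tries)) {
        ox <- stats::runif(1, margin_um, side - bw[i] - margin_um)
        oy <- stats::runif(1, margin_um, side - bh[i] - margin_um)
        box <- c(ox, ox + bw[i], oy, oy + bh[i])
        if (i == 1L || !any(
          box[1] < placed[seq_len(i - 1), 2] + margin_um &
          box[2] > placed[seq_len(i - 1), 1] - margin_um &
          box[3] < placed[seq_len(i - 1), 4] + margin_um &
          box[4] > placed[seq_len(i - 1), 3] - margin_um, na.rm = TRUE)) {
          placed[i, ] <- box
          shifts[i, ] <- c(ox - boxes[i, "xmin"], oy - boxes[i, "ymin"])
          done <- TRUE
          break
        }
      }
      if (done) break
      side <- side * 1.3
    }
  }

  nxy <- ceiling(side / pixel_size_um) + 1L
  mask <- matrix(0L, nxy, nxy)  # [row = y, col = x]
  channels <- names(spec$peak_offsets_um)
  imgs <- stats::setNames(
    lapply(channels, function(ch) matrix(background, nxy, nxy)), channels)

  shift_trace <- function(tr, sh) {
    polyline_trace(sweep(as.matrix(tr), 2, -sh), role = trace_role(tr))
  }
  placed_cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- cells[[i]]
    sh <- shifts[i, ]
    body <- shift_trace(cell$body_axis, sh)
    hyphae <- lapply(cell$hyphae, shift_trace, sh = sh)
    bud <- if (cell$has_bud) shift_trace(cell$bud_path, sh) else NULL
    placed_cells[[i]] <- cell_record(cell$id, body, hyphae, bud_path = bud,
                                     stage = cell$stage)
    # crop grid for this cell
    x0 <- max(0L, floor((placed[i, 1] - margin_um / 2) / pixel_size_um))
    x1 <- min(nxy - 1L, ceiling((placed[i, 2] + margin_um / 2) / pixel_size_um))
    y0 <- max(0L, floor((placed[i, 3] - margin_um / 2) / pixel_size_um))
    y1 <- min(nxy - 1L, ceiling((placed[i, 4] + margin_um / 2) / pixel_size_um))
    xx <- (x0:x1) * pixel_size_um
    yy <- (y0:y1) * pixel_size_um
    # the body capsule surface passes through the axis poles: draw the
    # tube along the axis shrunk by one half-width at each end
    bp <- as.matrix(body)
    nb <- nrow(bp)
    rb <- spec$body_width_um / 2
    if (arc_length(bp) > 2 * rb) {
      u1 <- bp[2, ] - bp[1, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- bp[nb, ] - bp[nb - 1, ]; u2 <- u2 / sqrt(sum(u2^2))
      bp[1, ] <- bp[1, ] + u1 * rb
      bp[nb, ] <- bp[nb, ] - u2 * rb
    } else {
      bp <- rbind(colMeans(bp[c(1, nb), ]), colMeans(bp[c(1, nb), ]) + 1e-6)
    }
    d_body <- dist_to_polyline(xx, yy, bp)
    inside <- d_body <= spec$body_width_um / 2
    if (length(hyphae)) {
      for (h in hyphae) {
        inside <- inside |
          (dist_to_polyline(xx, yy, as.matrix(h)) <= spec$hypha_width_um / 2)
      }
    }
    if (!is.null(bud)) {
      ctr <- colMeans(as.matrix(bud))
      X <- matrix(xx, length(yy), length(xx), byrow = TRUE)
      Y <- matrix(yy, length(yy), length(xx))
      inside <- inside |
        ((X - ctr[1])^2 + (Y - ctr[2])^2 <= (spec$bud_diameter_um / 2)^2)
    }
    rows <- (y0:y1) + 1L; colsx <- (x0:x1) + 1L
    sub <- mask[rows, colsx]
    sub[inside] <- i
    mask[rows, colsx] <- sub
    # fluorescence: tube intensity plus channel peaks
    tip_path <- NULL
    if (length(hyphae)) {
      tip_path <- as.matrix(hyphae[[1]])
      if (!is.null(bud)) tip_path <- rbind(tip_path, as.matrix(bud)[-1, , drop = FALSE])
    }
    for (ch in channels) {
      add <- matrix(0, length(yy), length(xx))
      add[inside] <- tube_intensity
      if (!is.null(tip_path)) {
        s <- arc_positions(tip_path)
        target <- max(0, s[length(s)] - spec$peak_offsets_um[[ch]])
        px <- stats::approx(s, tip_path[, 1], xout = target)$y
        py <- stats::approx(s, tip_path[, 2], xout = target)$y
        X <- matrix(xx, length(yy), length(xx), byrow = TRUE)
        Y <- matrix(yy, length(yy), length(xx))
        add <- add + peak_amplitude *
          exp(-((X - px)^2 + (Y - py)^2) / (2 * peak_sigma_um^2))
      }
      imgs[[ch]][rows, colsx] <- imgs[[ch]][rows, colsx] + add
    }
  }

  for (ch in channels) {
    im <- imgs[[ch]]
    if (psf_sigma_um > 0) {
      im <- t(as.matrix(EBImage::gblur(EBImage::Image(t(im)),
                                       sigma = psf_sigma_um / pixel_size_um)))
    }
    if (poisson_scale > 0) {
      im <- stats::rpois(length(im), pmax(im, 0) * poisson_scale) / poisson_scale
      im <- matrix(im, nxy, nxy)
    }
    if (gaussian_sd > 0) {
      im <- im + stats::rnorm(length(im), 0, gaussian_sd)
    }
    imgs[[ch]] <- im
  }

  structure(list(images = imgs, mask = mask, cells = placed_cells,
                 truth = sim$truth, pixel_size_um = pixel_size_um,
                 spec = spec),
            class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %d cells, %dx%d px at %.3f um/px, channels: %s\n",
              length(x$cells), nrow(x$mask), ncol(x$mask), x$pixel_size_um,
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}

#' Estimate image signal-to-noise ratio
#'
#' Mean background-subtracted signal inside the mask divided by the standard
#' deviation of the background outside it.
#'
#' @param image Intensity matrix.
#' @param mask Label matrix of the same dimensions.
#' @return Scalar SNR.
#' @export
snr_estimate <- function(image, mask) {
  bg <- image[mask == 0]
  fg <- image[mask > 0]
  (mean(fg) - mean(bg)) / stats::sd(bg)
}

#' Read and write single-channel TIFF images
#'
#' Images are stored as 16-bit grayscale TIFF with a fixed intensity scale
#' of 1 unit per 1/65535, i.e. values are divided by 65535 on write and
#' multiplied back on read; label masks round-trip exactly for labels up to
#' 65535.
#'
#' @param image Numeric matrix (`[row, col]`), values in \[0, 65535\].
#' @param path File path.
#' @export
write_image_tiff <- function(image, path) {
  m <- pmin(pmax(image, 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param integer_labels Round to integers on read (for label masks).
#' @export
read_image_tiff <- function(path, integer_labels = FALSE) {
  m <- tiff::readTIFF(path) * 65535
  if (integer_labels) m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  m
}
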