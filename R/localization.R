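#' Build a demograph from per-cell fluorescence profiles
#'
#' A demograph stacks per-cell normalized intensity profiles as the rows of
#' a matrix, sorted ascending by cell length, with columns binning arc
#' length from the non-hyphal body pole. Each profile is min-max normalized
#' per cell (constant profiles map to all zeros), so within-cell
#' localization patterns are preserved while absolute brightness is
#' discarded. Rows occupy exactly `ceiling(length / bin_step)` leading bins;
#' the rest are `NA`.
#'
#' @param cells List of [cell_record()]s with profiles.
#' @param stage Stage group to include: `"no_hypha"`, `"hypha_no_bud"` or
#'   `"budding"`.
#' @param channel Profile channel name.
#' @param bin_step_um Arc-length bin width (default 0.05).
#' @return Object of class `demograph`: list with `matrix` (rows = cells,
#'   sorted by length), `cell_lengths_um`, `bin_step_um`, `stage`,
#'   `channel`, `cell_ids`, and `bin_centers_um`.
#' @export
build_demograph <- function(cells, stage, channel, bin_step_um = 0.05) {
  stage <- match.arg(stage, c("no_hypha", "hypha_no_bud", "budding"))
  stopifnot(bin_step_um > 0)
  sel <- Filter(function(cell) {
    cell$stage == stage && !is.null(cell$profiles) &&
      channel %in% names(cell$profiles)
  }, cells)
  if (length(sel) == 0L) {
    stop(sprintf("empty group: no cells of stage `%s` with channel `%s` profiles",
                 stage, channel))
  }
  lens <- vapply(sel, function(cell) cell$cell_length_um, numeric(1))
  ord <- order(lens)
  sel <- sel[ord]; lens <- lens[ord]
  nbin <- ceiling(max(lens) / bin_step_um)
  centers <- (seq_len(nbin) - 0.5) * bin_step_um
  mat <- matrix(NA_real_, length(sel), nbin)
  for (i in seq_along(sel)) {
    cell <- sel[[i]]
    p <- cell$profiles[[channel]]
    s <- (seq_along(p) - 1) * cell$profile_step_um
    occ <- ceiling(lens[i] / bin_step_um)
    v <- stats::approx(s, p, xout = centers[seq_len(occ)], rule = 2)$y
    rng <- range(v)
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
    mat[i, seq_len(occ)] <- v
  }
  structure(list(matrix = mat, cell_lengths_um = lens,
                 bin_step_um = bin_step_um, bin_centers_um = centers,
                 stage = stage, channel = channel,
                 cell_ids = vapply(sel, function(cell) as.character(cell$id),
                                   character(1))),
            class = "demograph")
}

#' @export
print.demograph <- function(x, ...) {
  cat(sprintf("<demograph> stage=%s channel=%s: %d cells x %d bins (%.3f um), lengths %.2f-%.2f um\n",
              x$stage, x$channel, nrow(x$matrix), ncol(x$matrix),
              x$bin_step_um, min(x$cell_lengths_um), max(x$cell_lengths_um)))
  invisible(x)
}

#' @export
#' @rdname build_demograph
#' @param x A `demograph`.
#' @param col Color palette.
#' @param ... Further arguments to [graphics::image()].
plot.demograph <- function(x, col = grDevices::hcl.colors(64, "viridis"), ...) {
  m <- x$matrix
  graphics::image(x = x$bin_centers_um, y = seq_len(nrow(m)), z = t(m),
                  col = col, xlab = "arc length from non-hyphal pole (um)",
                  ylab = "cells (sorted by length)",
                  main = sprintf("%s / %s", x$stage, x$channel), ...)
  invisible(x)
}

#' Write a demograph matrix to CSV
#'
#' Dense matrix CSV with a header row of bin centers (micrometres) and a
#' sidecar YAML file of metadata (stage, channel, bin step, cell ids).
#'
#' @param dg A [build_demograph()] result.
#' @param path CSV output path; the sidecar is `<path>.meta.yaml`.
#' @export
write_demograph_csv <- function(dg, path) {
  m <- dg$matrix
  colnames(m) <- sprintf("%.4f", dg$bin_centers_um)
  df <- data.frame(cell_id = dg$cell_ids,
                   cell_length_um = dg$cell_lengths_um, m,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(stage = dg$stage, channel = dg$channel,
                        bin_step_um = dg$bin_step_um,
                        n_cells = nrow(dg$matrix)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Distance of the fluorescence peak from the hyphal tip
#'
#' The profile is restricted to the hypha (plus bud) segment, smoothed with
#' a moving average of window `window_um`, and the arc position of its
#' maximum located; the reported distance is tip position minus peak
#' position, with ties broken toward the tip. A distance of 0 means the
#' signal peaks terminally at the hyphal tip; positive values mean
#' subterminal localization.
#'
#' @param cell A [cell_record()] with at least one hypha and a profile for
#'   `channel`.
#' @param channel Profile channel name.
#' @param window_um Moving-average smoothing window (default 0.15); 0
#'   disables smoothing.
#' @param include_bud Include the bud segment in the search (default TRUE).
#' @return List of class `peak_distance` with `cell_id`, `channel`,
#'   `distance_um`, `peak_arc_um`, `tip_arc_um`.
#' @export
peak_to_tip <- function(cell, channel, window_um = 0.15, include_bud = TRUE) {
  stopifnot(inherits(cell, "cell_record"))
  if (length(cell$hyphae) == 0L) {
    stop(sprintf("ineligible cell %s: no hypha", cell$id))
  }
  if (is.null(cell$profiles) || !channel %in% names(cell$profiles)) {
    stop(sprintf("cell %s has no profile for channel `%s`", cell$id, channel))
  }
  p <- cell$profiles[[channel]]
  step <- cell$profile_step_um
  s <- (seq_along(p) - 1) * step
  body_len <- arc_length(cell$body_axis)
  # the tip is the geometric end of the path, which can lie up to one
  # sampling step beyond the last profile sample
  end_arc <- if (include_bud || !cell$has_bud) {
    cell$cell_length_um
  } else {
    body_len + arc_length(cell$hyphae[[1]])
  }
  w <- max(1L, round(window_um / step))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- if (w > 1L) {
    as.numeric(stats::filter(p, rep(1 / w, w), sides = 2))
  } else p
  # shrink the window at the edges instead of dropping samples
  h <- w %/% 2L
  for (i in which(is.na(sm))) {
    k <- min(h, i - 1L, length(p) - i)
    sm[i] <- mean(p[(i - k):(i + k)])
  }
  idx <- which(s >= body_len & s <= end_arc)
  if (length(idx) == 0L) idx <- length(p)
  v <- sm[idx]
  peak_i <- idx[length(v) - which.max(rev(v)) + 1L]  # ties toward the tip
  peak_arc <- s[peak_i]
  # sub-sample refinement: parabola through the three samples at the peak
  if (peak_i > idx[1] && peak_i < idx[length(idx)]) {
    y0 <- sm[peak_i - 1L]; y1 <- sm[peak_i]; y2 <- sm[peak_i + 1L]
    den <- y0 - 2 * y1 + y2
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (y0 - y2) / den
      peak_arc <- peak_arc + max(-0.5, min(0.5, delta)) * step
    }
  }
  structure(list(cell_id = as.character(cell$id), channel = channel,
                 distance_um = max(0, end_arc - peak_arc),
                 peak_arc_um = peak_arc, tip_arc_um = end_arc),
            class = "peak_distance")
}

#' Peak-to-tip distances for many cells and channels
#'
#' @param cells List of [cell_record()]s.
#' @param channels Channel names; default: all channels of the first cell
#'   with profiles.
#' @inheritParams peak_to_tip
#' @return Data frame `cell_id`, `channel`, `distance_um` (one row per
#'   eligible cell x channel; ineligible cells are omitted).
#' @export
peak_distance_table <- function(cells, channels = NULL, window_um = 0.15,
                                include_bud = TRUE) {
  if (is.null(channels)) {
    withp <- Filter(function(cell) !is.null(cell$profiles), cells)
    if (!length(withp)) stop("no cells with profiles")
    channels <- names(withp[[1]]$profiles)
  }
  rows <- list()
  for (cell in cells) {
    if (length(cell$hyphae) == 0L || is.null(cell$profiles)) next
    for (ch in channels) {
      pd <- peak_to_tip(cell, ch, window_um, include_bud)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = pd$cell_id, channel = ch, distance_um = pd$distance_um,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no eligible cells")
  do.call(rbind, rows)
}

#' Paired between-channel peak-offset comparison
#'
#' For cells measured in both channels, summarizes the per-cell difference
#' of peak-to-tip distances (channel_b minus channel_a). Because both
#' channels share the same cell geometry, tip-position errors cancel in the
#' paired difference.
#'
#' @param dist_table Output of [peak_distance_table()].
#' @param channel_a,channel_b Channel names.
#' @return List with the per-cell `differences_um`, `median_offset_um`,
#'   `median_a_um`, `median_b_um`, and `n`.
#' @export
paired_peak_offsets <- function(dist_table, channel_a, channel_b) {
  a <- dist_table[dist_table$channel == channel_a, ]
  b <- dist_table[dist_table$channel == channel_b, ]
  common <- intersect(a$cell_id, b$cell_id)
  if (!length(common)) stop("no cells measured in both channels")
  da <- a$distance_um[match(common, a$cell_id)]
  db <- b$distance_um[match(common, b$cell_id)]
  list(differences_um = db - da,
       median_offset_um = stats::median(db - da),
       median_a_um = stats::median(da),
       median_b_um = stats::median(db),
       n = length(common))
}
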