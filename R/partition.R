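## Partition a skeletonized cell into body / hypha / bud using the local
## width profile from the distance transform, and sample fluorescence
## profiles along the resulting medial path.

## Moving-average smoothing of path coordinates with shrinking windows at
## the ends; removes the pixel staircase of thinned skeletons.
smooth_path <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n < 3L || window < 3L) return(pts)
  h <- window %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    if (k > 0L) out[i, ] <- colMeans(pts[(i - k):(i + k), , drop = FALSE])
  }
  out
}

## Contiguous runs of a logical vector; matrix with cols start, end.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Partition a skeleton into body, hypha and bud traces
#'
#' The widest long region of the skeleton's width profile (local width >=
#' `body_width_ratio` x maximum width) is the cell body; thin terminal paths
#' are hyphae; a terminal thick region at a hypha's distal end (width >=
#' `bud_width_ratio` x body width) is a nascent bud. Compartment boundaries
#' at width-threshold crossings are refined by a cap-radius correction: the
#' crossing sits inside the wide compartment's polar cap at a depth roughly
#' equal to the local half-width, so the boundary is shifted toward the thin
#' side by (half-width at crossing - hyphal half-width). Terminal skeleton
#' retraction is compensated by extending each end by its local half-width.
#'
#' A skeleton junction in the thin region marks a branched hypha; the cell
#' is retained with `branched = TRUE` (and is thereby excluded from
#' deformity measurement). Junction spurs inside the body shorter than the
#' local width are thinning artifacts and are absorbed.
#'
#' @param skel A [skeletonize_cell()] result.
#' @param body_width_ratio Body threshold as a fraction of the maximum local
#'   width (default 0.6).
#' @param bud_width_ratio Bud threshold as a fraction of the body width
#'   (default 0.5).
#' @param min_hypha_um Minimum arc length for a thin tail to count as a
#'   hypha (default 0.3).
#' @param min_bud_um Minimum arc length of a terminal thick run to count as
#'   a bud (default 0.1).
#' @param smooth_window Pixel window of the path coordinate smoother
#'   (default 5).
#' @param simplify_tol_um Tolerance forwarded to trace bookkeeping.
#' @param id Cell identifier for the resulting record.
#' @return A [cell_record()] (with `exclusion_reason` set when the topology
#'   is ambiguous or the component touched the image border).
#' @export
partition_cell <- function(skel, body_width_ratio = 0.6, bud_width_ratio = 0.5,
                           min_hypha_um = 0.3, min_bud_um = 0.1,
                           smooth_window = 5L, simplify_tol_um = 0.05,
                           id = "cell") {
  stopifnot(inherits(skel, "skeleton_graph"))
  px_um <- skel$pixel_size_um
  path_rc <- main_skeleton_path(skel$sk)
  if (nrow(path_rc) < 4L) stop("degenerate skeleton path")
  # off-path skeleton structures that survived spur pruning: side branches
  # (in the thin region) or additional appendages (attached at the body)
  branched <- FALSE
  extra_branch <- FALSE
  maxw_all <- max(skel$width_um)
  comps <- off_path_components(skel$sk, path_rc)
  for (cmp in comps) {
    clen <- length(cmp$pixels) * px_um
    if (is.na(cmp$attach)) next
    attach_halfw <- skel$dist_um[cmp$attach]
    # spurs shorter than the local width are thinning artifacts of blunt or
    # irregular compartment ends; longer structures are real side branches
    if (clen < max(min_hypha_um, 2 * attach_halfw)) next
    if (2 * attach_halfw < body_width_ratio * maxw_all) {
      branched <- TRUE       # branch emerging from the thin hypha
    } else {
      extra_branch <- TRUE   # additional appendage at the cell body
    }
  }

  halfw <- skel$dist_um[path_rc]
  # crop-frame [row, col] -> full-image um coordinates (x, y)
  pts <- cbind((path_rc[, 2] - 1L + skel$offset["x"]),
               (path_rc[, 1] - 1L + skel$offset["y"])) * px_um
  colnames(pts) <- c("x_um", "y_um")
  pts <- smooth_path(pts, smooth_window)

  # compensate terminal skeleton retraction: extend ends by local half-width
  k <- min(5L, nrow(pts) - 1L)
  d1 <- pts[1, ] - pts[1 + k, ]
  d1 <- d1 / sqrt(sum(d1^2))
  d2 <- pts[nrow(pts), ] - pts[nrow(pts) - k, ]
  d2 <- d2 / sqrt(sum(d2^2))
  pts <- rbind(pts[1, ] + d1 * halfw[1], pts, pts[nrow(pts), ] + d2 * halfw[length(halfw)])
  halfw <- c(halfw[1], halfw, halfw[length(halfw)])

  s <- arc_positions(pts)
  w <- 2 * halfw
  maxw <- max(w)
  wide <- w >= body_width_ratio * maxw
  runs <- logical_runs(wide)
  if (nrow(runs) == 0) stop("no body region found")
  run_len <- s[runs[, 2]] - s[runs[, 1]]
  run_maxw <- vapply(seq_len(nrow(runs)),
                     function(i) max(w[runs[i, 1]:runs[i, 2]]), numeric(1))
  body_i <- which.max(run_len + 1e-9 * run_maxw)
  ambiguous <- sum(run_len >= 0.8 * run_len[body_i] &
                   run_maxw >= 0.9 * maxw) > 1L
  body_run <- runs[body_i, ]
  body_w <- run_maxw[body_i]

  classify_tail <- function(idx_range, from_body_idx) {
    # idx_range ordered body -> tip; the width-threshold crossing sits
    # inside the body's polar cap, so walk tipward until the local width
    # reaches the hyphal tube width (the cap surface)
    if (length(idx_range) < 2L) return(NULL)
    r_h <- stats::median(halfw[idx_range])
    cut <- max(1.2 * r_h, r_h + 0.03)
    first_thin <- which(halfw[idx_range] <= cut)
    if (!length(first_thin)) return(NULL)
    keep <- idx_range[first_thin[1]:length(idx_range)]
    if (length(keep) < 2L) return(NULL)
    if (abs(s[keep[length(keep)]] - s[keep[1]]) < min_hypha_um) return(NULL)
    keep
  }

  hyphae_idx <- list()
  if (body_run[1] > 1L) {
    tl <- classify_tail(seq(body_run[1] - 1L, 1L), body_run[1])
    if (!is.null(tl)) hyphae_idx[[length(hyphae_idx) + 1L]] <- tl
  }
  if (body_run[2] < length(w)) {
    tl <- classify_tail(seq(body_run[2] + 1L, length(w)), body_run[2])
    if (!is.null(tl)) hyphae_idx[[length(hyphae_idx) + 1L]] <- tl
  }

  # bud detection at the distal end of each tail; the neck is walked back
  # from the width-threshold crossing to the bud surface (local width down
  # at the hyphal tube width again)
  bud_of <- function(idx) {
    wt <- w[idx]
    thick <- wt >= bud_width_ratio * body_w
    if (!thick[length(thick)]) return(NULL)
    run <- rev(cumprod(rev(thick))) == 1
    hy <- idx[!run]
    r_h <- stats::median(halfw[hy %||% idx])
    neck_i <- which(run)[1]
    if (abs(s[idx[length(idx)]] - s[idx[neck_i]]) < min_bud_um) return(NULL)
    cut <- max(1.2 * r_h, r_h + 0.03)
    while (neck_i > 1L && halfw[idx[neck_i - 1L]] > cut) neck_i <- neck_i - 1L
    list(neck_arc = s[idx[neck_i]], tip_idx = idx[length(idx)])
  }

  mk_trace <- function(idx, role) {
    p <- pts[idx, , drop = FALSE]
    # drop duplicated consecutive points introduced by smoothing
    keep <- c(TRUE, rowSums(diff(p)^2) > 0)
    p <- p[keep, , drop = FALSE]
    if (nrow(p) < 2L) return(NULL)
    polyline_trace(p, role)
  }

  hyphae <- list(); bud_trace <- NULL
  primary_tail <- NULL
  if (length(hyphae_idx)) {
    lens <- vapply(hyphae_idx, function(ii) abs(s[ii[length(ii)]] - s[ii[1]]),
                   numeric(1))
    ord <- order(lens, decreasing = TRUE)
    hyphae_idx <- hyphae_idx[ord]
    primary_tail <- hyphae_idx[[1]]
    for (hi in seq_along(hyphae_idx)) {
      idx <- hyphae_idx[[hi]]
      bud <- if (hi == 1L) bud_of(idx) else NULL
      if (!is.null(bud)) {
        to_tip <- sign(s[idx[length(idx)]] - s[idx[1]])
        hyp_part <- idx[(s[idx] - bud$neck_arc) * to_tip <= 0]
        bud_part <- idx[(s[idx] - bud$neck_arc) * to_tip >= 0]
        tr <- mk_trace(hyp_part, "hypha")
        bt <- mk_trace(bud_part, "bud_path")
        if (!is.null(tr)) hyphae[[length(hyphae) + 1L]] <- tr
        bud_trace <- bt
      } else {
        tr <- mk_trace(idx, "hypha")
        if (!is.null(tr)) hyphae[[length(hyphae) + 1L]] <- tr
      }
    }
  }

  # body axis: everything that is not a tail, oriented toward the primary
  # hypha so that profile paths start at the non-hyphal pole
  tail_ids <- unlist(hyphae_idx)
  body_idx <- setdiff(seq_along(w), tail_ids)
  body_idx <- body_idx[order(s[body_idx])]
  if (length(primary_tail) && s[primary_tail[1]] < s[body_idx[1]]) {
    body_idx <- rev(body_idx)
  }
  body_trace <- mk_trace(body_idx, "body_axis")
  if (is.null(body_trace)) stop("degenerate body axis")

  excl <- NA_character_
  if (extra_branch) excl <- "second hypha or appendage at the cell body"
  if (ambiguous) excl <- "ambiguous topology: two near-equal wide regions"
  if (skel$border) excl <- "cell touches the image border"

  cell_record(id, body_axis = body_trace, hyphae = hyphae,
              bud_path = bud_trace, branched = branched,
              exclusion_reason = excl)
}

## Vectorized bilinear interpolation of an image matrix at 0-based pixel
## coordinates (x = col, y = row).
bilinear <- function(im, x, y) {
  nr <- nrow(im); nc <- ncol(im)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  im[i00] * (1 - fx) * (1 - fy) + im[i01] * fx * (1 - fy) +
    im[i10] * (1 - fx) * fy + im[i11] * fx * fy
}

#' Sample fluorescence intensity profiles along a cell's medial path
#'
#' Intensities are sampled along the concatenated medial path (non-hyphal
#' body pole -> body -> hypha -> bud) at uniform arc-length steps with
#' bilinear interpolation, averaged across a 3-pixel window perpendicular to
#' the path. All channels share the same geometry, so profiles have
#' identical length.
#'
#' @param images Named list of intensity matrices (`[row, col]`), one per
#'   channel; all of identical dimensions.
#' @param cell A [cell_record()] from [partition_cell()].
#' @param pixel_size_um Pixel size in micrometres.
#' @param sample_step_um Arc-length sampling step (default 0.05).
#' @param normal_halfwidth_px Half-width of the perpendicular averaging
#'   window in pixels (default 1, i.e. a 3-pixel window).
#' @return The cell record with `profiles` and `profile_step_um` filled and
#'   `cell_length_um` set to the sampled path length.
#' @export
extract_profiles <- function(images, cell, pixel_size_um,
                             sample_step_um = 0.05, normal_halfwidth_px = 1L) {
  stopifnot(inherits(cell, "cell_record"), length(images) >= 1L,
            sample_step_um > 0)
  if (is.null(names(images)) || any(names(images) == "")) {
    names(images) <- paste0("ch", seq_along(images))
  }
  path <- as.matrix(cell$body_axis)
  if (length(cell$hyphae)) {
    path <- rbind(path, as.matrix(cell$hyphae[[1]])[-1, , drop = FALSE])
  }
  if (cell$has_bud) {
    path <- rbind(path, as.matrix(cell$bud_path)[-1, , drop = FALSE])
  }
  rs <- resample_polyline(path, sample_step_um)
  n <- nrow(rs)
  # unit normals from central-difference tangents
  tx <- c(rs[2, 1] - rs[1, 1], rs[3:n, 1] - rs[1:(n - 2), 1],
          rs[n, 1] - rs[n - 1, 1])
  ty <- c(rs[2, 2] - rs[1, 2], rs[3:n, 2] - rs[1:(n - 2), 2],
          rs[n, 2] - rs[n - 1, 2])
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl; ny <- tx / tl
  im1 <- images[[1]]
  xr <- range(rs[, 1] / pixel_size_um)
  yr <- range(rs[, 2] / pixel_size_um)
  if (xr[1] < -0.5 || yr[1] < -0.5 || xr[2] > ncol(im1) - 0.5 ||
      yr[2] > nrow(im1) - 0.5) {
    stop(sprintf("cell %s: medial path exits the image bounds (truncated)", cell$id))
  }
  offs <- seq(-normal_halfwidth_px, normal_halfwidth_px)
  profiles <- lapply(images, function(im) {
    acc <- 0
    for (o in offs) {
      xs <- (rs[, 1] + o * nx * pixel_size_um) / pixel_size_um
      ys <- (rs[, 2] + o * ny * pixel_size_um) / pixel_size_um
      acc <- acc + bilinear(im, xs, ys)
    }
    acc / length(offs)
  })
  cell$profiles <- profiles
  cell$profile_step_um <- sample_step_um
  cell$cell_length_um <- arc_length(path)
  cell
}

#' Trace all cells of a labelled mask
#'
#' Runs [skeletonize_cell()], [partition_cell()] and (when intensity images
#' are supplied) [extract_profiles()] for every label of a mask, collecting
#' per-cell quality-control information so that no cell is silently dropped.
#'
#' @param mask Integer label matrix (0 = background).
#' @param images Optional named list of intensity matrices matching the mask
#'   dimensions.
#' @param pixel_size_um Pixel size in micrometres.
#' @param image_id Identifier prefix for cell ids.
#' @param ... Passed on to [skeletonize_cell()] and [partition_cell()]
#'   (e.g. `prune_len_um`, `body_width_ratio`, `bud_width_ratio`).
#' @param sample_step_um Profile sampling step.
#' @return List with `cells` (list of [cell_record()]s) and `qc` (data frame
#'   with label, area, stage, widths, and exclusion reason per cell).
#' @export
trace_cells <- function(mask, images = NULL, pixel_size_um = 0.065,
                        image_id = "img", sample_step_um = 0.05, ...) {
  dots <- list(...)
  skel_args <- dots[names(dots) %in% c("prune_len_um", "min_area_px")]
  part_args <- dots[names(dots) %in%
    c("body_width_ratio", "bud_width_ratio", "min_hypha_um", "min_bud_um",
      "smooth_window", "simplify_tol_um")]
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  cells <- list()
  qc <- list()
  for (lab in labels) {
    cid <- sprintf("%s_%04d", image_id, lab)
    area <- sum(mask == lab)
    res <- tryCatch({
      skel <- suppressWarnings(do.call(skeletonize_cell,
        c(list(mask = mask, label = lab, pixel_size_um = pixel_size_um),
          skel_args)))
      cell <- do.call(partition_cell, c(list(skel = skel, id = cid), part_args))
      if (!is.null(images)) {
        cell <- extract_profiles(images, cell, pixel_size_um,
                                 sample_step_um = sample_step_um)
      }
      cell
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "cell_record")) {
      cells[[length(cells) + 1L]] <- res
      qc[[length(qc) + 1L]] <- data.frame(
        cell_id = cid, label = lab, area_px = area, stage = res$stage,
        n_hyphae = length(res$hyphae), branched = res$branched,
        eligible = res$included_for_deformity,
        cell_length_um = res$cell_length_um,
        exclusion_reason = res$exclusion_reason, stringsAsFactors = FALSE)
    } else {
      qc[[length(qc) + 1L]] <- data.frame(
        cell_id = cid, label = lab, area_px = area, stage = NA_character_,
        n_hyphae = NA_integer_, branched = NA, eligible = FALSE,
        cell_length_um = NA_real_, exclusion_reason = res,
        stringsAsFactors = FALSE)
    }
  }
  list(cells = cells, qc = do.call(rbind, qc) %||%
         data.frame(cell_id = character()))
}
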