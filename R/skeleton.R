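## Binary image morphology: Zhang-Suen thinning and skeleton path helpers.
## Matrices are indexed [row, col] = [y + 1, x + 1] with 0-based pixel
## coordinates x = column, y = row, pixel centers at integer coordinates.

shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ys <- seq_len(nr) + dy
  xs <- seq_len(nc) + dx
  ok_y <- ys >= 1L & ys <= nr
  ok_x <- xs >= 1L & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Topological thinning of a binary mask
#'
#' Iterative two-subiteration (Zhang-Suen) thinning, producing a one-pixel
#' wide 8-connected skeleton that preserves the topology of the input
#' component.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same dimensions.
#' @export
thin_binary <- function(mask) {
  p <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: p2..p9
      p2 <- shift_mat(p, -1L, 0L); p3 <- shift_mat(p, -1L, 1L)
      p4 <- shift_mat(p, 0L, 1L);  p5 <- shift_mat(p, 1L, 1L)
      p6 <- shift_mat(p, 1L, 0L);  p7 <- shift_mat(p, 1L, -1L)
      p8 <- shift_mat(p, 0L, -1L); p9 <- shift_mat(p, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- p == 1L & b >= 2L & b <= 6L & a == 1L
      if (step == 1) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p == 1L
}

## Number of 8-connected skeleton neighbours of each skeleton pixel.
neighbour_counts <- function(sk) {
  s <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  n <- shift_mat(s, -1L, 0L) + shift_mat(s, -1L, 1L) + shift_mat(s, 0L, 1L) +
       shift_mat(s, 1L, 1L) + shift_mat(s, 1L, 0L) + shift_mat(s, 1L, -1L) +
       shift_mat(s, 0L, -1L) + shift_mat(s, -1L, -1L)
  n[!sk] <- 0L
  n
}

## Breadth-first search over skeleton pixels (8-connected) from a linear
## start index. The skeleton must not touch the matrix border. Returns
## integer vectors `dist` (hops, NA when unreachable) and `parent` (linear
## index) over the full matrix.
sk_bfs <- function(sk, start) {
  nr <- nrow(sk)
  n <- length(sk)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  queue <- integer(sum(sk))
  queue[1L] <- start
  dist[start] <- 0L
  head <- 1L; tail <- 1L
  while (head <= tail) {
    cur <- queue[head]; head <- head + 1L
    for (o in offs) {
      nb <- cur + o
      if (sk[nb] && is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        parent[nb] <- cur
        tail <- tail + 1L
        queue[tail] <- nb
      }
    }
  }
  list(dist = dist, parent = parent)
}

## Longest geodesic through the skeleton by BFS double sweep (the tree
## diameter heuristic). Returns an ordered [row, col] matrix of path pixels.
main_skeleton_path <- function(sk) {
  idx <- which(sk)
  if (length(idx) == 0L) stop("empty skeleton")
  if (length(idx) == 1L) {
    rc <- arrayInd(idx, dim(sk))
    return(rc)
  }
  b1 <- sk_bfs(sk, idx[1])
  a <- idx[which.max(b1$dist[idx])]
  b2 <- sk_bfs(sk, a)
  b <- idx[which.max(b2$dist[idx])]
  # reconstruct b -> a, then reverse
  path <- integer(b2$dist[b] + 1L)
  cur <- b
  for (i in seq_along(path)) {
    path[i] <- cur
    cur <- b2$parent[cur]
  }
  arrayInd(rev(path), dim(sk))
}

## Connected components (8-conn) of skeleton pixels off the main path.
## Returns a list of components, each with `pixels` (linear indices) and
## `attach` (linear index of a main-path pixel adjacent to the component,
## or NA).
off_path_components <- function(sk, path_rc) {
  on_path <- matrix(FALSE, nrow(sk), ncol(sk))
  on_path[path_rc] <- TRUE
  rem <- sk & !on_path
  idx <- which(rem)
  if (length(idx) == 0L) return(list())
  nr <- nrow(sk)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  seen <- rep(FALSE, length(sk))
  comps <- list()
  for (s0 in idx) {
    if (seen[s0]) next
    queue <- s0; seen[s0] <- TRUE
    pix <- integer(); attach <- NA_integer_
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      pix <- c(pix, cur)
      for (o in offs) {
        nb <- cur + o
        if (rem[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        } else if (on_path[nb] && is.na(attach)) {
          attach <- nb
        }
      }
    }
    comps[[length(comps) + 1L]] <- list(pixels = pix, attach = attach)
  }
  comps
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Skeletonize one labelled cell
#'
#' Extracts the component of `label` from a labelled mask, thins it to a
#' medial-axis skeleton, attaches per-pixel local width from the Euclidean
#' distance transform, and prunes side spurs shorter than `prune_len_um`
#' (thinning artifacts at tube caps and staircase corners).
#'
#' @param mask Integer label matrix (0 = background), or a `labeled_mask`.
#' @param label Positive integer label to extract.
#' @param pixel_size_um Pixel size in micrometres (default 0.065).
#' @param prune_len_um Spurs shorter than this are removed (default 0.2).
#' @param min_area_px Components smaller than this are rejected (default 20).
#' @return An object of class `skeleton_graph`: a list with `pixels`
#'   (n x 2 matrix of 0-based x/y pixel coordinates), `width_um` (local
#'   width at each skeleton pixel, twice the distance transform), `sk`
#'   (logical skeleton matrix in cropped frame), `path_rc` (ordered
#'   `[row, col]` pixels of the longest geodesic), `offset` (0-based x/y of
#'   the crop origin), `pixel_size_um`, `border` (TRUE if the component
#'   touches the image border), and `dist_um` (distance-transform matrix of
#'   the crop).
#' @export
skeletonize_cell <- function(mask, label, pixel_size_um = 0.065,
                             prune_len_um = 0.2, min_area_px = 20) {
  m <- as.matrix(mask)
  sel <- m == label
  if (!any(sel)) stop(sprintf("missing label: %d not present in mask", label))
  if (sum(sel) < min_area_px) {
    stop(sprintf("component %d smaller than the %d px minimum area", label, min_area_px))
  }
  ri <- which(sel, arr.ind = TRUE)
  border <- any(ri[, 1] == 1L | ri[, 1] == nrow(m) |
                ri[, 2] == 1L | ri[, 2] == ncol(m))
  if (border) {
    warning(sprintf("component %d touches the image border; flagged for exclusion", label))
  }
  pad <- 2L
  r0 <- min(ri[, 1]); r1 <- max(ri[, 1]); c0 <- min(ri[, 2]); c1 <- max(ri[, 2])
  crop <- matrix(FALSE, r1 - r0 + 1L + 2L * pad, c1 - c0 + 1L + 2L * pad)
  crop[pad + seq_len(r1 - r0 + 1L), pad + seq_len(c1 - c0 + 1L)] <-
    sel[r0:r1, c0:c1]
  dist_px <- t(as.matrix(EBImage::distmap(EBImage::Image(t(crop) * 1))))
  sk <- thin_binary(crop)
  path_rc <- main_skeleton_path(sk)
  # prune short side spurs; keep longer off-path structures (real branches)
  comps <- off_path_components(sk, path_rc)
  for (cmp in comps) {
    if (length(cmp$pixels) * pixel_size_um < prune_len_um) {
      sk[cmp$pixels] <- FALSE
    }
  }
  pix <- which(sk, arr.ind = TRUE)
  # 0-based full-image coordinates (x = col, y = row)
  x <- pix[, 2] - 1L - pad + (c0 - 1L)
  y <- pix[, 1] - 1L - pad + (r0 - 1L)
  structure(list(
    pixels = cbind(x = x, y = y),
    width_um = 2 * dist_px[pix] * pixel_size_um,
    sk = sk,
    path_rc = path_rc,
    dist_um = dist_px * pixel_size_um,
    offset = c(x = c0 - 1L - pad, y = r0 - 1L - pad),
    pixel_size_um = pixel_size_um,
    border = border
  ), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  nb <- neighbour_counts(x$sk)
  cat(sprintf("<skeleton_graph> %d px, %d terminal px, main path %d px, max width %.2f um\n",
              nrow(x$pixels), sum(nb[x$sk] == 1L), nrow(x$path_rc),
              max(x$width_um)))
  invisible(x)
}
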