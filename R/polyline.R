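#' Construct a polyline trace
#'
#' A polyline trace is an ordered sequence of planar points (in micrometres,
#' with y increasing downward to match image row order) describing one medial
#' axis segment of a cell: the cell-body long axis, a hypha, or the path
#' through a nascent bud.
#'
#' @param points Two-column numeric matrix (or data frame) of x/y coordinates
#'   in micrometres, at least two rows. Consecutive points must be distinct.
#' @param role One of `"body_axis"`, `"hypha"`, `"bud_path"`.
#' @return An object of class `polyline_trace`: the coordinate matrix with a
#'   `role` attribute.
#' @examples
#' tr <- polyline_trace(cbind(c(0, 3), c(0, 4)), "hypha")
#' arc_length(tr)  # 5
#' @export
polyline_trace <- function(points, role = c("hypha", "body_axis", "bud_path")) {
  role <- match.arg(role)
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L) {
    stop("`points` must be a two-column numeric matrix of x/y coordinates")
  }
  if (nrow(pts) < 2L) {
    stop("invalid trace: a polyline trace needs at least 2 points")
  }
  if (anyNA(pts) || any(!is.finite(pts))) {
    stop("invalid trace: coordinates must be finite")
  }
  seg <- diff(pts)
  if (any(rowSums(seg^2) == 0)) {
    stop("invalid trace: consecutive points must be distinct")
  }
  dimnames(pts) <- list(NULL, c("x_um", "y_um"))
  structure(pts, role = role, class = c("polyline_trace", "matrix", "array"))
}

#' @export
print.polyline_trace <- function(x, ...) {
  cat(sprintf("<polyline_trace> role=%s, %d points, arc length %.3f um\n",
              attr(x, "role"), nrow(x), arc_length(x)))
  invisible(x)
}

trace_role <- function(trace) attr(trace, "role")

#' Arc length of a polyline trace
#'
#' Sum of Euclidean segment lengths, in micrometres.
#'
#' @param trace A [polyline_trace()] or a two-column coordinate matrix with at
#'   least two rows.
#' @return Positive scalar, micrometres.
#' @export
arc_length <- function(trace) {
  pts <- as.matrix(trace)
  if (nrow(pts) < 2L) stop("invalid trace: need at least 2 points")
  sum(sqrt(rowSums(diff(pts)^2)))
}

## Cumulative arc position of each vertex (first vertex at 0).
arc_positions <- function(pts) {
  pts <- as.matrix(pts)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

#' Deflection (turn) angle at a vertex
#'
#' The angle between the incoming direction `p_prev -> p_vertex` and the
#' outgoing direction `p_vertex -> p_next`, i.e. the magnitude of the turn.
#' 0 degrees means the path continues collinearly; 180 degrees is a full
#' reversal. Computed through `atan2(|cross|, dot)` for stability near 0 and
#' 180 degrees.
#'
#' @param p_prev,p_vertex,p_next Numeric length-2 vectors (x, y).
#' @return Angle in degrees, in \[0, 180\].
#' @export
deflection_angle <- function(p_prev, p_vertex, p_next) {
  u <- as.numeric(p_vertex) - as.numeric(p_prev)
  v <- as.numeric(p_next) - as.numeric(p_vertex)
  angle_between(u, v)
}

## Angle between two direction vectors, degrees in [0, 180].
angle_between <- function(u, v) {
  if (sum(u^2) == 0 || sum(v^2) == 0) {
    stop("invalid geometry: coincident points give a zero direction vector")
  }
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  unname(atan2(abs(cross), dot) * 180 / pi)
}

#' Simplify a polyline by recursive maximum perpendicular deviation
#'
#' Ramer-Douglas-Peucker simplification: vertices whose perpendicular distance
#' from the chord of their enclosing span is below `tol_um` are dropped.
#' `tol_um = 0` keeps every vertex. Used to remove pixel-level jitter from
#' skeleton-derived traces before kink angles are measured.
#'
#' @param pts Two-column coordinate matrix.
#' @param tol_um Tolerance in micrometres, >= 0.
#' @return Logical vector marking the vertices kept.
#' @export
simplify_polyline <- function(pts, tol_um) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (tol_um < 0) stop("`tol_um` must be >= 0")
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  if (n <= 2L || tol_um == 0) {
    if (tol_um == 0) keep[] <- TRUE
    return(keep)
  }
  # iterative stack of (first, last) index spans
  stack <- list(c(1L, n))
  while (length(stack)) {
    span <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- span[1]; j <- span[2]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    idx <- (i + 1L):(j - 1L)
    rel <- sweep(pts[idx, , drop = FALSE], 2, a)
    if (len2 == 0) {
      d <- sqrt(rowSums(rel^2))
    } else {
      d <- abs(rel[, 1] * ab[2] - rel[, 2] * ab[1]) / sqrt(len2)
    }
    k <- which.max(d)
    if (d[k] > tol_um) {
      v <- idx[k]
      keep[v] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, v)
      stack[[length(stack) + 1L]] <- c(v, j)
    }
  }
  keep
}

#' Detect kinks along a trace
#'
#' A kink is a localized direction change along the medial axis exceeding a
#' deflection threshold. The trace is first simplified with
#' [simplify_polyline()] at tolerance `simplify_tol_um` (which collapses
#' sub-resolution jitter), then every interior vertex of the simplified
#' polyline whose deflection angle is at least `min_kink_deg` is reported,
#' ordered from attachment to tip.
#'
#' Because digitization (skeleton tracing, point clicking) rounds sharp
#' corners over a finite length scale, one physical kink can surface as a
#' short run of simplified vertices that share a turn direction. Simplified
#' vertices closer than `merge_radius_um` along the path are therefore
#' clustered and their signed deflections summed into a single kink before
#' thresholding; `merge_radius_um = 0` reproduces plain per-vertex
#' detection.
#'
#' @param trace A [polyline_trace()] or coordinate matrix.
#' @param simplify_tol_um Simplification tolerance in micrometres (default
#'   0.05, about one pixel at a typical 100x magnification).
#' @param min_kink_deg Minimum deflection counted as a kink, degrees in
#'   (0, 180); default 10.
#' @param merge_radius_um Arc radius within which consecutive simplified
#'   vertices are merged into one kink (default 0.2, about the corner
#'   rounding scale of a skeleton-traced thin hypha).
#' @return Data frame with columns `vertex_index` (index into the original
#'   trace) and `angle_deg`. Zero rows for a straight hypha.
#' @export
detect_kinks <- function(trace, simplify_tol_um = 0.05, min_kink_deg = 10,
                         merge_radius_um = 0.2) {
  if (min_kink_deg <= 0 || min_kink_deg >= 180) {
    stop("`min_kink_deg` must lie strictly between 0 and 180 degrees")
  }
  pts <- as.matrix(trace)
  keep <- simplify_polyline(pts, simplify_tol_um)
  idx <- which(keep)
  sp <- pts[idx, , drop = FALSE]
  m <- nrow(sp)
  if (m < 3L) {
    return(data.frame(vertex_index = integer(), angle_deg = numeric()))
  }
  signed <- vapply(2:(m - 1L), function(k) {
    u <- sp[k, ] - sp[k - 1L, ]
    v <- sp[k + 1L, ] - sp[k, ]
    atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
  }, numeric(1))
  sv <- arc_positions(sp)[2:(m - 1L)]
  if (merge_radius_um > 0 && length(signed) > 1L) {
    cluster <- cumsum(c(1, diff(sv) > merge_radius_um))
  } else {
    cluster <- seq_along(signed)
  }
  ang <- abs(as.numeric(tapply(signed, cluster, sum)))
  ang <- pmin(ang, 360 - ang)  # represent turns as magnitudes in [0, 180]
  rep_vertex <- as.integer(tapply(seq_along(signed), cluster, function(ii) {
    ii[which.max(abs(signed[ii]))]
  }))
  sel <- ang >= min_kink_deg
  data.frame(vertex_index = idx[rep_vertex + 1L][sel], angle_deg = ang[sel])
}

## Direction of the first simplified segment of a trace (unit vector not
## required; callers only use the direction).
initial_direction <- function(trace, simplify_tol_um = 0.05) {
  pts <- as.matrix(trace)
  keep <- simplify_polyline(pts, simplify_tol_um)
  idx <- which(keep)
  pts[idx[2], ] - pts[idx[1], ]
}

## Resample a polyline at uniform arc-length steps. Returns a matrix of
## points, including both end points.
resample_polyline <- function(pts, step_um) {
  pts <- as.matrix(pts)
  s <- arc_positions(pts)
  total <- s[length(s)]
  pos <- unique(c(seq(0, total, by = step_um), total))
  x <- stats::approx(s, pts[, 1], xout = pos, ties = "ordered")$y
  y <- stats::approx(s, pts[, 2], xout = pos, ties = "ordered")$y
  cbind(x, y)
}
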