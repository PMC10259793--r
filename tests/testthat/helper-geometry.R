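# Shared fixtures: all geometry is built in code.

# A deformity-eligible budding cell from explicit angles: body along +x,
# hypha emerging at `junction_deg`, kinks at the given angles with ~1 um
# segments (well above any merge radius).
make_cell <- function(junction_deg = 0, kink_degs = numeric(), id = "cell",
                      seg_um = 1) {
  rot <- function(v, deg) {
    a <- deg * pi / 180
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
  }
  body <- polyline_trace(rbind(c(-2, 0), c(0, 0)), "body_axis")
  dir <- rot(c(1, 0), junction_deg)
  pts <- matrix(c(0, 0), 1)
  cur <- c(0, 0)
  for (k in c(kink_degs, NA)) {
    cur <- cur + dir * seg_um
    pts <- rbind(pts, cur)
    if (!is.na(k)) dir <- rot(dir, k)
  }
  hyp <- polyline_trace(pts, "hypha")
  bud <- polyline_trace(rbind(cur, cur + dir * 0.5), "bud_path")
  cell_record(id, body, list(hyp), bud_path = bud)
}

# Independent brute-force evaluation of the deformity formula on a cell
# built by make_cell-style geometry: angles from acos of normalized dot
# products (a different numeric path than the package's atan2 route).
brute_force_dh <- function(cell, min_kink_deg = 10) {
  hp <- unclass(as.matrix(cell$hyphae[[1]]))
  bp <- unclass(as.matrix(cell$body_axis))
  ang_acos <- function(u, v) {
    c <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(max(-1, min(1, c))) * 180 / pi
  }
  attach_pt <- hp[1, ]
  if (sum((bp[1, ] - attach_pt)^2) < sum((bp[nrow(bp), ] - attach_pt)^2)) {
    bp <- bp[nrow(bp):1, , drop = FALSE]
  }
  junction <- ang_acos(bp[nrow(bp), ] - bp[1, ], hp[2, ] - hp[1, ])
  kinks <- c()
  if (nrow(hp) >= 3) {
    for (k in 2:(nrow(hp) - 1)) {
      a <- ang_acos(hp[k, ] - hp[k - 1, ], hp[k + 1, ] - hp[k, ])
      if (a >= min_kink_deg) kinks <- c(kinks, a)
    }
  }
  deg2rad <- pi / 180
  (sin(junction * deg2rad) + sum(sin(kinks * deg2rad))) / (1 + length(kinks))
}

# Apply a rigid transform (+ optional reflection/scaling) to every trace of
# a cell and rebuild the record.
transform_cell <- function(cell, angle_deg = 0, shift = c(0, 0),
                           reflect = FALSE, scale = 1) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  if (reflect) R <- R %*% diag(c(1, -1))
  tf <- function(tr) {
    pts <- unclass(as.matrix(tr)) %*% t(R) * scale
    pts <- sweep(pts, 2, -shift)
    polyline_trace(pts, attr(tr, "role"))
  }
  cell_record(cell$id, tf(cell$body_axis), lapply(cell$hyphae, tf),
              bud_path = if (cell$has_bud) tf(cell$bud_path) else NULL)
}

# Reference recursive Ramer-Douglas-Peucker implementation (independent of
# the package's iterative version).
rdp_reference <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  d <- if (sum(ab^2) == 0) {
    sqrt(rowSums(sweep(pts, 2, a)^2))
  } else {
    abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / sqrt(sum(ab^2))
  }
  i <- which.max(d[2:(n - 1)]) + 1L
  if (d[i] > tol) {
    left <- rdp_reference(pts[1:i, , drop = FALSE], tol)
    right <- rdp_reference(pts[i:n, , drop = FALSE], tol)
    rbind(left, right[-1, , drop = FALSE])
  } else {
    rbind(a, b)
  }
}
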