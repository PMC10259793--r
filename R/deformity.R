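#' Construct a cell record
#'
#' A `cell_record` holds one cell's decomposed geometry: the body long-axis
#' trace, zero or more hypha traces, an optional bud path, the growth-stage
#' label, and (optionally) per-channel intensity profiles sampled along the
#' concatenated medial path.
#'
#' Growth stages follow the early life cycle of hyphal budding bacteria:
#' `no_hypha` (settled mother cell before hyphal outgrowth), `hypha_no_bud`
#' (one polar hypha, tip not yet swollen), and `budding` (daughter-cell
#' formation initiated by widening of the hyphal tip). Only budding cells
#' with exactly one unbranched hypha are eligible for deformity measurement:
#' bud initiation signals that hyphal growth has completed, and cells with a
#' branch or a second hypha are disregarded.
#'
#' @param id Cell identifier.
#' @param body_axis [polyline_trace()] with role `body_axis`.
#' @param hyphae List of [polyline_trace()]s with role `hypha` (may be empty).
#' @param bud_path Optional [polyline_trace()] with role `bud_path`, the
#'   medial path through the nascent bud; implies `has_bud`.
#' @param stage Stage label; inferred from `hyphae`/`bud_path` if missing.
#' @param branched `TRUE` if the cell carries a branched hypha (always
#'   excluded from deformity measurement).
#' @param profiles Named list of numeric vectors, one per channel; or `NULL`.
#' @param profile_step_um Arc-length sampling step of the profiles.
#' @param exclusion_reason Optional string explaining why the cell is not
#'   measurable (border contact, ambiguous topology, ...).
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(id, body_axis, hyphae = list(), bud_path = NULL,
                        stage = NULL, branched = FALSE, profiles = NULL,
                        profile_step_um = NA_real_,
                        exclusion_reason = NA_character_) {
  stopifnot(inherits(body_axis, "polyline_trace"))
  if (inherits(hyphae, "polyline_trace")) hyphae <- list(hyphae)
  has_bud <- !is.null(bud_path)
  n_hyphae <- length(hyphae)
  if (is.null(stage)) {
    stage <- if (n_hyphae == 0L) "no_hypha" else if (has_bud) "budding" else "hypha_no_bud"
  }
  stage <- match.arg(stage, c("no_hypha", "hypha_no_bud", "budding"))
  if (stage == "no_hypha" && n_hyphae > 0L) {
    stop("stage `no_hypha` is inconsistent with the presence of hypha traces")
  }
  if (stage == "budding" && !has_bud) {
    stop("stage `budding` requires a bud path")
  }
  if (stage == "hypha_no_bud" && (has_bud || n_hyphae == 0L)) {
    stop("stage `hypha_no_bud` requires >=1 hypha and no bud")
  }
  included <- has_bud && n_hyphae == 1L && !branched && is.na(exclusion_reason)
  len <- arc_length(body_axis) +
    (if (n_hyphae > 0L) sum(vapply(hyphae, arc_length, numeric(1))) else 0) +
    (if (has_bud) arc_length(bud_path) else 0)
  structure(list(
    id = id,
    body_axis = body_axis,
    hyphae = hyphae,
    bud_path = bud_path,
    has_bud = has_bud,
    stage = stage,
    branched = branched,
    included_for_deformity = included,
    cell_length_um = len,
    profiles = profiles,
    profile_step_um = profile_step_um,
    exclusion_reason = exclusion_reason
  ), class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> %s: stage=%s, %d hypha(e), bud=%s, length %.2f um%s\n",
              x$id, x$stage, length(x$hyphae),
              if (x$has_bud) "yes" else "no", x$cell_length_um,
              if (x$included_for_deformity) ", deformity-eligible" else ""))
  invisible(x)
}

#' Angle between the cell long axis and the emerging hypha
#'
#' Buckled-hypha phenotypes often already emerge inclined from the cell body,
#' so the emergence angle is measured alongside the kinks: the turn between
#' the body long-axis direction (pointing toward the hyphal pole) and the
#' initial direction of the hypha. 0 degrees means the hypha continues the
#' long axis collinearly.
#'
#' The body direction is taken from the full chord of the body axis,
#' oriented toward the pole nearest the hypha attachment. The hypha
#' direction is its initial chord: by default the first segment after
#' simplification at `simplify_tol_um`; when `chord_um > 0` it is instead
#' the chord from the attachment point to the point `chord_um` of arc
#' length into the hypha, which is robust against the smooth bend that
#' skeleton-derived medial axes exhibit inside the polar cap.
#'
#' @param body_axis,hypha [polyline_trace()]s; the hypha's first point is its
#'   attachment point.
#' @param simplify_tol_um Simplification tolerance for the hypha's initial
#'   direction (micrometres).
#' @param chord_um Arc length of the initial-direction chord; 0 uses the
#'   first simplified segment.
#' @param chord_skip_um Arc length skipped before the chord starts (default
#'   0.15, about the corner-rounding scale of skeleton tracing); only used
#'   when `chord_um > 0`.
#' @return Angle in degrees, in \[0, 180\].
#' @export
junction_angle <- function(body_axis, hypha, simplify_tol_um = 0.05,
                           chord_um = 0, chord_skip_um = 0.15) {
  bp <- as.matrix(body_axis)
  hp <- as.matrix(hypha)
  if (arc_length(bp) < max(simplify_tol_um, 1e-9)) {
    stop("invalid geometry: body axis shorter than the resolution tolerance")
  }
  attach_pt <- hp[1, ]
  d_first <- sum((bp[1, ] - attach_pt)^2)
  d_last <- sum((bp[nrow(bp), ] - attach_pt)^2)
  # orient the body axis so that it points toward the hyphal pole
  if (d_first < d_last) bp <- bp[nrow(bp):1, , drop = FALSE]
  axis_dir <- bp[nrow(bp), ] - bp[1, ]
  if (chord_um > 0) {
    s <- arc_positions(hp)
    total <- s[length(s)]
    b <- min(chord_skip_um + chord_um, total)
    a <- min(chord_skip_um, max(0, b - 0.1))
    at <- function(t) c(stats::approx(s, hp[, 1], xout = t, ties = "ordered")$y,
                        stats::approx(s, hp[, 2], xout = t, ties = "ordered")$y)
    hyph_dir <- at(b) - at(a)
  } else {
    hyph_dir <- initial_direction(hp, simplify_tol_um)
  }
  angle_between(axis_dir, hyph_dir)
}

#' Hyphal deformity score
#'
#' The per-hypha deformity statistic: every kink angle along the hypha is
#' measured, the emergence (junction) angle between the cell long axis and
#' the hypha is included, the sines of all N angles are summed and divided
#' by N. The score is 0 for a perfectly straight, collinearly emerging hypha
#' and approaches 1 for strongly buckled hyphae dominated by right-angle
#' turns. Because sin(180 - a) = sin(a), the score is identical whether
#' angles are recorded as interior angles or as deflections.
#'
#' Only cells with initiated or finished bud formation and exactly one
#' unbranched hypha are eligible; other cells raise an error naming the
#' violated inclusion rule.
#'
#' @param cell A [cell_record()] with `included_for_deformity = TRUE`.
#' @param simplify_tol_um,min_kink_deg Kink detection parameters, see
#'   [detect_kinks()].
#' @param include_junction Include the emergence angle as one of the N
#'   measured angles (default `TRUE`); with `FALSE` only kinks are counted
#'   and a kink-free hypha scores `NA`.
#' @param merge_radius_um Kink clustering radius, see [detect_kinks()].
#' @param junction_chord_um Initial-direction chord for the emergence
#'   angle, see [junction_angle()]; 0 uses the first simplified segment.
#' @return An object of class `deformity_set` with fields `junction_deg`,
#'   `kink_degs`, `n_angles`, `d_h`.
#' @examples
#' body <- polyline_trace(cbind(c(-2, 0), c(0, 0)), "body_axis")
#' hyp <- polyline_trace(cbind(c(0, 1, 1), c(0, 0, 1)), "hypha")
#' cell <- cell_record("c1", body, list(hyp),
#'                     bud_path = polyline_trace(cbind(c(1, 1), c(1, 1.5)), "bud_path"))
#' compute_deformity(cell)$d_h  # one 90-degree kink, collinear emergence: 0.5
#' @export
compute_deformity <- function(cell, simplify_tol_um = 0.05, min_kink_deg = 10,
                              include_junction = TRUE, merge_radius_um = 0.2,
                              junction_chord_um = 0) {
  stopifnot(inherits(cell, "cell_record"))
  if (!cell$included_for_deformity) {
    reason <- if (!cell$has_bud) {
      "no initiated or finished bud formation"
    } else if (length(cell$hyphae) != 1L) {
      sprintf("%d hyphae present (exactly one required)", length(cell$hyphae))
    } else if (cell$branched) {
      "hypha is branched"
    } else {
      cell$exclusion_reason
    }
    stop(sprintf("ineligible cell %s: %s", cell$id, reason))
  }
  hyp <- cell$hyphae[[1]]
  if (arc_length(hyp) < 2 * simplify_tol_um) {
    stop(sprintf("ineligible cell %s: hypha shorter than 2x the simplification tolerance, unmeasurable",
                 cell$id))
  }
  jd <- junction_angle(cell$body_axis, hyp, simplify_tol_um, junction_chord_um)
  kk <- detect_kinks(hyp, simplify_tol_um, min_kink_deg, merge_radius_um)
  deformity_set(jd, kk$angle_deg, include_junction = include_junction)
}

#' Assemble a deformity set from measured angles
#'
#' Low-level constructor used both by [compute_deformity()] and by the
#' synthetic generator's analytic ground truth.
#'
#' @param junction_deg Emergence angle, degrees in \[0, 180\].
#' @param kink_degs Numeric vector of kink angles, degrees in \[0, 180\].
#' @param include_junction Count the junction angle as one of the N angles.
#' @return `deformity_set` object.
#' @export
deformity_set <- function(junction_deg, kink_degs = numeric(),
                          include_junction = TRUE) {
  stopifnot(junction_deg >= 0, junction_deg <= 180,
            all(kink_degs >= 0), all(kink_degs <= 180))
  if (include_junction) {
    n <- 1L + length(kink_degs)
    s <- sin(junction_deg * pi / 180) + sum(sin(kink_degs * pi / 180))
    dh <- s / n
  } else {
    n <- length(kink_degs)
    dh <- if (n == 0L) NA_real_ else sum(sin(kink_degs * pi / 180)) / n
  }
  structure(list(junction_deg = junction_deg,
                 kink_degs = as.numeric(kink_degs),
                 n_angles = n, d_h = dh),
            class = "deformity_set")
}

#' @export
print.deformity_set <- function(x, ...) {
  cat(sprintf("<deformity_set> d_h = %.4f (junction %.1f deg, %d kink(s), N = %d)\n",
              x$d_h, x$junction_deg, length(x$kink_degs), x$n_angles))
  invisible(x)
}

#' Deformity and length table for a set of cells
#'
#' Applies [compute_deformity()] and hyphal [arc_length()] to every eligible
#' cell; ineligible cells appear with `NA` measurements and the inclusion
#' rule they violate, so no cell is silently dropped.
#'
#' @param cells List of [cell_record()]s.
#' @param group Optional vector of strain/condition labels (recycled).
#' @inheritParams compute_deformity
#' @return Data frame with columns `cell_id`, `group`, `stage`, `eligible`,
#'   `n_angles`, `junction_deg`, `kink_degs` (semicolon-joined), `d_h`,
#'   `hypha_length_um`, `cell_length_um`, `exclusion_reason`.
#' @export
deformity_table <- function(cells, group = NA_character_,
                            simplify_tol_um = 0.05, min_kink_deg = 10,
                            include_junction = TRUE, merge_radius_um = 0.2,
                            junction_chord_um = 0) {
  group <- rep_len(group, length(cells))
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    base <- data.frame(
      cell_id = as.character(cell$id), group = group[i], stage = cell$stage,
      eligible = cell$included_for_deformity,
      n_angles = NA_integer_, junction_deg = NA_real_,
      kink_degs = NA_character_, d_h = NA_real_,
      hypha_length_um = if (length(cell$hyphae) == 1L)
        arc_length(cell$hyphae[[1]]) else NA_real_,
      cell_length_um = cell$cell_length_um,
      exclusion_reason = NA_character_,
      stringsAsFactors = FALSE
    )
    if (!cell$included_for_deformity) {
      base$exclusion_reason <- exclusion_reason_of(cell)
      return(base)
    }
    ds <- tryCatch(
      compute_deformity(cell, simplify_tol_um, min_kink_deg, include_junction,
                        merge_radius_um, junction_chord_um),
      error = function(e) NULL)
    if (is.null(ds)) {
      base$exclusion_reason <- "hypha unmeasurable at the configured tolerance"
      return(base)
    }
    base$n_angles <- ds$n_angles
    base$junction_deg <- ds$junction_deg
    base$kink_degs <- paste(sprintf("%.6g", ds$kink_degs), collapse = ";")
    base$d_h <- ds$d_h
    base
  })
  do.call(rbind, rows)
}

exclusion_reason_of <- function(cell) {
  if (!is.na(cell$exclusion_reason)) return(cell$exclusion_reason)
  if (!cell$has_bud) return("no bud formation initiated")
  if (length(cell$hyphae) == 0L) return("no hypha")
  if (length(cell$hyphae) > 1L) return("second hypha present")
  if (cell$branched) return("branched hypha")
  "ineligible"
}

#' Read and write medial-axis trace CSV files
#'
#' The trace interchange format has columns `cell_id`, `trace_role`
#' (`body_axis`, `hypha`, `bud_path`), `point_index`, `x_um`, `y_um`. It is
#' both the output of mask-based tracing and the import path for manually
#' digitized polylines.
#'
#' @param path CSV file path.
#' @return `read_traces_csv()`: a list of [cell_record()]s (without
#'   profiles). `write_traces_csv()`: the path, invisibly.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "trace_role", "point_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$cell_id), function(cd) {
    # a restart of point_index marks a new trace of the same role
    traces <- unlist(lapply(split(cd, cd$trace_role), function(td) {
      run <- cumsum(c(TRUE, diff(td$point_index) <= 0))
      lapply(split(td, run), function(one) {
        polyline_trace(cbind(one$x_um, one$y_um), role = one$trace_role[1])
      })
    }), recursive = FALSE)
    roles <- vapply(traces, trace_role, character(1))
    hyphae <- unname(traces[roles == "hypha"])
    body <- traces[[which(roles == "body_axis")[1]]]
    bud <- if (any(roles == "bud_path")) traces[[which(roles == "bud_path")[1]]] else NULL
    cell_record(cd$cell_id[1], body_axis = body, hyphae = hyphae,
                bud_path = bud)
  })
}

#' @rdname read_traces_csv
#' @param cells List of [cell_record()]s.
#' @export
write_traces_csv <- function(cells, path) {
  rows <- lapply(cells, function(cell) {
    traces <- c(list(cell$body_axis), cell$hyphae,
                if (cell$has_bud) list(cell$bud_path))
    do.call(rbind, lapply(traces, function(tr) {
      pts <- as.matrix(tr)
      data.frame(cell_id = as.character(cell$id), trace_role = trace_role(tr),
                 point_index = seq_len(nrow(pts)),
                 x_um = pts[, 1], y_um = pts[, 2])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
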