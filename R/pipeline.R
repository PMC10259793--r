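#' Assemble a reproducible run configuration
#'
#' Collects every tunable parameter of the pipeline stages with its default,
#' plus seed, input paths and output directory. The effective configuration
#' (defaults resolved, version-stamped) is written beside the outputs of
#' every run so a run can be replayed exactly.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    input_dir = NULL, trace_csv = NULL, mask_tiff = NULL,
    image_tiffs = NULL, out_dir = ".",
    pixel_size_um = 0.065,
    simplify_tol_um = 0.05, min_kink_deg = 10, include_junction = TRUE,
    merge_radius_um = 0.3, junction_chord_um = 0.4,
    prune_len_um = 0.2, min_area_px = 20,
    body_width_ratio = 0.6, bud_width_ratio = 0.5,
    sample_step_um = 0.05, bin_step_um = 0.05, peak_window_um = 0.15,
    thresholds = as.list(significance_thresholds()),
    seed = 1L,
    version = as.character(utils::packageVersion("hyphometry"))
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) != "version"])
}

write_manifest <- function(out_dir, config, inputs, outputs) {
  files <- c(inputs, outputs)
  files <- files[file.exists(files)]
  manifest <- list(
    package = "hyphometry",
    version = as.character(utils::packageVersion("hyphometry")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a ground-truthed dataset to disk
#'
#' Generates a synthetic population per [generate_cells()], rasterizes it
#' with [rasterize_cells()], and writes one intensity TIFF per channel, the
#' label-mask TIFF, the ground-truth CSV, the trace CSV of the generating
#' polylines (in field coordinates), and the effective configuration for
#' exact replay.
#'
#' @param spec A [phenotype_spec()].
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()] providing pixel size and seed context.
#' @param ... Passed to [rasterize_cells()].
#' @return Invisibly, the `synthetic_field`.
#' @export
run_simulate <- function(spec, out_dir, config = run_config(), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_cells(spec)
  field <- rasterize_cells(sim, pixel_size_um = config$pixel_size_um, ...)
  outs <- character()
  for (ch in names(field$images)) {
    f <- file.path(out_dir, sprintf("%s_%s.tif", spec$name, ch))
    write_image_tiff(field$images[[ch]], f)
    outs <- c(outs, f)
  }
  fm <- file.path(out_dir, sprintf("%s_mask.tif", spec$name))
  write_image_tiff(field$mask, fm)
  ft <- file.path(out_dir, sprintf("%s_truth.csv", spec$name))
  utils::write.csv(field$truth, ft, row.names = FALSE)
  fc <- file.path(out_dir, sprintf("%s_traces.csv", spec$name))
  write_traces_csv(field$cells, fc)
  fy <- file.path(out_dir, sprintf("%s_config.yaml", spec$name))
  write_run_config(config, fy)
  yaml::write_yaml(lapply(unclass(spec), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    file.path(out_dir, sprintf("%s_spec.yaml", spec$name)))
  write_manifest(out_dir, config, character(), c(outs, fm, ft, fc, fy))
  invisible(field)
}

load_cells_from_config <- function(config) {
  if (!is.null(config$trace_csv)) {
    cells <- read_traces_csv(config$trace_csv)
    return(list(cells = cells, qc = NULL))
  }
  if (is.null(config$mask_tiff)) {
    stop("no input: configuration must name either `trace_csv` or `mask_tiff`")
  }
  mask <- read_image_tiff(config$mask_tiff, integer_labels = TRUE)
  images <- NULL
  if (!is.null(config$image_tiffs)) {
    images <- lapply(config$image_tiffs, read_image_tiff)
  }
  trace_cells(mask, images = images, pixel_size_um = config$pixel_size_um,
              sample_step_um = config$sample_step_um,
              prune_len_um = config$prune_len_um,
              min_area_px = config$min_area_px,
              body_width_ratio = config$body_width_ratio,
              bud_width_ratio = config$bud_width_ratio,
              simplify_tol_um = config$simplify_tol_um)
}

#' Run the deformity stage of the pipeline
#'
#' Loads cells (trace CSV, or mask/image TIFFs via [trace_cells()]),
#' computes per-cell deformity scores and hyphal lengths with an exclusion
#' log, writes `deformity.csv` and `qc.csv`, and, when at least two
#' condition labels are present, a group comparison report. No cell is
#' silently dropped: measured + excluded counts equal the input count.
#'
#' @param config A [run_config()] naming the inputs.
#' @param group Optional per-cell condition labels, or a single label.
#' @return Invisibly, a list with `table` (the deformity data frame), `qc`,
#'   and `comparison` (or `NULL`).
#' @export
run_deformity <- function(config, group = NA_character_) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  loaded <- load_cells_from_config(config)
  if (length(loaded$cells) == 0L) {
    stop("zero traceable cells in input; see the QC table for reasons")
  }
  tab <- deformity_table(loaded$cells, group = group,
                         simplify_tol_um = config$simplify_tol_um,
                         min_kink_deg = config$min_kink_deg,
                         include_junction = config$include_junction,
                         merge_radius_um = config$merge_radius_um,
                         junction_chord_um = config$junction_chord_um)
  if (!any(tab$eligible)) {
    counts <- table(tab$exclusion_reason)
    stop("zero eligible cells; exclusion reasons: ",
         paste(sprintf("%s (%d)", names(counts), counts), collapse = "; "))
  }
  f1 <- file.path(config$out_dir, "deformity.csv")
  utils::write.csv(tab, f1, row.names = FALSE)
  outs <- f1
  if (!is.null(loaded$qc)) {
    fq <- file.path(config$out_dir, "qc.csv")
    utils::write.csv(loaded$qc, fq, row.names = FALSE)
    outs <- c(outs, fq)
  }
  comparison <- NULL
  meas <- tab[!is.na(tab$d_h), ]
  if (length(unique(stats::na.omit(meas$group))) >= 2L) {
    comparison <- compare_groups(
      data.frame(group = meas$group, value = meas$d_h), metric = "d_h",
      thresholds = unlist(config$thresholds))
    fr <- file.path(config$out_dir, "comparison.csv")
    utils::write.csv(comparison$summary, fr, row.names = FALSE)
    txt <- file.path(config$out_dir, "comparison.txt")
    sink(txt); print(comparison); sink()
    outs <- c(outs, fr, txt)
  }
  write_run_config(config, file.path(config$out_dir, "effective_config.yaml"))
  write_manifest(config$out_dir, config,
                 c(config$trace_csv, config$mask_tiff,
                   unlist(config$image_tiffs)) %||% character(), outs)
  invisible(list(table = tab, qc = loaded$qc, comparison = comparison))
}

#' Run the localization stage of the pipeline
#'
#' Builds one demograph per growth stage per channel (empty stage groups
#' are skipped with a log entry), computes per-cell peak-to-tip distances,
#' and, when two channels are present, the paired between-channel offset
#' summary. Writes demograph CSVs (+ PNG heatmaps), `peak_distances.csv`
#' and `paired_offsets.yaml`.
#'
#' @param config A [run_config()] naming mask and image TIFF inputs.
#' @return Invisibly, a list with `demographs`, `peaks`, `paired`.
#' @export
run_localization <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  loaded <- load_cells_from_config(config)
  cells <- Filter(function(cell) !is.null(cell$profiles), loaded$cells)
  if (length(cells) == 0L) stop("no cells with intensity profiles; supply image TIFFs")
  channels <- names(cells[[1]]$profiles)
  outs <- character()
  demographs <- list()
  for (stage in c("no_hypha", "hypha_no_bud", "budding")) {
    for (ch in channels) {
      dg <- tryCatch(build_demograph(cells, stage, ch, config$bin_step_um),
                     error = function(e) {
                       message(sprintf("skipping %s/%s: %s", stage, ch,
                                       conditionMessage(e)))
                       NULL
                     })
      if (is.null(dg)) next
      key <- sprintf("%s_%s", stage, ch)
      demographs[[key]] <- dg
      f <- file.path(config$out_dir, sprintf("demograph_%s.csv", key))
      write_demograph_csv(dg, f)
      png <- file.path(config$out_dir, sprintf("demograph_%s.png", key))
      grDevices::png(png, width = 900, height = 600)
      plot(dg)
      grDevices::dev.off()
      outs <- c(outs, f, png)
    }
  }
  peaks <- peak_distance_table(cells, channels,
                               window_um = config$peak_window_um)
  fp <- file.path(config$out_dir, "peak_distances.csv")
  utils::write.csv(peaks, fp, row.names = FALSE)
  outs <- c(outs, fp)
  paired <- NULL
  if (length(channels) >= 2L) {
    paired <- paired_peak_offsets(peaks, channels[1], channels[2])
    fy <- file.path(config$out_dir, "paired_offsets.yaml")
    yaml::write_yaml(paired[c("median_offset_um", "median_a_um",
                              "median_b_um", "n")], fy)
    outs <- c(outs, fy)
  }
  write_run_config(config, file.path(config$out_dir, "effective_config.yaml"))
  write_manifest(config$out_dir, config,
                 c(config$mask_tiff, unlist(config$image_tiffs)) %||% character(),
                 outs)
  invisible(list(demographs = demographs, peaks = peaks, paired = paired))
}
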