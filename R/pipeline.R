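# Orchestration of the two imaging workflows (field morphometry and
# high-speed flickering), the hemolysis readout and the statistical report,
# plus the fixture simulator. Each run_* function is deterministic given its
# config and writes its resolved configuration next to its outputs so no
# number is separable from the conventions that produced it.

#' Resolved run configuration
#'
#' Defaults mirror the reference acquisition: 0.103 um/px bright-field
#' fields analysed with 720-angle degree-12 contours, 2000 fps videos at
#' 50 nm/px with 1024-angle degree-18 contours, 37 C.
#'
#' @param pixel_size_um Field pixel size, micrometers per pixel.
#' @param video_pixel_size_um Video pixel size, micrometers per pixel.
#' @param fps Video frame rate.
#' @param n_angles,spline_degree Field contour sampling and smoothing.
#' @param video_n_angles,video_spline_degree Video contour sampling and
#'   smoothing.
#' @param temperature Temperature in K.
#' @param mode_used Mode (or band) for the ensemble tension.
#' @param msd_fit_lags MSD fit window in lags.
#' @param volatility_window_s,volatility_stride_s Volatility windows (s).
#' @param criteria An [acceptance_criteria()].
#' @param seed Integer seed for any simulated input.
#' @return List of class `rbc_config`.
#' @export
run_config <- function(pixel_size_um = 0.103, video_pixel_size_um = 0.05,
                       fps = 2000, n_angles = 720L, spline_degree = 12L,
                       video_n_angles = 1024L, video_spline_degree = 18L,
                       temperature = 310.15, mode_used = 3L,
                       msd_fit_lags = 10L, volatility_window_s = 0.5,
                       volatility_stride_s = 0.25,
                       criteria = acceptance_criteria(), seed = 1L) {
  cfg <- list(pixel_size_um = pixel_size_um,
              video_pixel_size_um = video_pixel_size_um, fps = fps,
              n_angles = as.integer(n_angles),
              spline_degree = as.integer(spline_degree),
              video_n_angles = as.integer(video_n_angles),
              video_spline_degree = as.integer(video_spline_degree),
              temperature = temperature, mode_used = as.integer(mode_used),
              msd_fit_lags = as.integer(msd_fit_lags),
              volatility_window_s = volatility_window_s,
              volatility_stride_s = volatility_stride_s,
              criteria = unclass(criteria), seed = as.integer(seed))
  stopifnot(cfg$pixel_size_um > 0, cfg$video_pixel_size_um > 0, cfg$fps > 0,
            cfg$temperature > 0)
  structure(cfg, class = "rbc_config")
}

write_resolved_config <- function(config, out_dir) {
  jsonlite::write_json(unclass(config),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# --- TIFF and annotated CSV I/O ----------------------------------------

#' Read and write grayscale (multi-page) TIFF stacks
#'
#' Frames are stored in conventional raster orientation; in memory the
#' package uses matrices with dim1 = x. Intensities are clipped to [0, 1]
#' on write (16-bit output).
#'
#' @param x Matrix or 3-D array (x, y, frame).
#' @param path File path.
#' @return `read_tiff_stack` returns a 3-D array (x, y, frame).
#' @export
write_tiff_stack <- function(x, path) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  frames <- lapply(seq_len(dim(x)[3L]),
                   function(k) t(pmin(pmax(x[, , k], 0), 1)))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  arr <- array(0, c(ncol(frames[[1L]]), nrow(frames[[1L]]), length(frames)))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1L]  # tolerate grayscale-as-RGB
    arr[, , k] <- t(fr)
  }
  arr
}

# CSV with '#'-prefixed provenance header lines; read back with
# read.csv(..., comment.char = "#").
write_annotated_csv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# --- simulate ----------------------------------------------------------

#' Simulate a fixture bundle
#'
#' Dispatches to the synthetic-data generators and writes a TIFF/CSV/JSON
#' bundle with its ground-truth manifest.
#'
#' @param kind One of "field" (bright-field scene + manifest), "ensemble"
#'   (static contours + truth), "video" (fluctuating-contour stack +
#'   truth), "absorbance" (Harboe records).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param spec Optional generator spec ([scene_spec()], [ensemble_spec()]
#'   or [ou_spec()]); a scaled-down default is used when omitted.
#' @param ... For kind "video": `radius0`, `image_size`, `pixel_size`,
#'   `drift`, passed to [render_contour_video()]; for "absorbance":
#'   `hb_level`, `blank_sd` passed to [generate_absorbance()].
#' @return Invisibly, the list of files written.
#' @export
run_simulate <- function(kind = c("field", "ensemble", "video", "absorbance"),
                         out_dir, seed = 1L, spec = NULL, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- switch(kind,
    field = {
      spec <- spec %||% demo_scene_spec(seed)
      scene <- generate_field_scene(spec)
      fi <- file.path(out_dir, "field.tif")
      fm <- file.path(out_dir, "field_manifest.json")
      write_tiff_stack(scene$image, fi)
      jsonlite::write_json(scene$manifest, fm, auto_unbox = FALSE,
                           digits = NA, pretty = TRUE, na = "null")
      c(fi, fm)
    },
    ensemble = {
      spec <- spec %||% ensemble_spec(seed = seed)
      ens <- generate_static_ensemble(spec)
      long <- do.call(rbind, lapply(ens$contours, function(ct)
        data.frame(cell_id = ct$cell_id, theta = ct$angles,
                   R_m = ct$radii)))
      fc <- file.path(out_dir, "ensemble_contours.csv")
      ft <- file.path(out_dir, "ensemble_truth.json")
      write_annotated_csv(long, fc,
        meta = c("synthetic static contour ensemble",
                 sprintf("sigma0_N_per_m=%g", ens$truth$sigma0)))
      jsonlite::write_json(ens$truth, ft, auto_unbox = TRUE, digits = NA)
      c(fc, ft)
    },
    video = {
      spec <- spec %||% ou_spec(n_angles = 128L, n_frames = 200L,
                                fps = 2000, seed = seed)
      dyn <- generate_angle_dynamics(spec)
      args <- list(...)
      vid <- render_contour_video(
        dyn$field, radius0 = args$radius0 %||% 1.5e-6,
        image_size = args$image_size %||% 96L,
        pixel_size = args$pixel_size %||% 50e-9,
        drift = args$drift %||% c(0, 0), seed = seed)
      fv <- file.path(out_dir, "video.tif")
      ft <- file.path(out_dir, "video_truth.json")
      write_tiff_stack(vid, fv)
      jsonlite::write_json(dyn$truth, ft, auto_unbox = TRUE, digits = NA)
      c(fv, ft)
    },
    absorbance = {
      args <- list(...)
      rec <- generate_absorbance(hb_level = args$hb_level %||% 0.25,
                                 blank_sd = args$blank_sd %||% 0.005,
                                 seed = seed)
      fa <- file.path(out_dir, "absorbance.csv")
      write_annotated_csv(rec, fa, meta = "synthetic Harboe absorbance records")
      fa
    })
  invisible(files)
}

# --- morphometry workflow ----------------------------------------------

#' Field-morphometry workflow
#'
#' For every bright-field TIFF: preprocess, Otsu segmentation, acceptance
#' filtering, contour extraction, and morphometric measurement of every
#' accepted cell; the per-field normocyte fraction is recorded alongside.
#'
#' @param field_paths Character vector of TIFF paths (single-page fields).
#' @param out_dir Output directory.
#' @param config An [run_config()].
#' @param condition Label written into every row.
#' @return Invisibly, list with `cells`, `acceptance`, `fields`
#'   data.frames (also written as CSV).
#' @export
run_morpho <- function(field_paths, out_dir, config = run_config(),
                       condition = NA_character_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  crit <- do.call(acceptance_criteria, config$criteria)
  cells <- list(); acc <- list(); fields <- list()
  for (fp in field_paths) {
    if (!file.exists(fp)) stop("input field not found: ", fp)
    field_id <- sub("\\.tiff?$", "", basename(fp))
    img <- read_tiff_stack(fp)[, , 1L]
    fr <- preprocess_frame(img)
    det <- detect_and_filter(fr, crit, pixel_size = config$pixel_size_um)
    message(sprintf("[morpho] %s: %d detected, %d accepted, %d rejected",
                    field_id, det$n_detected, nrow(det$accepted),
                    nrow(det$rejected)))
    log_df <- rbind(det$accepted, det$rejected)
    if (nrow(log_df)) log_df <- cbind(field_id = field_id, log_df)
    acc[[fp]] <- log_df
    fields[[fp]] <- data.frame(
      field_id = field_id, n_detected = det$n_detected,
      n_accepted = nrow(det$accepted),
      normocyte_fraction = if (det$n_detected > 0)
        normocyte_fraction(nrow(det$accepted), det$n_detected) else NA_real_)
    if (nrow(det$accepted)) {
      rows <- lapply(seq_len(nrow(det$accepted)), function(i) {
        id <- det$accepted$id[i]
        ct <- extract_contour(fr, det$labels, id,
                              n_angles = config$n_angles,
                              spline_degree = config$spline_degree,
                              pixel_size = config$pixel_size_um * 1e-6)
        m <- measure_contour(ct, cell_id = sprintf("%s_c%02d", field_id, id),
                             condition = condition)
        data.frame(condition = condition, field_id = field_id,
                   cell_id = m$cell_id, A_um2 = m$A_m2 * 1e12,
                   P_um = m$P_m * 1e6, Req_um = m$Req_m * 1e6,
                   R0_um = m$R0_m * 1e6, C = m$C, C_lin = m$C_lin,
                   F = m$F, E = m$E, a_um = m$a_m * 1e6,
                   b_um = m$b_m * 1e6, delta_nm = m$delta_m * 1e9,
                   stringsAsFactors = FALSE)
      })
      cells[[fp]] <- do.call(rbind, rows)
    }
  }
  out <- list(cells = if (length(cells)) do.call(rbind, cells) else NULL,
              acceptance = do.call(rbind, acc),
              fields = do.call(rbind, fields))
  rownames(out$acceptance) <- rownames(out$fields) <- NULL
  if (!is.null(out$cells)) rownames(out$cells) <- NULL
  meta <- c(sprintf("temperature_K=%g", config$temperature),
            sprintf("pixel_size_um=%g", config$pixel_size_um),
            sprintf("circularity_min=%g", crit$circularity_min),
            sprintf("radius_window_um=%g..%g", crit$radius_window[1L],
                    crit$radius_window[2L]))
  if (!is.null(out$cells))
    write_annotated_csv(out$cells, file.path(out_dir, "morphometry.csv"), meta)
  write_annotated_csv(out$acceptance, file.path(out_dir, "acceptance.csv"), meta)
  write_annotated_csv(out$fields, file.path(out_dir, "fields.csv"), meta)
  write_resolved_config(config, out_dir)
  invisible(out)
}

# --- flickering workflow -----------------------------------------------

#' High-speed flickering workflow
#'
#' Tracks each single-cell video, computes the per-cell viscoelastic
#' descriptors, and (optionally) an ensemble tension from the per-frame
#' contour spectra. Videos whose tracking fails (blank or multi-cell
#' frames) are skipped with a logged reason.
#'
#' @param video_paths Character vector of multi-page TIFF stacks.
#' @param out_dir Output directory.
#' @param config An [run_config()].
#' @param condition Label written into every record.
#' @return Invisibly, list with `records` (per-cell data.frame), `skipped`
#'   (data.frame path/reason); also written as CSV.
#' @export
run_flicker <- function(video_paths, out_dir, config = run_config(),
                        condition = NA_character_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thermal <- thermal_context(config$temperature)
  recs <- list(); skipped <- list()
  for (vp in video_paths) {
    if (!file.exists(vp)) stop("input video not found: ", vp)
    cell_id <- sub("\\.tiff?$", "", basename(vp))
    res <- tryCatch({
      stack <- read_tiff_stack(vp)
      fld <- track_video(stack, fps = config$fps,
                         pixel_size = config$video_pixel_size_um * 1e-6,
                         n_angles = config$video_n_angles,
                         spline_degree = config$video_spline_degree,
                         cell_id = cell_id)
      cell_summary(fld, thermal, fit_lags = config$msd_fit_lags,
                   window_s = config$volatility_window_s,
                   stride_s = config$volatility_stride_s,
                   condition = condition)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("[flicker] skipped %s: %s", cell_id,
                      conditionMessage(res)))
      skipped[[vp]] <- data.frame(path = vp, reason = conditionMessage(res),
                                  stringsAsFactors = FALSE)
    } else {
      recs[[vp]] <- as.data.frame(res)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else NULL
  if (!is.null(records)) rownames(records) <- NULL
  meta <- c(sprintf("temperature_K=%g", config$temperature),
            sprintf("fps=%g", config$fps),
            sprintf("msd_fit_lags=%d", config$msd_fit_lags))
  if (!is.null(records))
    write_annotated_csv(records, file.path(out_dir, "dynamics.csv"), meta)
  sk <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(path = character(), reason = character())
  rownames(sk) <- NULL
  write_annotated_csv(sk, file.path(out_dir, "skipped.csv"), meta)
  write_resolved_config(config, out_dir)
  invisible(list(records = records, skipped = sk))
}

# --- hemolysis workflow ------------------------------------------------

#' Hemolysis workflow over an absorbance record CSV
#'
#' @param absorbance_path CSV in the [generate_absorbance()] schema.
#' @param out_dir Output directory.
#' @param condition,timepoint Labels.
#' @return Invisibly, the one-row [hemolysis_readout()] result (also
#'   written as CSV).
#' @export
run_hemolysis <- function(absorbance_path, out_dir,
                          condition = NA_character_,
                          timepoint = NA_character_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- utils::read.csv(absorbance_path, comment.char = "#")
  res <- hemolysis_readout(rec, condition = condition, timepoint = timepoint)
  write_annotated_csv(res, file.path(out_dir, "hemolysis.csv"),
                      meta = "Harboe readout, LOD = 3.3 x propagated blank sd")
  invisible(res)
}

# --- statistical report ------------------------------------------------

#' Statistical report over per-cell descriptor tables
#'
#' Runs the nonparametric comparison layer (Kruskal-Wallis + planned
#' Mann-Whitney pairs with trend banding) over every descriptor column,
#' emits a Table-style label matrix (descriptor x pair), per-group
#' median/IQR summaries, and the rigidity-frequency plane when the
#' dynamics descriptors are present.
#'
#' @param cells data.frame with a `condition` column and numeric
#'   descriptor columns, or the path of such a CSV.
#' @param out_dir Output directory.
#' @param descriptors Descriptor columns to analyse (default: every
#'   numeric column).
#' @param pairs Planned pairs, see [compare_groups()].
#' @return Invisibly, list with `comparisons` (long format), `labels`
#'   (descriptor x pair matrix), `summaries`, `plane`.
#' @export
run_report <- function(cells, out_dir, descriptors = NULL, pairs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(cells)) cells <- utils::read.csv(cells, comment.char = "#")
  if (!nrow(cells) || !"condition" %in% names(cells))
    stop("schema error: need a non-empty table with a 'condition' column")
  if (is.null(descriptors)) {
    descriptors <- names(cells)[vapply(cells, is.numeric, TRUE)]
    descriptors <- setdiff(descriptors, c("n_angles_used"))
  }
  missing <- setdiff(descriptors, names(cells))
  if (length(missing))
    stop("schema error: missing descriptor column(s): ",
         paste(missing, collapse = ", "))
  comp_rows <- list(); summ_rows <- list()
  for (d in descriptors) {
    by_grp <- split(cells[[d]], cells$condition)
    by_grp <- lapply(by_grp, function(v) v[is.finite(v)])
    for (g in names(by_grp)) {
      s <- summarize_median_iqr(by_grp[[g]])
      summ_rows[[paste(d, g)]] <- data.frame(
        descriptor = d, condition = g, median = s$median, iqr = s$iqr,
        n = s$n, stringsAsFactors = FALSE)
    }
    cg <- compare_groups(by_grp, pairs = pairs)
    cg$pairwise$descriptor <- d
    cg$pairwise$kruskal_p <- cg$kruskal$p
    comp_rows[[d]] <- cg$pairwise
  }
  comparisons <- do.call(rbind, comp_rows)
  rownames(comparisons) <- NULL
  pair_id <- paste(comparisons$group_a, "vs", comparisons$group_b)
  labels <- stats::xtabs(~ descriptor + pair_id,
                         data = cbind(comparisons, pair_id))
  lab_mat <- matrix(NA_character_, nrow(labels), ncol(labels),
                    dimnames = dimnames(labels))
  for (i in seq_len(nrow(comparisons)))
    lab_mat[comparisons$descriptor[i], pair_id[i]] <- comparisons$label[i]
  summaries <- do.call(rbind, summ_rows)
  rownames(summaries) <- NULL
  plane <- NULL
  if (all(c("k_eff", "omega_c") %in% names(cells)))
    plane <- mech_plane(cells)
  note <- "within-condition, within-run comparisons only; no population-level inference"
  write_annotated_csv(comparisons, file.path(out_dir, "comparisons.csv"), note)
  write_annotated_csv(as.data.frame(lab_mat),
                      file.path(out_dir, "labels_matrix.csv"), note)
  write_annotated_csv(summaries, file.path(out_dir, "summaries.csv"), note)
  if (!is.null(plane)) {
    write_annotated_csv(plane$table, file.path(out_dir, "mech_plane.csv"), note)
    if (!plane$fit_skipped)
      jsonlite::write_json(plane$fit, file.path(out_dir, "mech_plane_fit.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  invisible(list(comparisons = comparisons, labels = lab_mat,
                 summaries = summaries, plane = plane))
}
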