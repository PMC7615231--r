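#' Write a simulated dataset to disk
#'
#' Standard on-disk layout, one directory per sequence:
#' `seq_%04d/{features.csv, gaze.csv, probe.csv, manifest.json}`. Gaze is
#' stored as raw pixels (`t,x_px,y_px`; normalization happens on load),
#' probe as `t,qw,qx,qy,qz`, and the manifest records the target
#' quaternion, plane type, seed, and image size. Partially written
#' sequence directories are removed on failure.
#'
#' @param dataset list of `sim_sequence` objects (or compatible lists).
#' @param dir output directory (created if needed).
#' @param image_size `c(width, height)` used to de-normalize gaze.
#' @return `dir`, invisibly.
#' @export
write_scan_dataset <- function(dataset, dir, image_size = c(288L, 224L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset)) {
    sq <- dataset[[i]]
    sdir <- file.path(dir, sprintf("seq_%04d", i))
    ok <- FALSE
    dir.create(sdir, showWarnings = FALSE)
    tryCatch({
      T_len <- nrow(sq$gaze)
      px <- denormalize_gaze(as.matrix(sq$gaze), image_size)
      data.table::fwrite(data.table::data.table(
        t = seq_len(T_len), x_px = px[, 1L], y_px = px[, 2L]),
        file.path(sdir, "gaze.csv"))
      q <- as.matrix(sq$quats)
      data.table::fwrite(data.table::data.table(
        t = seq_len(T_len), qw = q[, 1L], qx = q[, 2L], qy = q[, 3L],
        qz = q[, 4L]), file.path(sdir, "probe.csv"))
      data.table::fwrite(data.table::as.data.table(as.matrix(sq$features)),
                         file.path(sdir, "features.csv"))
      jsonlite::write_json(list(
        q_target = as.numeric(sq$q_target),
        plane_type = sq$plane_type,
        seed = sq$seed,
        angle_to_target = as.numeric(sq$angle_to_target),
        image_size = as.integer(image_size)),
        file.path(sdir, "manifest.json"), digits = NA, auto_unbox = TRUE)
      ok <- TRUE
    }, finally = if (!ok) unlink(sdir, recursive = TRUE))
  }
  manifest <- list(n_sequences = length(dataset),
                   sequences = sprintf("seq_%04d", seq_along(dataset)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a scan dataset from disk
#'
#' Inverse of [write_scan_dataset()]: gaze pixels are normalized on load
#' using the manifest's image size.
#'
#' @param dir dataset directory.
#' @return list of sequences.
#' @export
read_scan_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(man$sequences, function(sname) {
    sdir <- file.path(dir, sname)
    m <- jsonlite::read_json(file.path(sdir, "manifest.json"),
                             simplifyVector = TRUE)
    gz <- data.table::fread(file.path(sdir, "gaze.csv"))
    pb <- data.table::fread(file.path(sdir, "probe.csv"))
    ft <- as.matrix(data.table::fread(file.path(sdir, "features.csv")))
    dimnames(ft) <- NULL
    gaze <- normalize_gaze(cbind(gz$x_px, gz$y_px), m$image_size)
    attr(gaze, "clamped") <- NULL
    structure(list(features = ft, gaze = gaze,
                   quats = unname(as.matrix(pb[, c("qw", "qx", "qy", "qz")])),
                   q_target = m$q_target,
                   angle_to_target = m$angle_to_target,
                   plane_type = m$plane_type, seed = m$seed),
              class = "sim_sequence")
  })
}

#' Dump fixation-center windows as JSON
#'
#' Serializes the output of [sliding_centers()] (skipping frames without a
#' window) to a JSON array of per-frame records with the window span,
#' centers, and weights.
#'
#' @param windows list from [sliding_centers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_center_windows <- function(windows, path) {
  recs <- list()
  for (t in seq_along(windows)) {
    cw <- windows[[t]]
    if (is.null(cw)) next
    recs[[length(recs) + 1L]] <- list(
      t = t, window_start = cw$window_start, window_end = cw$window_end,
      centers = unname(apply(cw$centers, 1L, as.numeric, simplify = FALSE)),
      weights = as.numeric(cw$weights))
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Dump decoded per-step policy distributions as JSON
#'
#' Serializes a [guidenet_rollout()] result to per-step parameter records
#' (gaze density and probe density), for inspection or for external
#' saliency rendering.
#'
#' @param predictions list from [guidenet_rollout()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_policy_params <- function(predictions, path) {
  recs <- lapply(predictions, function(pr) {
    gz <- if (inherits(pr$gaze, "gaze_mixture")) {
      list(type = "mixture", pi = as.numeric(pr$gaze$pi),
           components = lapply(pr$gaze$components, function(cp)
             list(mu = as.numeric(cp$mu), sigma = as.numeric(cp$sigma),
                  rho = cp$rho)))
    } else {
      list(type = "bivariate", mu = as.numeric(pr$gaze$mu),
           sigma = as.numeric(pr$gaze$sigma), rho = pr$gaze$rho)
    }
    list(t = pr$t, gaze = gz,
         probe = list(mu = as.numeric(pr$probe$mu),
                      chol = unname(apply(pr$probe$chol, 1L, as.numeric,
                                          simplify = FALSE))))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
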