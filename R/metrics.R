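#' Coarse/fine scan staging from the angle to the standard plane
#'
#' Frames with probe rotation angle to the standard plane above 10 degrees
#' are in the coarse-adjustment stage; at or below 10 degrees, fine
#' adjustment. Guidance metrics are averaged within stage.
#'
#' @param quats T x 4 probe orientations.
#' @param q_target standard-plane quaternion.
#' @return list with `stage` (character "coarse"/"fine" per frame) and
#'   `angle` (degrees to target per frame).
#' @export
stage_split <- function(quats, q_target) {
  ang <- quat_angle(as.matrix(quats), matrix(q_target, 1L))
  list(stage = ifelse(ang > 10, "coarse", "fine"), angle = ang)
}

#' Rotation-direction accuracy of probe guidance
#'
#' A predicted rotation step at frame t counts as correct if applying it at
#' q_{t-1} does not increase the angular distance to the guidance target:
#' the next true orientation q_t under the one-step (OP) policy, the fixed
#' standard-plane orientation q_T under SP. Accuracy is reported overall,
#' per stage (staging always against the standard plane), and per 10-degree
#' angle bin over 0-30 degrees.
#'
#' @param pred N x 4 matrix of predicted rotation quaternions for frames
#'   t = t0..T (row i is the step predicted at t = t0 + i - 1).
#' @param quats T x 4 true orientations.
#' @param q_plane standard-plane quaternion (used for staging, and as the
#'   accuracy target under SP).
#' @param policy "OP" or "SP".
#' @param t0 first predicted frame.
#' @return list with `overall`, `by_stage` (named vector), `by_bin`
#'   (named vector over "0-10", "10-20", "20-30"), and the per-frame table
#'   `frames`.
#' @export
direction_accuracy <- function(pred, quats, q_plane, policy = c("OP", "SP"),
                               t0 = 6L) {
  policy <- match.arg(policy)
  pred <- as.matrix(pred); quats <- as.matrix(quats)
  T_len <- nrow(quats)
  ts <- t0:T_len
  stopifnot(nrow(pred) == length(ts))
  correct <- logical(length(ts)); ang_plane <- numeric(length(ts))
  for (i in seq_along(ts)) {
    t <- ts[i]
    tgt <- if (policy == "OP") quats[t, ] else q_plane
    correct[i] <- is_toward_target(quats[t - 1L, ], pred[i, ], tgt)
    ang_plane[i] <- quat_angle(quats[t - 1L, ], q_plane)
  }
  stage <- ifelse(ang_plane > 10, "coarse", "fine")
  bins <- cut(ang_plane, breaks = c(0, 10, 20, 30), include.lowest = TRUE,
              labels = c("0-10", "10-20", "20-30"))
  by_stage <- vapply(c(coarse = "coarse", fine = "fine"), function(sg)
    if (any(stage == sg)) mean(correct[stage == sg]) else NA_real_, numeric(1))
  by_bin <- vapply(levels(bins), function(b)
    if (any(bins == b, na.rm = TRUE)) mean(correct[which(bins == b)]) else NA_real_,
    numeric(1))
  list(overall = mean(correct), by_stage = by_stage, by_bin = by_bin,
       frames = data.frame(t = ts, correct = correct, angle = ang_plane,
                           stage = stage))
}

#' Continuation baseline rotations
#'
#' The rotation baseline reuses the previous true rotation as the predicted
#' step at the current frame: r_hat_t = r_{t-1} = conj(q_{t-2}) q_{t-1}.
#'
#' @param quats T x 4 true orientations.
#' @param t0 first predicted frame (must be at least 3).
#' @return (T - t0 + 1) x 4 matrix of predicted rotation quaternions.
#' @export
baseline_continuation <- function(quats, t0 = 6L) {
  stopifnot(t0 >= 3L)
  quats <- as.matrix(quats)
  ts <- t0:nrow(quats)
  out <- matrix(0, length(ts), 4L)
  for (i in seq_along(ts)) {
    t <- ts[i]
    out[i, ] <- quat_relative(quats[t - 2L, ], quats[t - 1L, ])$r
  }
  out
}

#' Pixel error of a gaze prediction
#'
#' Both points are mapped back to pixels and compared by Euclidean
#' distance.
#'
#' @param pred,truth normalized gaze points (length 2).
#' @param image_size `c(width, height)` in pixels (default 288 x 224).
#' @return error in pixels.
#' @export
gaze_l2_error <- function(pred, truth, image_size = c(288L, 224L)) {
  d <- denormalize_gaze(pred, image_size) - denormalize_gaze(truth, image_size)
  sqrt(sum(d^2))
}

#' Best-of-N gaze error over sampled predictions
#'
#' Minimum pixel error over a set of sampled gaze points (the starred,
#' best-sampling variant of the gaze error).
#'
#' @param samples N x 2 matrix of sampled normalized gaze points.
#' @param truth normalized gaze point.
#' @param image_size `c(width, height)` in pixels.
#' @return minimum error in pixels.
#' @export
best_of_n_error <- function(samples, truth, image_size = c(288L, 224L)) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) >= 1L)
  min(vapply(seq_len(nrow(samples)), function(i)
    gaze_l2_error(samples[i, ], truth, image_size), numeric(1)))
}

# pixel-center grids in normalized coordinates
.px_grid <- function(image_size) {
  list(x = (seq_len(image_size[1L]) - 0.5) / image_size[1L] - 0.5,
       y = (seq_len(image_size[2L]) - 0.5) / image_size[2L] - 0.5)
}

.saliency <- function(values, norm = "sum1") {
  structure(list(values = values, norm = norm), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency map %d x %d (%s), max %.3g\n",
              nrow(x$values), ncol(x$values), x$norm, max(x$values)))
  invisible(x)
}

.biv_density_grid <- function(mu, sigma, rho, grid) {
  dx <- (grid$x - mu[1]) / sigma[1]
  dy <- (grid$y - mu[2]) / sigma[2]
  omr2 <- max(1 - rho^2, 1e-6)
  # rows = y (height), cols = x (width)
  qx <- matrix(dx^2, length(grid$y), length(grid$x), byrow = TRUE)
  qy <- matrix(dy^2, length(grid$y), length(grid$x))
  qxy <- outer(dy, dx)
  z <- (qx - 2 * rho * qxy + qy) / (2 * omr2)
  exp(-z) / (2 * pi * sigma[1] * sigma[2] * sqrt(omr2))
}

#' Render a predicted gaze distribution as a saliency map
#'
#' Translates the predicted shift distribution to absolute screen position
#' through its anchor — the previous gaze point for the one-step policy
#' (g_hat = g_{t-1} + s), the previous window's fixation centers for the
#' multi-step mixture (c_hat^l = c^l_{t-F} + s^l) — then evaluates the
#' density at every pixel center and normalizes the map to sum 1. If more
#' than half the probability mass falls off screen the map is flagged
#' (attribute `offscreen`, plus a warning) but still rendered on the
#' clamped domain.
#'
#' @param dist a `bivariate_gaussian` or `gaze_mixture`.
#' @param anchor length-2 normalized gaze point (OG), or a `center_window`
#'   / L x 2 matrix of anchor centers (MG).
#' @param image_size `c(width, height)` in pixels.
#' @return a `saliency_map` (values sum to 1).
#' @export
render_saliency <- function(dist, anchor, image_size = c(288L, 224L)) {
  grid <- .px_grid(image_size)
  if (inherits(dist, "bivariate_gaussian")) {
    comps <- list(dist); wts <- 1
    anchors <- matrix(anchor, 1L)
  } else if (inherits(dist, "gaze_mixture")) {
    comps <- dist$components; wts <- dist$pi
    anchors <- if (inherits(anchor, "center_window")) anchor$centers
               else as.matrix(anchor)
    stopifnot(nrow(anchors) == length(comps))
  } else stop("dist must be a bivariate_gaussian or gaze_mixture")
  vals <- 0
  for (l in seq_along(comps)) {
    mu_abs <- anchors[l, ] + comps[[l]]$mu
    vals <- vals + wts[l] *
      .biv_density_grid(mu_abs, comps[[l]]$sigma, comps[[l]]$rho, grid)
  }
  mass_on <- sum(vals) / (prod(image_size))  # density integral over screen
  off <- mass_on < 0.5
  if (off) warning("more than 50% of predicted gaze mass falls off screen")
  total <- sum(vals)
  if (total <= 0) vals <- matrix(1 / prod(image_size), image_size[2L], image_size[1L])
  else vals <- vals / total
  structure(.saliency(vals, "sum1"), offscreen = off)
}

#' Empirical saliency map from real gaze points
#'
#' Sum of isotropic pixel-space Gaussians centered at the gaze points,
#' normalized to sum 1.
#'
#' @param points N x 2 matrix (or length-2 vector) of normalized gaze
#'   points.
#' @param blur_sigma_px Gaussian blur sd in pixels (default 8, roughly one
#'   degree of visual angle at typical viewing distance).
#' @param image_size `c(width, height)` in pixels.
#' @return a `saliency_map`.
#' @export
empirical_saliency <- function(points, blur_sigma_px = 8,
                               image_size = c(288L, 224L)) {
  pts <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  stopifnot(nrow(pts) >= 1L)
  px <- denormalize_gaze(pts, image_size)
  vals <- matrix(0, image_size[2L], image_size[1L])
  xs <- seq_len(image_size[1L]) - 0.5
  ys <- seq_len(image_size[2L]) - 0.5
  for (i in seq_len(nrow(px))) {
    vals <- vals + outer(stats::dnorm(ys, px[i, 2L], blur_sigma_px),
                         stats::dnorm(xs, px[i, 1L], blur_sigma_px))
  }
  .saliency(vals / sum(vals), "sum1")
}

.as_sum1 <- function(p) {
  v <- p$values
  if (!isTRUE(all.equal(sum(v), 1, tolerance = 1e-6))) {
    warning("saliency map not sum-normalized; normalizing")
    v <- v / sum(v)
  }
  v
}

#' Saliency similarity (histogram intersection)
#'
#' Sum over pixels of the pixel-wise minimum of the two sum-normalized
#' maps; 1 for identical maps, 0 for disjoint support.
#'
#' @param p,q `saliency_map`s on the same raster.
#' @return scalar in \[0, 1\].
#' @export
saliency_sim <- function(p, q) sum(pmin(.as_sum1(p), .as_sum1(q)))

#' Linear correlation coefficient between saliency maps
#'
#' Pearson correlation of the flattened maps; 0 (with a warning) if either
#' map has zero variance.
#'
#' @param p,q `saliency_map`s on the same raster.
#' @return scalar in \[-1, 1\].
#' @export
saliency_cc <- function(p, q) {
  a <- as.numeric(p$values); b <- as.numeric(q$values)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance saliency map; CC defined as 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Kullback-Leibler divergence between saliency maps
#'
#' KL(p || q) with p the empirical target map and q the prediction
#' (saliency-benchmark convention), epsilon-stabilized:
#' sum p * log(eps + p / (q + eps)).
#'
#' @param p empirical (target) `saliency_map`.
#' @param q predicted `saliency_map`.
#' @param eps stabilizer (default 1e-7).
#' @return non-negative scalar (up to eps effects).
#' @export
saliency_kld <- function(p, q, eps = 1e-7) {
  pv <- .as_sum1(p); qv <- .as_sum1(q)
  sum(pv * log(eps + pv / (qv + eps)))
}

.fix_pixels <- function(fixations, image_size) {
  pts <- if (is.null(dim(fixations))) matrix(fixations, 1L) else as.matrix(fixations)
  px <- pmin(image_size[1L], pmax(1L, ceiling((pts[, 1L] + 0.5) * image_size[1L])))
  py <- pmin(image_size[2L], pmax(1L, ceiling((pts[, 2L] + 0.5) * image_size[2L])))
  cbind(py, px)  # row (y), col (x) indices into the map
}

#' AUC-Judd fixation metric
#'
#' ROC area with fixated pixels as positives: thresholds are taken at each
#' fixation's saliency value; the true-positive rate is the fraction of
#' fixations above threshold and the false-positive rate the fraction of
#' all pixels above threshold; the curve (with endpoints (0,0) and (1,1))
#' is integrated by trapezoid. A constant map scores 0.5 by convention.
#'
#' @param p a `saliency_map`.
#' @param fixations normalized gaze points (N x 2 or length-2).
#' @param image_size `c(width, height)`; defaults to the map's raster.
#' @return scalar in \[0, 1\].
#' @export
saliency_auc_judd <- function(p, fixations,
                              image_size = c(ncol(p$values), nrow(p$values))) {
  v <- p$values
  if (stats::sd(as.numeric(v)) == 0) return(0.5)
  idx <- .fix_pixels(fixations, image_size)
  fv <- v[idx]
  allv <- as.numeric(v)
  th <- sort(unique(fv), decreasing = TRUE)
  tpr <- vapply(th, function(h) mean(fv >= h), numeric(1))
  fpr <- vapply(th, function(h) mean(allv >= h), numeric(1))
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  ord <- order(xs, ys)
  xs <- xs[ord]; ys <- ys[ord]
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Normalized scanpath saliency
#'
#' Z-scores the map over pixels and averages the values at the fixated
#' pixels; 0 for a zero-variance map.
#'
#' @inheritParams saliency_auc_judd
#' @return scalar.
#' @export
saliency_nss <- function(p, fixations,
                         image_size = c(ncol(p$values), nrow(p$values))) {
  v <- as.numeric(p$values)
  s <- stats::sd(v)
  if (s == 0) return(0)
  z <- (p$values - mean(v)) / s
  idx <- .fix_pixels(fixations, image_size)
  mean(z[idx])
}

#' Evaluate a trained model on a dataset
#'
#' Rolls the model over each sequence (teacher-forced, one-step-ahead),
#' draws `n_samples` trajectories per step from the predicted densities and
#' averages them into point predictions, and computes: rotation-direction
#' accuracy (per stage and angle bin), gaze pixel error and best-of-N
#' error, and optionally the five saliency metrics against the empirical
#' map of the real gaze points in the trailing F-frame window. Per-sequence
#' scores average over the frames within each stage; cross-sequence summary
#' is mean and sd.
#'
#' @param model a `guidenet`.
#' @param dataset list of sequences.
#' @param n_samples sampled trajectories per step (default 100).
#' @param seed RNG seed for the sampling.
#' @param saliency also compute SIM/CC/KLD/AUC/NSS (slower).
#' @param image_size `c(width, height)` pixels for gaze metrics.
#' @return list with `per_sequence` (long-format data frame
#'   `sequence, stage, metric, value`) and `summary` (mean and sd by
#'   stage and metric).
#' @export
evaluate_guidenet <- function(model, dataset, n_samples = 100L, seed = 1L,
                              saliency = FALSE, image_size = c(288L, 224L)) {
  cfg <- model$config
  set.seed(seed)
  rows <- list()
  add <- function(sq, stage, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(sequence = sq, stage = stage,
                                             metric = metric, value = value)
  }
  for (si in seq_along(dataset)) {
    sq <- dataset[[si]]
    preds <- guidenet_rollout(model, sq)
    T_len <- nrow(sq$gaze)
    ts <- cfg$t0:T_len
    centers <- if (saliency && cfg$policy_gaze == "MG")
      sliding_centers(as.matrix(sq$gaze), cfg$L, cfg$F_win) else NULL
    pred_rot <- matrix(0, length(ts), 4L)
    gaze_err <- numeric(length(ts)); best_err <- numeric(length(ts))
    sal <- if (saliency) matrix(NA_real_, length(ts), 5L,
                                dimnames = list(NULL, c("SIM", "CC", "KLD", "AUC", "NSS")))
           else NULL
    for (i in seq_along(ts)) {
      t <- ts[i]; pr <- preds[[i]]
      draws_r <- sample_policy(pr$probe, n_samples)
      pred_rot[i, ] <- point_prediction(draws_r, quaternion = TRUE)
      draws_s <- sample_policy(pr$gaze, n_samples)
      s_hat <- point_prediction(draws_s, quaternion = FALSE)
      g_prev <- sq$gaze[t - 1L, ]
      g_hat <- reconstruct_gaze(g_prev, s_hat)
      gaze_err[i] <- gaze_l2_error(g_hat, sq$gaze[t, ], image_size)
      pts <- sweep(draws_s, 2L, as.numeric(g_prev), "+")
      pts[] <- pmin(0.5, pmax(-0.5, pts))
      best_err[i] <- best_of_n_error(pts, sq$gaze[t, ], image_size)
      if (saliency && t > cfg$F_win) {
        # mixtures are anchored at the previous window's fixation centers
        # (c_hat^l = c^l_{t-F} + s^l); the one-step density at g_{t-1}
        anchor <- if (cfg$policy_gaze == "MG") {
          cw <- if (t - cfg$F_win >= 1L) centers[[t - cfg$F_win]] else NULL
          if (!is.null(cw) && nrow(cw$centers) == cfg$L) cw else NULL
        } else g_prev
        if (!is.null(anchor)) {
          win_pts <- sq$gaze[(t - cfg$F_win + 1L):t, , drop = FALSE]
          pm <- render_saliency(pr$gaze, anchor, image_size)
          em <- empirical_saliency(win_pts, image_size = image_size)
          sal[i, ] <- c(saliency_sim(pm, em), saliency_cc(pm, em),
                        saliency_kld(em, pm),
                        saliency_auc_judd(pm, win_pts, image_size),
                        saliency_nss(pm, win_pts, image_size))
        }
      }
    }
    acc <- direction_accuracy(pred_rot, sq$quats, sq$q_target,
                              policy = cfg$policy_probe, t0 = cfg$t0)
    stage <- acc$frames$stage
    for (sg in unique(stage)) {
      sel <- stage == sg
      add(si, sg, "direction_accuracy", mean(acc$frames$correct[sel]))
      add(si, sg, "gaze_error_px", mean(gaze_err[sel]))
      add(si, sg, "gaze_error_best_px", mean(best_err[sel]))
      if (saliency) for (m in colnames(sal)) {
        vv <- sal[sel, m]
        if (any(!is.na(vv))) add(si, sg, m, mean(vv, na.rm = TRUE))
      }
    }
  }
  per_seq <- do.call(rbind, rows)
  summ <- stats::aggregate(value ~ stage + metric, per_seq, function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  summ <- data.frame(stage = summ$stage, metric = summ$metric,
                     mean = summ$value[, "mean"], sd = summ$value[, "sd"])
  list(per_sequence = per_seq, summary = summ)
}
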