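#' Synthetic scan simulator configuration
#'
#' Generates synchronized probe/gaze/feature streams with the statistical
#' structure the guidance model assumes: a quaternion trajectory that
#' approaches a random target plane geodesically (coarse phase, angle above
#' 10 degrees) and then oscillates back and forth while drifting onto it
#' (fine phase, at or below 10 degrees); fixation-saccade gaze dynamics over
#' 1-3 latent centers whose positions drift as the probe closes in; and
#' frame features that are an informative (seeded random linear) embedding
#' of the probe's angular error, the plane type, and the gaze position.
#'
#' Defaults emulate a 10 s clip at 6 Hz (T = 60) starting 30 degrees from
#' the target, closing 8% of the remaining geodesic per coarse step with
#' 0.5 degrees of per-step angular noise, two fixation centers with a 0.15
#' per-frame saccade probability, and 0.02 normalized units of fixation
#' jitter.
#'
#' @param n_sequences number of sequences.
#' @param T_len frames per sequence (60, i.e. 10 s at 6 Hz).
#' @param start_angle_deg initial angle to the target plane (30).
#' @param approach_fraction geodesic fraction closed per step (0.08), used
#'   in the default `"fraction"` approach mode.
#' @param approach_mode `"fraction"` closes a constant fraction of the
#'   remaining geodesic per step (decelerating approach); `"fixed"` rotates
#'   a constant `fixed_step_deg` toward the target each frame until arrival.
#' @param fixed_step_deg per-frame step size in degrees for the
#'   `"fixed"` approach mode (2).
#' @param fine_oscillation_deg amplitude of away-steps near the target (1).
#' @param rot_noise_deg sd of per-step angular noise in degrees (0.5).
#' @param n_fixation_centers latent fixation centers, 1..3 (2).
#' @param saccade_rate per-frame probability of switching center (0.15).
#' @param gaze_jitter sd of fixation noise in normalized units (0.02).
#' @param feature_dim frame-feature width (1,920).
#' @param feature_noise_sd additive feature noise sd (0.1).
#' @param plane_type one of "TVP", "ACP", "FSP".
#' @param seed global seed; per-sequence seeds fan out from it through a
#'   counter, so any single sequence is reproducible in isolation.
#' @return a `scan_sim_config` list.
#' @export
scan_sim_config <- function(n_sequences = 1L, T_len = 60L,
                            start_angle_deg = 30, approach_fraction = 0.08,
                            approach_mode = c("fraction", "fixed"),
                            fixed_step_deg = 2,
                            fine_oscillation_deg = 1, rot_noise_deg = 0.5,
                            n_fixation_centers = 2L, saccade_rate = 0.15,
                            gaze_jitter = 0.02, feature_dim = 1920L,
                            feature_noise_sd = 0.1,
                            plane_type = c("TVP", "ACP", "FSP"), seed = 1L) {
  plane_type <- match.arg(plane_type)
  approach_mode <- match.arg(approach_mode)
  stopifnot(saccade_rate >= 0, saccade_rate <= 1,
            approach_fraction >= 0, approach_fraction <= 1,
            n_fixation_centers >= 1L, n_fixation_centers <= 3L,
            T_len > 11L)
  structure(as.list(environment()), class = "scan_sim_config")
}

# anchor fixation centers per plane (normalized screen coordinates):
# head midline + lateral structures for TVP, closely spaced abdominal
# structures for ACP, the two femur ends for FSP.
.plane_layouts <- list(
  TVP = rbind(c(-0.02, -0.10), c(0.12, 0.08), c(-0.18, 0.15)),
  ACP = rbind(c(0.04, 0.00), c(-0.08, 0.09), c(0.12, -0.08)),
  FSP = rbind(c(-0.22, 0.04), c(0.22, -0.04), c(0.00, 0.12))
)

.seq_seed <- function(seed, i) (as.integer(seed) + i * 1000003L) %% 2147483647L

#' Simulate a probe-orientation trajectory
#'
#' Starts `start_angle_deg` from a uniformly random target orientation and
#' slerps `approach_fraction` of the remaining geodesic toward it each step,
#' perturbed by `rot_noise_deg` of angular noise about a random axis. Once
#' within 10 degrees (fine phase) every other step additionally backs away
#' by up to `fine_oscillation_deg` along the geodesic, emulating the
#' forward-and-backward refinements of a sonographer finalizing the plane.
#' With zero noise the final frame ends within 1 degree of the target.
#'
#' @param cfg a [scan_sim_config()].
#' @param seed optional seed override (defaults to `cfg$seed`).
#' @return list with `quats` (T x 4), `q_target`, `angle_to_target`
#'   (degrees, length T).
#' @export
simulate_probe <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  q_target <- quat_random(1L)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  q <- quat_canonicalize(quat_multiply(q_target,
        quat_from_axis_angle(ax, cfg$start_angle_deg)))
  T_len <- cfg$T_len
  quats <- matrix(0, T_len, 4L); quats[1L, ] <- q
  ang <- numeric(T_len); ang[1L] <- quat_angle(q, q_target)
  for (t in 2L:T_len) {
    a_prev <- quat_angle(q, q_target)
    if (t == T_len && cfg$rot_noise_deg == 0) {
      # settle onto the plane: end within 1 degree
      frac <- if (a_prev > 1) 1 - 1 / a_prev else 0
      base <- if (identical(cfg$approach_mode, "fixed"))
        min(1, cfg$fixed_step_deg / max(a_prev, 1e-9)) else cfg$approach_fraction
      q <- quat_slerp(q, q_target, max(frac, base))
    } else {
      frac <- if (identical(cfg$approach_mode, "fixed")) {
        min(1, cfg$fixed_step_deg / max(a_prev, 1e-9))
      } else cfg$approach_fraction
      q <- quat_slerp(q, q_target, frac)
      if (a_prev <= 10 && cfg$fine_oscillation_deg > 0 && t %% 2L == 0L) {
        a_now <- quat_angle(q, q_target)
        osc <- min(cfg$fine_oscillation_deg, 0.5 * a_now) * stats::runif(1)
        if (a_now > 1e-6)
          q <- quat_slerp(q_target, q, 1 + osc / a_now)
      }
      if (cfg$rot_noise_deg > 0) {
        nax <- stats::rnorm(3); nax <- nax / sqrt(sum(nax^2))
        q <- quat_multiply(q, quat_from_axis_angle(nax,
              stats::rnorm(1, 0, cfg$rot_noise_deg)))
      }
    }
    q <- quat_canonicalize(q)
    quats[t, ] <- q
    ang[t] <- quat_angle(q, q_target)
  }
  list(quats = quats, q_target = q_target, angle_to_target = ang)
}

#' Simulate a fixation-saccade gaze trace
#'
#' A hidden fixation index over the plane's anchor centers switches with
#' probability `saccade_rate` per frame; gaze is the current center plus
#' isotropic Gaussian jitter, clamped to the normalized screen. Center
#' positions drift toward their anchors as the probe approaches (each
#' carries a random initial offset scaled by the remaining angular error).
#'
#' @param cfg a [scan_sim_config()].
#' @param angle_to_target per-frame angle to target in degrees (length T).
#' @param seed optional seed override.
#' @param plane_layout matrix of anchor centers per row (defaults to the
#'   built-in layout for `cfg$plane_type`).
#' @return list with `gaze` (T x 2), `true_centers` (T x n x 2 array),
#'   `fix_index` (length T).
#' @export
simulate_gaze <- function(cfg, angle_to_target, seed = cfg$seed,
                          plane_layout = NULL) {
  set.seed(seed)
  n <- cfg$n_fixation_centers
  anchors <- if (is.null(plane_layout)) {
    .plane_layouts[[cfg$plane_type]][seq_len(n), , drop = FALSE]
  } else plane_layout[seq_len(n), , drop = FALSE]
  T_len <- length(angle_to_target)
  offs <- matrix(stats::rnorm(2L * n, 0, 0.06), n, 2L)
  rel <- angle_to_target / max(cfg$start_angle_deg, 1e-9)
  centers <- array(0, c(T_len, n, 2L))
  for (t in seq_len(T_len))
    centers[t, , ] <- anchors + rel[t] * offs
  idx <- integer(T_len)
  idx[1L] <- sample.int(n, 1L)
  if (T_len > 1L) for (t in 2L:T_len) {
    idx[t] <- if (stats::runif(1) < cfg$saccade_rate && n > 1L)
      sample(setdiff(seq_len(n), idx[t - 1L]), 1L) else idx[t - 1L]
  }
  g <- matrix(0, T_len, 2L)
  for (t in seq_len(T_len))
    g[t, ] <- centers[t, idx[t], ] + stats::rnorm(2, 0, cfg$gaze_jitter)
  g <- pmin(pmax(g, -0.4999), 0.4999)
  list(gaze = g, true_centers = centers, fix_index = idx)
}

#' Simulate frame features from the latent scan state
#'
#' Features stand in for the frame encoder's pooled output: a fixed,
#' seeded random linear embedding of a low-dimensional state code
#' (harmonic encodings of the angle to target, the plane one-hot, and the
#' gaze position) plus Gaussian noise. The embedding matrix is held fixed
#' across sequences and datasets so the feature-to-state mapping is stable
#' and linearly decodable.
#'
#' @param cfg a [scan_sim_config()].
#' @param angle_to_target length-T angles in degrees.
#' @param gaze T x 2 normalized gaze.
#' @param seed optional seed override (noise only; the embedding matrix has
#'   its own fixed seed).
#' @return T x feature_dim matrix.
#' @export
simulate_features <- function(cfg, angle_to_target, gaze, seed = cfg$seed) {
  stopifnot(length(angle_to_target) == nrow(gaze))
  a <- angle_to_target * pi / 180
  onehot <- matrix(0, length(a), 3L)
  onehot[, match(cfg$plane_type, c("TVP", "ACP", "FSP"))] <- 1
  z <- cbind(1, angle_to_target / 30, cos(a), sin(a), cos(2 * a), sin(2 * a),
             onehot, gaze)
  old <- .Random.seed_save()
  set.seed(97531L)  # fixed: the embedding is part of the simulator's design
  E <- matrix(stats::rnorm(ncol(z) * cfg$feature_dim, 0, 1 / sqrt(ncol(z))),
              ncol(z), cfg$feature_dim)
  .Random.seed_restore(old)
  set.seed(seed)
  out <- z %*% E
  if (cfg$feature_noise_sd > 0)
    out <- out + matrix(stats::rnorm(length(out), 0, cfg$feature_noise_sd),
                        nrow(out), ncol(out))
  out
}

#' Simulate one synchronized scan sequence
#'
#' @param cfg a [scan_sim_config()].
#' @param index sequence counter used to fan the global seed out to a
#'   per-sequence seed.
#' @return a `sim_sequence`: list with `features`, `gaze`, `quats`,
#'   `q_target`, `angle_to_target`, `true_centers`, `fix_index`,
#'   `plane_type`, `seed`.
#' @export
simulate_scan <- function(cfg, index = 1L) {
  sd_i <- .seq_seed(cfg$seed, index)
  pr <- simulate_probe(cfg, seed = sd_i)
  gz <- simulate_gaze(cfg, pr$angle_to_target, seed = sd_i + 1L)
  ft <- simulate_features(cfg, pr$angle_to_target, gz$gaze, seed = sd_i + 2L)
  structure(list(features = ft, gaze = gz$gaze, quats = pr$quats,
                 q_target = pr$q_target,
                 angle_to_target = pr$angle_to_target,
                 true_centers = gz$true_centers, fix_index = gz$fix_index,
                 plane_type = cfg$plane_type, seed = sd_i),
            class = "sim_sequence")
}

#' Simulate sequences with state-independent Gaussian gaze shifts
#'
#' Identification dataset for the one-step gaze head: probe and features
#' come from the standard simulator, but the gaze trace is a random walk
#' whose per-step shifts are i.i.d. draws from a known bivariate Gaussian
#' (mean `mu`, standard deviations `sigma`, correlation `rho`),
#' unconstrained by the screen. Because the shifts carry no state
#' dependence, a correctly trained one-step gaze head must converge to this
#' generating distribution — which makes the dataset a ground-truthed probe
#' of distribution recovery rather than a realistic scan.
#'
#' @param cfg a [scan_sim_config()] (probe/feature settings and
#'   `n_sequences`, `T_len`, `seed`).
#' @param mu,sigma length-2 generating mean and sd of the shifts.
#' @param rho generating correlation.
#' @return list of sequences; the generating parameters are attached as
#'   attribute `generating`.
#' @export
simulate_og_recovery_dataset <- function(cfg, mu = c(0.05, -0.03),
                                         sigma = c(0.3, 0.2), rho = 0.3) {
  ds <- lapply(seq_len(cfg$n_sequences), function(i) {
    sd_i <- .seq_seed(cfg$seed, i)
    pr <- simulate_probe(cfg, seed = sd_i)
    set.seed(sd_i + 7L)
    z1 <- stats::rnorm(cfg$T_len - 1L); z2 <- stats::rnorm(cfg$T_len - 1L)
    shifts <- cbind(mu[1] + sigma[1] * z1,
                    mu[2] + sigma[2] * (rho * z1 + sqrt(1 - rho^2) * z2))
    gaze <- rbind(c(0, 0), apply(shifts, 2L, cumsum))
    ft <- simulate_features(cfg, pr$angle_to_target, gaze * 0, seed = sd_i + 2L)
    structure(list(features = ft, gaze = gaze, quats = pr$quats,
                   q_target = pr$q_target,
                   angle_to_target = pr$angle_to_target,
                   plane_type = cfg$plane_type, seed = sd_i),
              class = "sim_sequence")
  })
  attr(ds, "generating") <- list(mu = mu, sigma = sigma, rho = rho)
  ds
}

#' Simulate a dataset of scan sequences in memory
#'
#' @param cfg a [scan_sim_config()].
#' @return list of `n_sequences` [simulate_scan()] results.
#' @export
simulate_dataset <- function(cfg) {
  lapply(seq_len(cfg$n_sequences), function(i) simulate_scan(cfg, i))
}

#' @export
print.sim_sequence <- function(x, ...) {
  cat(sprintf("sim_sequence (%s): %d frames, start %.1f deg, end %.2f deg\n",
              x$plane_type, nrow(x$gaze), x$angle_to_target[1],
              x$angle_to_target[length(x$angle_to_target)]))
  invisible(x)
}
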