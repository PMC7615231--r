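#' Policy distribution heads
#'
#' The guidance policies emit raw head vectors that are decoded into one of
#' three densities: a bivariate Gaussian over the next gaze shift (one-step
#' gaze policy, 5 raw numbers), an L-component bivariate Gaussian mixture
#' over fixation-center displacements (multi-step gaze policy, 6L raw
#' numbers including component-weight logits), and a 4-D multivariate
#' Gaussian over the quaternion rotation step (one-step / to-plane probe
#' policies, 14 raw numbers: a 4-vector mean plus a 10-entry Cholesky factor
#' of the covariance).
#'
#' Squashing transforms: the gaze mean passes through sigmoid(x) - 0.5 so it
#' stays on the normalized screen; standard deviations through exp;
#' correlations through tanh; mixture weights through softmax; the
#' quaternion covariance through a Cholesky factor with softplus diagonal.
#' The quaternion mean is left unconstrained — unit norm is encouraged only
#' softly by [quaternion_prior()] during training.
#'
#' @name density_heads
NULL

.sigmoid <- function(x) 1 / (1 + exp(-x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Decode the one-step gaze head
#'
#' @param raw numeric length-5 raw head output: (mu_x, mu_y, log sigma_x,
#'   log sigma_y, atanh-scale rho).
#' @return a `bivariate_gaussian`: list with `mu` (2-vector in (-0.5, 0.5)),
#'   `sigma` (positive 2-vector), `rho` (in (-1, 1)).
#' @export
decode_og <- function(raw) {
  stopifnot(length(raw) == 5L, all(is.finite(raw)))
  structure(list(mu = .sigmoid(raw[1:2]) - 0.5,
                 sigma = exp(raw[3:4]),
                 rho = tanh(raw[5])),
            class = "bivariate_gaussian")
}

#' Decode the multi-step gaze mixture head
#'
#' Raw layout: L blocks of 5 (as [decode_og()]) followed by L component
#' weight logits, softmaxed onto the simplex.
#'
#' @param raw numeric vector of length 6 L.
#' @param L number of mixture components.
#' @return a `gaze_mixture`: list with `components` (list of
#'   `bivariate_gaussian`) and `pi` (simplex weights).
#' @export
decode_mg <- function(raw, L) {
  if (L < 1L) stop("L must be at least 1")
  stopifnot(length(raw) == 6L * L, all(is.finite(raw)))
  comps <- lapply(seq_len(L), function(l) decode_og(raw[(5L * (l - 1L) + 1L):(5L * l)]))
  logits <- raw[(5L * L + 1L):(6L * L)]
  e <- exp(logits - max(logits))
  structure(list(components = comps, pi = e / sum(e)),
            class = "gaze_mixture")
}

#' Decode the probe rotation head
#'
#' The 14 raw numbers are the 4-D Gaussian mean (entries 1..4, unconstrained)
#' and the lower-triangular Cholesky factor of the covariance (entries 5..14,
#' column-major lower triangle; diagonal entries softplus-transformed with a
#' small floor so the covariance stays positive definite).
#'
#' @param raw numeric length-14 raw head output.
#' @return a `quat_gaussian`: list with `mu` (4-vector) and `chol`
#'   (4 x 4 lower triangular, positive diagonal); covariance is
#'   `chol %*% t(chol)`.
#' @export
decode_op <- function(raw) {
  stopifnot(length(raw) == 14L, all(is.finite(raw)))
  mu <- raw[1:4]
  Lm <- matrix(0, 4L, 4L)
  Lm[lower.tri(Lm, diag = TRUE)] <- raw[5:14]
  diag(Lm) <- .softplus(diag(Lm)) + 1e-4
  structure(list(mu = mu, chol = Lm), class = "quat_gaussian")
}

#' Negative log-likelihood of a gaze shift under the bivariate Gaussian
#'
#' Closed-form bivariate normal NLL with (1 - rho^2) floored at 1e-6 for
#' numerical safety.
#'
#' @param params a `bivariate_gaussian`.
#' @param s length-2 shift.
#' @return scalar NLL.
#' @export
nll_bivariate <- function(params, s) {
  dx <- (s[1] - params$mu[1]) / params$sigma[1]
  dy <- (s[2] - params$mu[2]) / params$sigma[2]
  r <- params$rho
  omr2 <- max(1 - r^2, 1e-6)
  z <- dx^2 - 2 * r * dx * dy + dy^2
  log(2 * pi) + log(params$sigma[1]) + log(params$sigma[2]) +
    0.5 * log(omr2) + z / (2 * omr2)
}

#' Negative log-likelihood under the gaze-center mixture
#'
#' -log sum_l pi_l N_l(s), computed through log-sum-exp so it is stable for
#' component log-densities down to -700.
#'
#' @param params a `gaze_mixture`.
#' @param s length-2 displacement.
#' @return scalar NLL.
#' @export
nll_mixture <- function(params, s) {
  ll <- vapply(seq_along(params$components), function(l) {
    log(params$pi[l]) - nll_bivariate(params$components[[l]], s)
  }, numeric(1))
  m <- max(ll)
  -(m + log(sum(exp(ll - m))))
}

#' Negative log-likelihood of a rotation step under the 4-D Gaussian
#'
#' Standard multivariate normal NLL evaluated at the (sign-canonical)
#' quaternion components of the rotation step, using the Cholesky factor
#' directly (triangular solve; no covariance inversion).
#'
#' @param params a `quat_gaussian`.
#' @param r a `rotation_step` or length-4 quaternion.
#' @return scalar NLL.
#' @export
nll_quat <- function(params, r) {
  if (inherits(r, "rotation_step")) r <- r$r
  d <- as.numeric(r) - params$mu
  y <- forwardsolve(params$chol, d)
  2 * log(2 * pi) + sum(log(diag(params$chol))) + 0.5 * sum(y^2)
}

#' Unit-norm prior on the predicted quaternion mean
#'
#' eta * (1 - ||mu||_2)^2: zero exactly on the unit sphere. Added to the
#' training loss so the probe head's Gaussian mean behaves like a rotation
#' without hard normalization.
#'
#' @param mu 4-vector mean.
#' @param eta prior weight (default 50).
#' @return scalar penalty.
#' @export
quaternion_prior <- function(mu, eta = 50) {
  eta * (1 - sqrt(sum(mu^2)))^2
}

#' Sample from a decoded policy distribution
#'
#' i.i.d. draws: bivariate Gaussians via the Cholesky of their 2 x 2
#' covariance; mixtures pick a component by its weight then sample it;
#' quaternion Gaussians via their 4 x 4 Cholesky factor. Reproducible under
#' a fixed seed.
#'
#' @param params a `bivariate_gaussian`, `gaze_mixture`, or `quat_gaussian`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return n x d matrix of draws (d = 2 or 4).
#' @export
sample_policy <- function(params, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  UseMethod("sample_policy")
}

#' @export
sample_policy.bivariate_gaussian <- function(params, n, seed = NULL) {
  sx <- params$sigma[1]; sy <- params$sigma[2]; r <- params$rho
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(params$mu[1] + sx * z1,
        params$mu[2] + sy * (r * z1 + sqrt(max(1 - r^2, 1e-12)) * z2))
}

#' @export
sample_policy.gaze_mixture <- function(params, n, seed = NULL) {
  comp <- sample.int(length(params$pi), n, replace = TRUE, prob = params$pi)
  out <- matrix(0, n, 2L)
  for (l in unique(comp)) {
    idx <- which(comp == l)
    out[idx, ] <- sample_policy.bivariate_gaussian(params$components[[l]], length(idx))
  }
  out
}

#' @export
sample_policy.quat_gaussian <- function(params, n, seed = NULL) {
  z <- matrix(stats::rnorm(4L * n), n, 4L)
  sweep(z %*% t(params$chol), 2L, params$mu, "+")
}

#' Average sampled draws into a single point prediction
#'
#' Component-wise mean of the draws; quaternion draws are additionally
#' renormalized to unit norm and sign-canonicalized so the average is again
#' a rotation.
#'
#' @param draws n x d matrix of draws from [sample_policy()].
#' @param quaternion treat columns as quaternion components (renormalize).
#' @return length-d point prediction.
#' @export
point_prediction <- function(draws, quaternion = ncol(draws) == 4L) {
  stopifnot(nrow(draws) >= 1L)
  m <- colMeans(draws)
  if (quaternion) {
    n <- sqrt(sum(m^2))
    if (n < 1e-12) return(quat_identity())
    m <- quat_canonicalize(m / n)
  }
  m
}
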