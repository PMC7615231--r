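# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: rotations go through Rodrigues-formula matrices,
# densities through generic solve()-based formulas, clustering through
# exhaustive partition enumeration.

# internal tape primitives, pulled into the test environment
for (.nm in c("tp_new", "tp_push", "tp_val", "tp_const", "tp_param",
              "tp_matmul", "tp_add", "tp_sub", "tp_mul", "tp_div",
              "tp_add_bias", "tp_colmul", "tp_rowmul", "tp_rowdot",
              "tp_scale", "tp_addc", "tp_neg", "tp_sigmoid", "tp_tanh",
              "tp_relu", "tp_exp", "tp_log", "tp_sqrt", "tp_softplus",
              "tp_pmax_const", "tp_sum", "tp_mean", "tp_cbind", "tp_cols",
              "tp_rows", "tp_addn", "tp_softmax_rows", "tp_logsumexp_rows",
              "tp_batchnorm", "tp_backward", "tp_grad")) {
  assign(.nm, getFromNamespace(.nm, "sonoguide"))
}

# Rodrigues rotation matrix from axis (unnormalized ok) and angle in degrees
oracle_rotmat <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation matrix from a unit quaternion, written out independently
oracle_quat2mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, 3, byrow = TRUE)
}

# rotation angle (degrees) of a rotation matrix
oracle_mat_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# generic multivariate normal negative log density via solve()
oracle_mvn_nll <- function(x, mu, Sigma) {
  d <- length(mu)
  dev <- x - mu
  0.5 * (d * log(2 * pi) + as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
           as.numeric(t(dev) %*% solve(Sigma) %*% dev))
}

oracle_biv_cov <- function(sigma, rho) {
  matrix(c(sigma[1]^2, rho * prod(sigma), rho * prod(sigma), sigma[2]^2), 2, 2)
}

# all partitions of n points into at most k non-empty groups (n small)
oracle_partitions <- function(n, k) {
  grow <- function(assign, next_label) {
    i <- length(assign) + 1L
    if (i > n) return(list(assign))
    out <- list()
    for (l in seq_len(min(next_label, k))) {
      out <- c(out, grow(c(assign, l), next_label + (l == next_label)))
    }
    out
  }
  grow(integer(0), 1L)
}

# minimal total within-cluster sum of squares over all partitions into <= k
oracle_best_wss <- function(points, k) {
  parts <- oracle_partitions(nrow(points), k)
  best <- Inf
  for (p in parts) {
    w <- 0
    for (l in unique(p)) {
      m <- points[p == l, , drop = FALSE]
      w <- w + sum(sweep(m, 2, colMeans(m))^2)
    }
    best <- min(best, w)
  }
  best
}

cluster_wss <- function(points, cw) {
  w <- 0
  for (l in unique(cw$assign)) {
    m <- points[cw$assign == l, , drop = FALSE]
    w <- w + sum(sweep(m, 2, colMeans(m))^2)
  }
  w
}

random_raw_quat <- function() stats::rnorm(4)

# small model used throughout the recurrent-core tests
tiny_model <- function(seed = 1, hidden = 8, ...) {
  cfg <- guidenet_config(feature_dim = 16, embed = hidden, hidden = hidden,
                         proj = 12, ...)
  guidenet_init(cfg, seed = seed)
}

tiny_sequence <- function(seed = 1, T_len = 16) {
  cfg <- scan_sim_config(n_sequences = 1, feature_dim = 16, T_len = T_len,
                         seed = seed)
  simulate_scan(cfg, 1)
}
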