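# Density heads: decoding transforms, NLLs against generic oracles,
# sampling, and point predictions.

test_that("one-step gaze decode squashes into valid parameter ranges", {
  p <- decode_og(rep(0, 5))
  expect_equal(p$mu, c(0, 0))
  expect_equal(p$sigma, c(1, 1))
  expect_equal(p$rho, 0)
  pe <- decode_og(c(20, -20, 0, 0, 0))  # +/-20 saturates sigmoid to ~1e-9 of the rail
  expect_true(all(abs(pe$mu) < 0.5))
  set.seed(31)
  for (i in 1:1000) {
    p <- decode_og(rnorm(5, 0, 3))
    ev <- eigen(oracle_biv_cov(p$sigma, p$rho), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("mixture decode yields simplex weights and reduces to one component", {
  p <- decode_mg(rep(0, 18), 3L)
  expect_equal(p$pi, rep(1 / 3, 3))
  raw <- rnorm(6)
  p1 <- decode_mg(raw, 1L)
  ref <- decode_og(raw[1:5])
  expect_equal(p1$components[[1]], ref)
  expect_equal(p1$pi, 1)
  set.seed(32)
  for (i in 1:1000) {
    p <- decode_mg(rnorm(18, 0, 4), 3L)
    expect_equal(sum(p$pi), 1, tolerance = 1e-6)
    expect_true(all(p$pi >= 0))
  }
  expect_error(decode_mg(numeric(0), 0L), "at least 1")
})

test_that("probe decode consumes exactly 14 numbers into a PD Gaussian", {
  p <- decode_op(rep(0, 14))
  expect_equal(p$mu, rep(0, 4))
  sp0 <- log(1 + exp(0)) + 1e-4
  expect_equal(p$chol %*% t(p$chol), diag(sp0^2, 4), tolerance = 1e-12)
  expect_error(decode_op(rep(0, 13)))
  expect_error(decode_op(rep(0, 15)))
  set.seed(33)
  for (i in 1:1000) {
    p <- decode_op(rnorm(14, 0, 2))
    ev <- eigen(p$chol %*% t(p$chol), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("bivariate NLL matches the closed form and the generic MVN oracle", {
  std <- decode_og(rep(0, 5))
  expect_equal(nll_bivariate(std, c(0, 0)), log(2 * pi))
  set.seed(34)
  for (i in 1:100) {
    p <- decode_og(rnorm(5))
    s <- rnorm(2, 0, 0.3)
    expect_equal(nll_bivariate(p, s),
                 oracle_mvn_nll(s, p$mu, oracle_biv_cov(p$sigma, p$rho)),
                 tolerance = 1e-8)
  }
  # minimized exactly at the mean
  p <- decode_og(c(0.3, -0.2, -1, -0.5, 0.4))
  base <- nll_bivariate(p, p$mu)
  for (d in list(c(1e-3, 0), c(-1e-3, 0), c(0, 1e-3), c(0, -1e-3)))
    expect_gt(nll_bivariate(p, p$mu + d), base)
})

test_that("mixture NLL is a stable log-sum-exp of its components", {
  raw <- rnorm(6)
  p1 <- decode_mg(raw, 1L)
  expect_equal(nll_mixture(p1, c(0.1, 0)), nll_bivariate(p1$components[[1]], c(0.1, 0)))
  set.seed(35)
  for (i in 1:100) {
    p <- decode_mg(rnorm(18), 3L)
    s <- rnorm(2, 0, 0.3)
    direct <- -log(sum(vapply(1:3, function(l)
      p$pi[l] * exp(-nll_bivariate(p$components[[l]], s)), numeric(1))))
    expect_equal(nll_mixture(p, s), direct, tolerance = 1e-8)
    # permutation symmetry
    perm <- p; perm$components <- p$components[c(3, 1, 2)]; perm$pi <- p$pi[c(3, 1, 2)]
    expect_equal(nll_mixture(perm, s), nll_mixture(p, s))
    # log-sum-exp sandwich around the best weighted component
    nlls <- vapply(1:3, function(l) nll_bivariate(p$components[[l]], s),
                   numeric(1))
    expect_lte(nll_mixture(p, s), min(nlls - log(p$pi)) + 1e-9)
    expect_gte(nll_mixture(p, s), min(nlls) - log(3) - 1e-9)
  }
})

test_that("quaternion NLL matches the Cholesky-free oracle", {
  p <- structure(list(mu = c(0.9, 0.1, 0, 0), chol = diag(4)),
                 class = "quat_gaussian")
  expect_equal(nll_quat(p, c(0.9, 0.1, 0, 0)), 2 * log(2 * pi))
  set.seed(36)
  for (i in 1:100) {
    p <- decode_op(rnorm(14))
    r <- rnorm(4)
    Sigma <- p$chol %*% t(p$chol)
    expect_equal(nll_quat(p, r), oracle_mvn_nll(r, p$mu, Sigma),
                 tolerance = 1e-8)
  }
})

test_that("quaternion prior vanishes exactly on the unit sphere", {
  expect_equal(quaternion_prior(quat_random()), 0, tolerance = 1e-12)
  expect_equal(quaternion_prior(c(0, 0, 0, 0), eta = 50), 50)
  # finite-difference gradient: nonzero off the sphere, ~zero on it
  fd_grad <- function(mu) {
    vapply(1:4, function(j) {
      e <- rep(0, 4); e[j] <- 1e-6
      (quaternion_prior(mu + e) - quaternion_prior(mu - e)) / 2e-6
    }, numeric(1))
  }
  set.seed(37)
  off <- rnorm(4) * 0.5
  expect_gt(max(abs(fd_grad(off))), 1e-3)
  expect_lt(max(abs(fd_grad(quat_random()))), 1e-4)
})

test_that("sampling reproduces the distribution and is seed-deterministic", {
  p <- decode_og(c(0.5, -0.3, -2, -1.5, 0.7))
  n <- 1e5
  dr <- sample_policy(p, n, seed = 41)
  se <- p$sigma / sqrt(n)
  expect_lt(max(abs(colMeans(dr) - p$mu) / se), 3)
  expect_lt(max(abs(apply(dr, 2, sd) / p$sigma - 1)), 0.02)
  expect_equal(cor(dr[, 1], dr[, 2]), p$rho, tolerance = 0.02)
  expect_identical(sample_policy(p, 100, seed = 42), sample_policy(p, 100, seed = 42))

  pm <- decode_mg(c(rep(0, 15), 0.3, -0.2, 0.8), 3L)
  comp_draw <- sample_policy(pm, n, seed = 43)
  expect_true(is.matrix(comp_draw) && ncol(comp_draw) == 2)

  pq <- decode_op(rnorm(14))
  dq <- sample_policy(pq, n, seed = 44)
  se_q <- sqrt(diag(pq$chol %*% t(pq$chol)) / n)
  expect_lt(max(abs(colMeans(dq) - pq$mu) / se_q), 3.5)
})

test_that("mixture component frequencies follow the weights", {
  pm <- decode_mg(c(0.4, 0, -6, -6, 0,  -0.4, 0, -6, -6, 0,  log(2), 0), 2L)
  # components well separated in x; classify draws by nearest mean
  n <- 1e5
  dr <- sample_policy(pm, n, seed = 45)
  frac1 <- mean(dr[, 1] > 0)
  se <- sqrt(pm$pi[1] * (1 - pm$pi[1]) / n)
  expect_lt(abs(frac1 - pm$pi[1]), 3 * se + 1e-3)
})

test_that("point prediction averages draws and renormalizes quaternions", {
  d <- matrix(rep(c(0.1, -0.2), each = 5), 5, 2)
  expect_equal(point_prediction(d), c(0.1, -0.2))
  d2 <- rbind(c(0.3, 0.1), -c(0.3, 0.1))
  expect_equal(point_prediction(d2), c(0, 0))
  pq <- structure(list(mu = quat_random(), chol = diag(4) * 1e-3),
                  class = "quat_gaussian")
  dq <- sample_policy(pq, 100, seed = 46)
  pp <- point_prediction(dq, quaternion = TRUE)
  expect_equal(sum(pp^2), 1, tolerance = 1e-9)
  expect_lt(max(abs(pp - quat_canonicalize(pq$mu))), 3e-3)
})

test_that("decoded densities integrate to one over their support", {
  p <- decode_og(c(0.2, -0.1, -2, -2.2, 0.5))
  gx <- seq(p$mu[1] - 6 * p$sigma[1], p$mu[1] + 6 * p$sigma[1], length.out = 201)
  gy <- seq(p$mu[2] - 6 * p$sigma[2], p$mu[2] + 6 * p$sigma[2], length.out = 201)
  dxy <- diff(gx)[1] * diff(gy)[1]
  tot <- sum(vapply(gx, function(x) sum(exp(-vapply(gy, function(y)
    nll_bivariate(p, c(x, y)), numeric(1)))), numeric(1))) * dxy
  expect_equal(tot, 1, tolerance = 0.01)
  pm <- decode_mg(c(0.2, -0.1, -2, -2.2, 0.5, -0.2, 0.1, -2, -2, 0, 0.3, -0.3), 2L)
  tot_m <- sum(vapply(seq(-0.5, 0.5, length.out = 301), function(x)
    sum(exp(-vapply(seq(-0.5, 0.5, length.out = 301), function(y)
      nll_mixture(pm, c(x, y)), numeric(1)))), numeric(1))) * (1 / 300)^2
  expect_equal(tot_m, 1, tolerance = 0.01)
})
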