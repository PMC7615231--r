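# Evaluation machinery: staging, direction accuracy, gaze errors, and the
# five saliency metrics against hand-computed toys.

test_that("stage labels split at the 10-degree boundary", {
  q_t <- quat_random()
  traj5 <- do.call(rbind, lapply(1:10, function(i)
    quat_multiply(q_t, quat_from_axis_angle(c(1, 0, 0), 5))))
  st <- stage_split(traj5, q_t)
  expect_true(all(st$stage == "fine"))
  q10 <- quat_multiply(q_t, quat_from_axis_angle(c(0, 1, 0), 10))
  expect_equal(stage_split(matrix(q10, 1), q_t)$stage, "fine")
  q11 <- quat_multiply(q_t, quat_from_axis_angle(c(0, 1, 0), 10.01))
  expect_equal(stage_split(matrix(q11, 1), q_t)$stage, "coarse")
  # monotone approach crosses coarse -> fine exactly once
  traj <- t(vapply(seq(0, 1, length.out = 40), function(f)
    quat_slerp(quat_multiply(q_t, quat_from_axis_angle(c(0, 0, 1), 30)), q_t, f),
    numeric(4)))
  stm <- stage_split(traj, q_t)
  expect_equal(sum(diff(stm$stage == "fine") != 0), 1L)
})

test_that("direction accuracy scores true, identity, and inverted steps", {
  cfg <- scan_sim_config(T_len = 40, rot_noise_deg = 0,
                         fine_oscillation_deg = 0, seed = 101)
  pr <- simulate_probe(cfg)
  ts <- 6:40
  truth <- t(vapply(ts, function(t)
    quat_relative(pr$quats[t - 1, ], pr$quats[t, ])$r, numeric(4)))
  expect_equal(direction_accuracy(truth, pr$quats, pr$q_target, "OP")$overall, 1)
  idp <- matrix(rep(quat_identity(), length(ts)), ncol = 4, byrow = TRUE)
  expect_equal(direction_accuracy(idp, pr$quats, pr$q_target, "OP")$overall, 1)
  inv <- t(apply(truth, 1, quat_conjugate))
  acc_inv <- direction_accuracy(inv, pr$quats, pr$q_target, "SP")$overall
  expect_equal(acc_inv, 0)
  # per-bin output covers the 0-30 degree axis
  da <- direction_accuracy(truth, pr$quats, pr$q_target, "SP")
  expect_named(da$by_bin, c("0-10", "10-20", "20-30"))
})

test_that("the continuation baseline is perfect on noiseless approaches and degrades with noise", {
  acc_at_noise <- function(noise) {
    accs <- vapply(1:15, function(i) {
      cfg <- scan_sim_config(T_len = 40, rot_noise_deg = noise,
                             fine_oscillation_deg = 0, seed = 200 + i)
      pr <- simulate_probe(cfg)
      direction_accuracy(baseline_continuation(pr$quats, 6L), pr$quats,
                         pr$q_target, "OP", 6L)$overall
    }, numeric(1))
    mean(accs)
  }
  expect_equal(acc_at_noise(0), 1)
  a1 <- acc_at_noise(1); a4 <- acc_at_noise(4)
  expect_lt(a1, 1)
  expect_lt(a4, a1)
})

test_that("gaze pixel errors follow the screen geometry", {
  expect_equal(gaze_l2_error(c(0.1, 0.1), c(0.1, 0.1)), 0)
  expect_equal(gaze_l2_error(c(0, 0), c(0.5, 0), c(288, 224)), 144)
  a <- c(0.12, -0.3); b <- c(-0.2, 0.05)
  expect_equal(gaze_l2_error(a, b), gaze_l2_error(b, a))
})

test_that("best-of-N error is the minimum and never hurt by more samples", {
  truth <- c(0.1, 0.1)
  s1 <- matrix(c(0.2, 0.1), 1)
  expect_equal(best_of_n_error(s1, truth), gaze_l2_error(c(0.2, 0.1), truth))
  set.seed(103)
  p <- decode_og(c(0.4, 0.4, -3, -3, 0))
  draws <- sample_policy(p, 100, seed = 7)
  e_all <- best_of_n_error(draws, truth)
  e_half <- best_of_n_error(draws[1:50, ], truth)
  expect_lte(e_all, e_half)
  mean_err <- mean(vapply(seq_len(100), function(i)
    gaze_l2_error(draws[i, ], truth), numeric(1)))
  expect_lte(e_all, mean_err)
})

test_that("rendered saliency maps are normalized densities with the right modes", {
  p <- decode_og(c(0, 0, log(0.02), log(0.02), 0))
  sm <- render_saliency(p, c(0, 0), c(288, 224))
  expect_equal(sum(sm$values), 1, tolerance = 1e-9)
  peak <- which(sm$values == max(sm$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(112, 144), tolerance = 2)
  # two well-separated mixture components give two local maxima
  raw <- c(0, 0, log(0.03), log(0.03), 0,
           0, 0, log(0.03), log(0.03), 0, 0, 0)
  pm <- decode_mg(raw, 2L)
  anchors <- rbind(c(-0.25, 0), c(0.25, 0))
  sm2 <- render_saliency(pm, anchors, c(288, 224))
  px <- sonoguide:::.fix_pixels(anchors, c(288, 224))
  for (i in 1:2) {
    v <- sm2$values
    r <- px[i, 1]; c <- px[i, 2]
    expect_true(v[r, c] > v[r - 8, c] && v[r, c] > v[r + 8, c] &&
                  v[r, c] > v[r, c - 8] && v[r, c] > v[r, c + 8])
  }
  expect_warning(render_saliency(decode_og(c(20, 20, log(0.01), log(0.01), 0)),
                                 c(0.49, 0.49), c(288, 224)), "off screen")
})

test_that("empirical saliency is an order-invariant unit-mass blur", {
  pts <- rbind(c(-0.2, 0.1), c(0.3, -0.2), c(0, 0))
  m1 <- empirical_saliency(pts, 8, c(288, 224))
  m2 <- empirical_saliency(pts[c(3, 1, 2), ], 8, c(288, 224))
  expect_equal(sum(m1$values), 1, tolerance = 1e-9)
  expect_equal(m1$values, m2$values)
  single <- empirical_saliency(c(0.1, 0), 8, c(288, 224))
  pk <- which(single$values == max(single$values), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), unname(sonoguide:::.fix_pixels(c(0.1, 0), c(288, 224))[1, ]),
               tolerance = 1.5)
})

test_that("SIM, CC, KLD reproduce hand-computed toy values", {
  mk <- function(v, nr = 2) structure(list(values = matrix(v, nr), norm = "sum1"),
                                      class = "saliency_map")
  p <- mk(c(0.5, 0.5, 0, 0)); q <- mk(rep(0.25, 4))
  expect_equal(saliency_sim(p, q), 0.5)
  expect_equal(saliency_sim(p, p), 1)
  expect_equal(saliency_sim(p, mk(c(0, 0, 0.5, 0.5))), 0)
  expect_equal(saliency_cc(p, p), 1)
  anti <- mk(0.5 - matrix(p$values, 2))
  expect_equal(saliency_cc(p, anti), -1)
  set.seed(104)
  a <- mk(runif(4)); b <- mk(runif(4))
  co <- function(x) as.numeric(x$values)
  expect_equal(saliency_cc(a, b),
               mean((co(a) - mean(co(a))) * (co(b) - mean(co(b)))) /
                 (sd(co(a)) * sd(co(b)) * (3 / 4)), tolerance = 1e-10)
  expect_warning(cc0 <- saliency_cc(a, mk(rep(0.25, 4))), "zero-variance")
  expect_equal(cc0, 0)
  # KLD toy: p = (1, 0), q = (0.5, 0.5) -> log 2
  p2 <- mk(c(1, 0), nr = 1); q2 <- mk(c(0.5, 0.5), nr = 1)
  expect_equal(saliency_kld(p2, q2), log(2), tolerance = 1e-5)
  expect_equal(saliency_kld(p2, p2), 0, tolerance = 1e-5)
  for (i in 1:20) {
    x <- mk(prop.table(runif(4))); y <- mk(prop.table(runif(4)))
    expect_gte(saliency_kld(x, y), -1e-6)
  }
})

test_that("AUC-Judd and NSS behave on constructed maps", {
  sz <- c(40L, 30L)
  delta <- matrix(1e-9, sz[2], sz[1])
  fx <- c(0.1, -0.1)
  px <- sonoguide:::.fix_pixels(fx, sz)
  delta[px] <- 1
  dm <- structure(list(values = delta / sum(delta), norm = "sum1"),
                  class = "saliency_map")
  expect_gt(saliency_auc_judd(dm, fx, sz), 0.99)
  const <- structure(list(values = matrix(1 / prod(sz), sz[2], sz[1]),
                          norm = "sum1"), class = "saliency_map")
  expect_equal(saliency_auc_judd(const, fx, sz), 0.5)
  expect_equal(saliency_nss(const, fx, sz), 0)
  # several fixations parked on the lowest-saliency pixels score near zero
  set.seed(105)
  vals <- matrix(runif(prod(sz), 0.5, 1), sz[2], sz[1])
  fx_low <- cbind(seq(-0.45, 0.45, length.out = 20), rep(0.2, 20))
  px_low <- sonoguide:::.fix_pixels(fx_low, sz)
  vals[px_low] <- seq(0.001, 0.005, length.out = 20)
  low <- structure(list(values = vals / sum(vals), norm = "sum1"),
                   class = "saliency_map")
  expect_lt(saliency_auc_judd(low, fx_low, sz), 0.05)
  # NSS direct-formula oracle and positivity at the brightest pixel
  rnd <- structure(list(values = matrix(runif(prod(sz)), sz[2], sz[1]),
                        norm = "density"), class = "saliency_map")
  v <- as.numeric(rnd$values)
  z <- (rnd$values - mean(v)) / sd(v)
  expect_equal(saliency_nss(rnd, fx, sz), z[px], tolerance = 1e-10)
  bright <- which(rnd$values == max(rnd$values), arr.ind = TRUE)[1, ]
  fx_bright <- c((bright[2] - 0.5) / sz[1] - 0.5, (bright[1] - 0.5) / sz[2] - 0.5)
  expect_gt(saliency_nss(rnd, fx_bright, sz), 0)
})

test_that("a matched predictive density beats a translated one on all metrics", {
  set.seed(106)
  gen <- decode_og(c(0, 0, log(0.04), log(0.04), 0))
  fix <- sample_policy(gen, 40, seed = 9)
  sz <- c(96L, 72L)
  emp <- empirical_saliency(fix, blur_sigma_px = 3, sz)
  match_map <- render_saliency(gen, c(0, 0), sz)
  shifted <- decode_og(c(2, 2, log(0.04), log(0.04), 0))  # mean pushed off
  mis_map <- render_saliency(shifted, c(0, 0), sz)
  expect_gt(saliency_sim(match_map, emp), saliency_sim(mis_map, emp))
  expect_gt(saliency_cc(match_map, emp), saliency_cc(mis_map, emp))
  expect_lt(saliency_kld(emp, match_map), saliency_kld(emp, mis_map))
  expect_gt(saliency_auc_judd(match_map, fix, sz),
            saliency_auc_judd(mis_map, fix, sz))
  expect_gt(saliency_nss(match_map, fix, sz), saliency_nss(mis_map, fix, sz))
})

test_that("model evaluation produces staged long-format scores", {
  m <- tiny_model(seed = 107)
  cfg <- scan_sim_config(n_sequences = 2, feature_dim = 16, T_len = 30,
                         seed = 107)
  ds <- simulate_dataset(cfg)
  ev <- evaluate_guidenet(m, ds, n_samples = 10L, seed = 1L)
  expect_true(all(c("sequence", "stage", "metric", "value") %in%
                    names(ev$per_sequence)))
  expect_true(all(ev$per_sequence$stage %in% c("coarse", "fine")))
  expect_true(all(c("direction_accuracy", "gaze_error_px",
                    "gaze_error_best_px") %in% ev$per_sequence$metric))
  expect_true(all(is.finite(ev$per_sequence$value)))
})

test_that("mixture-policy evaluation anchors saliency at the window centers", {
  cfg <- guidenet_config("OP", "MG", L = 2L, feature_dim = 16, embed = 8,
                         hidden = 8, proj = 12)
  m <- guidenet_init(cfg, seed = 108)
  ds <- simulate_dataset(scan_sim_config(n_sequences = 1, feature_dim = 16,
                                         T_len = 24, n_fixation_centers = 2L,
                                         saccade_rate = 0.4, seed = 108))
  ev <- suppressWarnings(evaluate_guidenet(m, ds, n_samples = 5L, seed = 1,
                                           saliency = TRUE))
  expect_true(all(c("SIM", "CC", "KLD", "AUC", "NSS") %in%
                    ev$per_sequence$metric))
  expect_true(all(is.finite(ev$per_sequence$value)))
})
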