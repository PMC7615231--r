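# Twin GCGRU streams, bidirectional pathway, heads, and rollout semantics.

test_that("gates are sigmoid-bounded and match hand arithmetic on a toy", {
  m <- tiny_model(seed = 71, hidden = 2)
  set.seed(71)
  g <- gru_gates(m, "s", rnorm(2), rnorm(2), rnorm(2))
  expect_true(all(g$z > 0 & g$z < 1))
  expect_true(all(g$gamma > 0 & g$gamma < 1))

  m0 <- m
  m0$params[["gru.s.Uz"]][] <- 0; m0$params[["gru.s.Ug"]][] <- 0
  m0$params[["gru.s.bz"]][] <- 0; m0$params[["gru.s.bg"]][] <- 0
  g0 <- gru_gates(m0, "s", c(0, 0), c(0, 0), rnorm(2))
  expect_equal(g0$z, c(0.5, 0.5))
  expect_equal(g0$gamma, c(0.5, 0.5))

  # hand-worked 2-channel case
  mh <- m
  mh$params[["gru.s.Uz"]] <- matrix(c(0.5, -0.25, 1, 0.75), 2, 2)
  mh$params[["gru.s.bz"]] <- matrix(c(0.1, -0.2), 1, 2)
  h_prev <- c(1, -2); msg_z <- c(0.3, 0.4)
  pre <- msg_z + as.numeric(h_prev %*% mh$params[["gru.s.Uz"]]) + c(0.1, -0.2)
  gh <- gru_gates(mh, "s", msg_z, c(0, 0), h_prev)
  expect_equal(gh$z, 1 / (1 + exp(-pre)))
})

test_that("candidate state is tanh-bounded and drops recurrence at gamma 0", {
  m <- tiny_model(seed = 72, hidden = 4)
  set.seed(72)
  msg_h <- rnorm(4); h_prev <- rnorm(4)
  cand <- candidate_state(m, "r", msg_h, runif(4), h_prev)
  expect_true(all(abs(cand) < 1))
  c0 <- candidate_state(m, "r", msg_h, rep(0, 4), h_prev)
  expect_equal(c0, as.numeric(tanh(msg_h + m$params[["gru.r.bh"]])))
  # hand-worked scalar-style check
  mh <- m
  mh$params[["gru.r.Uh"]] <- diag(4) * 2
  mh$params[["gru.r.bh"]][] <- 0
  gam <- c(1, 0.5, 0, 1)
  expect_equal(candidate_state(mh, "r", rep(0, 4), gam, h_prev),
               as.numeric(tanh(2 * gam * h_prev)))
})

test_that("pathway coefficients form a convex combination and recover the GRU", {
  set.seed(73)
  for (i in 1:200) {
    h_s <- rnorm(8); h_r <- rnorm(8); c_s <- rnorm(8); c_r <- rnorm(8)
    z_s <- runif(8); z_r <- runif(8); a <- runif(8); b <- runif(8)
    hw <- pathway_update(h_s, h_r, c_s, c_r, z_s, z_r, a, b)
    # coefficient identity: with h_prev = cand = 1 the update must return 1
    one <- rep(1, 8)
    hw1 <- pathway_update(one, one, one, one, z_s, z_r, a, b)
    expect_equal(hw1$h_s, one, tolerance = 1e-6)
    expect_equal(hw1$h_r, one, tolerance = 1e-6)
    # alpha = 1 / beta = 1 are exactly the standard GRU updates
    hw_std <- pathway_update(h_s, h_r, c_s, c_r, z_s, z_r, rep(1, 8), rep(1, 8))
    expect_equal(hw_std$h_s, (1 - z_s) * h_s + z_s * c_s)
    expect_equal(hw_std$h_r, (1 - z_r) * h_r + z_r * c_r)
  }
  # hand-worked scalar case: alpha 0.5, z_s 0.2, z_r 0.8
  hw <- pathway_update(1, 2, -1, -2, 0.2, 0.8, 0.5, 0.5)
  expect_equal(hw$h_s, 0.5 * (0.8 * 1 + 0.2 * -1) + 0.5 * (0.8 * 1 + 0.2 * -1))
  expect_equal(hw$h_r, 0.5 * (0.2 * 2 + 0.8 * -2) + 0.5 * (0.2 * 2 + 0.8 * -2))
})

test_that("head sizes follow the policies and the step is a pure function", {
  sizes <- list(c("OP", "OG", 1L, 5L), c("OP", "MG", 3L, 18L),
                c("SP", "OG", 1L, 5L))
  for (sp in sizes) {
    cfg <- guidenet_config(sp[[1]], sp[[2]], L = as.integer(sp[[3]]),
                           feature_dim = 16)
    m <- guidenet_init(cfg, seed = 74)
    st <- guidenet_step(m, rnorm(16), c(0.01, 0), quat_identity())
    expect_length(st$raw_gaze, as.integer(sp[[4]]))
    expect_length(st$raw_probe, 14L)
    st2 <- guidenet_step(m, rnorm(16), c(0.01, 0), quat_identity())
    expect_length(st2$raw_gaze, as.integer(sp[[4]]))
  }
  expect_error(guidenet_config("SP", "MG"), "unsupported")
  m <- tiny_model(seed = 74)
  set.seed(74)
  xI <- rnorm(16); s <- rnorm(2, 0, 0.1); r <- quat_random()
  st1 <- guidenet_step(m, xI, s, r)
  st2 <- guidenet_step(m, xI, s, r)
  expect_identical(st1, st2)
})

test_that("hidden state stays finite over long random rollouts", {
  m <- tiny_model(seed = 75)
  set.seed(75)
  state <- NULL
  for (i in 1:1000) {
    st <- guidenet_step(m, rnorm(16), rnorm(2, 0, 0.1), quat_random(), state)
    state <- st$state
    expect_true(all(is.finite(c(state$h_s, state$h_r))))
  }
  expect_lt(max(abs(c(state$h_s, state$h_r))), 10)
})

test_that("rollout is one-step-ahead with no target leakage", {
  m <- tiny_model(seed = 76)
  sq <- tiny_sequence(seed = 76, T_len = 20)
  ro <- guidenet_rollout(m, sq, t0 = 6L)
  expect_length(ro, 20 - 6 + 1)
  expect_equal(vapply(ro, function(p) p$t, numeric(1)), 6:20)
  # perturbing inputs at frame t must not change the prediction for t
  t_probe <- 12L
  sq2 <- sq
  sq2$features[t_probe, ] <- sq2$features[t_probe, ] + 10
  sq2$gaze[t_probe, ] <- sq2$gaze[t_probe, ] * -1
  ro2 <- guidenet_rollout(m, sq2, t0 = 6L)
  i <- t_probe - 6 + 1
  expect_equal(ro[[i]]$probe$mu, ro2[[i]]$probe$mu)
  expect_equal(ro[[i]]$gaze$mu, ro2[[i]]$gaze$mu)
  # ...but it does change the prediction for t + 1
  expect_false(isTRUE(all.equal(ro[[i + 1]]$probe$mu, ro2[[i + 1]]$probe$mu)))
  expect_error(guidenet_rollout(m, list(gaze = sq$gaze[1:6, ]), t0 = 6L),
               "shorter")
})

test_that("identical inputs give identical rollouts (stationary parameters)", {
  m <- tiny_model(seed = 77)
  sq <- tiny_sequence(seed = 77, T_len = 18)
  ro1 <- guidenet_rollout(m, sq)
  ro2 <- guidenet_rollout(m, sq)
  expect_identical(ro1, ro2)
})

test_that("disabling the pathway reduces each stream to a standard GCGRU", {
  cfg_on <- guidenet_config(feature_dim = 16)
  m_on <- guidenet_init(cfg_on, seed = 78)
  m_off <- m_on
  m_off$config$bidirectional <- FALSE
  # with alpha and beta forced to 1, the coupled model equals the uncoupled one
  m_sat <- m_on
  m_sat$params[["alpha"]][] <- 100   # sigmoid ~ 1
  m_sat$params[["beta"]][] <- 100
  set.seed(78)
  xI <- rnorm(16); s <- rnorm(2, 0, 0.1); r <- quat_random()
  st_off <- guidenet_step(m_off, xI, s, r)
  st_sat <- guidenet_step(m_sat, xI, s, r)
  expect_equal(st_off$state$h_s, st_sat$state$h_s, tolerance = 1e-8)
  expect_equal(st_off$state$h_r, st_sat$state$h_r, tolerance = 1e-8)
})

test_that("training-path forward agrees with the numeric inference path", {
  m <- tiny_model(seed = 79)
  sq <- tiny_sequence(seed = 79, T_len = 14)
  prep <- list(list(ins = guidenet_inputs(sq),
                    tgt = make_targets(sq, m$config), T_len = 14))
  batch <- sonoguide:::.gn_make_batch(prep, cbind(1L, 1L), 14L, m$config)
  tcfg <- guidenet_train_config(window = 14)
  tp <- tp_new()
  pid <- sonoguide:::.gn_tape_params(tp, m)
  fl <- sonoguide:::.gn_tape_loss(tp, m, pid, batch, tcfg, training = FALSE)
  ro <- guidenet_rollout(m, sq)
  tg <- make_targets(sq, m$config)
  expect_equal(as.numeric(tp_val(tp, fl$loss)),
               as.numeric(multitask_loss(ro, tg, tcfg)), tolerance = 1e-8)
})

test_that("mixture-policy training loss agrees with the decoded objective", {
  cfg <- guidenet_config("OP", "MG", L = 2L, feature_dim = 16, embed = 8,
                         hidden = 8, proj = 12)
  m <- guidenet_init(cfg, seed = 81)
  sim <- scan_sim_config(n_sequences = 1, feature_dim = 16, T_len = 24,
                         n_fixation_centers = 2L, saccade_rate = 0.4,
                         gaze_jitter = 0.01, seed = 81)
  sq <- simulate_scan(sim, 1)
  tg <- make_targets(sq, cfg)
  expect_gt(sum(tg$gaze_mask), 3)
  prep <- list(list(ins = guidenet_inputs(sq), tgt = tg, T_len = 24))
  batch <- sonoguide:::.gn_make_batch(prep, cbind(1L, 1L), 24L, cfg)
  tcfg <- guidenet_train_config(window = 24)
  tp <- tp_new()
  pid <- sonoguide:::.gn_tape_params(tp, m)
  fl <- sonoguide:::.gn_tape_loss(tp, m, pid, batch, tcfg, training = FALSE)
  ro <- guidenet_rollout(m, sq)
  expect_equal(as.numeric(tp_val(tp, fl$loss)),
               as.numeric(multitask_loss(ro, tg, tcfg)), tolerance = 1e-8)
  # and the mixture head receives gradient through the masked steps
  grads <- tp_backward(tp, fl$loss)
  expect_gt(max(abs(tp_grad(grads, pid[["head.s.W"]]))), 0)
})

test_that("the loss sends gradient into every parameter group", {
  m <- tiny_model(seed = 80)
  sq <- tiny_sequence(seed = 80, T_len = 14)
  prep <- list(list(ins = guidenet_inputs(sq),
                    tgt = make_targets(sq, m$config), T_len = 14))
  batch <- sonoguide:::.gn_make_batch(prep, cbind(1L, 1L), 14L, m$config)
  tp <- tp_new()
  pid <- sonoguide:::.gn_tape_params(tp, m)
  fl <- sonoguide:::.gn_tape_loss(tp, m, pid, batch,
                                  guidenet_train_config(window = 14),
                                  training = FALSE)
  grads <- tp_backward(tp, fl$loss)
  for (nm in names(m$params)) {
    g <- tp_grad(grads, pid[[nm]])
    expect_false(is.null(g), label = sprintf("gradient reaches %s", nm))
    if (nm == "M") {
      # only the gaze/probe rows of the mask feed the two streams; the
      # image row is structurally unused (no image-side recurrence)
      expect_gt(max(abs(g[1, 4:9])), 0)
    } else {
      expect_gt(max(abs(g)), 0)
    }
  }
})
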