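#' Training configuration
#'
#' The multi-task objective sums, over prediction steps t0..T, the weighted
#' gaze and probe negative log-likelihoods plus the unit-norm quaternion
#' prior on the probe mean:
#' L = sum_t (-lambda_s log P_s - lambda_r log P_r + eta (1 - ||mu_r||)^2).
#'
#' @param lambda_s,lambda_r task weights (defaults 1, 1: the two
#'   log-likelihoods live on the same scale).
#' @param eta quaternion prior weight (default 50; the prior is a hard
#'   constraint relative to the two unit-weight likelihood terms).
#' @param window frames per training clip (default 32; clips are cut at
#'   random from each sequence every epoch).
#' @param lr initial learning rate (default 0.001).
#' @param decay multiplicative learning-rate factor (default 0.01) applied
#'   every `decay_every` epochs (default 8).
#' @param epochs training epochs.
#' @param batch_size clips per optimizer step.
#' @param windows_per_seq random clips drawn from each sequence per epoch.
#' @param weight_decay decoupled weight decay of the AdamW optimizer.
#' @param clip_norm global gradient-norm clipping threshold; `Inf`
#'   (default) disables clipping. Useful for probe-only regression-like
#'   tasks whose likelihoods occasionally produce steep steps; it distorts
#'   the adaptive moments when gradients are persistently large, so it is
#'   off by default.
#' @param ema_decay decay of a Polyak (exponential moving) average of the
#'   parameters, evaluated in place of the last iterate when positive;
#'   0 (default) disables averaging. Averaged weights damp the
#'   iterate-to-iterate noise of stochastic likelihood training.
#' @param seed RNG seed governing initialization, clip sampling, and
#'   batch order; fixed seed gives bit-identical training runs.
#' @return a `guidenet_train_config` list.
#' @export
guidenet_train_config <- function(lambda_s = 1, lambda_r = 1, eta = 50,
                                  window = 32L, lr = 0.001, decay = 0.01,
                                  decay_every = 8L, epochs = 10L,
                                  batch_size = 16L, windows_per_seq = 1L,
                                  weight_decay = 1e-4, clip_norm = Inf,
                                  ema_decay = 0, seed = 1L) {
  stopifnot(lambda_s >= 0, lambda_r >= 0, eta >= 0)
  structure(list(lambda_s = lambda_s, lambda_r = lambda_r, eta = eta,
                 window = as.integer(window), lr = lr, decay = decay,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 windows_per_seq = as.integer(windows_per_seq),
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 ema_decay = ema_decay, seed = as.integer(seed)),
            class = "guidenet_train_config")
}

#' Build aligned target streams for a sequence
#'
#' Targets for prediction step t (teacher-forced, one-step-ahead):
#' * OG: the gaze shift s_t;
#' * MG: the L fixation-center displacements c^l_t - c^l_{t-F} from
#'   sliding-window clustering, defined (masked in) only where both windows
#'   exist with stable center correspondence and t >= t0 + F;
#' * OP: the relative rotation r_t = conj(q_{t-1}) q_t;
#' * SP: the rotation to the standard plane conj(q_{t-1}) q_T, recomputed
#'   each step against the fixed target quaternion (which must be present).
#'
#' @param sequence list with `gaze` (T x 2), `quats` (T x 4), and
#'   `q_target` (required under SP).
#' @param config a [guidenet_config()].
#' @return list with `probe` (T x 4 canonical quaternions; row 1 identity),
#'   `gaze` (T x 2 shifts for OG; length-T list of L x 2 center
#'   displacements for MG), `gaze_mask` (length-T logical), `centers`
#'   (MG only: the per-frame `center_window`s).
#' @export
make_targets <- function(sequence, config) {
  T_len <- nrow(sequence$gaze)
  ins <- guidenet_inputs(sequence)
  if (config$policy_probe == "OP") {
    probe <- ins$r
  } else {
    if (is.null(sequence$q_target))
      stop("SP policy requires the sequence's target quaternion q_target")
    q <- as.matrix(sequence$quats)
    probe <- matrix(0, T_len, 4L); probe[1L, ] <- quat_identity()
    rr <- quat_multiply(quat_conjugate(q[-T_len, , drop = FALSE]),
                        matrix(sequence$q_target, 1L))
    probe[-1L, ] <- .quat_mat_canonicalize(.quat_mat(rr))
  }
  if (config$policy_gaze == "OG") {
    gaze <- ins$s
    mask <- c(FALSE, rep(TRUE, T_len - 1L))
    centers <- NULL
  } else {
    F_win <- config$F_win; L <- config$L
    centers <- sliding_centers(as.matrix(sequence$gaze), L, F_win)
    gaze <- vector("list", T_len)
    mask <- rep(FALSE, T_len)
    t_min <- F_win + max(config$t0, F_win)
    for (t in seq_len(T_len)) {
      if (t < t_min) next
      cw_t <- centers[[t]]; cw_p <- centers[[t - F_win]]
      if (is.null(cw_t) || is.null(cw_p)) next
      if (nrow(cw_t$centers) != L || nrow(cw_p$centers) != L) next
      gaze[[t]] <- center_displacement(cw_t, cw_p)
      mask[t] <- TRUE
    }
  }
  list(probe = probe, gaze = gaze, gaze_mask = mask, centers = centers)
}

#' Multi-task loss of decoded predictions against targets
#'
#' Evaluates the training objective on an already-decoded rollout: the sum
#' over prediction steps of lambda_s * gaze NLL + lambda_r * probe NLL +
#' eta * (1 - ||mu_r||)^2. Under MG, the gaze term sums the mixture NLL over
#' the L observed center displacements and masked-out steps contribute
#' nothing. A non-finite term raises an error naming the step and term.
#'
#' @param predictions output of [guidenet_rollout()].
#' @param targets output of [make_targets()] on the same sequence.
#' @param cfg a [guidenet_train_config()] (uses lambda_s, lambda_r, eta).
#' @return scalar loss with attribute `components` (summed gaze NLL, probe
#'   NLL, prior).
#' @export
multitask_loss <- function(predictions, targets, cfg = guidenet_train_config()) {
  tot_s <- 0; tot_r <- 0; tot_p <- 0
  for (pr in predictions) {
    t <- pr$t
    nll_s <- 0
    if (targets$gaze_mask[t]) {
      if (inherits(pr$gaze, "gaze_mixture")) {
        disp <- targets$gaze[[t]]
        nll_s <- sum(vapply(seq_len(nrow(disp)), function(m)
          nll_mixture(pr$gaze, disp[m, ]), numeric(1)))
      } else {
        nll_s <- nll_bivariate(pr$gaze, targets$gaze[t, ])
      }
    }
    nll_r <- nll_quat(pr$probe, targets$probe[t, ])
    prior <- quaternion_prior(pr$probe$mu, cfg$eta)
    for (nm in c("nll_s", "nll_r", "prior")) {
      v <- get(nm)
      if (!is.finite(v))
        stop(sprintf("non-finite %s term at step t=%d",
                     c(nll_s = "gaze NLL", nll_r = "probe NLL",
                       prior = "quaternion prior")[[nm]], t))
    }
    tot_s <- tot_s + nll_s; tot_r <- tot_r + nll_r; tot_p <- tot_p + prior
  }
  structure(cfg$lambda_s * tot_s + cfg$lambda_r * tot_r + tot_p,
            components = c(gaze_nll = tot_s, probe_nll = tot_r, prior = tot_p))
}

# ---- tape forward / loss (training path) ---------------------------------

.gn_tape_params <- function(tp, model) {
  ids <- lapply(model$params, function(p) tp_param(tp, p))
  ids
}

.gn_tape_embed <- function(tp, model, pid, x_id, blk, training) {
  h <- tp_matmul(tp, x_id, pid[[paste0("emb.", blk, ".W")]])
  h <- tp_add_bias(tp, h, pid[[paste0("emb.", blk, ".b")]])
  h <- tp_batchnorm(tp, h, pid[[paste0("emb.", blk, ".g")]],
                    pid[[paste0("emb.", blk, ".be")]],
                    model$bn[[blk]], training)
  tp_relu(tp, h)
}

# One recurrent step on the tape. emb: list(I, s, r) node ids; state: list
# (h_s, h_r) node ids. Returns list(state=, raw_gaze=, raw_probe=).
.gn_tape_step <- function(tp, model, pid, emb, state, al_id, be_id) {
  cfg <- model$config
  H <- cfg$hidden
  th <- lapply(emb[c("s", "r")], function(f)
    tp_add_bias(tp, tp_matmul(tp, f, pid[["theta.W"]]), pid[["theta.b"]]))
  ph <- lapply(emb, function(f)
    tp_add_bias(tp, tp_matmul(tp, f, pid[["phi.W"]]), pid[["phi.b"]]))
  Arow <- list()
  for (j in c("s", "r")) {
    sc <- tp_cbind(tp, c(tp_rowdot(tp, th[[j]], ph$I),
                         tp_rowdot(tp, th[[j]], ph$s),
                         tp_rowdot(tp, th[[j]], ph$r)))
    soft <- tp_softmax_rows(tp, sc)
    jrow <- if (j == "s") 2L else 3L
    Mrow <- tp_cols(tp, pid[["M"]], ((jrow - 1L) * 3L + 1L):((jrow - 1L) * 3L + 3L))
    Arow[[j]] <- tp_add_bias(tp, soft, Mrow)
  }
  msg <- list()
  for (j in c("s", "r")) {
    pieces <- vector("list", 3L)
    for (k in 1:3) {
      Pk <- tp_matmul(tp, emb[[k]], pid[[paste0("msg.", j, ".W")]])
      a_jk <- tp_cols(tp, Arow[[j]], k)
      pieces[[k]] <- tp_sigmoid(tp, tp_colmul(tp, a_jk, Pk))
    }
    m <- tp_addn(tp, pieces)
    msg[[j]] <- list(z = tp_cols(tp, m, 1:H),
                     g = tp_cols(tp, m, (H + 1L):(2L * H)),
                     h = tp_cols(tp, m, (2L * H + 1L):(3L * H)))
  }
  gate <- function(j, hprev, which, bias) {
    tp_sigmoid(tp, tp_add_bias(tp, tp_add(tp, msg[[j]][[which]],
      tp_matmul(tp, hprev, pid[[paste0("gru.", j, ".U", which)]])),
      pid[[paste0("gru.", j, ".b", which)]]))
  }
  z_s <- gate("s", state$h_s, "z"); g_s <- gate("s", state$h_s, "g")
  z_r <- gate("r", state$h_r, "z"); g_r <- gate("r", state$h_r, "g")
  cand <- function(j, hprev, gamma) {
    tp_tanh(tp, tp_add_bias(tp, tp_add(tp, msg[[j]]$h,
      tp_matmul(tp, tp_mul(tp, gamma, hprev), pid[[paste0("gru.", j, ".Uh")]])),
      pid[[paste0("gru.", j, ".bh")]]))
  }
  c_s <- cand("s", state$h_s, g_s)
  c_r <- cand("r", state$h_r, g_r)
  omz_s <- tp_addc(tp, tp_neg(tp, z_s), 1)
  omz_r <- tp_addc(tp, tp_neg(tp, z_r), 1)
  own_s <- tp_add(tp, tp_mul(tp, omz_s, state$h_s), tp_mul(tp, z_s, c_s))
  own_r <- tp_add(tp, tp_mul(tp, omz_r, state$h_r), tp_mul(tp, z_r, c_r))
  if (cfg$bidirectional) {
    cross_s <- tp_add(tp, tp_mul(tp, z_r, state$h_s), tp_mul(tp, omz_r, c_s))
    cross_r <- tp_add(tp, tp_mul(tp, z_s, state$h_r), tp_mul(tp, omz_s, c_r))
    al <- tp_sigmoid(tp, al_id); be <- tp_sigmoid(tp, be_id)
    oma <- tp_addc(tp, tp_neg(tp, al), 1)
    omb <- tp_addc(tp, tp_neg(tp, be), 1)
    h_s <- tp_add(tp, tp_rowmul(tp, al, own_s), tp_rowmul(tp, oma, cross_s))
    h_r <- tp_add(tp, tp_rowmul(tp, be, own_r), tp_rowmul(tp, omb, cross_r))
  } else {
    h_s <- own_s; h_r <- own_r
  }
  raw_gaze <- tp_add_bias(tp, tp_matmul(tp, h_s, pid[["head.s.W"]]),
                          pid[["head.s.b"]])
  raw_probe <- tp_add_bias(tp, tp_matmul(tp, h_r, pid[["head.r.W"]]),
                           pid[["head.r.b"]])
  list(state = list(h_s = h_s, h_r = h_r),
       raw_gaze = raw_gaze, raw_probe = raw_probe)
}

.gn_tape_nll_og <- function(tp, raw, target_id) {
  mu <- tp_addc(tp, tp_sigmoid(tp, tp_cols(tp, raw, 1:2)), -0.5)
  logsig <- tp_cols(tp, raw, 3:4)
  sig <- tp_exp(tp, logsig)
  rho <- tp_tanh(tp, tp_cols(tp, raw, 5L))
  dn <- tp_div(tp, tp_sub(tp, target_id, mu), sig)
  dx <- tp_cols(tp, dn, 1L); dy <- tp_cols(tp, dn, 2L)
  cross <- tp_mul(tp, dx, dy)
  omr2 <- tp_pmax_const(tp, tp_addc(tp, tp_neg(tp, tp_mul(tp, rho, rho)), 1), 1e-6)
  z <- tp_sub(tp, tp_rowdot(tp, dn, dn), tp_scale(tp, tp_mul(tp, rho, cross), 2))
  quad <- tp_div(tp, z, tp_scale(tp, omr2, 2))
  ls <- tp_add(tp, tp_cols(tp, logsig, 1L), tp_cols(tp, logsig, 2L))
  tp_addc(tp, tp_addn(tp, c(ls, tp_scale(tp, tp_log(tp, omr2), 0.5), quad)),
          log(2 * pi))
}

.gn_tape_nll_quat <- function(tp, raw, target_id) {
  mu <- tp_cols(tp, raw, 1:4)
  d <- tp_sub(tp, target_id, mu)
  dcol <- lapply(1:4, function(j) tp_cols(tp, d, j))
  sp <- function(j) tp_addc(tp, tp_softplus(tp, tp_cols(tp, raw, j)), 1e-4)
  l11 <- sp(5L); l21 <- tp_cols(tp, raw, 6L); l31 <- tp_cols(tp, raw, 7L)
  l41 <- tp_cols(tp, raw, 8L); l22 <- sp(9L); l32 <- tp_cols(tp, raw, 10L)
  l42 <- tp_cols(tp, raw, 11L); l33 <- sp(12L); l43 <- tp_cols(tp, raw, 13L)
  l44 <- sp(14L)
  y1 <- tp_div(tp, dcol[[1]], l11)
  y2 <- tp_div(tp, tp_sub(tp, dcol[[2]], tp_mul(tp, l21, y1)), l22)
  y3 <- tp_div(tp, tp_sub(tp, dcol[[3]],
         tp_add(tp, tp_mul(tp, l31, y1), tp_mul(tp, l32, y2))), l33)
  y4 <- tp_div(tp, tp_sub(tp, dcol[[4]],
         tp_addn(tp, c(tp_mul(tp, l41, y1), tp_mul(tp, l42, y2),
                       tp_mul(tp, l43, y3)))), l44)
  quad <- tp_scale(tp, tp_addn(tp, c(tp_mul(tp, y1, y1), tp_mul(tp, y2, y2),
                                     tp_mul(tp, y3, y3), tp_mul(tp, y4, y4))), 0.5)
  logdet <- tp_addn(tp, c(tp_log(tp, l11), tp_log(tp, l22),
                          tp_log(tp, l33), tp_log(tp, l44)))
  nll <- tp_addc(tp, tp_add(tp, quad, logdet), 2 * log(2 * pi))
  list(nll = nll, mu = mu)
}

.gn_tape_prior <- function(tp, mu, eta) {
  n <- tp_sqrt(tp, tp_addc(tp, tp_rowdot(tp, mu, mu), 1e-12))
  t1 <- tp_addc(tp, tp_neg(tp, n), 1)
  tp_scale(tp, tp_mul(tp, t1, t1), eta)
}

.gn_tape_nll_mg <- function(tp, raw, target_mats, L) {
  # target_mats: list over observed center index m of B x 2 const ids; the
  # mixture NLL is evaluated at each observed displacement and summed.
  logits <- tp_cols(tp, raw, (5L * L + 1L):(6L * L))
  lse <- tp_logsumexp_rows(tp, logits)
  logpi <- tp_sub(tp, logits, tp_cbind(tp, rep(c(lse), L)))
  per_m <- lapply(target_mats, function(tgt) {
    cols <- lapply(seq_len(L), function(l) {
      comp_raw <- tp_cols(tp, raw, (5L * (l - 1L) + 1L):(5L * l))
      nll_l <- .gn_tape_nll_og(tp, comp_raw, tgt)
      tp_sub(tp, tp_cols(tp, logpi, l), nll_l)
    })
    tp_neg(tp, tp_logsumexp_rows(tp, tp_cbind(tp, unlist(cols))))
  })
  tp_addn(tp, per_m)
}

# Forward + loss for one batch of teacher-forced clips.
# batch: list(features, s, r: lists over input step u of B x d matrices;
#             tgt_gaze: list over prediction t of targets; tgt_probe ditto;
#             mask: steps x B matrix; t0)
.gn_tape_loss <- function(tp, model, pid, batch, tcfg, training = TRUE) {
  cfg <- model$config
  W <- length(batch$features) + 1L
  B <- nrow(batch$features[[1L]])
  zero <- tp_const(tp, matrix(0, B, cfg$hidden))
  state <- list(h_s = zero, h_r = zero)
  al_id <- pid[["alpha"]]; be_id <- pid[["beta"]]
  terms <- list()
  comp <- c(gaze = 0, probe = 0, prior = 0, n_gaze = 0, n_probe = 0)
  # embed all time steps jointly so batch normalization sees the pooled
  # batch x time distribution (the same distribution its running statistics
  # estimate for evaluation)
  emb_all <- list(
    I = .gn_tape_embed(tp, model, pid,
                       tp_const(tp, do.call(rbind, batch$features)), "I", training),
    s = .gn_tape_embed(tp, model, pid,
                       tp_const(tp, do.call(rbind, batch$s)), "s", training),
    r = .gn_tape_embed(tp, model, pid,
                       tp_const(tp, do.call(rbind, batch$r)), "r", training))
  for (u in seq_len(W - 1L)) {
    rows_u <- ((u - 1L) * B + 1L):(u * B)
    emb <- list(I = tp_rows(tp, emb_all$I, rows_u),
                s = tp_rows(tp, emb_all$s, rows_u),
                r = tp_rows(tp, emb_all$r, rows_u))
    stp <- .gn_tape_step(tp, model, pid, emb, state, al_id, be_id)
    state <- stp$state
    t_pred <- u + 1L
    if (t_pred < cfg$t0) next
    # probe term
    pq <- .gn_tape_nll_quat(tp, stp$raw_probe, tp_const(tp, batch$tgt_probe[[t_pred]]))
    prior <- .gn_tape_prior(tp, pq$mu, tcfg$eta)
    if (!cfg$variance) {
      d <- tp_sub(tp, tp_const(tp, batch$tgt_probe[[t_pred]]), pq$mu)
      pnll <- tp_rowdot(tp, d, d)
    } else pnll <- pq$nll
    # gaze term (possibly masked)
    mrow <- batch$mask[t_pred, ]
    if (any(mrow)) {
      if (cfg$policy_gaze == "OG") {
        tgt <- tp_const(tp, batch$tgt_gaze[[t_pred]])
        if (!cfg$variance) {
          mu <- tp_addc(tp, tp_sigmoid(tp, tp_cols(tp, stp$raw_gaze, 1:2)), -0.5)
          dd <- tp_sub(tp, tgt, mu)
          gnll <- tp_rowdot(tp, dd, dd)
        } else gnll <- .gn_tape_nll_og(tp, stp$raw_gaze, tgt)
      } else {
        tgts <- lapply(batch$tgt_gaze[[t_pred]], function(m) tp_const(tp, m))
        gnll <- .gn_tape_nll_mg(tp, stp$raw_gaze, tgts, cfg$L)
      }
      if (!all(mrow)) gnll <- tp_colmul(tp, tp_const(tp, matrix(as.numeric(mrow), ncol = 1L)), gnll)
      comp[["gaze"]] <- comp[["gaze"]] + sum(tp_val(tp, gnll))
      comp[["n_gaze"]] <- comp[["n_gaze"]] + sum(mrow)
      terms <- c(terms, tp_sum(tp, tp_scale(tp, gnll, tcfg$lambda_s)))
    }
    comp[["probe"]] <- comp[["probe"]] + sum(tp_val(tp, pnll))
    comp[["prior"]] <- comp[["prior"]] + sum(tp_val(tp, prior))
    comp[["n_probe"]] <- comp[["n_probe"]] + B
    terms <- c(terms, tp_sum(tp, tp_scale(tp, pnll, tcfg$lambda_r)),
               tp_sum(tp, prior))
  }
  loss <- tp_scale(tp, tp_addn(tp, terms), 1 / B)
  list(loss = loss, components = comp)
}

# ---- optimizer -----------------------------------------------------------

.adamw_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamw_step <- function(opt, params, grads, lr, wd = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  list(opt = opt, params = params)
}

# ---- training loop -------------------------------------------------------

#' Train a guidance network on a dataset of scan sequences
#'
#' Teacher-forced training of the joint objective with AdamW and a stepwise
#' learning-rate schedule (multiplied by `decay` every `decay_every`
#' epochs). Every epoch draws `windows_per_seq` random clips of `window`
#' continuous frames from each sequence and consumes them in shuffled
#' mini-batches. Fully deterministic under `tcfg$seed`. Training aborts
#' with diagnostics if the loss turns non-finite.
#'
#' @param dataset list of sequences (each as in [guidenet_rollout()], with
#'   `q_target` under SP).
#' @param config a [guidenet_config()].
#' @param tcfg a [guidenet_train_config()].
#' @param model optionally, an existing `guidenet` to continue training.
#' @param verbose print per-epoch loss.
#' @return a `guidenet_fit`: list with `model` and `history` (data frame
#'   `epoch, loss, gaze_nll, probe_nll, prior`, per-step means).
#' @export
train_guidenet <- function(dataset, config = guidenet_config(),
                           tcfg = guidenet_train_config(), model = NULL,
                           verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  if (tcfg$window <= config$t0 + 1L)
    stop("training window must exceed t0 + 1 frames")
  if (is.null(model)) model <- guidenet_init(config, seed = tcfg$seed)
  config <- model$config
  set.seed(tcfg$seed)
  prep <- lapply(dataset, function(sq) {
    ins <- guidenet_inputs(sq)
    tgt <- make_targets(sq, config)
    list(ins = ins, tgt = tgt, T_len = nrow(sq$gaze))
  })
  opt <- .adamw_new(model$params)
  ema <- if (tcfg$ema_decay > 0) model$params else NULL
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     gaze_nll = numeric(), probe_nll = numeric(),
                     prior = numeric())
  W <- tcfg$window
  for (epoch in seq_len(tcfg$epochs)) {
    lr_e <- tcfg$lr * tcfg$decay^((epoch - 1L) %/% tcfg$decay_every)
    pairs <- do.call(rbind, lapply(seq_along(prep), function(i) {
      span <- prep[[i]]$T_len - W + 1L
      if (span < 1L) stop("sequence shorter than the training window")
      cbind(i, sample.int(span, tcfg$windows_per_seq, replace = span < tcfg$windows_per_seq))
    }))
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    nb <- ceiling(nrow(pairs) / tcfg$batch_size)
    ep <- c(loss = 0, gaze = 0, probe = 0, prior = 0, n_g = 0, n_p = 0, nb = 0)
    for (b in seq_len(nb)) {
      rows <- pairs[((b - 1L) * tcfg$batch_size + 1L):min(b * tcfg$batch_size, nrow(pairs)), , drop = FALSE]
      batch <- .gn_make_batch(prep, rows, W, config)
      tp <- tp_new(16384L)
      pid <- .gn_tape_params(tp, model)
      fl <- .gn_tape_loss(tp, model, pid, batch, tcfg, training = TRUE)
      lval <- as.numeric(tp_val(tp, fl$loss))
      if (!is.finite(lval))
        stop(sprintf("training diverged: non-finite loss at epoch %d batch %d", epoch, b))
      grads <- tp_backward(tp, fl$loss)
      gl <- lapply(pid, function(id) tp_grad(grads, id))
      if (is.finite(tcfg$clip_norm)) {
        gn <- sqrt(sum(vapply(gl, function(g)
          if (is.null(g)) 0 else sum(g^2), numeric(1))))
        if (gn > tcfg$clip_norm)
          gl <- lapply(gl, function(g) if (is.null(g)) g else g * (tcfg$clip_norm / gn))
      }
      upd <- .adamw_step(opt, model$params, gl, lr_e, tcfg$weight_decay)
      opt <- upd$opt; model$params <- upd$params
      if (!is.null(ema)) {
        d <- tcfg$ema_decay
        for (nm in names(ema)) ema[[nm]] <- d * ema[[nm]] + (1 - d) * model$params[[nm]]
      }
      ep["loss"] <- ep["loss"] + lval
      ep["gaze"] <- ep["gaze"] + fl$components[["gaze"]]
      ep["probe"] <- ep["probe"] + fl$components[["probe"]]
      ep["prior"] <- ep["prior"] + fl$components[["prior"]]
      ep["n_g"] <- ep["n_g"] + fl$components[["n_gaze"]]
      ep["n_p"] <- ep["n_p"] + fl$components[["n_probe"]]
      ep["nb"] <- ep["nb"] + 1
    }
    hist <- rbind(hist, data.frame(
      epoch = epoch, loss = ep[["loss"]] / ep[["nb"]],
      gaze_nll = if (ep[["n_g"]] > 0) ep[["gaze"]] / ep[["n_g"]] else NA_real_,
      probe_nll = ep[["probe"]] / ep[["n_p"]],
      prior = ep[["prior"]] / ep[["n_p"]]))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f (lr %.2g)", epoch,
                      ep[["loss"]] / ep[["nb"]], lr_e))
  }
  if (!is.null(ema)) model$params <- ema
  structure(list(model = model, history = hist, tcfg = tcfg),
            class = "guidenet_fit")
}

.gn_make_batch <- function(prep, rows, W, config) {
  B <- nrow(rows)
  feats <- vector("list", W - 1L); s_in <- vector("list", W - 1L)
  r_in <- vector("list", W - 1L)
  tgt_probe <- vector("list", W); tgt_gaze <- vector("list", W)
  mask <- matrix(FALSE, W, B)
  D <- ncol(prep[[rows[1L, 1L]]]$ins$features)
  for (u in seq_len(W - 1L)) {
    feats[[u]] <- matrix(0, B, D); s_in[[u]] <- matrix(0, B, 2L)
    r_in[[u]] <- matrix(0, B, 4L)
  }
  for (t in 2L:W) {
    tgt_probe[[t]] <- matrix(0, B, 4L)
    if (config$policy_gaze == "OG") tgt_gaze[[t]] <- matrix(0, B, 2L)
    else tgt_gaze[[t]] <- lapply(seq_len(config$L), function(l) matrix(0, B, 2L))
  }
  for (i in seq_len(B)) {
    pp <- prep[[rows[i, 1L]]]; a <- rows[i, 2L]
    for (u in seq_len(W - 1L)) {
      ab <- a + u - 1L
      feats[[u]][i, ] <- pp$ins$features[ab, ]
      s_in[[u]][i, ] <- pp$ins$s[ab, ]
      r_in[[u]][i, ] <- pp$ins$r[ab, ]
    }
    for (t in 2L:W) {
      ab <- a + t - 1L
      tgt_probe[[t]][i, ] <- pp$tgt$probe[ab, ]
      if (config$policy_gaze == "OG") {
        tgt_gaze[[t]][i, ] <- pp$tgt$gaze[ab, ]
        mask[t, i] <- pp$tgt$gaze_mask[ab]
      } else if (pp$tgt$gaze_mask[ab]) {
        disp <- pp$tgt$gaze[[ab]]
        for (l in seq_len(config$L)) tgt_gaze[[t]][[l]][i, ] <- disp[l, ]
        mask[t, i] <- TRUE
      }
    }
  }
  list(features = feats, s = s_in, r = r_in,
       tgt_probe = tgt_probe, tgt_gaze = tgt_gaze, mask = mask)
}

#' Save / load a trained model
#'
#' Checkpoints hold all parameter arrays, batch-norm running statistics,
#' and the configuration in a single RDS archive.
#'
#' @param model a `guidenet`.
#' @param path file path.
#' @export
save_guidenet <- function(model, path) {
  bn <- lapply(model$bn, function(st) list(rm = st$rm, rv = st$rv,
                                           momentum = st$momentum,
                                           initialized = isTRUE(st$initialized)))
  saveRDS(list(config = unclass(model$config), params = model$params,
               bn = bn), path)
  invisible(path)
}

#' @rdname save_guidenet
#' @export
load_guidenet <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "guidenet_config")
  bn <- lapply(obj$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$rm <- st$rm; e$rv <- st$rv; e$momentum <- st$momentum
    e$initialized <- isTRUE(st$initialized)
    e
  })
  structure(list(config = cfg, params = obj$params, bn = bn),
            class = "guidenet")
}
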