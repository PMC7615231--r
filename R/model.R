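#' Configuration of the multimodal guidance network
#'
#' Defines the model: which probe policy ("OP" = one-step rotation, "SP" =
#' rotation to the standard plane) and gaze policy ("OG" = one-step shift,
#' "MG" = L-component mixture over fixation-center displacements) the two
#' output heads realize, and the layer widths. The combination SP+MG (both
#' global policies, no local step action) is not supported and rejected
#' here.
#'
#' @param policy_probe "OP" or "SP".
#' @param policy_gaze "OG" or "MG".
#' @param L mixture components for MG (at most 3; about one fixation per
#'   third of a second of gaze at 6 Hz).
#' @param feature_dim image-representation width (1,920 from the frame
#'   encoder).
#' @param embed per-modality embedding channels (128).
#' @param hidden GRU hidden channels (128).
#' @param proj adjacency projection width for theta/phi (256).
#' @param t0 warm-up frames before predictions start (6, i.e. 1 s at 6 Hz).
#' @param F_win sliding-window length for fixation clustering (5).
#' @param bidirectional enable the gaze-probe pathway coupling the two
#'   hidden-state updates (ablation switch).
#' @param variance predict full densities (`TRUE`) or train the means by
#'   squared error only (`FALSE`; ablation switch).
#' @return a `guidenet_config` list, with derived head sizes `d_gaze`
#'   (5 for OG, 6 L for MG) and `d_probe` (14).
#' @export
guidenet_config <- function(policy_probe = c("OP", "SP"),
                            policy_gaze = c("OG", "MG"),
                            L = 3L, feature_dim = 1920L, embed = 128L,
                            hidden = 128L, proj = 256L, t0 = 6L, F_win = 5L,
                            bidirectional = TRUE, variance = TRUE) {
  policy_probe <- match.arg(policy_probe)
  policy_gaze <- match.arg(policy_gaze)
  if (policy_probe == "SP" && policy_gaze == "MG")
    stop("the SP+MG policy combination is unsupported: no local step action")
  if (policy_gaze == "MG" && (L < 1L || L > 3L))
    stop("MG component count L must be 1..3")
  structure(list(
    policy_probe = policy_probe, policy_gaze = policy_gaze, L = as.integer(L),
    feature_dim = as.integer(feature_dim), embed = as.integer(embed),
    hidden = as.integer(hidden), proj = as.integer(proj),
    t0 = as.integer(t0), F_win = as.integer(F_win),
    bidirectional = bidirectional, variance = variance,
    d_gaze = if (policy_gaze == "OG") 5L else 6L * as.integer(L),
    d_probe = 14L
  ), class = "guidenet_config")
}

.xavier <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Initialize a guidance network
#'
#' Builds all parameter arrays: the three FC+BN+ReLU embedding blocks (image
#' 1,920 -> 128, gaze shift 2 -> 128, rotation 4 -> 128), the adjacency
#' projections theta/phi (128 -> 256) and the learnable 3 x 3 adjacency mask
#' M (zero-initialized, so training starts from the pure feature-similarity
#' graph), per-stream graph-message kernels for the three GRU gates, the
#' GRU recurrences, the channel-wise pathway weights alpha/beta (zero
#' pre-squash, i.e. 0.5 after sigmoid: streams start half-coupled), and the
#' two policy output heads.
#'
#' @param config a [guidenet_config()].
#' @param seed integer seed for weight initialization.
#' @return a `guidenet` model object.
#' @export
guidenet_init <- function(config = guidenet_config(), seed = 1L) {
  old <- .Random.seed_save()
  set.seed(seed)
  E <- config$embed; H <- config$hidden; P <- config$proj
  dims_in <- c(I = config$feature_dim, s = 2L, r = 4L)
  p <- list()
  for (blk in c("I", "s", "r")) {
    p[[paste0("emb.", blk, ".W")]] <- .xavier(dims_in[[blk]], E)
    p[[paste0("emb.", blk, ".b")]] <- matrix(0, 1L, E)
    p[[paste0("emb.", blk, ".g")]] <- matrix(1, 1L, E)
    p[[paste0("emb.", blk, ".be")]] <- matrix(0, 1L, E)
  }
  p[["theta.W"]] <- .xavier(E, P); p[["theta.b"]] <- matrix(0, 1L, P)
  p[["phi.W"]] <- .xavier(E, P); p[["phi.b"]] <- matrix(0, 1L, P)
  p[["M"]] <- matrix(0, 1L, 9L)  # row-major rows (I, s, r)
  for (st in c("s", "r")) {
    p[[paste0("msg.", st, ".W")]] <- .xavier(E, 3L * H)  # gates z | gamma | h
    p[[paste0("gru.", st, ".Uz")]] <- .xavier(H, H)
    p[[paste0("gru.", st, ".Ug")]] <- .xavier(H, H)
    p[[paste0("gru.", st, ".Uh")]] <- .xavier(H, H)
    p[[paste0("gru.", st, ".bz")]] <- matrix(0, 1L, H)
    p[[paste0("gru.", st, ".bg")]] <- matrix(0, 1L, H)
    p[[paste0("gru.", st, ".bh")]] <- matrix(0, 1L, H)
  }
  p[["alpha"]] <- matrix(0, 1L, H)
  p[["beta"]] <- matrix(0, 1L, H)
  # output heads start near zero so the initial predicted densities sit at
  # the decoded bias values; large random initial means combined with the
  # unbounded Cholesky entries destabilize the likelihood early on
  p[["head.s.W"]] <- .xavier(H, config$d_gaze) * 0.01
  p[["head.s.b"]] <- matrix(0, 1L, config$d_gaze)
  p[["head.r.W"]] <- .xavier(H, config$d_probe) * 0.01
  p[["head.r.b"]] <- matrix(0, 1L, config$d_probe)
  # probe mean starts at the identity rotation: 6 Hz probe steps are small,
  # and starting on the unit sphere keeps the quaternion prior from
  # amplifying an arbitrary initial direction
  p[["head.r.b"]][1L, 1L] <- 1
  # the probe spread starts at the data scale: quaternion steps at 6 Hz
  # are a few hundredths in component units, so sigma ~ 0.1 instead of ~1
  # keeps the early quadratic terms well conditioned. Gaze spreads keep the
  # conventional unit init: shifts can span the screen.
  p[["head.r.b"]][1L, 4L + c(1L, 5L, 8L, 10L)] <- log(expm1(0.1))
  bn <- lapply(c(I = "I", s = "s", r = "r"), function(blk) {
    st <- new.env(parent = emptyenv())
    st$rm <- rep(0, E); st$rv <- rep(1, E); st$momentum <- 0.1
    st
  })
  .Random.seed_restore(old)
  structure(list(config = config, params = p, bn = bn), class = "guidenet")
}

#' @export
print.guidenet <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("guidenet model: %s+%s policies, %d parameters\n",
              cfg$policy_probe, cfg$policy_gaze, np))
  cat(sprintf("  embed %d, hidden %d, proj %d, heads gaze=%d probe=%d\n",
              cfg$embed, cfg$hidden, cfg$proj, cfg$d_gaze, cfg$d_probe))
  invisible(x)
}

# ---- numeric reference path (inference; semantic definition) -------------

#' Embed one modality into the shared 128-channel space
#'
#' FC -> batch normalization -> ReLU for one of the three modality blocks.
#' In training mode BN uses batch statistics over the rows; in evaluation
#' mode the frozen running statistics (so single-sequence inference is
#' deterministic).
#'
#' @param model a `guidenet`.
#' @param x input matrix (B x 1920 for "I", B x 2 for "s", B x 4 for "r");
#'   a plain vector is treated as one row.
#' @param block one of "I", "s", "r".
#' @param training use batch statistics.
#' @return B x 128 non-negative matrix (vector input gives a vector).
#' @export
embed_modality <- function(model, x, block = c("I", "s", "r"),
                           training = FALSE) {
  block <- match.arg(block)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  p <- model$params
  want <- nrow(p[[paste0("emb.", block, ".W")]])
  if (ncol(X) != want)
    stop(sprintf("block %s expects %d input channels, got %d", block, want, ncol(X)))
  h <- sweep(X %*% p[[paste0("emb.", block, ".W")]], 2L,
             as.numeric(p[[paste0("emb.", block, ".b")]]), "+")
  st <- model$bn[[block]]
  if (training && nrow(h) > 1L) {
    mu <- colMeans(h); v <- colMeans(sweep(h, 2L, mu)^2)
  } else {
    mu <- st$rm; v <- st$rv
  }
  hh <- sweep(sweep(h, 2L, mu), 2L, sqrt(v + 1e-5), "/")
  hh <- sweep(sweep(hh, 2L, as.numeric(p[[paste0("emb.", block, ".g")]]), "*"),
              2L, as.numeric(p[[paste0("emb.", block, ".be")]]), "+")
  out <- pmax(hh, 0)
  if (vec) as.numeric(out) else out
}

#' Adaptive modality adjacency
#'
#' The 3 x 3 adjacency over the (image, gaze, probe) nodes: entry (j, k) of
#' the soft term is softmax over k of the score theta(f_j)' phi(f_k) — each
#' row is a distribution over source nodes — and the full adjacency adds the
#' learnable unconstrained mask M.
#'
#' @param model a `guidenet`.
#' @param emb named list with 128-vectors `I`, `s`, `r` (one sample).
#' @return list with `A_soft` (row-stochastic 3 x 3), `M`, and `A = A_soft + M`,
#'   rows/columns ordered (I, s, r).
#' @export
compute_adjacency <- function(model, emb) {
  p <- model$params
  f <- rbind(I = emb$I, s = emb$s, r = emb$r)                # 3 x 128
  th <- sweep(f %*% p[["theta.W"]], 2L, as.numeric(p[["theta.b"]]), "+")
  ph <- sweep(f %*% p[["phi.W"]], 2L, as.numeric(p[["phi.b"]]), "+")
  S <- th %*% t(ph)                                          # scores (j, k)
  A_soft <- t(apply(S, 1L, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  M <- matrix(as.numeric(p[["M"]]), 3L, 3L, byrow = TRUE)
  dimnames(A_soft) <- dimnames(M) <- list(c("I", "s", "r"), c("I", "s", "r"))
  list(A_soft = A_soft, M = M, A = A_soft + M)
}

#' Graph-convolution message for one stream and gate
#'
#' sum over source nodes k of elementwise sigmoid(A(j,k) * f_k W_{j,gate}) —
#' the sigmoid sits inside the sum, so every output channel lies in (0, 3).
#'
#' @param model a `guidenet`.
#' @param A full 3 x 3 adjacency (from [compute_adjacency()]`$A`).
#' @param emb named list of 128-vectors `I`, `s`, `r`.
#' @param stream target node: "s" or "r".
#' @param gate which GRU gate kernel: "z", "g" (reset), or "h" (candidate).
#' @return 128-vector with entries in (0, 3).
#' @export
graph_message <- function(model, A, emb, stream = c("s", "r"),
                          gate = c("z", "g", "h")) {
  stream <- match.arg(stream); gate <- match.arg(gate)
  H <- model$config$hidden
  off <- c(z = 0L, g = H, h = 2L * H)[[gate]]
  W <- model$params[[paste0("msg.", stream, ".W")]][, (off + 1L):(off + H), drop = FALSE]
  j <- c(I = 1L, s = 2L, r = 3L)[[stream]]
  nodes <- c("I", "s", "r")
  out <- numeric(H)
  for (k in 1:3)
    out <- out + .sigmoid(A[j, k] * as.numeric(emb[[nodes[k]]] %*% W))
  out
}

#' Standard GRU gates driven by graph messages
#'
#' z = sigmoid(message_z + h_prev U_z + b_z) and reset gate gamma likewise,
#' for one stream.
#'
#' @param model a `guidenet`.
#' @param stream "s" or "r".
#' @param msg_z,msg_g graph messages for the update and reset gates
#'   (vectors or B x H matrices).
#' @param h_prev previous hidden state.
#' @return list with `z` and `gamma`, entries in (0, 1).
#' @export
gru_gates <- function(model, stream, msg_z, msg_g, h_prev) {
  p <- model$params
  mz <- rbind(msg_z); mg <- rbind(msg_g); h <- rbind(h_prev)
  z <- .sigmoid(sweep(mz + h %*% p[[paste0("gru.", stream, ".Uz")]], 2L,
                      as.numeric(p[[paste0("gru.", stream, ".bz")]]), "+"))
  g <- .sigmoid(sweep(mg + h %*% p[[paste0("gru.", stream, ".Ug")]], 2L,
                      as.numeric(p[[paste0("gru.", stream, ".bg")]]), "+"))
  if (is.null(dim(msg_z))) list(z = as.numeric(z), gamma = as.numeric(g))
  else list(z = z, gamma = g)
}

#' GRU candidate activation
#'
#' tanh(message_h + (gamma (.) h_prev) U_h + b_h): the reset-gated candidate
#' state, entries in (-1, 1).
#'
#' @inheritParams gru_gates
#' @param msg_h graph message for the candidate.
#' @param gamma reset gate.
#' @return candidate vector/matrix.
#' @export
candidate_state <- function(model, stream, msg_h, gamma, h_prev) {
  p <- model$params
  mh <- rbind(msg_h); g <- rbind(gamma); h <- rbind(h_prev)
  out <- tanh(sweep(mh + (g * h) %*% p[[paste0("gru.", stream, ".Uh")]], 2L,
                    as.numeric(p[[paste0("gru.", stream, ".bh")]]), "+"))
  if (is.null(dim(msg_h))) as.numeric(out) else out
}

#' Bidirectional pathway hidden-state update
#'
#' Each stream's new hidden state blends its own GRU update with the
#' cross-stream update gated by the other stream's update gate, with
#' channel-wise weights alpha (gaze) and beta (probe) in (0, 1):
#'
#' h_s = alpha(1 - z_s) h_s_prev + alpha z_s cand_s
#'       + (1 - alpha) z_r h_s_prev + (1 - alpha)(1 - z_r) cand_s,
#'
#' and the mirrored expression for the probe stream (roles of s/r and
#' alpha/beta exchanged). For every channel the coefficients on
#' (h_prev, cand) sum to exactly 1, and alpha = 1 (resp. beta = 1) recovers
#' the standard GRU update.
#'
#' @param h_prev_s,h_prev_r previous hidden states.
#' @param cand_s,cand_r candidate activations.
#' @param z_s,z_r update gates.
#' @param alpha,beta channel-wise weights in (0, 1).
#' @return list with updated `h_s` and `h_r`.
#' @export
pathway_update <- function(h_prev_s, h_prev_r, cand_s, cand_r, z_s, z_r,
                           alpha, beta) {
  h_s <- alpha * ((1 - z_s) * h_prev_s + z_s * cand_s) +
    (1 - alpha) * (z_r * h_prev_s + (1 - z_r) * cand_s)
  h_r <- beta * ((1 - z_r) * h_prev_r + z_r * cand_r) +
    (1 - beta) * (z_s * h_prev_r + (1 - z_s) * cand_r)
  list(h_s = h_s, h_r = h_r)
}

#' One recurrent step of the guidance network
#'
#' Embeds the three modality inputs, computes the adaptive adjacency and the
#' per-gate graph messages, runs both GRU streams, applies the bidirectional
#' pathway (or the standard GRU update when the pathway is disabled), and
#' emits the raw head vectors. Pure function of (inputs, state, parameters).
#'
#' @param model a `guidenet`.
#' @param x_I image feature vector (length `feature_dim`).
#' @param s gaze shift (length 2).
#' @param r rotation step quaternion (length 4).
#' @param state list with `h_s`, `h_r` (128-vectors); `NULL` for zeros.
#' @param training embedding BN in batch-statistics mode.
#' @return list with `state` (updated) and raw head outputs `raw_gaze`
#'   (length 5 for OG, 6 L for MG) and `raw_probe` (length 14).
#' @export
guidenet_step <- function(model, x_I, s, r, state = NULL, training = FALSE) {
  cfg <- model$config
  if (is.null(state))
    state <- list(h_s = numeric(cfg$hidden), h_r = numeric(cfg$hidden))
  emb <- list(I = embed_modality(model, x_I, "I", training),
              s = embed_modality(model, s, "s", training),
              r = embed_modality(model, r, "r", training))
  A <- compute_adjacency(model, emb)$A
  msgs <- lapply(c(s = "s", r = "r"), function(st)
    lapply(c(z = "z", g = "g", h = "h"), function(gt)
      graph_message(model, A, emb, st, gt)))
  gs <- gru_gates(model, "s", msgs$s$z, msgs$s$g, state$h_s)
  gr <- gru_gates(model, "r", msgs$r$z, msgs$r$g, state$h_r)
  cs <- candidate_state(model, "s", msgs$s$h, gs$gamma, state$h_s)
  cr <- candidate_state(model, "r", msgs$r$h, gr$gamma, state$h_r)
  if (cfg$bidirectional) {
    al <- .sigmoid(as.numeric(model$params[["alpha"]]))
    be <- .sigmoid(as.numeric(model$params[["beta"]]))
  } else {
    al <- rep(1, cfg$hidden); be <- rep(1, cfg$hidden)
  }
  hw <- pathway_update(state$h_s, state$h_r, cs, cr, gs$z, gr$z, al, be)
  p <- model$params
  raw_gaze <- as.numeric(hw$h_s %*% p[["head.s.W"]]) + as.numeric(p[["head.s.b"]])
  raw_probe <- as.numeric(hw$h_r %*% p[["head.r.W"]]) + as.numeric(p[["head.r.b"]])
  list(state = list(h_s = as.numeric(hw$h_s), h_r = as.numeric(hw$h_r)),
       raw_gaze = raw_gaze, raw_probe = raw_probe)
}

#' Teacher-forced rollout over a sequence
#'
#' Runs the network along a synchronized sequence with one-step-ahead
#' conditioning: inputs up to frame t - 1 produce the predicted
#' distributions for frame t, so predictions never see their own targets.
#' Predictions are emitted for t in \[t0, T\].
#'
#' @param model a `guidenet`.
#' @param sequence list with `features` (T x feature_dim), `gaze` (T x 2
#'   normalized), `quats` (T x 4 unit quaternions); `q_target` required for
#'   the SP policy (only by downstream target construction).
#' @param t0 warm-up index (default from the model config).
#' @return list of length T - t0 + 1; element i (for t = t0 + i - 1) has
#'   `t`, `gaze` (decoded `bivariate_gaussian` or `gaze_mixture`), `probe`
#'   (decoded `quat_gaussian`).
#' @export
guidenet_rollout <- function(model, sequence, t0 = model$config$t0) {
  cfg <- model$config
  T_len <- nrow(sequence$gaze)
  if (T_len < t0 + 2L) stop("sequence shorter than t0 + 2 frames")
  ins <- guidenet_inputs(sequence)
  state <- NULL
  out <- vector("list", T_len - t0 + 1L)
  for (u in seq_len(T_len - 1L)) {
    stp <- guidenet_step(model, ins$features[u, ], ins$s[u, ], ins$r[u, ],
                         state, training = FALSE)
    state <- stp$state
    t_pred <- u + 1L
    if (t_pred >= t0) {
      gz <- if (cfg$policy_gaze == "OG") decode_og(stp$raw_gaze)
            else decode_mg(stp$raw_gaze, cfg$L)
      out[[t_pred - t0 + 1L]] <- list(t = t_pred, gaze = gz,
                                      probe = decode_op(stp$raw_probe))
    }
  }
  out
}

#' Derive the teacher-forcing input streams of a sequence
#'
#' Input at frame t is the triple (feature_t, s_t, r_t) with
#' s_t = g_t - g_{t-1} and r_t = conj(q_{t-1}) q_t (canonical sign);
#' at t = 1 the shift is zero and the rotation the identity.
#'
#' @param sequence as in [guidenet_rollout()].
#' @return list with `features` (T x D), `s` (T x 2), `r` (T x 4).
#' @export
guidenet_inputs <- function(sequence) {
  T_len <- nrow(sequence$gaze)
  s <- rbind(c(0, 0), diff(as.matrix(sequence$gaze)))
  q <- as.matrix(sequence$quats)
  r <- matrix(0, T_len, 4L); r[1L, ] <- quat_identity()
  if (T_len > 1L) {
    rr <- quat_multiply(quat_conjugate(q[-T_len, , drop = FALSE]),
                        q[-1L, , drop = FALSE])
    r[-1L, ] <- .quat_mat_canonicalize(.quat_mat(rr))
  }
  list(features = as.matrix(sequence$features), s = s, r = r)
}
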