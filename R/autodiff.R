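# Internal reverse-mode automatic differentiation over matrix primitives.
#
# A tape records each intermediate value together with its parents and a
# backward closure; tp_backward() walks the tape in reverse, accumulating
# gradients into every leaf registered with tp_param(). All values are
# numeric matrices (scalars are 1 x 1). This is deliberately minimal: just
# the primitives the guidance network needs, each gradient-checked against
# central finite differences in the test suite.

tp_new <- function(capacity = 8192L) {
  tp <- new.env(parent = emptyenv())
  tp$val <- new.env(hash = TRUE, size = capacity, parent = emptyenv())
  tp$par <- new.env(hash = TRUE, size = capacity, parent = emptyenv())
  tp$bck <- new.env(hash = TRUE, size = capacity, parent = emptyenv())
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = NULL, backward = NULL) {
  n <- tp$n + 1L
  k <- as.character(n)
  assign(k, value, envir = tp$val)
  if (!is.null(parents)) {
    assign(k, parents, envir = tp$par)
    assign(k, backward, envir = tp$bck)
  }
  tp$n <- n
  n
}

tp_val <- function(tp, id) tp$val[[as.character(id)]]

tp_const <- function(tp, x) tp_push(tp, as.matrix(x))
tp_param <- tp_const  # leaves; gradients are read off after backward

# ---- primitives ----------------------------------------------------------

tp_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A %*% B, c(a, b),
          function(g) list(tcrossprod(g, B), crossprod(A, g)))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) + tp_val(tp, b), c(a, b),
          function(g) list(g, g))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) - tp_val(tp, b), c(a, b),
          function(g) list(g, -g))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

tp_div <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A / B, c(a, b),
          function(g) list(g / B, -g * A / B^2))
}

# row-broadcast: matrix (B x d) + bias (1 x d)
tp_add_bias <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); bb <- tp_val(tp, b)
  tp_push(tp, sweep(A, 2L, as.numeric(bb), "+"), c(a, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

# column-broadcast: (B x 1) scaling each row of (B x d)
tp_colmul <- function(tp, a, x) {
  force(a); force(x)
  av <- as.numeric(tp_val(tp, a)); X <- tp_val(tp, x)
  tp_push(tp, X * av, c(a, x),
          function(g) list(matrix(rowSums(g * X), ncol = 1L), g * av))
}

# row-broadcast: (1 x d) scaling each column of (B x d)
tp_rowmul <- function(tp, r, x) {
  force(r); force(x)
  rv <- as.numeric(tp_val(tp, r)); X <- tp_val(tp, x)
  tp_push(tp, sweep(X, 2L, rv, "*"), c(r, x),
          function(g) list(matrix(colSums(g * X), 1L), sweep(g, 2L, rv, "*")))
}

# per-row dot product of two (B x d) matrices -> (B x 1)
tp_rowdot <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, matrix(rowSums(A * B), ncol = 1L), c(a, b),
          function(g) { gv <- as.numeric(g); list(B * gv, A * gv) })
}

tp_scale <- function(tp, a, k) {
  force(a)
  tp_push(tp, tp_val(tp, a) * k, a, function(g) list(g * k))
}

tp_addc <- function(tp, a, k) {
  force(a)
  tp_push(tp, tp_val(tp, a) + k, a, function(g) list(g))
}

tp_neg <- function(tp, a) tp_scale(tp, a, -1)

tp_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp_val(tp, a)))
  tp_push(tp, y, a, function(g) list(g * y * (1 - y)))
}

tp_tanh <- function(tp, a) {
  force(a)
  y <- tanh(tp_val(tp, a))
  tp_push(tp, y, a, function(g) list(g * (1 - y^2)))
}

tp_relu <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, pmax(x, 0), a, function(g) list(g * (x > 0)))
}

tp_exp <- function(tp, a) {
  force(a)
  y <- exp(tp_val(tp, a))
  tp_push(tp, y, a, function(g) list(g * y))
}

tp_log <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, log(x), a, function(g) list(g / x))
}

tp_sqrt <- function(tp, a) {
  force(a)
  y <- sqrt(tp_val(tp, a))
  tp_push(tp, y, a, function(g) list(g / (2 * y)))
}

tp_softplus <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  y <- ifelse(x > 30, x, log1p(exp(x)))
  tp_push(tp, y, a, function(g) list(g / (1 + exp(-x))))
}

# clamp below at constant k; gradient passes only where not clamped
tp_pmax_const <- function(tp, a, k) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, pmax(x, k), a, function(g) list(g * (x > k)))
}

tp_sum <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, matrix(sum(x), 1L, 1L), a,
          function(g) list(matrix(as.numeric(g), nrow(x), ncol(x))))
}

tp_mean <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, matrix(mean(x), 1L, 1L), a,
          function(g) list(matrix(as.numeric(g) / length(x), nrow(x), ncol(x))))
}

tp_cbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp_val(tp, i))
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  tp_push(tp, do.call(cbind, vals), ids,
          function(g) lapply(seq_along(ids), function(i)
            g[, starts[i]:ends[i], drop = FALSE]))
}

tp_cols <- function(tp, a, j) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, x[, j, drop = FALSE], a,
          function(g) { out <- matrix(0, nrow(x), ncol(x)); out[, j] <- g; list(out) })
}

# row slice (contiguous or not); backward scatters into the source rows
tp_rows <- function(tp, a, i) {
  force(a)
  x <- tp_val(tp, a)
  tp_push(tp, x[i, , drop = FALSE], a,
          function(g) { out <- matrix(0, nrow(x), ncol(x)); out[i, ] <- g; list(out) })
}

tp_addn <- function(tp, ids) {
  force(ids)
  if (length(ids) == 1L) return(ids[[1L]])
  v <- tp_val(tp, ids[[1L]])
  for (i in ids[-1L]) v <- v + tp_val(tp, i)
  tp_push(tp, v, ids, function(g) rep(list(g), length(ids)))
}

tp_softmax_rows <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  y <- e / rowSums(e)
  tp_push(tp, y, a, function(g) list(y * (g - rowSums(g * y))))
}

tp_logsumexp_rows <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  m <- apply(x, 1L, max)
  s <- rowSums(exp(x - m))
  y <- matrix(m + log(s), ncol = 1L)
  soft <- exp(x - as.numeric(y))
  tp_push(tp, y, a, function(g) list(soft * as.numeric(g)))
}

# Fused batch normalization (per-feature over the batch dimension).
# In training mode uses batch statistics and imperatively updates the
# running estimates held in `state` (an environment with rm, rv, momentum);
# in evaluation mode it is the frozen affine map through the running stats.
tp_batchnorm <- function(tp, x, gamma, beta, state, training, eps = 1e-5) {
  force(x); force(gamma); force(beta)
  X <- tp_val(tp, x); ga <- as.numeric(tp_val(tp, gamma)); be <- as.numeric(tp_val(tp, beta))
  B <- nrow(X)
  if (training && B > 1L) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc^2)
    if (!isTRUE(state$initialized)) {
      # warm-start the running estimates at the first batch's statistics so
      # evaluation-mode normalization is sane from the start of training
      state$rm <- mu
      state$rv <- v * B / (B - 1L)
      state$initialized <- TRUE
    } else {
      state$rm <- (1 - state$momentum) * state$rm + state$momentum * mu
      state$rv <- (1 - state$momentum) * state$rv + state$momentum * v * B / (B - 1L)
    }
    ivar <- 1 / sqrt(v + eps)
    xh <- sweep(xc, 2L, ivar, "*")
    y <- sweep(sweep(xh, 2L, ga, "*"), 2L, be, "+")
    tp_push(tp, y, c(x, gamma, beta), function(g) {
      dgamma <- matrix(colSums(g * xh), 1L)
      dbeta <- matrix(colSums(g), 1L)
      dxh <- sweep(g, 2L, ga, "*")
      t1 <- sweep(dxh, 2L, colMeans(dxh))
      t2 <- sweep(xh, 2L, colMeans(dxh * xh), "*")
      dx <- sweep(t1 - t2, 2L, ivar, "*")
      list(dx, dgamma, dbeta)
    })
  } else {
    ivar <- 1 / sqrt(state$rv + eps)
    xh <- sweep(sweep(X, 2L, state$rm), 2L, ivar, "*")
    y <- sweep(sweep(xh, 2L, ga, "*"), 2L, be, "+")
    tp_push(tp, y, c(x, gamma, beta), function(g) {
      list(sweep(g, 2L, ga * ivar, "*"),
           matrix(colSums(g * xh), 1L),
           matrix(colSums(g), 1L))
    })
  }
}

# ---- backward pass -------------------------------------------------------

tp_grad <- function(grads, id) grads[[as.character(id)]]

tp_backward <- function(tp, loss_id) {
  grads <- new.env(hash = TRUE, size = tp$n, parent = emptyenv())
  g0 <- tp_val(tp, loss_id)
  grads[[as.character(loss_id)]] <- matrix(1, nrow(g0), ncol(g0))
  for (id in loss_id:1L) {
    k <- as.character(id)
    g <- grads[[k]]
    if (is.null(g)) next
    parents <- tp$par[[k]]
    if (is.null(parents)) next
    pg <- tp$bck[[k]](g)
    for (j in seq_along(parents)) {
      pk <- as.character(parents[[j]])
      grads[[pk]] <- if (is.null(grads[[pk]])) pg[[j]] else grads[[pk]] + pg[[j]]
    }
  }
  grads
}
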