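#' Gaze-point normalization and step shifts
#'
#' Raw eye-tracker output is in screen pixels; the model works in normalized
#' screen coordinates on (-0.5, 0.5) with the image center mapped to (0, 0),
#' x rightward and y downward. `normalize_gaze` applies the affine map,
#' clamping (and flagging) points that fall outside the image;
#' `denormalize_gaze` inverts it.
#'
#' @param raw_xy numeric length-2 pixel coordinates (x, y), or an N x 2
#'   matrix of points.
#' @param image_size integer length-2 `c(width, height)` in pixels.
#' @return for `normalize_gaze`, normalized coordinates of the same shape,
#'   with attribute `clamped` (logical) marking points that were outside the
#'   image; for `denormalize_gaze`, pixel coordinates.
#' @export
normalize_gaze <- function(raw_xy, image_size) {
  stopifnot(length(image_size) == 2L, all(image_size > 0))
  vec <- is.null(dim(raw_xy))
  m <- if (vec) matrix(raw_xy, nrow = 1L) else as.matrix(raw_xy)
  out <- sweep(m, 2L, image_size, "/") - 0.5
  clamped <- out[, 1L] < -0.5 | out[, 1L] > 0.5 | out[, 2L] < -0.5 | out[, 2L] > 0.5
  out[] <- pmin(0.5, pmax(-0.5, out))
  out <- if (vec) drop(out) else out
  attr(out, "clamped") <- if (vec) clamped[1L] else clamped
  out
}

#' @rdname normalize_gaze
#' @param norm_xy normalized coordinates in (-0.5, 0.5).
#' @export
denormalize_gaze <- function(norm_xy, image_size) {
  stopifnot(length(image_size) == 2L, all(image_size > 0))
  vec <- is.null(dim(norm_xy))
  m <- if (vec) matrix(norm_xy, nrow = 1L) else as.matrix(norm_xy)
  out <- sweep(m + 0.5, 2L, image_size, "*")
  if (vec) drop(out) else out
}

#' Per-step gaze shift
#'
#' The frame-to-frame displacement s_t = g_t - g_{t-1} of the gaze point in
#' normalized coordinates; the quantity the one-step gaze policy predicts.
#'
#' @param g_prev,g_curr normalized gaze points (length-2 or N x 2).
#' @return displacement of the same shape.
#' @export
gaze_shift <- function(g_prev, g_curr) {
  g_curr - g_prev
}

#' Reconstruct an absolute gaze point from a predicted shift
#'
#' g_hat = g_prev + s_hat, clamped to the normalized screen (-0.5, 0.5).
#'
#' @param g_prev normalized gaze point.
#' @param s_hat predicted shift.
#' @return normalized gaze point.
#' @export
reconstruct_gaze <- function(g_prev, s_hat) {
  pmin(pmax(g_prev + s_hat, -0.5), 0.5)
}

#' Cluster one sliding window of gaze points into fixation centers
#'
#' k-means over the F gaze points of one window, giving at most L fixation
#' centers with member-fraction weights. The first window of a sequence is
#' initialized with k-means++-style seeding; subsequent windows should pass
#' the previous window's result as `init`, so that cluster index l keeps its
#' identity across windows (the correspondence the multi-step gaze policy
#' needs for center displacements).
#'
#' If the window holds fewer distinct points than L, the cluster count is
#' reduced and the result flagged via attribute `reduced`.
#'
#' @param points F x 2 matrix of normalized gaze points (default F = 5).
#' @param L requested number of clusters (1..3 in practice; must not exceed
#'   the number of points).
#' @param init optional `center_window` from the previous window used to
#'   seed the centers.
#' @param window_start,window_end frame indices the window spans (metadata).
#' @return a `center_window`: list with `centers` (L x 2), `weights`
#'   (fractions summing to 1), `assign` (per-point cluster index),
#'   `window_start`, `window_end`.
#' @export
cluster_gaze_window <- function(points, L, init = NULL,
                                window_start = NA_integer_,
                                window_end = NA_integer_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, L >= 1L, L <= nrow(points))
  n <- nrow(points)
  uniq <- unique(points)
  L_eff <- min(L, nrow(uniq))
  reduced <- L_eff < L

  if (!is.null(init)) {
    centers0 <- init$centers
    if (nrow(centers0) != L)
      stop("init center count does not match L (correspondence broken)")
    centers0 <- centers0[seq_len(L_eff), , drop = FALSE]
  } else {
    centers0 <- NULL
  }

  if (L_eff == 1L) {
    centers <- matrix(colMeans(points), nrow = 1L)
    assign <- rep(1L, n)
  } else if (is.null(centers0) && n <= 8L) {
    # unseeded first window: windows are tiny, so take the exactly optimal
    # partition by enumeration instead of a local k-means solution
    assign <- .best_partition(points, L_eff)
    L_eff <- max(assign)
    reduced <- reduced || L_eff < min(L, nrow(uniq))
    centers <- t(vapply(seq_len(L_eff), function(l)
      colMeans(points[assign == l, , drop = FALSE]), numeric(2L)))
  } else {
    if (is.null(centers0)) centers0 <- .kmeanspp_init(uniq, L_eff)
    # Lloyd iterations from explicit seeds; stats::kmeans with matrix centers
    # drops empty clusters in ways that break the cross-window index
    # correspondence, so assignment is kept explicit here (tiny n: F points).
    centers <- centers0
    assign <- rep(1L, n)
    for (it in 1:25) {
      d2 <- .pairwise_sq(points, centers)
      new_assign <- max.col(-d2, ties.method = "first")
      for (l in seq_len(L_eff)) {
        mem <- new_assign == l
        if (any(mem)) centers[l, ] <- colMeans(points[mem, , drop = FALSE])
      }
      if (all(new_assign == assign) && it > 1L) break
      assign <- new_assign
    }
    # merge genuinely empty clusters (can happen with degenerate seeds)
    used <- sort(unique(assign))
    if (length(used) < L_eff) {
      centers <- centers[used, , drop = FALSE]
      assign <- match(assign, used)
      L_eff <- length(used)
      reduced <- TRUE
    }
  }

  w <- tabulate(assign, nbins = L_eff) / n
  structure(list(centers = centers, weights = w, assign = assign,
                 window_start = window_start, window_end = window_end),
            class = "center_window", reduced = reduced)
}

# exact minimum within-cluster-variance partition into at most k groups,
# by enumeration of restricted-growth strings (n <= 8 in practice)
.best_partition <- function(points, k) {
  n <- nrow(points)
  best <- NULL; best_w <- Inf
  rec <- function(assign, nl) {
    i <- length(assign) + 1L
    if (i > n) {
      w <- 0
      for (l in seq_len(nl)) {
        m <- points[assign == l, , drop = FALSE]
        w <- w + sum(sweep(m, 2L, colMeans(m))^2)
      }
      if (w < best_w) { best_w <<- w; best <<- assign }
      return(invisible())
    }
    for (l in seq_len(min(nl + 1L, k))) rec(c(assign, l), max(nl, l))
    invisible()
  }
  rec(integer(0), 0L)
  # stable center identity for the unseeded window: order groups by their
  # mean coordinates so repeated calls agree
  ctr <- t(vapply(seq_len(max(best)), function(l)
    colMeans(points[best == l, , drop = FALSE]), numeric(2L)))
  ord <- order(ctr[, 1L], ctr[, 2L])
  match(best, ord)
}

.pairwise_sq <- function(x, c) {
  # n x k squared distances
  outer(rowSums(x^2), rep(1, nrow(c))) +
    outer(rep(1, nrow(x)), rowSums(c^2)) - 2 * x %*% t(c)
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  if (k >= n) return(x[seq_len(k), , drop = FALSE])
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(.pairwise_sq(x, x[idx, , drop = FALSE]), 1L, min)
    d2[idx] <- 0
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- c(idx, sample.int(n, 1L, prob = p))
  }
  x[idx, , drop = FALSE]
}

#' @export
print.center_window <- function(x, ...) {
  cat(sprintf("center window [%s, %s]: %d center(s)\n",
              x$window_start, x$window_end, nrow(x$centers)))
  for (l in seq_len(nrow(x$centers)))
    cat(sprintf("  c%d = (%.3f, %.3f)  weight %.2f\n",
                l, x$centers[l, 1], x$centers[l, 2], x$weights[l]))
  invisible(x)
}

#' Displacement of corresponding fixation centers across windows
#'
#' s^l_t = c^l_t - c^l_{t-F}: the per-center displacement between two
#' windows F steps apart, relying on the seeded index correspondence
#' established by [cluster_gaze_window()].
#'
#' @param window_t,window_prev `center_window` objects with equal cluster
#'   count.
#' @return L x 2 matrix of displacements.
#' @export
center_displacement <- function(window_t, window_prev) {
  if (nrow(window_t$centers) != nrow(window_prev$centers))
    stop("cluster count mismatch between windows (correspondence broken)")
  window_t$centers - window_prev$centers
}

#' Sliding-window fixation centers along a gaze trace
#'
#' Runs [cluster_gaze_window()] over every length-F window of a gaze trace,
#' seeding each window from the previous one so center indices correspond
#' through time. Window t covers frames (t - F + 1) .. t.
#'
#' @param gaze T x 2 matrix of normalized gaze points.
#' @param L number of centers.
#' @param F_win window length in frames (default 5, about 1 s at 6 Hz).
#' @return list of length T; element t is the `center_window` ending at t
#'   (NULL for t < F_win).
#' @export
sliding_centers <- function(gaze, L, F_win = 5L) {
  T_len <- nrow(gaze)
  out <- vector("list", T_len)
  prev <- NULL
  if (T_len < F_win) return(out)
  for (t in F_win:T_len) {
    win <- gaze[(t - F_win + 1L):t, , drop = FALSE]
    cw <- cluster_gaze_window(win, L, init = prev,
                              window_start = t - F_win + 1L, window_end = t)
    # keep correspondence only while the cluster count is stable
    prev <- if (nrow(cw$centers) == L) cw else NULL
    out[[t]] <- cw
  }
  out
}
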