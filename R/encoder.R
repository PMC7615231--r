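#' Pluggable ultrasound frame encoder
#'
#' The guidance network consumes a 1,920-channel vector per video frame.
#' Frames are first encoded into a 640-channel 7 x 9 feature map by a
#' backbone, then adaptively average-pooled to 640 x 1 x 3 and flattened
#' (640 * 3 = 1,920). The backbone is pluggable: any function mapping a
#' 224 x 288 grayscale image to a 640 x 7 x 9 array satisfies the contract.
#' [test_backbone()] builds a small randomly initialized two-layer
#' convolutional backbone (32 x 32 patch convolution followed by a 1 x 1
#' convolution, both ReLU) that honours the same shape contract and keeps
#' end-to-end tests self-contained; a pretrained classifier backbone can be
#' dropped in through the same interface.
#'
#' @param seed integer seed for the random weights.
#' @param zero_bias use zero biases (so an all-zero frame maps to an all-zero
#'   feature vector).
#' @return a `frame_backbone` closure: `function(image)` returning a
#'   640 x 7 x 9 array.
#' @export
test_backbone <- function(seed = 1L, zero_bias = TRUE) {
  old <- .Random.seed_save()
  set.seed(seed)
  a1 <- sqrt(6 / (1024 + 640))
  W1 <- matrix(stats::runif(1024 * 640, -a1, a1), 1024L, 640L)
  a2 <- sqrt(6 / (640 + 640))
  W2 <- matrix(stats::runif(640 * 640, -a2, a2), 640L, 640L)
  b1 <- if (zero_bias) rep(0, 640) else stats::runif(640, -0.01, 0.01)
  b2 <- if (zero_bias) rep(0, 640) else stats::runif(640, -0.01, 0.01)
  .Random.seed_restore(old)
  structure(function(image) {
    patches <- .patchify(image, 32L, 32L)        # 63 x 1024, grid 7 x 9
    h <- pmax(sweep(patches %*% W1, 2L, b1, "+"), 0)
    h <- pmax(sweep(h %*% W2, 2L, b2, "+"), 0)   # 63 x 640
    aperm(array(h, c(7L, 9L, 640L)), c(3L, 1L, 2L))
  }, class = "frame_backbone")
}

.patchify <- function(image, ph, pw) {
  nr <- nrow(image) %/% ph; nc <- ncol(image) %/% pw
  out <- matrix(0, nr * nc, ph * pw)
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      k <- k + 1L
      out[k, ] <- as.numeric(image[((i - 1L) * ph + 1L):(i * ph),
                                   ((j - 1L) * pw + 1L):(j * pw)])
    }
  }
  # row order: column-major over the 7 x 9 grid, matching array(h, c(7,9,.))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Encode one ultrasound frame into the 1,920-channel representation
#'
#' Runs the backbone, then adaptive average pooling of the 640 x 7 x 9
#' feature map to 640 x 1 x 3 (the 7 spatial rows pooled fully; the 9
#' columns pooled into 3 bins of 3) and flattening, channel-fastest.
#'
#' @param image 224 x 288 numeric matrix with values in \[0, 1\].
#' @param backbone a `frame_backbone` (default: [test_backbone()]).
#' @return list with `feature_map` (640 x 7 x 9 array) and `pooled`
#'   (length-1920 numeric vector).
#' @export
encode_frame <- function(image, backbone = test_backbone()) {
  if (!is.matrix(image) || nrow(image) != 224L || ncol(image) != 288L)
    stop("expected a 224 x 288 grayscale frame, got ",
         paste(dim(image), collapse = " x "))
  fm <- backbone(image)
  stopifnot(all(dim(fm) == c(640L, 7L, 9L)))
  pooled_bins <- vapply(1:3, function(b) {
    cols <- ((b - 1L) * 3L + 1L):(b * 3L)
    rowMeans(matrix(fm[, , cols], nrow = 640L))
  }, numeric(640L))                               # 640 x 3
  list(feature_map = fm, pooled = as.numeric(pooled_bins))
}

#' Photometric and crop augmentation of a training frame
#'
#' Brightness and contrast jitter within +/-10% and a random crop keeping at
#' least 80% of each side, resized back to 224 x 288 (bilinear). Output is
#' clamped to \[0, 1\]. Deterministic under `seed`; augmentation is a
#' training-time transform only and must be disabled at evaluation.
#'
#' @param image 224 x 288 numeric matrix in \[0, 1\].
#' @param seed integer seed.
#' @return augmented 224 x 288 matrix in \[0, 1\].
#' @export
augment_frame <- function(image, seed) {
  stopifnot(is.matrix(image), all(image >= 0 & image <= 1))
  old <- .Random.seed_save()
  set.seed(seed)
  b <- stats::runif(1, -0.1, 0.1)
  cfac <- 1 + stats::runif(1, -0.1, 0.1)
  keep_h <- stats::runif(1, 0.8, 1)
  keep_w <- stats::runif(1, 0.8, 1)
  h <- nrow(image); w <- ncol(image)
  ch <- max(2L, round(h * keep_h)); cw <- max(2L, round(w * keep_w))
  oy <- sample.int(h - ch + 1L, 1L); ox <- sample.int(w - cw + 1L, 1L)
  .Random.seed_restore(old)
  img <- (image - 0.5) * cfac + 0.5 + b
  img <- img[oy:(oy + ch - 1L), ox:(ox + cw - 1L)]
  img <- EBImage::resize(img, w = h, h = w)  # EBImage: first dim is `w`
  pmin(pmax(matrix(as.numeric(img), h, w), 0), 1)
}
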