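# Low-level audiovisual shot features over grayscale frame stacks:
# zero-order motion (next-adjacent frame correlation), luminance (mean of
# per-frame medians), and clutter (edge-pixel fraction).

#' Construct a frame stack
#'
#' @param frames List of numeric matrices (grayscale, 0--255), all the same
#'   size, in temporal order. A 3-D array `H x W x n` is also accepted.
#' @param frame_rate Frames per second (metadata only).
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate = 24) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, c(1L, 1L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical dimensions")
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames, %dx%d @ %g fps\n",
              length(x$frames), d[1], d[2], x$frame_rate))
  invisible(x)
}

#' Zero-order motion of a shot
#'
#' Mean Pearson correlation of pixel values over all next-adjacent frame
#' pairs (1--3, 2--4, 3--5, ...). Lower correlations represent more motion.
#' A pair of bit-identical frames contributes 1 (no change); a pair where a
#' frame has zero variance but the frames differ is skipped with a message.
#'
#' @param stack A `frame_stack` with at least 3 frames.
#' @return Correlation in \[-1, 1\].
#' @export
shot_motion <- function(stack) {
  f <- stack$frames
  n <- length(f)
  if (n < 3)
    stop("motion is undefined for stacks with fewer than 3 frames")
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 2)) {
    a <- as.vector(f[[i]]); b <- as.vector(f[[i + 2]])
    if (identical(a, b)) { vals <- c(vals, 1); next }
    if (sd(a) == 0 || sd(b) == 0) { skipped <- skipped + 1L; next }
    vals <- c(vals, cor(a, b))
  }
  if (skipped > 0)
    message("shot_motion: skipped ", skipped, " zero-variance frame pair(s)")
  if (length(vals) == 0)
    stop("motion is undefined: no frame pair with variance")
  mean(vals)
}

#' Shot luminance
#'
#' Median luminance (0--255) of every frame, averaged across frames.
#'
#' @param stack A `frame_stack`.
#' @return Value in \[0, 255\].
#' @export
shot_luminance <- function(stack) {
  mean(vapply(stack$frames, function(fr) median(as.vector(fr)), 1.0))
}

# Sobel gradient magnitude with edge-replication padding
sobel_magnitude <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  p[1, ] <- p[2, ]; p[H + 2, ] <- p[H + 1, ]
  p[, 1] <- p[, 2]; p[, W + 2] <- p[, W + 1]
  sub <- function(di, dj) p[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  gx <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
        (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  gy <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
        (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Shot clutter (edge-pixel fraction)
#'
#' Applies a Sobel edge operator (gradient magnitude over a fixed threshold)
#' to every tenth frame starting from the first, and averages the fraction of
#' edge pixels per frame. The operator and threshold are fixed so results are
#' bit-reproducible.
#'
#' @param stack A `frame_stack`.
#' @param threshold Gradient-magnitude threshold on the 0--255 intensity
#'   scale (default 100; a full-contrast step responds at 1020).
#' @param stride Frame sampling stride (default 10: frames 1, 11, 21, ...).
#' @return Edge-pixel fraction in \[0, 1\].
#' @export
shot_clutter <- function(stack, threshold = 100, stride = 10) {
  idx <- seq(1, length(stack$frames), by = stride)
  mean(vapply(idx, function(i) {
    g <- sobel_magnitude(stack$frames[[i]])
    mean(g > threshold)
  }, 1.0))
}

#' All three features for a list of shots
#'
#' @param stacks Named list of `frame_stack` objects (one per shot).
#' @return Tibble with `shot`, `motion`, `luminance`, `clutter`.
#' @export
shot_features <- function(stacks) {
  tibble::tibble(
    shot = if (is.null(names(stacks))) seq_along(stacks) else names(stacks),
    motion = vapply(stacks, shot_motion, 1.0),
    luminance = vapply(stacks, shot_luminance, 1.0),
    clutter = vapply(stacks, shot_clutter, 1.0)
  )
}
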