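# Internal numerical helpers shared across modules. All image code uses the
# (row, col) convention, 0-based displacements in pixel units, origin top-left.

# Clamp values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Linear index into a h x w matrix for (row, col) vectors (1-based)
lin_idx <- function(r, c, h) (c - 1L) * h + r

# Bilinear sampling of matrix `img` at fractional positions (rr, cc), 1-based,
# edge-clamped outside the domain. rr, cc are vectors of equal length.
bilinear_sample <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  rr <- clamp(rr, 1, h)
  cc <- clamp(cc, 1, w)
  r0 <- floor(rr); c0 <- floor(cc)
  r0 <- clamp(r0, 1, h); c0 <- clamp(c0, 1, w)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- rr - r0; fc <- cc - c0
  v00 <- img[lin_idx(r0, c0, h)]
  v10 <- img[lin_idx(r1, c0, h)]
  v01 <- img[lin_idx(r0, c1, h)]
  v11 <- img[lin_idx(r1, c1, h)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Nearest-neighbour sampling with edge clamping (used for label propagation:
# never invents interpolated label values).
nearest_sample <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  r0 <- clamp(round(rr), 1, h)
  c0 <- clamp(round(cc), 1, w)
  img[lin_idx(r0, c0, h)]
}

# Central-difference gradient, one-sided at borders.
# Returns list(dr = d/d row, dc = d/d col).
grad2d <- function(img) {
  h <- nrow(img); w <- ncol(img)
  dr <- matrix(0, h, w)
  dc <- matrix(0, h, w)
  if (h >= 3) dr[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  if (h >= 2) {
    dr[1, ] <- img[2, ] - img[1, ]
    dr[h, ] <- img[h, ] - img[h - 1, ]
  }
  if (w >= 3) dc[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  if (w >= 2) {
    dc[, 1] <- img[, 2] - img[, 1]
    dc[, w] <- img[, w] - img[, w - 1]
  }
  list(dr = dr, dc = dc)
}

# Row/col coordinate grids for a h x w image
coord_grid <- function(h, w) {
  list(
    r = matrix(rep(seq_len(h), w), h, w),
    c = matrix(rep(seq_len(w), each = h), h, w)
  )
}

# Separable Gaussian blur with replicate (edge-clamped) boundary.
# Implemented through EBImage's C filtering path for speed.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  h <- nrow(img); w <- ncol(img)
  ksz <- 2L * radius + 1L
  if (ksz > h || ksz > w) {
    # pad with edge replication so the kernel fits, filter, crop back
    pr <- max(0L, ksz - h); pc <- max(0L, ksz - w)
    ri <- clamp(seq_len(h + 2L * pr) - pr, 1L, h)
    ci <- clamp(seq_len(w + 2L * pc) - pc, 1L, w)
    padded <- img[ri, ci, drop = FALSE]
    out <- as.matrix(EBImage::filter2(padded, kern, boundary = "replicate"))
    out[pr + seq_len(h), pc + seq_len(w), drop = FALSE]
  } else {
    as.matrix(EBImage::filter2(img, kern, boundary = "replicate"))
  }
}

# Deterministic RNG scope: runs expr with the given seed without disturbing
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
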