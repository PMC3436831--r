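# Colony segmentation for phase-contrast frames.
#
# Pipeline: retinex gray-value adaptation (flattens uneven illumination and
# halo artifacts) -> total-variation denoising (removes noise, keeps edges)
# -> two-phase region-based active contour -> hole filling -> 8-connected
# component labeling with a minimum-size filter.

#' Segmentation parameters
#'
#' @param retinex_sigma Gaussian scale (pixels) of the retinex illumination
#'   estimate.
#' @param tv_weight Total-variation regularization weight.
#' @param tv_iterations Iterations of the TV projection algorithm.
#' @param ac_iterations Active-contour evolution steps.
#' @param ac_smoothing Curve-smoothing passes per active-contour step.
#' @param min_object_px Components smaller than this many pixels are dropped.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(retinex_sigma = 30,
                                tv_weight = 0.1,
                                tv_iterations = 30L,
                                ac_iterations = 200L,
                                ac_smoothing = 2L,
                                min_object_px = 30L) {
  p <- list(retinex_sigma = retinex_sigma, tv_weight = tv_weight,
            tv_iterations = as.integer(tv_iterations),
            ac_iterations = as.integer(ac_iterations),
            ac_smoothing = as.integer(ac_smoothing),
            min_object_px = as.integer(min_object_px))
  if (p$retinex_sigma <= 0) stopf("retinex_sigma must be > 0")
  if (p$tv_weight <= 0) stopf("tv_weight must be > 0")
  if (p$tv_iterations < 1L) stopf("tv_iterations must be >= 1")
  if (p$ac_iterations < 1L) stopf("ac_iterations must be >= 1")
  if (p$ac_smoothing < 0L) stopf("ac_smoothing must be >= 0")
  if (p$min_object_px < 0L) stopf("min_object_px must be >= 0")
  structure(p, class = "segmentation_params")
}

#' Single-scale retinex illumination correction
#'
#' Locally adapts gray values by subtracting a log-domain illumination
#' estimate: `log(image + eps) - log(G_sigma * image + eps)`, linearly
#' rescaled to `[0, 1]`. Smooth illumination gradients and phase-contrast
#' halos are flattened while local texture contrast is preserved. A constant
#' image (degenerate rescale) maps to 0.5.
#'
#' @param image Matrix in `[0, 1]`.
#' @param retinex_sigma Gaussian scale of the illumination estimate (pixels).
#' @param eps Log-domain stabilizer.
#' @return Matrix in `[0, 1]`.
#' @export
retinex_correct <- function(image, retinex_sigma = 30, eps = 1e-3) {
  if (retinex_sigma <= 0) stopf("retinex_sigma must be > 0")
  image <- frame_pixels(image)
  illum <- gaussian_blur(image, retinex_sigma)
  r <- log(image + eps) - log(illum + eps)
  rng <- range(r)
  if (rng[2] - rng[1] < 1e-12) {
    return(matrix(0.5, nrow(image), ncol(image)))
  }
  (r - rng[1]) / (rng[2] - rng[1])
}

#' Total-variation denoising
#'
#' Rudin-Osher-Fatemi denoising by Chambolle's dual projection algorithm:
#' minimizes `||x - image||^2 / (2 * weight) + TV(x)`. Larger weights smooth
#' more; `weight -> 0` returns the input. Output is clipped to `[0, 1]`.
#'
#' @param image Matrix in `[0, 1]`.
#' @param tv_weight Regularization weight (> 0).
#' @param tv_iterations Number of projection iterations.
#' @return Denoised matrix in `[0, 1]`; its total variation never exceeds the
#'   input's.
#' @export
tv_denoise <- function(image, tv_weight = 0.1, tv_iterations = 30L) {
  if (tv_weight <= 0) stopf("tv_weight must be > 0")
  if (tv_iterations < 1) stopf("tv_iterations must be >= 1")
  image <- frame_pixels(image)
  h <- nrow(image); w <- ncol(image)
  # Chambolle (2004) dual iteration: u = f + d with d = -div p, and the dual
  # field p updated by a normalized gradient step of size tau = 1/4.
  p1 <- matrix(0, h, w); p2 <- matrix(0, h, w)
  tau <- 0.25
  out <- image
  for (it in seq_len(tv_iterations)) {
    # forward differences of the current estimate (zero at far edges)
    gx <- rbind(out[2:h, , drop = FALSE] - out[1:(h - 1), , drop = FALSE], rep(0, w))
    gy <- cbind(out[, 2:w, drop = FALSE] - out[, 1:(w - 1), drop = FALSE], rep(0, h))
    nrm <- 1 + (tau / tv_weight) * sqrt(gx^2 + gy^2)
    p1 <- (p1 - tau * gx) / nrm
    p2 <- (p2 - tau * gy) / nrm
    d <- -(p1 + p2)
    d[2:h, ] <- d[2:h, , drop = FALSE] + p1[1:(h - 1), , drop = FALSE]
    d[, 2:w] <- d[, 2:w, drop = FALSE] + p2[, 1:(w - 1), drop = FALSE]
    out <- image + d
  }
  clamp(out, 0, 1)
}

# total variation (isotropic, forward differences) -- used by tests
total_variation <- function(image) {
  h <- nrow(image); w <- ncol(image)
  gx <- rbind(image[2:h, , drop = FALSE] - image[1:(h - 1), , drop = FALSE], rep(0, w))
  gy <- cbind(image[, 2:w, drop = FALSE] - image[, 1:(w - 1), drop = FALSE], rep(0, h))
  sum(sqrt(gx^2 + gy^2))
}

# ---- morphological two-phase active contour ---------------------------------

# shift a matrix by (dr, dc) with edge replication
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  r <- clamp(seq_len(h) + dr, 1, h)
  c <- clamp(seq_len(w) + dc, 1, w)
  m[r, c, drop = FALSE]
}

# sup/inf over the 4 discrete line segments of length 3 through each pixel
# (horizontal, vertical, two diagonals): the curvature-smoothing operators of
# the morphological active-contour scheme.
sup_inf <- function(u) {
  line_min <- function(a, b) pmin(pmin(a, u), b)
  l1 <- line_min(shift_mat(u, -1, 0), shift_mat(u, 1, 0))
  l2 <- line_min(shift_mat(u, 0, -1), shift_mat(u, 0, 1))
  l3 <- line_min(shift_mat(u, -1, -1), shift_mat(u, 1, 1))
  l4 <- line_min(shift_mat(u, -1, 1), shift_mat(u, 1, -1))
  pmax(pmax(l1, l2), pmax(l3, l4))
}

inf_sup <- function(u) {
  line_max <- function(a, b) pmax(pmax(a, u), b)
  l1 <- line_max(shift_mat(u, -1, 0), shift_mat(u, 1, 0))
  l2 <- line_max(shift_mat(u, 0, -1), shift_mat(u, 0, 1))
  l3 <- line_max(shift_mat(u, -1, -1), shift_mat(u, 1, 1))
  l4 <- line_max(shift_mat(u, -1, 1), shift_mat(u, 1, -1))
  pmin(pmin(l1, l2), pmin(l3, l4))
}

# morphological gradient: boundary band where the level set can move
morph_gradient <- function(u) {
  dil <- pmax(pmax(shift_mat(u, -1, 0), shift_mat(u, 1, 0)),
              pmax(shift_mat(u, 0, -1), shift_mat(u, 0, 1)))
  dil <- pmax(dil, pmax(pmax(shift_mat(u, -1, -1), shift_mat(u, 1, 1)),
                        pmax(shift_mat(u, -1, 1), shift_mat(u, 1, -1))))
  ero <- pmin(pmin(shift_mat(u, -1, 0), shift_mat(u, 1, 0)),
              pmin(shift_mat(u, 0, -1), shift_mat(u, 0, 1)))
  ero <- pmin(ero, pmin(pmin(shift_mat(u, -1, -1), shift_mat(u, 1, 1)),
                        pmin(shift_mat(u, -1, 1), shift_mat(u, 1, -1))))
  dil - ero
}

#' Two-phase region-based active contour
#'
#' Morphological implementation of the piecewise-constant (Chan-Vese-type)
#' two-phase model: pixels on the evolving boundary join the phase whose mean
#' gray value they are closer to (in the squared sense), followed by
#' morphological curvature smoothing. The foreground phase is the brighter
#' one when no initialization is given; with `init_mask`, the evolved
#' initialization is the foreground.
#'
#' @param image Preprocessed matrix in `[0, 1]` (retinex + TV).
#' @param init_mask Optional binary matrix initialization; default is a
#'   checkerboard, which finds objects anywhere in the frame.
#' @param ac_iterations Evolution steps.
#' @param ac_smoothing Smoothing passes per step.
#' @return Binary (0/1 integer) foreground mask. A constant image returns an
#'   empty mask.
#' @export
active_contour_segment <- function(image, init_mask = NULL,
                                   ac_iterations = 200L, ac_smoothing = 2L) {
  image <- frame_pixels(image)
  h <- nrow(image); w <- ncol(image)
  if (diff(range(image)) < 1e-9) {
    return(matrix(0L, h, w))  # degenerate: no contrast, no colony
  }
  had_init <- !is.null(init_mask)
  if (had_init) {
    check_same_shape(image, init_mask, "image and init_mask")
    u <- matrix(as.numeric(init_mask > 0), h, w)
    if (sum(u) == 0) had_init <- FALSE
  }
  if (!had_init) {
    g <- coord_grid(h, w)
    u <- matrix(as.numeric(((g$r %/% 10) + (g$c %/% 10)) %% 2 == 0), h, w)
  }
  prev1 <- NULL; prev2 <- NULL
  for (it in seq_len(ac_iterations)) {
    a_in <- sum(u); a_out <- length(u) - a_in
    if (a_in == 0 || a_out == 0) break
    c1 <- sum(image * u) / a_in
    c2 <- sum(image * (1 - u)) / a_out
    band <- morph_gradient(u) > 0
    crit <- (image - c1)^2 - (image - c2)^2
    u[band & (crit < 0)] <- 1
    u[band & (crit > 0)] <- 0
    if (it %% 2 == 0) {
      for (s in seq_len(ac_smoothing)) u <- sup_inf(inf_sup(u))
    } else {
      for (s in seq_len(ac_smoothing)) u <- inf_sup(sup_inf(u))
    }
    # stop when the contour stabilizes (allowing the period-2 alternation of
    # the smoothing operators)
    if ((!is.null(prev1) && identical(u, prev1)) ||
        (!is.null(prev2) && identical(u, prev2))) break
    prev2 <- prev1
    prev1 <- u
  }
  a_in <- sum(u)
  if (a_in == 0 || a_in == length(u)) {
    return(matrix(0L, h, w))
  }
  # orient foreground to the brighter phase when the contour self-organized
  if (!had_init) {
    c1 <- sum(image * u) / sum(u)
    c2 <- sum(image * (1 - u)) / sum(1 - u)
    if (c1 < c2) u <- 1 - u
  }
  m <- matrix(as.integer(u > 0), h, w)
  m
}

#' Fill internal holes in a binary mask
#'
#' Background components not connected to the image border become foreground;
#' foreground pixels are never removed. Idempotent.
#'
#' @param mask Binary matrix.
#' @return Binary (0/1 integer) matrix.
#' @export
fill_holes <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  filled <- EBImage::fillHull(m)
  matrix(as.integer(filled > 0), nrow(mask), ncol(mask))
}

# ---- 8-connected labeling ---------------------------------------------------

# EBImage::bwlabel is 4-connected; merge labels that touch diagonally via
# union-find, then renumber 1..K in raster-scan (row-major) order of each
# component's first pixel.
label_components <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- as.matrix(EBImage::bwlabel(m))
  n <- max(lab)
  if (n == 0) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  h <- nrow(lab); w <- ncol(lab)
  # diagonal adjacencies between distinct nonzero labels
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(h - 1), if (sh[2] == 1) 1:(w - 1) else 2:w, drop = FALSE]
    b <- lab[2:h, if (sh[2] == 1) 2:w else 1:(w - 1), drop = FALSE]
    sel <- which(a > 0 & b > 0 & a != b)
    if (length(sel) > 0) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab_merged <- matrix(0L, h, w)
  nz <- lab > 0
  lab_merged[nz] <- root[lab[nz]]
  relabel_raster_order(lab_merged)
}

# renumber nonzero labels 1..K by raster-scan (row-major) order of first pixel
relabel_raster_order <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  nz <- which(lab > 0)
  if (length(nz) == 0) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  # row-major rank of each pixel: (row-1)*w + col
  r <- (nz - 1L) %% h + 1L
  c <- (nz - 1L) %/% h + 1L
  rm_rank <- (r - 1L) * w + c
  first <- tapply(rm_rank, lab[nz], min)
  old_ids <- as.integer(names(first))
  new_of <- integer(max(old_ids))
  new_of[old_ids[order(first)]] <- seq_along(old_ids)
  out <- matrix(0L, h, w)
  out[nz] <- new_of[lab[nz]]
  out
}

#' Segment colonies in one frame
#'
#' Full detection pipeline: retinex correction, TV denoising, two-phase
#' active contour, hole filling, 8-connected component labeling, and removal
#' of components below `min_object_px`. Labels are assigned `1..K` in
#' raster-scan order of each component's first pixel, which makes the result
#' deterministic.
#'
#' @param frame Frame object or `[0, 1]` matrix.
#' @param params A [segmentation_params()] list.
#' @param init_mask Optional binary initialization for the active contour
#'   (used by the tracker, which initializes with propagated masks).
#' @return Integer label matrix (0 = background).
#' @export
segment_colonies <- function(frame, params = segmentation_params(),
                             init_mask = NULL) {
  stopifnot(inherits(params, "segmentation_params"))
  px <- frame_pixels(frame)
  pre <- retinex_correct(px, params$retinex_sigma)
  pre <- tv_denoise(pre, params$tv_weight, params$tv_iterations)
  fg <- active_contour_segment(pre, init_mask = init_mask,
                               ac_iterations = params$ac_iterations,
                               ac_smoothing = params$ac_smoothing)
  fg <- fill_holes(fg)
  lab <- label_components(fg)
  if (params$min_object_px > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < params$min_object_px)
    if (length(drop) > 0) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_raster_order(lab)
    }
  }
  lab
}
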