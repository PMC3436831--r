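# Structural and dynamical colony statistics.
#
# Global: covered-area fraction. Per colony: pixel area, elongation xi
# (1 - minor/major best-fit-ellipse axis ratio), circularity 4*pi*a/p^2 with
# a Crofton multi-directional perimeter estimate, base-e gray-level entropy
# of the pixels inside the colony, and mean/standard deviation of the
# within-colony displacement magnitudes. Plus per-frame median/quartile
# summaries and a rank-sum comparison between experimental conditions.

check_colony <- function(mask, colony_id) {
  sel <- mask == colony_id
  if (colony_id <= 0 || !any(sel)) {
    stopf("colony %s not present in mask", format(colony_id))
  }
  sel
}

#' Covered-area fraction
#'
#' Fraction of the frame covered by detected colonies: nonzero mask pixels
#' divided by total pixels.
#'
#' @param mask Integer label matrix.
#' @return Number in `[0, 1]`.
#' @export
covered_area_fraction <- function(mask) {
  sum(mask > 0) / length(mask)
}

#' Colony elongation
#'
#' `xi = 1 - minor/major`, the axis ratio of the best-fit ellipse obtained
#' from the second-order central moments of the colony's pixel set
#' (axis length = 4 * sqrt of the corresponding covariance eigenvalue).
#' Round colonies give `xi ~ 0`, elongated ones `xi -> 1`; degenerate
#' (collinear) pixel sets are capped at `1 - 1e-6`.
#'
#' @param mask Integer label matrix.
#' @param colony_id Positive label present in `mask`.
#' @return Number in `[0, 1)`.
#' @export
colony_elongation <- function(mask, colony_id) {
  sel <- check_colony(mask, colony_id)
  n <- sum(sel)
  if (n < 5) stopf("colony %d has area %d < 5 px; elongation undefined", colony_id, n)
  h <- nrow(mask)
  idx <- which(sel)
  r <- (idx - 1L) %% h + 1L
  c <- (idx - 1L) %/% h + 1L
  mu_rr <- stats::var(r) * (n - 1) / n
  mu_cc <- stats::var(c) * (n - 1) / n
  mu_rc <- stats::cov(r, c) * (n - 1) / n
  tr <- mu_rr + mu_cc
  disc <- sqrt(max(0, (mu_rr - mu_cc)^2 + 4 * mu_rc^2))
  l1 <- (tr + disc) / 2  # major-axis eigenvalue
  l2 <- (tr - disc) / 2
  if (l1 <= 0) return(1 - 1e-6)
  xi <- 1 - sqrt(max(0, l2) / l1)
  min(xi, 1 - 1e-6)
}

# Crofton 4-direction perimeter estimate: counts boundary crossings of the
# horizontal, vertical and both diagonal line families (spacing 1, 1,
# 1/sqrt(2), 1/sqrt(2)) and applies the Cauchy-Crofton formula
# P = (pi/8) * (N_h + N_v + (N_d1 + N_d2)/sqrt(2)).
crofton_perimeter <- function(sel) {
  h <- nrow(sel); w <- ncol(sel)
  m <- matrix(0L, h + 2, w + 2)
  m[2:(h + 1), 2:(w + 1)] <- as.integer(sel)
  hh <- nrow(m); ww <- ncol(m)
  n_v <- sum(m[2:hh, ] != m[1:(hh - 1), ])            # crossings along columns
  n_h <- sum(m[, 2:ww] != m[, 1:(ww - 1)])            # crossings along rows
  n_d1 <- sum(m[2:hh, 2:ww] != m[1:(hh - 1), 1:(ww - 1)])
  n_d2 <- sum(m[2:hh, 1:(ww - 1)] != m[1:(hh - 1), 2:ww])
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Colony circularity
#'
#' `gamma = 4 * pi * a / p^2` with pixel-count area `a` and a Crofton
#' multi-directional perimeter estimate `p` (raw boundary-pixel counting
#' would bias a disc's circularity to ~0.8; the Crofton estimator is
#' asymptotically unbiased, so a circle scores ~1). Mild discretization
#' overshoot is capped at 1.1.
#'
#' @inheritParams colony_elongation
#' @return Positive number, ~1 for a disc, decreasing with boundary
#'   irregularity.
#' @export
colony_circularity <- function(mask, colony_id) {
  sel <- check_colony(mask, colony_id)
  a <- sum(sel)
  p <- crofton_perimeter(sel)
  if (p <= 0) return(1.1)
  min(4 * pi * a / p^2, 1.1)
}

#' Gray-level entropy inside a colony
#'
#' Base-e Shannon entropy of the gray-value distribution inside the colony:
#' pixels are quantized into `n_levels` uniform bins on `[0, 1]`, and
#' `H = -sum_i p(g_i) * log(p(g_i))` with `0 * log 0 = 0`. With the default
#' 256 bins, the bins coincide with native 8-bit gray levels.
#'
#' @param frame Frame object or `[0, 1]` matrix.
#' @param mask Integer label matrix.
#' @param colony_id Positive label present in `mask`.
#' @param n_levels Number of uniform quantization bins (>= 2).
#' @return Entropy in nats, `>= 0`.
#' @export
colony_entropy <- function(frame, mask, colony_id, n_levels = 256L) {
  if (n_levels < 2) stopf("n_levels must be >= 2")
  px <- frame_pixels(frame)
  check_same_shape(px, mask, "frame and mask")
  sel <- check_colony(mask, colony_id)
  g <- px[sel]
  bins <- pmin(floor(g * n_levels), n_levels - 1)
  p <- tabulate(bins + 1L, nbins = as.integer(n_levels))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Within-colony displacement statistics
#'
#' Mean and population standard deviation of the displacement-vector norms
#' `||u(x)||` over the pixels of one colony; summarizes the internal motion
#' between the frame and its successor.
#'
#' @param field `h x w x 2` displacement array.
#' @param mask Integer label matrix (same shape).
#' @param colony_id Positive label present in `mask`.
#' @return Named numeric vector `c(mean, sd)` (pixels/frame).
#' @export
displacement_stats <- function(field, mask, colony_id) {
  check_same_shape(mask, field, "mask and field")
  sel <- check_colony(mask, colony_id)
  nrm <- sqrt(field[, , 1][sel]^2 + field[, , 2][sel]^2)
  m <- mean(nrm)
  s <- sqrt(mean((nrm - m)^2))  # population form
  c(mean = m, sd = s)
}

#' Measure a whole tracked sequence
#'
#' One record per colony per frame: area, elongation, circularity, entropy,
#' displacement mean/sd and centroid. Displacement statistics describe the
#' motion from each frame to its successor and are attached to the earlier
#' frame; they are `NA` on the final frame (no successor), and for colonies
#' whose area is below 5 px the ellipse-based elongation is `NA`.
#'
#' @param frames List of frames (or matrices).
#' @param masks List of label masks, same length.
#' @param fields List of displacement fields, one fewer than frames
#'   (`fields[[t]]` maps frame `t` onto `t + 1`); may be `NULL` to skip
#'   displacement features.
#' @param n_levels Entropy quantization bins.
#' @return Tibble with the fixed feature-table columns; the total pixel count
#'   per frame is attached as attribute `frame_px`.
#' @export
measure_sequence <- function(frames, masks, fields = NULL, n_levels = 256L) {
  n <- length(frames)
  if (length(masks) != n) stopf("got %d masks for %d frames", length(masks), n)
  if (!is.null(fields) && length(fields) != n - 1) {
    stopf("expected %d displacement fields, got %d", n - 1, length(fields))
  }
  rows <- list()
  for (t in seq_len(n)) {
    px <- frame_pixels(frames[[t]])
    mask <- masks[[t]]
    ids <- setdiff(sort(unique(as.integer(mask))), 0L)
    if (length(ids) == 0) next
    cen <- mask_centroids(mask)
    for (id in ids) {
      area <- sum(mask == id)
      disp <- if (!is.null(fields) && t < n) {
        displacement_stats(fields[[t]], mask, id)
      } else {
        c(mean = NA_real_, sd = NA_real_)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        frame = t - 1L,
        colony_id = id,
        area_px = as.integer(area),
        elongation = if (area >= 5) colony_elongation(mask, id) else NA_real_,
        circularity = colony_circularity(mask, id),
        entropy = colony_entropy(px, mask, id, n_levels),
        mean_displacement = disp[["mean"]],
        sd_displacement = disp[["sd"]],
        centroid_row = cen$centroid_row[cen$label == id],
        centroid_col = cen$centroid_col[cen$label == id])
    }
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(frame = integer(), colony_id = integer(),
                   area_px = integer(), elongation = numeric(),
                   circularity = numeric(), entropy = numeric(),
                   mean_displacement = numeric(), sd_displacement = numeric(),
                   centroid_row = numeric(), centroid_col = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  attr(out, "frame_px") <- length(frame_pixels(frames[[1]]))
  out
}

#' Per-frame distribution summaries of a colony feature
#'
#' Median and 0.25/0.75 quantiles (linear-interpolation definition) of one
#' feature across the colonies of each frame, with the colony count. Frames
#' without colonies (or with only `NA` feature values) are omitted.
#'
#' @param records Feature tibble from [measure_sequence()].
#' @param feature_name One of the feature columns (e.g. `"circularity"`).
#' @return Tibble with `frame`, `feature`, `median`, `q25`, `q75`,
#'   `n_colonies`.
#' @export
summarize_frames <- function(records, feature_name) {
  if (!feature_name %in% names(records)) {
    stopf("unknown feature '%s'", feature_name)
  }
  records |>
    dplyr::filter(!is.na(.data[[feature_name]])) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      feature = feature_name,
      median = stats::median(.data[[feature_name]]),
      q25 = stats::quantile(.data[[feature_name]], 0.25, names = FALSE),
      q75 = stats::quantile(.data[[feature_name]], 0.75, names = FALSE),
      n_colonies = dplyr::n(),
      .groups = "drop")
}

#' Compare a feature between two conditions
#'
#' Two-sided Wilcoxon rank-sum test on the pooled per-colony values of one
#' feature (pooled over frames, as when comparing whole experiments). Uses
#' the exact distribution for small tie-free pools and the tie-corrected
#' normal approximation otherwise.
#'
#' @param records_a,records_b Feature tibbles for the two conditions.
#' @param feature_name Feature column to compare.
#' @return One-row tibble: `feature`, `statistic` (rank-sum `W`), `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_conditions <- function(records_a, records_b, feature_name) {
  for (rec in list(records_a, records_b)) {
    if (!feature_name %in% names(rec)) stopf("unknown feature '%s'", feature_name)
  }
  xa <- records_a[[feature_name]]; xa <- xa[!is.na(xa)]
  xb <- records_b[[feature_name]]; xb <- xb[!is.na(xb)]
  if (length(xa) == 0 || length(xb) == 0) stopf("empty feature pool")
  use_exact <- length(xa) <= 20 && length(xb) <= 20 &&
    !any(duplicated(c(xa, xb)))
  ht <- stats::wilcox.test(xa, xb, exact = use_exact, correct = TRUE)
  tibble::tibble(
    feature = feature_name,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_a = length(xa),
    n_b = length(xb))
}
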