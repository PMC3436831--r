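# Shared fixture builders. Everything is generated in code, deterministically.

# rasterized disc mask (integer labels)
disc_mask <- function(h, w, cr, cc, r, label = 1L) {
  g <- coord_grid_t(h, w)
  m <- matrix(0L, h, w)
  m[sqrt((g$r - cr)^2 + (g$c - cc)^2) <= r] <- as.integer(label)
  m
}

coord_grid_t <- function(h, w) {
  list(r = matrix(rep(seq_len(h), w), h, w),
       c = matrix(rep(seq_len(w), each = h), h, w))
}

# smooth textured blob on a dark background; returns image + gaussian envelope
textured_blob <- function(seed, h = 128, w = 128, center = c(64, 64),
                          sigma_env = 8, tex_sigma = 2) {
  set.seed(seed)
  g <- coord_grid_t(h, w)
  env <- exp(-((g$r - center[1])^2 + (g$c - center[2])^2) / (2 * sigma_env^2))
  k <- stats::dnorm(seq(-3 * tex_sigma, 3 * tex_sigma), sd = tex_sigma)
  k <- outer(k, k); k <- k / sum(k)
  tex <- as.matrix(EBImage::filter2(matrix(stats::rnorm(h * w), h, w), k,
                                    boundary = "replicate"))
  tex <- (tex - min(tex)) / (max(tex) - min(tex))
  list(image = 0.2 + 0.6 * env * tex, envelope = env)
}

# frame pair deformed by a known analytic field: template = warp(source, u)
deformed_pair <- function(seed, field, ...) {
  b <- textured_blob(seed, ...)
  list(source = b$image, template = warp_image(b$image, field),
       envelope = b$envelope, field = field)
}

# synthetic segmentation frame: textured discs on background, mild noise
seg_frame <- function(seed, h = 160, w = 160, discs, noise = 0.03) {
  set.seed(seed)
  img <- matrix(0.2, h, w)
  g <- coord_grid_t(h, w)
  k <- stats::dnorm(-5:5, sd = 1.5); k <- outer(k, k); k <- k / sum(k)
  tex <- as.matrix(EBImage::filter2(matrix(stats::rnorm(h * w), h, w), k,
                                    boundary = "replicate"))
  tex <- 0.6 + 0.12 * tex / stats::sd(tex)
  truth <- matrix(0L, h, w)
  for (i in seq_along(discs)) {
    d <- discs[[i]]
    sel <- sqrt((g$r - d[1])^2 + (g$c - d[2])^2) <= d[3]
    img[sel] <- tex[sel]
    truth[sel] <- i
  }
  if (noise > 0) img <- pmin(pmax(img + matrix(stats::rnorm(h * w, 0, noise), h, w), 0), 1)
  list(image = img, truth = truth)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# best Jaccard of predicted label against a truth mask region
best_label_for <- function(mask, truth_sel) {
  tab <- table(mask[truth_sel & mask > 0])
  if (length(tab) == 0) return(NA_integer_)
  as.integer(names(which.max(tab)))
}
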