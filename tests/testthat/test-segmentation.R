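# Segmentation: retinex, TV denoising, active contour, hole filling, labeling

test_that("retinex flattens illumination gradients and compresses halos", {
  expect_equal(retinex_correct(matrix(0.4, 40, 40), 10), matrix(0.5, 40, 40))

  # multiplicative ramp x texture: output decorrelates from the ramp
  set.seed(11)
  g <- coord_grid_t(96, 96)
  ramp <- 0.3 + 0.6 * g$c / 96
  tex <- 0.7 + 0.3 * sin(g$r / 2) * cos(g$c / 3)
  img <- pmin(ramp * tex, 1)
  out <- retinex_correct(img, 20)
  expect_lt(abs(cor(as.numeric(out), as.numeric(ramp))),
            abs(cor(as.numeric(img), as.numeric(ramp))))

  # bright halo around a disc: output range compressed relative to input
  sf <- seg_frame(12, discs = list(c(80, 80, 30)), noise = 0)
  halo <- sf$image
  d <- sqrt((coord_grid_t(160, 160)$r - 80)^2 + (coord_grid_t(160, 160)$c - 80)^2)
  ring <- d > 30 & d <= 35
  halo[ring] <- pmin(halo[ring] + 0.35, 1)
  out2 <- retinex_correct(halo, 20)
  # the halo excursion, as a share of the image's dynamic range, shrinks
  bg <- d > 45
  rel_before <- (mean(halo[ring]) - mean(halo[bg])) / diff(range(halo))
  rel_after <- (mean(out2[ring]) - mean(out2[bg])) / diff(range(out2))
  expect_lt(rel_after, rel_before)

  expect_error(retinex_correct(matrix(0.5, 4, 4), -1), "retinex_sigma")
})

test_that("tv_denoise reduces noise, preserves edges, never raises total variation", {
  const <- matrix(0.6, 32, 32)
  expect_equal(tv_denoise(const, 0.1, 20), const)

  set.seed(9)
  step <- matrix(0.3, 64, 64); step[, 33:64] <- 0.7
  noisy <- pmin(pmax(step + matrix(rnorm(64 * 64, 0, 0.05), 64, 64), 0), 1)
  den <- tv_denoise(noisy, 0.1, 30)
  # noise variance in a flat region reduced at least 5x
  flat <- cbind(5:28, 5:28)
  expect_gt(var(as.numeric(noisy[5:28, 5:28])) /
              var(as.numeric(den[5:28, 5:28])), 5)
  # half-height edge crossing stays within 1 px of the true position
  crossings <- apply(den, 1, function(r) which(r > 0.5)[1])
  expect_true(all(abs(crossings - 33) <= 1))
  expect_lte(colonytrack:::total_variation(den),
             colonytrack:::total_variation(noisy))

  # weight -> 0 limit returns the input
  expect_lt(max(abs(tv_denoise(noisy, 1e-6, 10) - noisy)), 1e-3)

  expect_error(tv_denoise(noisy, 0), "tv_weight")
})

test_that("active contour finds a bright disc and respects initialization", {
  g <- coord_grid_t(96, 96)
  truth <- sqrt((g$r - 48)^2 + (g$c - 48)^2) <= 25
  img <- matrix(0.2, 96, 96); img[truth] <- 0.8
  fg <- active_contour_segment(img)
  expect_gte(jaccard(fg > 0, truth), 0.95)

  expect_equal(active_contour_segment(matrix(0.5, 48, 48)),
               matrix(0L, 48, 48))

  # with the true mask as init, a single iteration suffices; the default
  # (checkerboard) init is still far from done after the same budget
  fg_init <- active_contour_segment(img, init_mask = truth, ac_iterations = 1)
  fg_cold <- active_contour_segment(img, ac_iterations = 1)
  expect_gte(jaccard(fg_init > 0, truth), 0.95)
  expect_lt(jaccard(fg_cold > 0, truth), jaccard(fg_init > 0, truth))

  expect_error(active_contour_segment(img, init_mask = matrix(1, 4, 4)), "shape")
})

test_that("fill_holes closes internal holes only and is idempotent", {
  g <- coord_grid_t(64, 64)
  d1 <- sqrt((g$r - 20)^2 + (g$c - 20)^2)
  annulus <- matrix(0L, 64, 64); annulus[d1 <= 12 & d1 >= 7] <- 1L
  filled <- fill_holes(annulus)
  expect_equal(filled, matrix(as.integer(d1 <= 12), 64, 64))
  expect_true(all(filled[annulus == 1] == 1))  # foreground never shrinks

  solid <- matrix(0L, 32, 32); solid[10:20, 10:20] <- 1L
  expect_equal(fill_holes(solid), solid)
  expect_equal(fill_holes(fill_holes(annulus)), fill_holes(annulus))

  # two annuli -> two discs, background between them preserved
  d2 <- sqrt((g$r - 45)^2 + (g$c - 45)^2)
  two <- annulus; two[d2 <= 12 & d2 >= 7] <- 1L
  f2 <- fill_holes(two)
  lab <- colonytrack:::label_components(f2)
  expect_equal(max(lab), 2)
  expect_equal(sum(f2), sum(d1 <= 12) + sum(d2 <= 12))
})

test_that("segment_colonies labels separated discs and merges touching ones", {
  sf <- seg_frame(21, discs = list(c(45, 45, 25), c(110, 100, 30), c(40, 120, 15)))
  lab <- segment_colonies(sf$image)
  expect_equal(max(lab), 3)
  for (i in 1:3) {
    truth_sel <- sf$truth == i
    l <- best_label_for(lab, truth_sel)
    expect_gte(jaccard(lab == l, truth_sel), 0.9)
  }

  # two overlapping discs form one 8-connected object, hence one label
  sf2 <- seg_frame(22, discs = list(c(80, 60, 25), c(80, 95, 25)))
  lab2 <- segment_colonies(sf2$image)
  expect_equal(max(lab2), 1)

  expect_equal(max(segment_colonies(matrix(0.5, 64, 64))), 0)
})

test_that("segment_colonies is deterministic and enforces min_object_px", {
  sf <- seg_frame(23, discs = list(c(50, 50, 20), c(120, 120, 6)))
  lab1 <- segment_colonies(sf$image)
  lab2 <- segment_colonies(sf$image)
  expect_identical(lab1, lab2)

  # the r=6 disc (~113 px) survives the default threshold but not a large one
  sizes <- tabulate(lab1[lab1 > 0])
  expect_true(all(sizes >= 30))
  lab3 <- segment_colonies(sf$image, segmentation_params(min_object_px = 500))
  expect_equal(max(lab3), 1)
  expect_true(all(tabulate(lab3[lab3 > 0]) >= 500))
})

test_that("labels are assigned in raster-scan order of first pixel", {
  # object A starts at row 10, object B at row 30: A must get label 1
  m <- matrix(0L, 64, 64)
  m[30:40, 5:15] <- 1L   # drawn first but later in raster order
  m[10:20, 40:50] <- 1L
  lab <- colonytrack:::label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(unique(as.integer(lab[10:20, 40:50])), 1L)
  expect_equal(unique(as.integer(lab[30:40, 5:15])), 2L)

  # diagonal connectivity: a diagonal chain is one component
  d <- matrix(0L, 16, 16)
  for (i in 1:10) d[i, i] <- 1L
  expect_equal(max(colonytrack:::label_components(d)), 1)
})

test_that("per-object accuracy holds across the disc radius range", {
  for (cfg in list(list(seed = 31, r = 10), list(seed = 32, r = 35),
                   list(seed = 33, r = 60))) {
    sf <- seg_frame(cfg$seed, discs = list(c(80, 80, cfg$r)), noise = 0.05)
    lab <- segment_colonies(sf$image)
    expect_equal(max(lab), 1)
    expect_gte(jaccard(lab == 1, sf$truth == 1), 0.9)
  }
})
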