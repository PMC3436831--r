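# Structural and dynamical colony statistics

test_that("covered_area_fraction matches arithmetic and per-colony sums", {
  expect_equal(covered_area_fraction(matrix(0L, 10, 10)), 0)
  expect_equal(covered_area_fraction(matrix(1L, 10, 10)), 1)
  m <- matrix(0L, 480, 640)
  m[1:100, 1:100] <- 1L
  expect_equal(covered_area_fraction(m), 10000 / 307200)

  # equals the per-colony area sum over total pixels
  m2 <- disc_mask(80, 80, 20, 20, 10)
  m2[disc_mask(80, 80, 60, 60, 14) > 0] <- 2L
  per_colony <- sum(m2 == 1) + sum(m2 == 2)
  expect_equal(covered_area_fraction(m2), per_colony / length(m2))
})

test_that("elongation: disc ~ 0, 40:10 ellipse ~ 0.75, line ~ 1", {
  expect_lt(colony_elongation(disc_mask(120, 120, 60, 60, 40), 1), 0.02)

  g <- coord_grid_t(100, 200)
  ell <- matrix(0L, 100, 200)
  ell[((g$r - 50) / 10)^2 + ((g$c - 100) / 40)^2 <= 1] <- 1L
  expect_equal(colony_elongation(ell, 1), 0.75, tolerance = 0.03)

  line <- matrix(0L, 60, 10); line[5:54, 5] <- 1L
  expect_gte(colony_elongation(line, 1), 0.95)

  expect_error(colony_elongation(ell, 9), "not present")
})

test_that("elongation is rotation-stable", {
  # exact under 90 degree rotation
  g <- coord_grid_t(120, 120)
  ell <- matrix(0L, 120, 120)
  ell[((g$r - 60) / 12)^2 + ((g$c - 60) / 30)^2 <= 1] <- 1L
  rot90 <- t(ell)[, 120:1]
  expect_equal(colony_elongation(ell, 1), colony_elongation(rot90, 1),
               tolerance = 1e-10)
  # stable within 0.03 under arbitrary rotation (rasterized ellipse)
  th <- 30 * pi / 180
  rr <- cos(th) * (g$r - 60) + sin(th) * (g$c - 60)
  cc <- -sin(th) * (g$r - 60) + cos(th) * (g$c - 60)
  ell30 <- matrix(0L, 120, 120)
  ell30[(rr / 12)^2 + (cc / 30)^2 <= 1] <- 1L
  expect_equal(colony_elongation(ell30, 1), colony_elongation(ell, 1),
               tolerance = 0.03)
})

test_that("circularity: disc ~ 1, rectangle closed form, irregularity decreases it", {
  expect_gte(colony_circularity(disc_mask(120, 120, 60, 60, 50), 1), 0.95)
  expect_lte(colony_circularity(disc_mask(120, 120, 60, 60, 50), 1), 1.05)

  rect <- matrix(0L, 40, 300); rect[10:19, 20:269] <- 1L
  expect_lt(abs(colony_circularity(rect, 1) - 4 * pi * 2500 / 520^2), 0.02)

  # a plus-sign scores below a square of the same area
  sq <- matrix(0L, 80, 80); sq[30:49, 30:49] <- 1L          # 400 px
  plus <- matrix(0L, 80, 80)
  plus[35:44, 15:54] <- 1L; plus[15:54, 35:44] <- 1L        # 700 px
  sq2 <- matrix(0L, 80, 80); sq2[27:53, 27:52] <- 1L        # ~700 px
  expect_lt(colony_circularity(plus, 1), colony_circularity(sq2, 1))

  # increasingly star-shaped perturbations of a disc at fixed area: strictly
  # decreasing circularity
  g <- coord_grid_t(160, 160)
  ang <- atan2(g$c - 80, g$r - 80)
  d <- sqrt((g$r - 80)^2 + (g$c - 80)^2)
  vals <- vapply(c(0, 3, 6, 9), function(amp) {
    r_eff <- 40 + amp * cos(8 * ang)
    m <- matrix(0L, 160, 160); m[d <= r_eff] <- 1L
    colony_circularity(m, 1)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("entropy matches closed forms exactly", {
  mask <- matrix(1L, 16, 16)
  expect_equal(colony_entropy(matrix(0.37, 16, 16), mask, 1), 0)

  two <- matrix(c(0.3, 0.7), 16, 16)  # two equally frequent levels
  expect_equal(colony_entropy(two, mask, 1), log(2), tolerance = 1e-12)

  all256 <- matrix((0:255) / 255, 16, 16)  # every 8-bit level once
  expect_equal(colony_entropy(all256, mask, 1, n_levels = 256), log(256),
               tolerance = 1e-12)

  # permutation invariance: entropy depends only on the histogram
  set.seed(8)
  vals <- sample(c(0.1, 0.4, 0.8), 256, TRUE, prob = c(0.5, 0.3, 0.2))
  a <- matrix(vals, 16, 16)
  b <- matrix(sample(vals), 16, 16)
  expect_equal(colony_entropy(a, mask, 1), colony_entropy(b, mask, 1))

  expect_error(colony_entropy(two, mask, 1, n_levels = 1), "n_levels")
})

test_that("displacement statistics match closed forms", {
  mask <- disc_mask(32, 32, 16, 16, 10)
  u <- array(0, c(32, 32, 2)); u[, , 1] <- 3; u[, , 2] <- 4
  expect_equal(displacement_stats(u, mask, 1), c(mean = 5, sd = 0))

  expect_equal(displacement_stats(array(0, c(32, 32, 2)), mask, 1),
               c(mean = 0, sd = 0))

  # half the colony at norm 2, half at norm 4 -> mean 3, population sd 1
  m2 <- matrix(0L, 10, 10); m2[1:10, 1:4] <- 1L; m2[1:10, 5:8] <- 1L
  u2 <- array(0, c(10, 10, 2))
  u2[, 1:4, 1] <- 2; u2[, 5:8, 1] <- 4
  expect_equal(displacement_stats(u2, m2, 1), c(mean = 3, sd = 1))

  # mean scales linearly with the field
  set.seed(10)
  u3 <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  s1 <- displacement_stats(u3, mask, 1)
  s2 <- displacement_stats(u3 * 2.5, mask, 1)
  expect_equal(s2[["mean"]], 2.5 * s1[["mean"]])
  expect_equal(s2[["sd"]], 2.5 * s1[["sd"]])
})

test_that("measure_sequence produces one record per colony per frame", {
  mask <- matrix(0L, 40, 40)
  mask[5:14, 5:14] <- 1L; mask[25:34, 25:34] <- 2L
  frames <- replicate(5, matrix(0.5, 40, 40), simplify = FALSE)
  masks <- replicate(5, mask, simplify = FALSE)
  fields <- replicate(4, array(1, c(40, 40, 2)), simplify = FALSE)
  rec <- measure_sequence(frames, masks, fields)
  expect_equal(nrow(rec), 10)
  expect_equal(sum(!is.na(rec$mean_displacement)), 8)  # none on final frame
  expect_true(all(is.na(rec$mean_displacement[rec$frame == 4])))
  expect_equal(attr(rec, "frame_px"), 1600)

  # colony absent in one frame: no record there
  masks[[3]][masks[[3]] == 2L] <- 0L
  rec2 <- measure_sequence(frames, masks, fields)
  expect_equal(nrow(rec2), 9)
  expect_false(any(rec2$frame == 2 & rec2$colony_id == 2))

  # empty mask frame contributes no records
  masks[[3]][] <- 0L
  rec3 <- measure_sequence(frames, masks, fields)
  expect_equal(sum(rec3$frame == 2), 0)

  expect_error(measure_sequence(frames, masks[1:3], fields), "masks")
})

test_that("summarize_frames uses linear-interpolation quantiles", {
  rec <- tibble::tibble(frame = c(0L, 0L, 0L, 0L, 1L),
                        colony_id = c(1:4, 1L),
                        circularity = c(1, 2, 3, 4, 0.5))
  s <- summarize_frames(rec, "circularity")
  expect_equal(s$median[s$frame == 0], 2.5)
  expect_equal(s$q25[s$frame == 0], 1.75)
  expect_equal(s$q75[s$frame == 0], 3.25)
  expect_equal(s$n_colonies, c(4L, 1L))
  # single colony: median = q25 = q75
  expect_equal(s$median[s$frame == 1], 0.5)
  expect_equal(s$q25[s$frame == 1], 0.5)
  expect_equal(s$q75[s$frame == 1], 0.5)
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))

  expect_error(summarize_frames(rec, "sphericity"), "unknown feature")
})

test_that("condition comparison: symmetric null, separated pools, tiny pools", {
  recs <- function(x) tibble::tibble(frame = 0L, colony_id = seq_along(x),
                                     circularity = x)
  same <- compare_conditions(recs(1:20), recs(1:20), "circularity")
  expect_gt(same$p_value, 0.9)

  sep <- compare_conditions(recs(1:20), recs(101:120), "circularity")
  expect_lt(sep$p_value, 1e-6)

  tiny <- compare_conditions(recs(5), recs(7), "circularity")
  expect_equal(tiny$p_value, 1)

  expect_error(compare_conditions(recs(numeric(0)), recs(1), "circularity"),
               "empty")
})

test_that("rank-sum p-values agree with exact enumeration for small pools", {
  # independent oracle: enumerate all assignments of the pooled values
  exact_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    idx <- utils::combn(length(pooled), n)
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    ws <- apply(idx, 2, function(i) sum(rank(pooled)[i]) - n * (n + 1) / 2)
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  set.seed(99)
  for (trial in 1:6) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- round(runif(nx, 0, 100), 3); y <- round(runif(ny, 20, 120), 3)
    if (any(duplicated(c(x, y)))) next
    got <- compare_conditions(
      tibble::tibble(circularity = x), tibble::tibble(circularity = y),
      "circularity")$p_value
    expect_equal(got, exact_p(x, y), tolerance = 1e-10,
                 info = sprintf("trial %d (n=%d,m=%d)", trial, nx, ny))
  }
})
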