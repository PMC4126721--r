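test_that("foreground statistics match their definition on a tiny image", {
  img <- matrix(c(0, 0, 9, 11), 2, 2)
  cu <- foreground_stats_curve(img)
  row5 <- cu[cu$threshold == 5, ]
  expect_equal(row5$fg_count, 2)
  expect_equal(row5$fg_mean, 10)
  expect_equal(row5$fg_std, 1)          # population sd of {9, 11}
  expect_equal(cu$fg_count[cu$threshold == 1], sum(img >= 1))
  expect_error(foreground_stats_curve(matrix(7, 3, 3)), "degenerate")
})

test_that("foreground curve equals per-threshold brute force on random images", {
  for (seed in c(11, 12)) {
    img <- rand_img(seed)
    expect_equal(foreground_stats_curve(img), bf_fg_curve(img),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("between-class score follows the printed formula", {
  img <- matrix(c(0, 2, 9, 11), 2, 2)
  # classes {0,2} (mu 1, sd 1) and {9,11} (mu 10, sd 1)
  expect_equal(jt_score(img, 5), 2 * 2 * 81 / 2)
  # defined scores are non-negative everywhere
  jr <- vapply(1:255, function(t) jt_score(rand_img(3), t), numeric(1))
  expect_true(all(jr[!is.na(jr)] >= 0))
  # empty class is undefined
  expect_true(is.na(jt_score(img, 200)))
})

test_that("score values match brute force at every threshold", {
  for (seed in c(21, 22)) {
    img <- rand_img(seed)
    mine <- vapply(1:255, function(t) jt_score(img, t), numeric(1))
    ref <- vapply(1:255, function(t) bf_jt(img, t), numeric(1))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("score is invariant under a constant intensity shift", {
  img <- rand_img(31, lo = 0, hi = 200)
  for (t in c(40, 120, 199))
    expect_equal(jt_score(img, t), jt_score(img + 30, t + 30),
                 tolerance = 1e-9)
})

test_that("threshold selection separates a planted bimodal image", {
  sc <- generate_gj_image(gj_scene_spec(seed = 13, lateral_fraction = 0))
  g <- sc$image$green
  sel <- select_threshold(g)
  planted <- sc$truth$labels > 0
  recovered <- g >= sel$optimal_threshold
  # recovered foreground agrees with the planted mask up to noise margin
  expect_lt(sum(xor(planted, recovered)) / sum(planted), 0.01)
  expect_gt(sel$r_optimal, -3)
  expect_lt(sel$r_optimal, 3)
  expect_true(sel$optimal_threshold %in% 1:255)
})

test_that("degenerate r grids and two-valued images behave as specified", {
  img <- rand_img(41)
  sel0 <- select_threshold(img, r_grid = 0)
  expect_equal(sel0$optimal_threshold, round(sel0$mu_fg))
  # exactly two-valued image: threshold falls strictly between the values
  two <- matrix(rep(c(50, 200), each = 32), 8, 8)
  sel2 <- select_threshold(two)
  expect_gt(sel2$optimal_threshold, 50)
  expect_lte(sel2$optimal_threshold, 200)
  expect_true(all(two[two >= sel2$optimal_threshold] == 200))
})

test_that("a fixed cohort R overrides the per-image search", {
  img <- rand_img(43)
  sel <- select_threshold(img, fixed_r = -1.18)
  expect_equal(sel$r_optimal, -1.18)
  expect_equal(sel$optimal_threshold,
               min(max(round(sel$mu_fg - 1.18 * sel$sigma_fg), 1), 255))
})

test_that("segmented foreground intensity matches filtering and is monotone", {
  img <- matrix(c(0, 100, 200, 30), 2, 2)
  seg <- segment_foreground(img, 150)
  expect_equal(seg$n_pixels, 1)
  expect_equal(seg$integrated_intensity, 200)
  expect_equal(segment_foreground(img, 0)$integrated_intensity, sum(img))
  r <- rand_img(44)
  ints <- vapply(seq(0, 255, by = 5), function(t)
    segment_foreground(r, t)$integrated_intensity, numeric(1))
  expect_true(all(diff(ints) <= 0))
  expect_equal(segment_foreground(r, 77)$integrated_intensity,
               sum(r[r >= 77]))
})
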