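test_that("disk dilation matches the Euclidean disk on simple geometries", {
  m <- matrix(FALSE, 11, 11); m[6, 6] <- TRUE
  expect_equal(sum(dilate_mask(m, 1)), 5)    # center + 4-neighbours
  expect_equal(sum(dilate_mask(m, 2)), 13)   # offsets with dx^2+dy^2 <= 4
  corner <- matrix(FALSE, 8, 8); corner[1, 1] <- TRUE
  expect_equal(sum(dilate_mask(corner, 1)), 3)  # border clips the disk
  expect_identical(dilate_mask(m, 0), m)
  expect_error(dilate_mask(m, -1), "non-negative")
})

test_that("dilation equals all-pairs brute force on random masks", {
  for (seed in c(51, 52, 53)) {
    m <- rand_mask(seed, 24, 28)
    for (r in c(1, 3, 7))
      expect_identical(dilate_mask(m, r), bf_dilate(m, r))
  }
})

test_that("dilated coverage is monotone in radius", {
  m <- rand_mask(61, 20, 20)
  prev <- dilate_mask(m, 0)
  for (r in 1:8) {
    cur <- dilate_mask(m, r)
    expect_true(all(cur[prev]))          # r1 <= r2 implies containment
    prev <- cur
  }
})

test_that("pixel-by-pixel colocalization splits intensity by mask overlap", {
  cx <- matrix(FALSE, 10, 10); cx[5, 5] <- TRUE
  img <- matrix(0, 10, 10); img[5, 5] <- 100
  nc <- matrix(FALSE, 10, 10); nc[5, 5] <- TRUE
  r <- pixelwise_colocalization(cx, nc, img)
  expect_equal(r$ee_intensity, 100); expect_equal(r$ss_intensity, 0)
  r2 <- pixelwise_colocalization(cx, matrix(FALSE, 10, 10), img)
  expect_equal(r2$ee_intensity, 0); expect_equal(r2$ss_intensity, 100)
  expect_error(classify_cx43(cx, img, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("classification against a dilated mask follows distance", {
  img <- matrix(0, 12, 12)
  nc <- matrix(FALSE, 12, 12); nc[5, 5] <- TRUE
  cx <- matrix(FALSE, 12, 12)
  cx[5, 6] <- TRUE; img[5, 6] <- 100     # distance 1
  r1 <- classify_cx43(cx, img, dilate_mask(nc, 1))
  expect_equal(r1$ee_intensity, 100)
  cx2 <- matrix(FALSE, 12, 12); cx2[5, 9] <- TRUE
  img2 <- matrix(0, 12, 12); img2[5, 9] <- 100   # distance 4
  expect_equal(classify_cx43(cx2, img2, dilate_mask(nc, 1))$ss_intensity, 100)
  expect_equal(classify_cx43(cx2, img2, dilate_mask(nc, 4))$ee_intensity, 100)
})

test_that("radius-0 classification equals pixel-by-pixel colocalization", {
  for (seed in c(71, 72)) {
    img <- rand_img(seed, 24, 24)
    cxm <- img >= 150
    ncm <- rand_mask(seed + 100, 24, 24, p = 0.1)
    a <- classify_cx43(cxm, img, dilate_mask(ncm, 0))
    b <- pixelwise_colocalization(cxm, ncm, img)
    expect_identical(a, b)
  }
})

test_that("plateau detection applies the per-step rule", {
  curve <- c(0, 50, 90, 100, 100, 100, 100, 120, 150, 150, 150, 150)
  pl <- detect_plateaus(curve, tol = 0.01, window = 3)
  expect_equal(nrow(pl), 2)
  expect_equal(pl$level, c(100, 150))
  expect_equal(pl$start_radius, c(3, 8))
  # constant curve: one plateau spanning everything
  flat <- detect_plateaus(rep(42, 10))
  expect_equal(nrow(flat), 1)
  expect_equal(flat$level, 42)
  expect_equal(flat$n_points, 10)
  # strictly steep curve: no plateau
  expect_equal(nrow(detect_plateaus(seq(0, 900, by = 100), tol = 0.01,
                                    window = 3)), 0)
  expect_error(detect_plateaus(curve, tol = 0), "positive")
  expect_error(detect_plateaus(c(5, 3, 1)), "non-decreasing")
})

test_that("the sweep conserves intensity and is monotone at every radius", {
  sc <- generate_gj_image(gj_scene_spec(seed = 81, lateral_fraction = 0.3,
                                        width = 96, height = 96,
                                        n_plaques = 2,
                                        cx43_pixels_per_plaque = 80))
  g <- sc$image$green
  cxm <- g >= select_threshold(g)$optimal_threshold
  ncm <- sc$truth$ncad_mask
  diag_r <- ceiling(sqrt(sum(dim(g)^2)))
  sw <- radius_sweep(g, cxm, ncm, max_radius = diag_r)
  expect_true(all(diff(sw$ee_intensity) >= 0))
  for (i in c(1, 10, 25, 51)) {
    r <- sw$radii[i]
    cls <- classify_cx43(cxm, g, dilate_mask(ncm, r))
    expect_identical(cls$ee_intensity + cls$ss_intensity, sw$total_cx43)
    expect_identical(cls$ee_intensity, sw$ee_intensity[i])
  }
  # at a radius past the image diagonal everything is covered
  expect_identical(sw$ee_intensity[length(sw$radii)], sw$total_cx43)
})

test_that("single- and two-plateau scenes recover the planted split", {
  one <- generate_gj_image(gj_scene_spec(seed = 91, lateral_fraction = 0))
  q1 <- quantify_image(one$image)
  expect_equal(nrow(q1$sweep$plateaus), 1)
  expect_lt(q1$cx43_ss / q1$cx43_total, 0.02)

  two <- generate_gj_image(gj_scene_spec(seed = 92, lateral_fraction = 0.3))
  q2 <- quantify_image(two$image)
  expect_gte(nrow(q2$sweep$plateaus), 2)
  expect_lt(abs(q2$cx43_ee - two$truth$id_intensity) /
              two$truth$id_intensity, 0.02)
  expect_lt(abs(q2$cx43_ss - two$truth$lateral_intensity) /
              two$truth$lateral_intensity, 0.02)
  expect_gte(q2$optimal_radius, 2)
  expect_lte(q2$optimal_radius, 5)
})

test_that("an empty N-Cad mask yields a flagged all side-by-side result", {
  img <- rand_img(95, 16, 16)
  cxm <- img >= 150
  expect_warning(
    sw <- radius_sweep(img, cxm, matrix(FALSE, 16, 16), max_radius = 5),
    "empty N-Cad")
  expect_equal(sw$cx43_ee, 0)
  expect_equal(sw$cx43_ss, sw$total_cx43)
  expect_equal(nrow(sw$plateaus), 0)
  expect_true("empty_ncad" %in% sw$flags)
})
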