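test_that("channel statistics are population moments over all pixels", {
  img <- rgb_fix(matrix(100, 4, 4), matrix(100, 4, 4), matrix(100, 4, 4))
  s <- channel_stats(img)
  expect_equal(s$mu_R, 100); expect_equal(s$sigma_R, 0)
  two <- rgb_fix(matrix(c(90, 110), 1, 2), matrix(c(90, 110), 1, 2),
                 matrix(c(90, 110), 1, 2))
  s2 <- channel_stats(two)
  expect_equal(s2$mu_G, 100); expect_equal(s2$sigma_G, 10)
  r <- rgb_image(rand_img(1, 10, 10), rand_img(2, 10, 10),
                 rand_img(3, 10, 10))
  s3 <- channel_stats(r)
  expect_equal(s3$mu_B, mean(r$blue))
  expect_equal(s3$sigma_B, pop_sd_oracle(as.numeric(r$blue)))
})

test_that("the worked pixel classifications follow the rule inequalities", {
  probes <- list(collagen = c(r = 90, g = 120, b = 150),
                 white = c(r = 200, g = 200, b = 200),
                 muscle = c(r = 150, g = 90, b = 100))
  img <- probe_image(probes)
  s <- channel_stats(img)
  expect_lt(abs(s$mu_G - 100), 0.5)      # stats sit at mu 100, sigma 20
  expect_lt(abs(s$sigma_G - 20), 0.5)
  cls <- classify_mt_pixels(img)
  # probe pixels occupy the first three positions (column-major)
  expect_true(cls$collagen[1]); expect_false(cls$muscle[1])
  expect_true(cls$white[2])
  expect_true(cls$muscle[3]); expect_false(cls$collagen[3])
})

test_that("class masks are pairwise disjoint and partition the image", {
  sc <- generate_mt_image(seed = 7)
  cls <- classify_mt_pixels(sc$image)
  tot <- cls$white + cls$muscle + cls$collagen + cls$unclassified
  expect_true(all(tot == 1))             # exact partition
  expect_error(classify_mt_pixels(
    rgb_fix(matrix(100, 4, 4), matrix(100, 4, 4), matrix(100, 4, 4))),
    "blank field")
})

test_that("collagen-and-muscle overlaps resolve to muscle", {
  rules <- mt_rules(muscle = c(b = 3, g = 3),        # muscle matches all
                    collagen = c(b = -3, r = 3, g_low = -3, g_high = 3))
  sc <- generate_mt_image(seed = 8, white_fraction = 0)
  cls <- classify_mt_pixels(sc$image, rules)
  expect_equal(sum(cls$collagen), 0)     # overlap removed from collagen
  expect_gt(sum(cls$muscle), 0)
  expect_error(mt_rules(collagen = c(b = 1, r = 1, g_low = 2, g_high = 1)),
               "g_low")
})

test_that("the collagen fraction uses tissue (non-white) pixels as denominator", {
  sc <- generate_mt_image(seed = 9, collagen_fraction = 0.1,
                          white_fraction = 0.25)
  cls <- classify_mt_pixels(sc$image)
  q <- ic_fraction(cls)
  expect_equal(q$n_tissue, q$n_total - q$n_white)
  expect_equal(q$ic_fraction, q$n_collagen / q$n_tissue)
  expect_gte(q$ic_fraction, 0); expect_lte(q$ic_fraction, 1)
  expect_equal(q$n_white + q$n_muscle + q$n_collagen + q$n_unclassified,
               q$n_total)
})

test_that("planted collagen fractions are recovered and respond monotonically", {
  prev <- -1
  for (f in c(0, 0.05, 0.15, 0.30)) {
    q <- quantify_collagen(generate_mt_image(collagen_fraction = f,
                                             seed = 101)$image)
    planted <- generate_mt_image(collagen_fraction = f,
                                 seed = 101)$truth$planted_ic
    expect_lt(abs(q$ic_fraction - planted), 0.02)
    expect_gt(q$ic_fraction, prev)       # monotone in planted fraction
    prev <- q$ic_fraction
  }
})

test_that("the fraction is invariant under tiling the image", {
  sc <- generate_mt_image(seed = 11)
  img <- sc$image
  tile <- function(m) rbind(cbind(m, m), cbind(m, m))
  big <- rgb_image(tile(img$red), tile(img$green), tile(img$blue))
  expect_equal(quantify_collagen(big)$ic_fraction,
               quantify_collagen(img)$ic_fraction)
})
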