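# Independent brute-force oracles and small fixture builders.  The
# oracles deliberately use naive per-threshold / all-pairs computation,
# independent of the histogram and distance-transform paths they check.

# random 8-bit test image
rand_img <- function(seed, nr = 32, nc = 32, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(sample(lo:hi, nr * nc, replace = TRUE), nr, nc)
}

pop_sd_oracle <- function(v) sqrt(mean((v - mean(v))^2))

# per-threshold foreground statistics by explicit filtering
bf_fg_curve <- function(img) {
  v <- as.numeric(img)
  do.call(rbind, lapply(1:255, function(t) {
    fg <- v[v >= t]
    data.frame(threshold = t, fg_count = length(fg),
               fg_mean = if (length(fg) >= 1) mean(fg) else NA_real_,
               fg_std = if (length(fg) >= 2) pop_sd_oracle(fg) else NA_real_)
  }))
}

# two-class score by explicit class statistics
bf_jt <- function(img, t) {
  v <- as.numeric(img)
  bg <- v[v < t]; fg <- v[v >= t]
  if (length(bg) == 0 || length(fg) == 0) return(NA_real_)
  den <- pop_sd_oracle(bg)^2 + pop_sd_oracle(fg)^2
  if (den == 0) return(NA_real_)
  length(bg) * length(fg) * (mean(bg) - mean(fg))^2 / den
}

# minimum squared Euclidean distance from every pixel to a TRUE pixel
bf_dist2 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(Inf, nr, nc))
  px <- as.matrix(expand.grid(x = 1:nr, y = 1:nc))
  d2 <- outer(px[, 1], idx[, 1], "-")^2 + outer(px[, 2], idx[, 2], "-")^2
  matrix(apply(d2, 1, min), nr, nc)
}

bf_dilate <- function(mask, radius) bf_dist2(mask) <= radius^2

# small aligned rgb fixture from three matrices
rgb_fix <- function(r, g, b = matrix(0, nrow(r), ncol(r))) rgb_image(r, g, b)

# sparse random mask
rand_mask <- function(seed, nr = 32, nc = 32, p = 0.03) {
  set.seed(seed)
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[1, 1] <- TRUE
  m
}

# Trichrome probe fixture: an image whose per-channel statistics are
# (almost exactly) mu = 100, sigma = 20 - a balanced 80/120 filler plus
# probe pixels (occupying the first positions, column-major) whose
# classification is under test.
probe_image <- function(probes) {
  n_fill <- 5000
  base <- rep(c(80, 120), n_fill / 2)
  mk <- function(ch) {
    v <- c(vapply(probes, `[[`, numeric(1), ch), base)
    matrix(c(v, rep(100, 6 - (length(v) %% 6))), nrow = 6)
  }
  rgb_image(mk("r"), mk("g"), mk("b"))
}
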