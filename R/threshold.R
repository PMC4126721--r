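## Per-image staining-threshold calibration.
##
## The positive-staining threshold for a fluorescence channel is selected
## in two stages: (1) an initial threshold at the maximum of the
## foreground standard-deviation curve, fixing the foreground statistics
## mu_fg and sigma_fg; (2) a refinement over candidate thresholds
## t(R) = round(mu_fg + R * sigma_fg), choosing the R that maximizes the
## Otsu-style between-class score
##   J_T = P1 * P2 * (mu1 - mu2)^2 / (sigma1^2 + sigma2^2)
## where P1, P2 are the background/foreground pixel counts and mu/sigma
## their class means and population standard deviations.

## Per-intensity histogram plus suffix sums; the basis of every
## threshold-curve computation.  Intensities are binned at integers 0..255.
.intensity_sums <- function(img) {
  v <- round(as.numeric(img))
  stopifnot(all(v >= 0 & v <= 255))
  cnt <- tabulate(v + 1L, nbins = 256L)     # cnt[i] = #pixels == i-1
  lev <- 0:255
  list(cnt = cnt, s1 = cnt * lev, s2 = cnt * lev^2, n = length(v))
}

.pop_sd <- function(n, s1, s2) {
  m <- s1 / n
  sqrt(pmax(s2 / n - m^2, 0))
}

#' Foreground statistics as a function of threshold
#'
#' For every candidate threshold `t` in 1..255 the foreground is the set
#' of pixels with intensity `>= t`.  Returns the foreground pixel count,
#' mean and population standard deviation per threshold; thresholds with
#' fewer than 2 foreground pixels are marked undefined (`NA`).
#'
#' @param img single-channel image (matrix, intensities 0-255).
#' @return data frame with columns `threshold`, `fg_count`, `fg_mean`,
#'   `fg_std`.
#' @export
foreground_stats_curve <- function(img) {
  is <- .intensity_sums(img)
  if (sum(is$cnt > 0) < 2)
    stop("degenerate image: all pixels share one intensity")
  # suffix sums over intensities >= t for t = 1..255
  sufN  <- rev(cumsum(rev(is$cnt)))[-1]
  sufS1 <- rev(cumsum(rev(is$s1)))[-1]
  sufS2 <- rev(cumsum(rev(is$s2)))[-1]
  fg_mean <- ifelse(sufN >= 1, sufS1 / sufN, NA_real_)
  fg_std  <- ifelse(sufN >= 2, .pop_sd(sufN, sufS1, sufS2), NA_real_)
  data.frame(threshold = 1:255, fg_count = sufN,
             fg_mean = fg_mean, fg_std = fg_std)
}

## J_T for all thresholds t = 1..255 at once.  Returns NA where a class is
## empty or where sigma1^2 + sigma2^2 == 0 (both classes constant); the
## latter case is a perfect separation and is recorded in the "perfect"
## attribute so select_threshold() can fall back on it.
.jt_table <- function(img) {
  is <- .intensity_sums(img)
  cumN  <- cumsum(is$cnt);  cumS1 <- cumsum(is$s1);  cumS2 <- cumsum(is$s2)
  # background: intensity < t  -> cum sums up to t-1; foreground: >= t
  bgN  <- cumN[1:255];  bgS1 <- cumS1[1:255];  bgS2 <- cumS2[1:255]
  fgN  <- is$n - bgN;   fgS1 <- sum(is$s1) - bgS1; fgS2 <- sum(is$s2) - bgS2
  ok   <- bgN > 0 & fgN > 0
  jt   <- rep(NA_real_, 255)
  perfect <- rep(FALSE, 255)
  mu1 <- bgS1 / bgN; mu2 <- fgS1 / fgN
  v1  <- pmax(bgS2 / bgN - mu1^2, 0); v2 <- pmax(fgS2 / fgN - mu2^2, 0)
  den <- v1 + v2
  calc <- ok & den > 0
  jt[calc] <- (bgN * fgN * (mu1 - mu2)^2 / den)[calc]
  perfect[ok & den == 0 & mu1 != mu2] <- TRUE
  attr(jt, "perfect") <- perfect
  jt
}

#' Otsu-style between-class threshold score
#'
#' Splits the image at threshold `t` into background (`< t`) and
#' foreground (`>= t`) classes and returns
#' `P1 * P2 * (mu1 - mu2)^2 / (sigma1^2 + sigma2^2)` with `P` the class
#' pixel counts and `mu`/`sigma` the class means and population standard
#' deviations.  Undefined cases (an empty class, or both class variances
#' zero with distinct means) return `NA`.
#'
#' @param img single-channel image.
#' @param t integer threshold in 1..255.
#' @return the score (numeric scalar), or `NA` where undefined.
#' @export
jt_score <- function(img, t) {
  stopifnot(length(t) == 1, t >= 1, t <= 255)
  .jt_table(img)[as.integer(round(t))]
}

#' Select the positive-staining threshold for a channel
#'
#' Two-stage per-image calibration: the initial threshold is the
#' candidate maximizing the foreground standard deviation (smallest
#' threshold on ties, thresholds whose foreground holds fewer than
#' `min_fg_count` pixels ignored); `mu_fg` and `sigma_fg` are the
#' foreground mean and standard deviation there.  Each candidate `R` in
#' `r_grid` maps to threshold `round(mu_fg + R * sigma_fg)` clamped to
#' `[1, 255]`; the `R` maximizing the defined between-class score
#' [jt_score()] wins (smallest `R` on ties).  Candidates where the score
#' is undefined are skipped; if no candidate has a finite score but some
#' achieve perfect separation (both classes constant, distinct means),
#' the smallest such `R` is used.
#'
#' @param img single-channel image.
#' @param r_grid ordered candidate `R` values (default -3 to 3, step 0.01).
#' @param min_fg_count smallest foreground size considered when locating
#'   the standard-deviation peak; guards against noise-dominated tails.
#' @param fixed_r optional fixed `R` overriding the search (cohort-level
#'   calibration); the score is still evaluated at that `R`.
#' @return a `threshold_selection` list: `initial_threshold`, `mu_fg`,
#'   `sigma_fg`, `r_grid`, `jt_values`, `r_optimal`, `optimal_threshold`,
#'   and the full `curve` from [foreground_stats_curve()].
#' @export
select_threshold <- function(img, r_grid = seq(-3, 3, by = 0.01),
                             min_fg_count = 10, fixed_r = NULL) {
  if (length(r_grid) < 1) stop("r_grid must be nonempty")
  curve <- foreground_stats_curve(img)   # errors on degenerate images
  eligible <- !is.na(curve$fg_std) &
    curve$fg_count >= max(2, min_fg_count)
  if (!any(eligible))
    stop("no threshold leaves at least ", max(2, min_fg_count),
         " foreground pixels; image too sparse for calibration")
  sd_peak <- which(eligible)[which.max(curve$fg_std[eligible])]
  initial_threshold <- curve$threshold[sd_peak]
  mu_fg <- curve$fg_mean[sd_peak]
  sigma_fg <- curve$fg_std[sd_peak]

  if (!is.null(fixed_r)) r_grid <- fixed_r
  cand_t <- pmin(pmax(round(mu_fg + r_grid * sigma_fg), 1), 255)
  jt_all <- .jt_table(img)
  perfect <- attr(jt_all, "perfect")
  jt_values <- jt_all[cand_t]
  if (any(!is.na(jt_values))) {
    best <- which.max(jt_values)          # first (smallest R) on ties
  } else if (any(perfect[cand_t])) {
    best <- which(perfect[cand_t])[1]
    jt_values[best] <- Inf                # perfect separation
  } else {
    stop("no candidate R yields a defined between-class score; ",
         "the image may lack bimodal foreground/background structure")
  }
  structure(list(initial_threshold = initial_threshold,
                 mu_fg = mu_fg, sigma_fg = sigma_fg,
                 r_grid = r_grid, jt_values = jt_values,
                 r_optimal = r_grid[best],
                 optimal_threshold = cand_t[best],
                 curve = curve),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf(paste0("<threshold_selection: initial t=%d, mu_fg=%.2f, ",
                     "sigma_fg=%.2f, R*=%.2f, optimal t=%d>\n"),
              x$initial_threshold, x$mu_fg, x$sigma_fg, x$r_optimal,
              x$optimal_threshold), ...)
  invisible(x)
}

#' Foreground mask and integrated intensity at a threshold
#'
#' @param img single-channel image.
#' @param t threshold in `[0, 255]`; foreground is intensity `>= t`.
#' @return list with `mask` (logical matrix), `integrated_intensity`
#'   (sum of intensities over the mask) and `n_pixels`.
#' @export
segment_foreground <- function(img, t) {
  stopifnot(length(t) == 1, t >= 0, t <= 255)
  m <- matrix(as.numeric(img) >= t, nrow(as.matrix(img)))
  list(mask = m,
       integrated_intensity = sum(as.numeric(img)[m]),
       n_pixels = sum(m))
}
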