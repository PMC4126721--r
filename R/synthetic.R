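## Synthetic confocal and trichrome scenes with exact ground truth.
##
## The gap-junction generator emulates double-immunostained myocyte
## fields: elongated N-Cad plaques (intercalated discs), Cx43 clusters
## either on or within a few pixels of a plaque ("stellate",
## intercalated-disc associated) or planted far from every plaque
## (lateralized), plus nuclei in the blue channel.  Foreground and
## background intensities are Gaussian draws clipped to [0, 255]
## (8-bit); a per-image multiplicative gain emulates staining-efficiency
## variation.  Ground truth records the rendered intensity sums over the
## planted pixel sets exactly.

#' Specification of a synthetic gap-junction scene
#'
#' Defaults place 6 elongated N-Cad plaques in a 192x192 field, attach
#' intercalated-disc associated Cx43 within `stellate_offset_max` = 3 px
#' of a plaque, and plant the lateralized share of Cx43
#' (`lateral_fraction`) in a distance band starting `min_separation` =
#' 25 px from every plaque pixel.  Intensity distributions (foreground
#' mean 200, sd 8; background mean 15, sd 6; a few percent of the field
#' positive) give clean bimodal channels whose between-class score
#' optimum sits in the inter-mode valley, so the per-image calibration
#' separates planted foreground from background essentially exactly.
#'
#' @param width,height image size in pixels.
#' @param n_plaques number of N-Cad plaques.
#' @param plaque_length,plaque_width plaque geometry in pixels (an
#'   elongated cluster of roughly `length x width`).
#' @param cx43_pixels_per_plaque Cx43 pixels planted per plaque (split
#'   between the ID-associated and lateral pools by `lateral_fraction`).
#' @param stellate_offset_max largest Euclidean distance (px) of an
#'   ID-associated Cx43 pixel from the nearest N-Cad pixel.
#' @param lateral_fraction share (0-1) of planted Cx43 pixels placed in
#'   the lateral pool.
#' @param min_separation smallest distance (px) of lateral Cx43 from any
#'   N-Cad pixel; must exceed `stellate_offset_max`.
#' @param lateral_band width (px) of the lateral planting band:
#'   lateral pixels lie at distances `[min_separation,
#'   min_separation + lateral_band]`.
#' @param fg_mean,fg_sd,bg_mean,bg_sd foreground/background intensity
#'   distributions (8-bit units).
#' @param nuclei_mean,nuclei_sd,n_nuclei,nuclei_radius blue-channel
#'   nuclei parameters.
#' @param gain per-image multiplicative staining-efficiency factor
#'   applied to all channels (values re-clipped to `[0, 255]`).
#' @param drift per-layer plaque translation `c(dx, dy)` in px/layer for
#'   Z-stacks ([generate_gj_zstack()]).  The default (14 px/layer)
#'   exceeds the plaque cross-section plus `stellate_offset_max` plus
#'   the plateau detection window with margin for rasterization, so
#'   Cx43 anchored to the first layer's plaques is unambiguously
#'   non-junctional in later layers.
#' @param seed integer fixing all randomness.
#' @return a `gj_scene_spec` list.
#' @export
gj_scene_spec <- function(width = 192, height = 192, n_plaques = 6,
                          plaque_length = 20, plaque_width = 5,
                          cx43_pixels_per_plaque = 150,
                          stellate_offset_max = 3,
                          lateral_fraction = 0.2, min_separation = 25,
                          lateral_band = 6,
                          fg_mean = 200, fg_sd = 8,
                          bg_mean = 15, bg_sd = 6,
                          nuclei_mean = 120, nuclei_sd = 20,
                          n_nuclei = 6, nuclei_radius = 5,
                          gain = 1, drift = c(14, 0), seed = 1) {
  stopifnot(width >= 16, height >= 16, n_plaques >= 1,
            stellate_offset_max >= 0, lateral_band >= 1, gain > 0,
            length(drift) == 2)
  if (lateral_fraction < 0 || lateral_fraction > 1)
    stop("lateral_fraction must lie in [0, 1]")
  if (stellate_offset_max >= min_separation)
    stop("stellate_offset_max must be smaller than min_separation")
  structure(as.list(environment()), class = "gj_scene_spec")
}

## Rasterize one thick line segment (plaque) into TRUE pixels.
.rasterize_plaque <- function(cx, cy, angle, len, width, nr, nc) {
  half <- len / 2
  ts <- seq(-half, half, by = 0.25)
  ws <- seq(-(width - 1) / 2, (width - 1) / 2, by = 0.25)
  pts <- expand.grid(t = ts, w = ws)
  x <- round(cx + pts$t * cos(angle) - pts$w * sin(angle))
  y <- round(cy + pts$t * sin(angle) + pts$w * cos(angle))
  keep <- x >= 1 & x <= nr & y >= 1 & y <= nc
  unique(cbind(x[keep], y[keep]))
}

.clip8 <- function(x) pmin(pmax(round(x), 0), 255)

## Draw clipped-Gaussian intensities onto chosen pixels of a matrix.
.paint <- function(mat, idx, mean, sd) {
  mat[idx] <- .clip8(rnorm(length(idx), mean, sd))
  mat
}

## Place plaques and return the N-Cad mask plus plaque parameters.
.place_plaques <- function(spec, shift = c(0, 0)) {
  nr <- spec$height; nc <- spec$width
  margin <- ceiling(spec$plaque_length / 2) + 2
  if (nr <= 2 * margin || nc <= 2 * margin)
    stop("infeasible geometry: plaques cannot fit in the image")
  mask <- matrix(FALSE, nr, nc)
  for (k in seq_len(spec$n_plaques)) {
    px <- .rasterize_plaque(spec$plaque_centers[k, 1] + shift[1],
                            spec$plaque_centers[k, 2] + shift[2],
                            spec$plaque_angles[k], spec$plaque_length,
                            spec$plaque_width, nr, nc)
    if (nrow(px) == 0)
      stop("drift pushed a plaque fully out of frame")
    mask[px] <- TRUE
  }
  mask
}

## Sample plaque geometry into the spec (deterministic given the RNG
## state).  total_shift reserves room so that drifted plaques stay in
## frame across every layer of a stack.
.draw_geometry <- function(spec, total_shift = c(0, 0)) {
  nr <- spec$height; nc <- spec$width
  margin <- ceiling(spec$plaque_length / 2) + 2
  x_lo <- margin - min(0, total_shift[1]); x_hi <- nr - margin - max(0, total_shift[1])
  y_lo <- margin - min(0, total_shift[2]); y_hi <- nc - margin - max(0, total_shift[2])
  if (x_lo >= x_hi || y_lo >= y_hi)
    stop("infeasible geometry: plaques cannot fit in the image ",
         "(drift pushes plaques fully out of frame)")
  spec$plaque_centers <- cbind(
    sample(seq(x_lo, x_hi), spec$n_plaques, replace = TRUE),
    sample(seq(y_lo, y_hi), spec$n_plaques, replace = TRUE))
  spec$plaque_angles <- runif(spec$n_plaques, 0, pi)
  spec
}

## Choose Cx43 pixel positions for a given N-Cad mask.  Returns linear
## indices for the ID-associated and lateral pools.
.plant_cx43 <- function(spec, d2, lateral_d2 = d2) {
  n_total <- spec$cx43_pixels_per_plaque * spec$n_plaques
  n_lat <- round(n_total * spec$lateral_fraction)
  n_id <- n_total - n_lat
  id_cand <- which(d2 <= spec$stellate_offset_max^2)
  lat_cand <- which(lateral_d2 >= spec$min_separation^2 &
                    lateral_d2 <= (spec$min_separation + spec$lateral_band)^2)
  if (length(id_cand) < n_id || length(lat_cand) < n_lat)
    stop("infeasible geometry: not enough room to plant Cx43 pixels")
  list(id = if (n_id > 0) sample(id_cand, n_id) else integer(0),
       lateral = if (n_lat > 0) sample(lat_cand, n_lat) else integer(0))
}

## Nuclei blobs (blue channel); returns linear indices.
.plant_nuclei <- function(spec) {
  nr <- spec$height; nc <- spec$width
  idx <- integer(0)
  if (spec$n_nuclei == 0) return(idx)
  cx <- sample(seq_len(nr), spec$n_nuclei, replace = TRUE)
  cy <- sample(seq_len(nc), spec$n_nuclei, replace = TRUE)
  r2 <- spec$nuclei_radius^2
  for (k in seq_len(spec$n_nuclei)) {
    xs <- max(1, cx[k] - spec$nuclei_radius):min(nr, cx[k] + spec$nuclei_radius)
    ys <- max(1, cy[k] - spec$nuclei_radius):min(nc, cy[k] + spec$nuclei_radius)
    g <- expand.grid(x = xs, y = ys)
    keep <- (g$x - cx[k])^2 + (g$y - cy[k])^2 <= r2
    idx <- c(idx, g$x[keep] + (g$y[keep] - 1L) * nr)
  }
  unique(idx)
}

## Render one layer given fixed geometry; intensities are fresh draws.
.render_layer <- function(spec, ncad_mask, cx43_idx, nuclei_idx) {
  nr <- spec$height; nc <- spec$width
  bg <- function() matrix(.clip8(rnorm(nr * nc, spec$bg_mean, spec$bg_sd)),
                          nr, nc)
  red <- bg(); green <- bg(); blue <- bg()
  red <- .paint(red, which(ncad_mask), spec$fg_mean, spec$fg_sd)
  green <- .paint(green, c(cx43_idx$id, cx43_idx$lateral),
                  spec$fg_mean, spec$fg_sd)
  blue <- .paint(blue, nuclei_idx, spec$nuclei_mean, spec$nuclei_sd)
  if (spec$gain != 1) {
    red <- .clip8(red * spec$gain)
    green <- .clip8(green * spec$gain)
    blue <- .clip8(blue * spec$gain)
  }
  img <- rgb_image(red, green, blue)
  labels <- matrix(0L, nr, nc)
  labels[cx43_idx$id] <- 1L
  labels[cx43_idx$lateral] <- 2L
  truth <- list(id_intensity = sum(green[cx43_idx$id]),
                lateral_intensity = sum(green[cx43_idx$lateral]),
                total_cx43 = sum(green[c(cx43_idx$id, cx43_idx$lateral)]),
                ncad_intensity = sum(red[ncad_mask]),
                n_id_pixels = length(cx43_idx$id),
                n_lateral_pixels = length(cx43_idx$lateral),
                labels = labels, ncad_mask = ncad_mask)
  list(image = img, truth = truth)
}

#' Generate a synthetic Cx43/N-Cad scene with ground truth
#'
#' Deterministic for a fixed spec (the seed fixes all randomness).
#' Ground-truth intensity sums are computed from the rendered pixel
#' values over the planted label sets, so they match the image exactly.
#'
#' @param spec a [gj_scene_spec()].
#' @return list with `image` (an [rgb_image()]) and `truth` (planted
#'   ID-associated / lateral / total Cx43 and N-Cad intensity sums, pixel
#'   counts, a label matrix where 1 = ID-associated Cx43, 2 = lateral
#'   Cx43, and the planted N-Cad mask).
#' @export
generate_gj_image <- function(spec = gj_scene_spec()) {
  stopifnot(inherits(spec, "gj_scene_spec"))
  set.seed(spec$seed)
  spec <- .draw_geometry(spec)
  ncad_mask <- .place_plaques(spec)
  d2 <- .dist2_to_mask(ncad_mask)
  cx43_idx <- .plant_cx43(spec, d2)
  nuclei_idx <- .plant_nuclei(spec)
  out <- .render_layer(spec, ncad_mask, cx43_idx, nuclei_idx)
  out$spec <- spec
  out
}


## Geometry for drifting stacks.  Intercalated-disc plaques lie
## perpendicular to the fiber axis, and the focal-plane drift runs along
## the fibers, so plaque long axes are drawn perpendicular to the drift
## vector (small angular jitter).  Drift paths of distinct plaques are
## laid out on a jittered slot grid with a guaranteed gap, so that Cx43
## anchored to one plaque is never grazed by another plaque in a later
## layer.
.draw_stack_geometry <- function(spec, total_shift, min_gap = 8) {
  nr <- spec$height; nc <- spec$width
  h <- sqrt((spec$plaque_length / 2)^2 + (spec$plaque_width / 2)^2) + 2
  ext_x <- 2 * h + abs(total_shift[1])   # swept bounding box extents
  ext_y <- 2 * h + abs(total_shift[2])
  x_lo <- h - min(0, total_shift[1]); x_hi <- nr - h - max(0, total_shift[1])
  y_lo <- h - min(0, total_shift[2]); y_hi <- nc - h - max(0, total_shift[2])
  xs <- seq(x_lo, x_hi, by = ext_x + min_gap)
  ys <- seq(y_lo, y_hi, by = ext_y + min_gap)
  slots <- expand.grid(x = xs, y = ys)
  if (nrow(slots) < spec$n_plaques)
    stop("infeasible geometry: cannot place ", spec$n_plaques,
         " non-overlapping plaque drift paths; reduce n_plaques or drift")
  pick <- sample(nrow(slots), spec$n_plaques)
  spec$plaque_centers <- round(cbind(slots$x[pick], slots$y[pick]) +
                                 matrix(runif(2 * spec$n_plaques, -2, 2),
                                        ncol = 2))
  drift_angle <- atan2(spec$drift[2], spec$drift[1])
  spec$plaque_angles <- drift_angle + pi / 2 +
    runif(spec$n_plaques, -0.05, 0.05)
  spec
}

#' Generate a synthetic drifting-plaque Z-stack with ground truth
#'
#' Emulates a confocal stack in which the in-plane position of the N-Cad
#' plaques shifts from layer to layer (changing fiber orientation across
#' focal planes) while the Cx43 signal is stationary: ID-associated Cx43
#' is planted against the first layer's plaques and keeps its position
#' in every layer, and lateral Cx43 is planted at
#' `>= min_separation` px from the plaque positions of *all* layers.
#' Intensities are redrawn per layer.  This geometry makes the
#' maximum-projection quantification overestimate end-to-end Cx43 and
#' underestimate side-by-side Cx43 relative to layer-by-layer
#' quantification: the projected N-Cad union covers the stationary Cx43
#' near the layer-1 plaques in every layer's worth of signal, while the
#' per-layer analysis sees that Cx43 drift away from the moving plaques.
#'
#' @param spec a [gj_scene_spec()]; `spec$drift` is the per-layer plaque
#'   translation in px.
#' @param n_layers number of layers (>= 2 for drift scenarios).
#' @return list with `stack` (a [zstack_series()]), `per_layer_truth`
#'   (list of per-layer ground truths) and `union_ncad_mask`.
#' @export
generate_gj_zstack <- function(spec = gj_scene_spec(), n_layers = 6) {
  stopifnot(inherits(spec, "gj_scene_spec"), n_layers >= 1)
  total_shift <- (n_layers - 1) * spec$drift
  if (any(abs(total_shift) >= c(spec$height, spec$width)))
    stop("drift pushes plaques fully out of frame")
  set.seed(spec$seed)
  spec <- .draw_stack_geometry(spec, total_shift)
  masks <- lapply(seq_len(n_layers) - 1, function(i)
    .place_plaques(spec, shift = i * spec$drift))
  union_mask <- Reduce(`|`, masks)
  d2_layer1 <- .dist2_to_mask(masks[[1]])
  d2_union <- .dist2_to_mask(union_mask)
  # ID Cx43 anchored to the first layer's plaques; lateral Cx43 clear of
  # every layer's plaques
  cx43_idx <- .plant_cx43(spec, d2_layer1, lateral_d2 = d2_union)
  nuclei_idx <- .plant_nuclei(spec)
  layers <- vector("list", n_layers)
  truths <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    out <- .render_layer(spec, masks[[i]], cx43_idx, nuclei_idx)
    layers[[i]] <- out$image
    truths[[i]] <- out$truth
  }
  list(stack = zstack_series(layers,
                             stack_id = sprintf("synthstack_seed%d", spec$seed)),
       per_layer_truth = truths, union_ncad_mask = union_mask,
       spec = spec)
}

#' Trichrome color palette for the synthetic generator
#'
#' Class mean colors (R, G, B) chosen so that, for typical compositions,
#' each planted class satisfies its own [mt_rules()] inequality and no
#' other: muscle is red-dominant with low green/blue, collagen
#' blue-dominant with low red and high-band green, white bright on all
#' channels.  An optional `hard_mode` shifts collagen toward muscle to
#' probe rule robustness.
#'
#' @param hard_mode logical; overlap the class colors.
#' @return 3x3 numeric matrix, rows muscle/collagen/white, columns R/G/B.
#' @export
mt_palette <- function(hard_mode = FALSE) {
  p <- rbind(muscle   = c(180,  80,  70),
             collagen = c( 90, 215, 225),
             white    = c(230, 215, 230))
  if (hard_mode) p["collagen", ] <- c(130, 160, 190)
  colnames(p) <- c("R", "G", "B")
  p
}

#' Generate a synthetic Masson's Trichrome image with ground truth
#'
#' Plants spatially contiguous blobs: white (unstained space) blobs over
#' a muscle background, then collagen blobs within the tissue.
#' `white_fraction` is the target share of all pixels; the collagen
#' fraction is the target share of *tissue* (non-white) pixels, matching
#' the interstitial-collagen definition.  Per-pixel colors are the class
#' palette color plus Gaussian noise, clipped to `[0, 255]`.
#' Deterministic per seed; the returned planted fractions are the
#' actually rendered pixel shares.
#'
#' @param width,height image size.
#' @param collagen_fraction target collagen share of tissue pixels.
#' @param white_fraction target white share of all pixels.
#' @param palette a [mt_palette()] matrix.
#' @param noise_sd per-channel Gaussian color noise (8-bit units).
#' @param blob_radius range of blob radii in px.
#' @param seed integer fixing all randomness.
#' @return list with `image` (an [rgb_image()]) and `truth` (`labels`
#'   matrix with 0 muscle / 1 collagen / 2 white, planted pixel counts
#'   and `planted_ic`, the planted collagen share of tissue).
#' @export
generate_mt_image <- function(width = 128, height = 128,
                              collagen_fraction = 0.15,
                              white_fraction = 0.2,
                              palette = mt_palette(), noise_sd = 6,
                              blob_radius = c(3, 7), seed = 1) {
  if (collagen_fraction < 0 || white_fraction < 0 ||
      collagen_fraction > 1 || white_fraction > 1 ||
      collagen_fraction + white_fraction > 1)
    stop("class fractions must be in [0, 1] and sum to at most 1")
  set.seed(seed)
  nr <- height; nc <- width; n <- nr * nc
  labels <- matrix(0L, nr, nc)          # 0 muscle, 1 collagen, 2 white

  plant_blobs <- function(labels, target_n, class_code, allowed_code) {
    guard <- 0
    while (sum(labels == class_code) < target_n && guard < 10000) {
      guard <- guard + 1
      r <- sample(seq(blob_radius[1], blob_radius[2]), 1)
      cx <- sample(seq_len(nr), 1); cy <- sample(seq_len(nc), 1)
      xs <- max(1, cx - r):min(nr, cx + r)
      ys <- max(1, cy - r):min(nc, cy + r)
      g <- expand.grid(x = xs, y = ys)
      keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
      idx <- g$x[keep] + (g$y[keep] - 1L) * nr
      idx <- idx[labels[idx] == allowed_code]
      need <- target_n - sum(labels == class_code)
      if (length(idx) > need) idx <- idx[seq_len(need)]
      labels[idx] <- class_code
    }
    labels
  }

  labels <- plant_blobs(labels, round(n * white_fraction), 2L, 0L)
  n_white <- sum(labels == 2L)
  labels <- plant_blobs(labels, round((n - n_white) * collagen_fraction),
                        1L, 0L)

  chans <- lapply(1:3, function(ch) {
    base <- matrix(palette["muscle", ch], nr, nc)
    base[labels == 1L] <- palette["collagen", ch]
    base[labels == 2L] <- palette["white", ch]
    matrix(.clip8(base + rnorm(n, 0, noise_sd)), nr, nc)
  })
  img <- rgb_image(chans[[1]], chans[[2]], chans[[3]])
  n_collagen <- sum(labels == 1L); n_white <- sum(labels == 2L)
  list(image = img,
       truth = list(labels = labels, n_collagen = n_collagen,
                    n_white = n_white, n_muscle = sum(labels == 0L),
                    planted_ic = n_collagen / (n - n_white)))
}
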