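## Interstitial-collagen quantification from Masson's Trichrome RGB
## images.  MT stains collagen blue, myoplasm red and nuclei dark; white
## space is unstained section artifact.  Pixels are classified by simple
## per-image rules on each channel's mean and population standard
## deviation, and the interstitial-collagen (IC) fraction is the share
## of collagen pixels among tissue (non-white) pixels.

#' Per-channel intensity statistics of an RGB image
#'
#' @param rgb an [rgb_image()].
#' @return list with `mu_R`, `sigma_R`, `mu_G`, `sigma_G`, `mu_B`,
#'   `sigma_B` (means and population standard deviations over all
#'   pixels).
#' @export
channel_stats <- function(rgb) {
  stopifnot(inherits(rgb, "rgb_image"))
  st <- function(ch) {
    v <- as.numeric(ch); n <- length(v)
    c(mu = mean(v), sigma = sqrt(max(sum(v^2) / n - mean(v)^2, 0)))
  }
  r <- st(rgb$red); g <- st(rgb$green); b <- st(rgb$blue)
  list(mu_R = r[["mu"]], sigma_R = r[["sigma"]],
       mu_G = g[["mu"]], sigma_G = g[["sigma"]],
       mu_B = b[["mu"]], sigma_B = b[["sigma"]])
}

#' Trichrome pixel-classification rule set
#'
#' Coefficients of sigma added to mu per channel in the three class
#' rules.  Defaults (strict inequalities, evaluated against the
#' per-image [channel_stats()]):
#' * white (unstained space): `I_G > mu_G + 0.9 sigma_G` and
#'   `I_R > mu_R + 0.9 sigma_R`;
#' * muscle/nuclei: `I_B < mu_B + 0.3 sigma_B` and
#'   `I_G < mu_G - 0.1 sigma_G`;
#' * collagen: `I_B > mu_B + 0.9 sigma_B`, `I_R < mu_R + 0.25 sigma_R`
#'   and `mu_G + 0.75 sigma_G < I_G < mu_G + 2 sigma_G`.
#'
#' The coefficients are overridable because stain batches vary.
#'
#' @param white,muscle,collagen named numeric coefficient vectors as in
#'   the defaults.
#' @return a `mt_rules` list.
#' @export
mt_rules <- function(white = c(g = 0.9, r = 0.9),
                     muscle = c(b = 0.3, g = -0.1),
                     collagen = c(b = 0.9, r = 0.25,
                                  g_low = 0.75, g_high = 2)) {
  stopifnot(all(c("g", "r") %in% names(white)),
            all(c("b", "g") %in% names(muscle)),
            all(c("b", "r", "g_low", "g_high") %in% names(collagen)))
  if (collagen[["g_low"]] >= collagen[["g_high"]])
    stop("collagen green band: g_low must be below g_high")
  structure(list(white = white, muscle = muscle, collagen = collagen),
            class = "mt_rules")
}

#' Classify Masson's Trichrome pixels
#'
#' Evaluates the [mt_rules()] inequalities per pixel against the image's
#' own channel statistics.  Precedence: white (open space) first; muscle
#' and collagen are evaluated on the remaining pixels; pixels satisfying
#' both the muscle and collagen rules are assigned muscle (removed from
#' collagen, avoiding IC overestimation); everything else is
#' unclassified tissue.  The class masks are pairwise disjoint and,
#' together with `unclassified`, partition the image.
#'
#' @param rgb an [rgb_image()].
#' @param rules a [mt_rules()].
#' @return an `mt_classification` list: logical masks `white`, `muscle`,
#'   `collagen`, `unclassified`, plus `stats`.
#' @export
classify_mt_pixels <- function(rgb, rules = mt_rules()) {
  stopifnot(inherits(rgb, "rgb_image"))
  s <- channel_stats(rgb)
  if (s$sigma_R == 0 && s$sigma_G == 0 && s$sigma_B == 0)
    stop("unstained or blank field: zero variance on every channel")
  R <- rgb$red; G <- rgb$green; B <- rgb$blue
  white <- G > s$mu_G + rules$white[["g"]] * s$sigma_G &
           R > s$mu_R + rules$white[["r"]] * s$sigma_R
  muscle0 <- B < s$mu_B + rules$muscle[["b"]] * s$sigma_B &
             G < s$mu_G + rules$muscle[["g"]] * s$sigma_G
  collagen0 <- B > s$mu_B + rules$collagen[["b"]] * s$sigma_B &
               R < s$mu_R + rules$collagen[["r"]] * s$sigma_R &
               G > s$mu_G + rules$collagen[["g_low"]] * s$sigma_G &
               G < s$mu_G + rules$collagen[["g_high"]] * s$sigma_G
  muscle <- muscle0 & !white
  collagen <- collagen0 & !muscle0 & !white
  unclassified <- !white & !muscle & !collagen
  structure(list(white = white, muscle = muscle, collagen = collagen,
                 unclassified = unclassified, stats = s),
            class = "mt_classification")
}

#' Interstitial-collagen fraction from class masks
#'
#' Tissue pixels are all non-white pixels (stained tissue plus
#' unclassified); the IC fraction is the collagen share of tissue.  An
#' all-white field leaves the fraction `NA` with flag `"no_tissue"`.
#'
#' @param masks an `mt_classification` from [classify_mt_pixels()].
#' @return a `collagen_quantification` list: `n_total`, `n_white`,
#'   `n_muscle`, `n_collagen`, `n_unclassified`, `n_tissue`,
#'   `ic_fraction`, `flags`.
#' @export
ic_fraction <- function(masks) {
  stopifnot(inherits(masks, "mt_classification"))
  n_total <- length(masks$white)
  n_white <- sum(masks$white)
  n_muscle <- sum(masks$muscle)
  n_collagen <- sum(masks$collagen)
  n_tissue <- n_total - n_white
  flags <- character(0)
  if (n_tissue == 0) {
    flags <- "no_tissue"
    frac <- NA_real_
  } else frac <- n_collagen / n_tissue
  structure(list(n_total = n_total, n_white = n_white,
                 n_muscle = n_muscle, n_collagen = n_collagen,
                 n_unclassified = sum(masks$unclassified),
                 n_tissue = n_tissue, ic_fraction = frac,
                 stats = masks$stats, flags = flags),
            class = "collagen_quantification")
}

#' Quantify interstitial collagen in one trichrome image
#'
#' Convenience wrapper: [classify_mt_pixels()] then [ic_fraction()].
#'
#' @param rgb an [rgb_image()].
#' @param rules a [mt_rules()].
#' @param image_id identifier carried into reports.
#' @return a `collagen_quantification`.
#' @export
quantify_collagen <- function(rgb, rules = mt_rules(),
                              image_id = "image") {
  out <- ic_fraction(classify_mt_pixels(rgb, rules))
  out$image_id <- image_id
  out
}

#' @export
print.collagen_quantification <- function(x, ...) {
  cat(sprintf(paste0("<collagen_quantification: %d px (%d white, ",
                     "%d muscle, %d collagen), IC fraction %s>\n"),
              x$n_total, x$n_white, x$n_muscle, x$n_collagen,
              format(round(x$ic_fraction, 4))))
  invisible(x)
}

#' @export
as.data.frame.collagen_quantification <- function(x, ...) {
  data.frame(image_id = if (is.null(x$image_id)) "image" else x$image_id,
             n_total = x$n_total, n_white = x$n_white,
             n_muscle = x$n_muscle, n_collagen = x$n_collagen,
             n_unclassified = x$n_unclassified, n_tissue = x$n_tissue,
             ic_fraction = x$ic_fraction,
             mu_R = x$stats$mu_R, sigma_R = x$stats$sigma_R,
             mu_G = x$stats$mu_G, sigma_G = x$stats$sigma_G,
             mu_B = x$stats$mu_B, sigma_B = x$stats$sigma_B,
             flags = paste(x$flags, collapse = "+"),
             stringsAsFactors = FALSE)
}
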