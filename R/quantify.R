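## Per-image gap-junction quantification: threshold both channels, run
## the DNCU radius sweep, and normalize Cx43 values to the co-stained
## N-Cad signal as an internal reference.  The ratio cancels
## multiplicative staining/sectioning artifacts that act on both
## channels, so sections of identical biology but different staining
## efficiency quantify comparably.

#' Normalize a Cx43 quantity to the N-Cad internal reference
#'
#' Plain ratio `cx43_value / ncad_total`.  Exactly invariant under a
#' joint multiplicative gain on both channels.
#'
#' @param cx43_value quantified Cx43 intensity (or count).
#' @param ncad_total integrated N-Cad intensity (or count); must be
#'   positive.
#' @return the normalized ratio.
#' @export
ncad_normalize <- function(cx43_value, ncad_total) {
  if (length(ncad_total) != 1 || is.na(ncad_total) || ncad_total <= 0)
    stop("no N-Cad signal; normalization undefined")
  cx43_value / ncad_total
}

#' Quantify one Cx43/N-Cad image
#'
#' Runs the full single-image pipeline: per-channel threshold selection
#' ([select_threshold()]), foreground segmentation, DNCU radius sweep
#' ([radius_sweep()]), and N-Cad normalization.  A degenerate channel
#' (constant, or without bimodal structure) flags the record rather than
#' failing: a degenerate Cx43 channel reports zero Cx43; a degenerate
#' N-Cad channel leaves the normalized fields `NA`.
#'
#' @param rgb an [rgb_image()].
#' @param cfg a [gj_config()].
#' @param image_id identifier carried into reports.
#' @return a `gj_quantification` list with raw and normalized Cx43
#'   totals and end-to-end / side-by-side pools, thresholds, selected
#'   `R` values, `optimal_radius`, the full sweep, and `flags`.
#' @export
quantify_image <- function(rgb, cfg = gj_config(), image_id = "image") {
  stopifnot(inherits(rgb, "rgb_image"))
  cx43_img <- rgb[[cfg$channel_map[["cx43"]]]]
  ncad_img <- rgb[[cfg$channel_map[["ncad"]]]]
  flags <- character(0)

  sel <- function(img) tryCatch(
    select_threshold(img, .r_grid(cfg), cfg$min_fg_count, cfg$fixed_r),
    error = function(e) e)
  sel_cx43 <- sel(cx43_img)
  sel_ncad <- sel(ncad_img)

  value_img <- function(img) {
    if (cfg$measure == "count") array(1, dim(img)) else as.matrix(img)
  }

  if (inherits(sel_ncad, "error")) {
    flags <- c(flags, "degenerate_ncad")
    ncad_total <- NA_real_; ncad_threshold <- NA_integer_
    ncad_r <- NA_real_
    ncad_mask <- matrix(FALSE, nrow(ncad_img), ncol(ncad_img))
  } else {
    ncad_threshold <- sel_ncad$optimal_threshold
    ncad_r <- sel_ncad$r_optimal
    seg <- segment_foreground(ncad_img, ncad_threshold)
    ncad_mask <- seg$mask
    ncad_total <- if (cfg$normalize_by == "count") seg$n_pixels else
      seg$integrated_intensity
  }

  if (inherits(sel_cx43, "error")) {
    flags <- c(flags, "degenerate_cx43")
    cx43_threshold <- NA_integer_; cx43_r <- NA_real_
    cx43_total <- 0; cx43_ee <- 0; cx43_ss <- 0
    optimal_radius <- NA_integer_; sweep <- NULL
  } else {
    cx43_threshold <- sel_cx43$optimal_threshold
    cx43_r <- sel_cx43$r_optimal
    cx43_mask <- segment_foreground(cx43_img, cx43_threshold)$mask
    sweep <- withCallingHandlers(
      radius_sweep(value_img(cx43_img), cx43_mask, ncad_mask,
                   cfg$max_radius, cfg$plateau_tol, cfg$plateau_window),
      warning = function(w) invokeRestart("muffleWarning"))
    flags <- c(flags, sweep$flags)
    cx43_total <- sweep$total_cx43
    cx43_ee <- sweep$cx43_ee
    cx43_ss <- sweep$cx43_ss
    optimal_radius <- sweep$optimal_radius
  }

  norm <- function(v) {
    if (is.na(ncad_total) || ncad_total <= 0) NA_real_ else v / ncad_total
  }
  if (!is.na(ncad_total) && ncad_total <= 0)
    flags <- c(flags, "zero_ncad")

  structure(list(image_id = image_id,
                 cx43_total = cx43_total, cx43_ee = cx43_ee,
                 cx43_ss = cx43_ss, ncad_total = ncad_total,
                 cx43_total_norm = norm(cx43_total),
                 cx43_ee_norm = norm(cx43_ee),
                 cx43_ss_norm = norm(cx43_ss),
                 cx43_threshold = cx43_threshold,
                 ncad_threshold = ncad_threshold,
                 cx43_r_optimal = cx43_r, ncad_r_optimal = ncad_r,
                 optimal_radius = optimal_radius,
                 sweep = sweep, flags = flags),
            class = "gj_quantification")
}

#' @export
print.gj_quantification <- function(x, ...) {
  cat(sprintf(paste0("<gj_quantification '%s': Cx43 total %.0f ",
                     "(E-E %.0f, S-S %.0f), N-Cad %.0f, ",
                     "E-E/N-Cad %.3f%s>\n"),
              x$image_id, x$cx43_total, x$cx43_ee, x$cx43_ss,
              x$ncad_total, x$cx43_ee_norm,
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = "+"))
              else ""))
  invisible(x)
}

#' @export
as.data.frame.gj_quantification <- function(x, ...) {
  data.frame(image_id = x$image_id,
             cx43_total = x$cx43_total, cx43_ee = x$cx43_ee,
             cx43_ss = x$cx43_ss, ncad_total = x$ncad_total,
             cx43_total_norm = x$cx43_total_norm,
             cx43_ee_norm = x$cx43_ee_norm,
             cx43_ss_norm = x$cx43_ss_norm,
             cx43_threshold = x$cx43_threshold,
             ncad_threshold = x$ncad_threshold,
             cx43_r_optimal = x$cx43_r_optimal,
             ncad_r_optimal = x$ncad_r_optimal,
             optimal_radius = x$optimal_radius,
             flags = paste(x$flags, collapse = "+"),
             stringsAsFactors = FALSE)
}
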