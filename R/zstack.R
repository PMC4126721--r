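## Layer-by-layer Z-stack quantification and its comparison with
## maximum-projection quantification.  Each layer is an independent
## image under the per-image threshold calibration; the layerwise
## aggregate sums raw values across layers and normalizes once by the
## summed N-Cad signal, which weights layers by signal content the same
## way a projection does.

#' Quantify a confocal Z-stack layer by layer and by maximum projection
#'
#' Every layer is quantified independently ([quantify_image()]: own
#' thresholds, own DNCU sweep).  Layers flagged degenerate (constant
#' channel, no plateau, or no N-Cad) are excluded from the aggregate with
#' a warning.  The aggregate follows `cfg$aggregate`: `"sum"` sums raw
#' per-layer values and divides once by the summed N-Cad; `"mean_norm"`
#' averages per-layer normalized values.  The maximum projection of the
#' same stack is quantified for comparison.
#'
#' @param stack a [zstack_series()].
#' @param cfg a [gj_config()].
#' @return a `stack_quantification` list: `per_layer` (list of
#'   `gj_quantification`), `layerwise` (aggregate raw sums and normalized
#'   values), `projection` (`gj_quantification` of the maximum
#'   projection), `n_layers_used`.
#' @export
quantify_stack <- function(stack, cfg = gj_config()) {
  stopifnot(inherits(stack, "zstack_series"))
  per_layer <- lapply(seq_along(stack$layers), function(i)
    quantify_image(stack$layers[[i]], cfg,
                   image_id = sprintf("%s_layer%02d", stack$stack_id, i)))

  usable <- vapply(per_layer, function(q) {
    length(q$flags) == 0 && !is.na(q$ncad_total) && q$ncad_total > 0 &&
      !is.na(q$cx43_ee)
  }, logical(1))
  if (any(!usable))
    warning(sprintf("stack '%s': %d layer(s) flagged and excluded from the aggregate: %s",
                    stack$stack_id, sum(!usable),
                    paste(vapply(per_layer[!usable], `[[`, "", "image_id"),
                          collapse = ", ")))
  used <- per_layer[usable]
  if (length(used) == 0) {
    layerwise <- list(cx43_total = NA_real_, cx43_ee = NA_real_,
                      cx43_ss = NA_real_, ncad_total = NA_real_,
                      cx43_total_norm = NA_real_, cx43_ee_norm = NA_real_,
                      cx43_ss_norm = NA_real_)
  } else {
    gsum <- function(f) sum(vapply(used, `[[`, numeric(1), f))
    if (cfg$aggregate == "sum") {
      nc <- gsum("ncad_total")
      layerwise <- list(cx43_total = gsum("cx43_total"),
                        cx43_ee = gsum("cx43_ee"),
                        cx43_ss = gsum("cx43_ss"),
                        ncad_total = nc,
                        cx43_total_norm = gsum("cx43_total") / nc,
                        cx43_ee_norm = gsum("cx43_ee") / nc,
                        cx43_ss_norm = gsum("cx43_ss") / nc)
    } else {
      gmean <- function(f) mean(vapply(used, `[[`, numeric(1), f))
      layerwise <- list(cx43_total = gsum("cx43_total"),
                        cx43_ee = gsum("cx43_ee"),
                        cx43_ss = gsum("cx43_ss"),
                        ncad_total = gsum("ncad_total"),
                        cx43_total_norm = gmean("cx43_total_norm"),
                        cx43_ee_norm = gmean("cx43_ee_norm"),
                        cx43_ss_norm = gmean("cx43_ss_norm"))
    }
  }

  projection <- quantify_image(max_projection(stack), cfg,
                               image_id = paste0(stack$stack_id, "_maxproj"))
  structure(list(stack_id = stack$stack_id, per_layer = per_layer,
                 layerwise = layerwise, projection = projection,
                 n_layers_used = length(used)),
            class = "stack_quantification")
}

#' @export
print.stack_quantification <- function(x, ...) {
  cat(sprintf(paste0("<stack_quantification '%s': %d/%d layers used; ",
                     "layerwise E-E/N-Cad %.3f vs projection %.3f>\n"),
              x$stack_id, x$n_layers_used, length(x$per_layer),
              x$layerwise$cx43_ee_norm, x$projection$cx43_ee_norm))
  invisible(x)
}

#' @export
as.data.frame.stack_quantification <- function(x, ...) {
  rows <- do.call(rbind, lapply(x$per_layer, as.data.frame))
  agg <- data.frame(image_id = paste0(x$stack_id, "_layerwise"),
                    cx43_total = x$layerwise$cx43_total,
                    cx43_ee = x$layerwise$cx43_ee,
                    cx43_ss = x$layerwise$cx43_ss,
                    ncad_total = x$layerwise$ncad_total,
                    cx43_total_norm = x$layerwise$cx43_total_norm,
                    cx43_ee_norm = x$layerwise$cx43_ee_norm,
                    cx43_ss_norm = x$layerwise$cx43_ss_norm,
                    cx43_threshold = NA_integer_,
                    ncad_threshold = NA_integer_,
                    cx43_r_optimal = NA_real_, ncad_r_optimal = NA_real_,
                    optimal_radius = NA_integer_, flags = "",
                    stringsAsFactors = FALSE)
  rbind(rows, agg, as.data.frame(x$projection))
}
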