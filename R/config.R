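## Run configuration: one flat list of all tunable analysis parameters,
## shared by the R API, batch runner and CLI.

#' Analysis configuration
#'
#' Collects every tunable parameter of the gap-junction pipeline with its
#' default.  Defaults: `R` searched on `[-3, 3]` in steps of 0.01;
#' dilation radii swept to 40 IPD; plateaus flagged where per-step rises
#' stay below 0.5% of the curve maximum for at least 3 consecutive steps.
#'
#' @param r_min,r_max,r_step grid of candidate `R` values for
#'   [select_threshold()].
#' @param min_fg_count foreground-size floor for the initial-threshold
#'   search.
#' @param fixed_r optional fixed `R` (cohort calibration) overriding the
#'   per-image search.
#' @param max_radius largest DNCU dilation radius (IPD).
#' @param plateau_tol,plateau_window plateau detection parameters, see
#'   [detect_plateaus()].
#' @param measure `"intensity"` (sum of pixel intensities, the default)
#'   or `"count"` (positive-pixel counts) as the quantified measure.
#' @param normalize_by `"intensity"` (integrated N-Cad intensity) or
#'   `"count"` (N-Cad positive-pixel count) as the internal-reference
#'   denominator.
#' @param aggregate Z-stack aggregation: `"sum"` (sum raw layer values,
#'   normalize once by the summed N-Cad; default) or `"mean_norm"`
#'   (average per-layer normalized values).
#' @param channel_map named character vector mapping markers to channels.
#' @return a `gj_config` list.
#' @export
gj_config <- function(r_min = -3, r_max = 3, r_step = 0.01,
                      min_fg_count = 10, fixed_r = NULL,
                      max_radius = 40, plateau_tol = 0.005,
                      plateau_window = 3,
                      measure = c("intensity", "count"),
                      normalize_by = c("intensity", "count"),
                      aggregate = c("sum", "mean_norm"),
                      channel_map = c(ncad = "red", cx43 = "green",
                                      nuclei = "blue")) {
  stopifnot(r_min < r_max, r_step > 0, max_radius >= 1,
            plateau_tol > 0, plateau_window >= 2, min_fg_count >= 2)
  stopifnot(all(c("ncad", "cx43") %in% names(channel_map)),
            all(channel_map %in% c("red", "green", "blue")))
  structure(list(r_min = r_min, r_max = r_max, r_step = r_step,
                 min_fg_count = min_fg_count, fixed_r = fixed_r,
                 max_radius = max_radius, plateau_tol = plateau_tol,
                 plateau_window = plateau_window,
                 measure = match.arg(measure),
                 normalize_by = match.arg(normalize_by),
                 aggregate = match.arg(aggregate),
                 channel_map = channel_map),
            class = "gj_config")
}

.r_grid <- function(cfg) seq(cfg$r_min, cfg$r_max, by = cfg$r_step)

#' Read a configuration file
#'
#' Loads a YAML file whose keys override the [gj_config()] defaults.
#' Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `gj_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(gj_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$channel_map)) vals$channel_map <- unlist(vals$channel_map)
  do.call(gj_config, vals)
}
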