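#' Pipeline run configuration
#'
#' One declarative object carrying every tunable of the per-specimen
#' pipeline.  Serialisable to/from YAML via [read_config()] /
#' [write_config()], and recorded in the run log so interactive choices
#' (e.g. the bone threshold) stay reproducible.
#'
#' @param threshold_mode `"fixed"` (use `fixed_threshold`) or `"otsu"`
#'   (between-class-variance criterion on the grey histogram).
#' @param fixed_threshold grey value separating background from bone when
#'   `threshold_mode = "fixed"`.
#' @param icp_max_iterations,icp_convergence_tol,icp_trim_fraction trimmed
#'   iterative-closest-point settings: iteration cap, minimum RMS
#'   improvement (mm) to continue, and the fraction of worst
#'   correspondences discarded each iteration (the bone legitimately
#'   overhangs the tray; trimming keeps that overhang from biasing the
#'   pose).
#' @param distance_unit `"voxel"` (default, matching how mismatch is
#'   conventionally reported) or `"mm"`.
#' @param ap_split_fraction,ml_split_fraction where the implant footprint is
#'   split into anterior/posterior and medial/central, as a fraction of the
#'   footprint extent.
#' @param sclerosis_fraction cut-off position within the in-mask grey range
#'   (default 2/3: "upper third" of the grey values is sclerotic).
#' @param sclerosis_rule `"range"` (cut at min + fraction * (max - min)) or
#'   `"quantile"` (cut at the per-pixel quantile).
#' @param smooth_iterations,smooth_relaxation optional Taubin-style mesh
#'   smoothing after surface extraction; `smooth_iterations = 0` (default)
#'   disables it.
#' @param min_slice_area_fraction guard for the most-distal-slice pick: the
#'   chosen slice must hold at least this fraction of the maximal per-slice
#'   specimen area.
#' @param seed integer seed for any stochastic step (ICP vertex
#'   subsampling).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_mode = c("otsu", "fixed"),
                            fixed_threshold = NULL,
                            icp_max_iterations = 50L,
                            icp_convergence_tol = 1e-6,
                            icp_trim_fraction = 0.1,
                            distance_unit = c("voxel", "mm"),
                            ap_split_fraction = 0.5,
                            ml_split_fraction = 0.5,
                            sclerosis_fraction = 2 / 3,
                            sclerosis_rule = c("range", "quantile"),
                            smooth_iterations = 0L,
                            smooth_relaxation = 0.1,
                            min_slice_area_fraction = 0.5,
                            seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  distance_unit <- match.arg(distance_unit)
  sclerosis_rule <- match.arg(sclerosis_rule)
  if (threshold_mode == "fixed" && is.null(fixed_threshold))
    rf_stop("config", "fixed threshold mode needs fixed_threshold")
  fracs <- c(ap_split_fraction, ml_split_fraction, sclerosis_fraction,
             min_slice_area_fraction)
  if (any(fracs <= 0) || any(fracs >= 1))
    rf_stop("config", "all fractions must lie in (0, 1)")
  if (icp_max_iterations < 1L) rf_stop("config", "icp_max_iterations must be >= 1")
  if (icp_trim_fraction < 0 || icp_trim_fraction >= 0.5)
    rf_stop("config", "icp_trim_fraction must lie in [0, 0.5)")
  structure(list(
    threshold_mode = threshold_mode,
    fixed_threshold = fixed_threshold,
    icp_max_iterations = as.integer(icp_max_iterations),
    icp_convergence_tol = icp_convergence_tol,
    icp_trim_fraction = icp_trim_fraction,
    distance_unit = distance_unit,
    ap_split_fraction = ap_split_fraction,
    ml_split_fraction = ml_split_fraction,
    sclerosis_fraction = sclerosis_fraction,
    sclerosis_rule = sclerosis_rule,
    smooth_iterations = as.integer(smooth_iterations),
    smooth_relaxation = smooth_relaxation,
    min_slice_area_fraction = min_slice_area_fraction,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k,
                                  paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) rf_stop("config", "no such file: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    rf_stop("config", "unknown configuration keys: %s",
            paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path,
                   precision = 15L)
  invisible(path)
}
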