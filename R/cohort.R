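#' Implant volume in voxel units
#'
#' Enclosed mesh volume divided by the voxel volume, so bone (voxel-count)
#' and implant volumes are comparable in the same unit.
#'
#' @param implant a closed [triangle_mesh()].
#' @param voxel_size voxel edge length, mm.
#' @return list with `voxels` (mm^3 volume / voxel_size^3) and `mm3`.
#' @export
implant_voxel_volume <- function(implant, voxel_size) {
  stopifnot(inherits(implant, "triangle_mesh"))
  if (voxel_size <= 0) rf_stop("cohort", "voxel_size must be positive")
  mm <- suppressWarnings(mesh_metrics(implant))
  if (!mm$closed) rf_stop("cohort", "implant mesh is not closed")
  list(voxels = mm$volume / voxel_size^3, mm3 = mm$volume)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom.  The
#' pooled-variance variant is available for comparison but Welch is the
#' safe default when group sizes differ substantially.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (Student) statistic instead.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(group_a, group_b, pooled = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) rf_stop("cohort", "each group needs n >= 2")
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  dm <- mean(group_a) - mean(group_b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    t_ <- 0
    p <- 1
    if (dm != 0) { t_ <- Inf * sign(dm); p <- 0 }
    df <- if (is.finite(df)) df else na + nb - 2
  } else {
    t_ <- dm / se
    p <- 2 * stats::pt(-abs(t_), df)
  }
  list(t = t_, df = df, p = p)
}

#' Run the full per-specimen pipeline
#'
#' Executes segmentation, surface extraction, registration, distance
#' mapping, compartment analysis and sclerosis scoring in order, writing
#' every intermediate (mask, meshes, transform, distances, renders, result
#' JSON) to `out_dir`.  Deterministic for fixed inputs and configuration.
#' Any stage error propagates with the stage name attached.
#'
#' @param volume a [volume_image()] or a path readable by [read_volume()].
#' @param implant a [triangle_mesh()] or a path readable by [read_mesh()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory for intermediates; `NULL` skips all
#'   file output.
#' @param id specimen identifier used in file names and the result.
#' @param group optional group label carried into the result.
#' @param render write the six standardized view renders (slowest output;
#'   on by default when `out_dir` is set).
#' @return an object of class `specimen_result`.
#' @export
run_specimen <- function(volume, implant, config = pipeline_config(),
                         out_dir = NULL, id = "specimen", group = NA_character_,
                         render = !is.null(out_dir)) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      rf_stop(name, "%s", conditionMessage(e)))
  }
  vol <- stage("segment-input", {
    if (is.character(volume)) read_volume(volume) else {
      stopifnot(inherits(volume, "volume_image")); volume
    }
  })
  tray <- stage("register-input", {
    if (is.character(implant)) read_mesh(implant) else {
      stopifnot(inherits(implant, "triangle_mesh")); implant
    }
  })
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  mask <- stage("segment", {
    thr <- if (config$threshold_mode == "fixed") config$fixed_threshold
    else otsu_threshold(vol)
    rf_log("info", "[%s] bone threshold %.4g (%s)", id, thr, config$threshold_mode)
    largest_component(threshold_mask(vol, thr))
  })
  bone_vol <- mask_volume(mask)

  bone_mesh <- stage("surface", {
    mesh <- extract_surface(mask)
    if (config$smooth_iterations > 0L)
      mesh <- smooth_mesh(mesh, config$smooth_iterations, config$smooth_relaxation)
    mesh
  })

  reg <- stage("register", {
    icp(bone_mesh, tray,
        max_iterations = config$icp_max_iterations,
        tol = config$icp_convergence_tol,
        trim_fraction = config$icp_trim_fraction)
  })
  bone_aligned <- apply_transform(bone_mesh, reg$transform)

  voxel_size <- vol$spacing[1]
  dm <- stage("distmap", signed_distance(bone_aligned, tray,
                                         unit = config$distance_unit,
                                         voxel_size = voxel_size))
  dsum <- summarize_distances(dm)
  binning <- if (dm$unit == "voxel") bin_distances(dm) else NULL

  comp <- stage("compartments", {
    labels <- partition_compartments(bone_aligned, tray,
                                     ap_fraction = config$ap_split_fraction,
                                     ml_fraction = config$ml_split_fraction,
                                     dilate_mm = voxel_size)
    totals_and_quotient(max_elevation(labels, dm))
  })

  scl <- stage("sclerosis", {
    rc <- rotation_correct(vol, mask)
    sl <- most_distal_slice(rc$volume, rc$mask,
                            min_area_fraction = config$min_slice_area_fraction)
    thr <- sclerosis_threshold(sl$slice, sl$slice_mask,
                               fraction = config$sclerosis_fraction,
                               rule = config$sclerosis_rule)
    sclerosis_percent(sl$slice, sl$slice_mask, thr, sl$index)
  })

  ivol <- stage("cohort", implant_voxel_volume(tray, voxel_size))
  result <- structure(list(
    id = id, group = group,
    surface_distance_mean = dsum$mean_abs,
    surface_distance_sd = dsum$sd_abs,
    surface_distance_max = dsum$max_signed,
    distance_unit = dm$unit,
    volume_bone_voxels = bone_vol$voxels,
    volume_bone_mm3 = bone_vol$mm3,
    volume_implant_voxels = ivol$voxels,
    volume_implant_mm3 = ivol$mm3,
    volume_ratio = bone_vol$voxels / ivol$voxels,
    registration_rms = reg$rms,
    registration_iterations = reg$iterations,
    compartments = comp,
    binning = binning,
    sclerosis = scl
  ), class = "specimen_result")

  if (!is.null(out_dir)) {
    stage("output", {
      write_volume(mask, file.path(out_dir, paste0(id, "_mask.nii.gz")))
      write_mesh(bone_mesh, file.path(out_dir, paste0(id, "_bone.ply")))
      write_mesh(bone_aligned, file.path(out_dir, paste0(id, "_bone_aligned.ply")))
      write_transform(reg$transform, file.path(out_dir, paste0(id, "_transform.txt")))
      export_distances(bone_aligned, dm,
                       csv_path = file.path(out_dir, paste0(id, "_distances.csv")))
      jsonlite::write_json(specimen_result_row(result),
                           file.path(out_dir, paste0(id, "_result.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (render)
        render_views(bone_aligned, tray, dm, file.path(out_dir, "renders"))
    })
  }
  result
}

#' @export
print.specimen_result <- function(x, ...) {
  cat(sprintf("<specimen_result> %s (group %s)\n", x$id, x$group))
  cat(sprintf("  surface distance %.2f +/- %.2f %s (max %.2f)\n",
              x$surface_distance_mean, x$surface_distance_sd,
              x$distance_unit, x$surface_distance_max))
  cat(sprintf("  volumes: bone %d vox, implant %.0f vox, ratio %.2f\n",
              x$volume_bone_voxels, x$volume_implant_voxels, x$volume_ratio))
  cat(sprintf("  mismatch %.2f, quotient %s, sclerosis %.1f%%\n",
              x$compartments$total_mismatch,
              if (isTRUE(x$compartments$quotient_defined))
                sprintf("%.2f", x$compartments$quotient) else "undefined",
              x$sclerosis$percent))
  invisible(x)
}

# flatten a specimen result to one named numeric row
specimen_result_row <- function(r) {
  c(list(id = r$id, group = r$group),
    as.list(c(
      surface_distance_mean = r$surface_distance_mean,
      surface_distance_sd = r$surface_distance_sd,
      surface_distance_max = r$surface_distance_max,
      volume_bone_voxels = r$volume_bone_voxels,
      volume_implant_voxels = r$volume_implant_voxels,
      volume_ratio = r$volume_ratio,
      registration_rms = r$registration_rms,
      compartment_row(r$compartments),
      sclerosis_percent = r$sclerosis$percent,
      sclerosis_threshold = r$sclerosis$threshold
    )))
}

.cohort_metrics <- c(
  "surface_distance_mean", "volume_bone_voxels", "volume_implant_voxels",
  "volume_ratio", "total_amm", "total_amc", "total_pmm", "total_pmc",
  "total_mismatch", "quotient_central_medial", "sclerosis_percent"
)

#' Build the cohort summary table
#'
#' One row per metric (surface distance, volumes, ratio, four compartment
#' totals, total mismatch, central/medial quotient, sclerosis percent),
#' with the all-specimen mean, per-group mean and standard deviation, and
#' the Welch two-sided p-value for the group contrast.  With a single
#' group the p column is omitted with a warning.
#'
#' @param results list of [run_specimen()] results (>= 2 specimens per
#'   group for p-values).
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return a `data.frame` with class `cohort_table`.
#' @export
build_cohort_table <- function(results, pooled = FALSE) {
  stopifnot(length(results) >= 1)
  rows <- lapply(results, specimen_result_row)
  groups <- vapply(rows, function(r) as.character(r$group), "")
  glev <- unique(groups)
  num <- function(metric) vapply(rows, function(r) {
    v <- r[[metric]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
  tab <- do.call(rbind, lapply(.cohort_metrics, function(metric) {
    v <- num(metric)
    row <- data.frame(metric = metric, all_mean = mean(v, na.rm = TRUE),
                      all_sd = sd_or_zero(v))
    for (g in glev) {
      vg <- v[groups == g]
      row[[paste0("mean_", g)]] <- mean(vg, na.rm = TRUE)
      row[[paste0("sd_", g)]] <- sd_or_zero(vg)
    }
    if (length(glev) == 2) {
      va <- v[groups == glev[1]]
      vb <- v[groups == glev[2]]
      row$p <- if (sum(!is.na(va)) >= 2 && sum(!is.na(vb)) >= 2)
        welch_t(va, vb, pooled = pooled)$p else NA_real_
    }
    row
  }))
  if (length(glev) < 2)
    warning("single group: no p-values computed")
  n_per <- vapply(glev, function(g) sum(groups == g), 0L)
  attr(tab, "n_per_group") <- n_per
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

sd_or_zero <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) > 1) stats::sd(v) else 0
}

#' Write a cohort table as CSV
#' @param tab a [build_cohort_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Run a cohort of specimens from a manifest
#'
#' The manifest is a CSV with columns `id`, `group`, `volume_path`,
#' `implant_path`.  Each specimen runs through [run_specimen()] with
#' per-specimen output directories under `out_dir`; the cohort table is
#' written as `cohort.csv`.
#'
#' @param manifest path to the manifest CSV.
#' @param config a [pipeline_config()].
#' @param out_dir cohort output directory.
#' @param render write per-specimen renders.
#' @return list with `results` and `table`.
#' @export
run_cohort <- function(manifest, config = pipeline_config(), out_dir = NULL,
                       render = FALSE) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "group", "volume_path", "implant_path")
  if (!all(need %in% names(man)))
    rf_stop("cohort", "manifest must have columns %s", paste(need, collapse = ", "))
  results <- lapply(seq_len(nrow(man)), function(i) {
    run_specimen(man$volume_path[i], man$implant_path[i], config,
                 out_dir = if (is.null(out_dir)) NULL
                 else file.path(out_dir, man$id[i]),
                 id = man$id[i], group = man$group[i], render = render)
  })
  tab <- build_cohort_table(results)
  if (!is.null(out_dir)) write_cohort_table(tab, file.path(out_dir, "cohort.csv"))
  list(results = results, table = tab)
}
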