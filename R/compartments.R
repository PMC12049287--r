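#' Partition bone vertices into the four matched-surface compartments
#'
#' The implant footprint's axis-aligned bounding rectangle in the
#' medial-lateral / anterior-posterior plane of the implant frame is split
#' at configurable fractions (default midpoints) into anterior/posterior
#' and medial/central halves, giving the four compartments AMM, AMC, PMM,
#' PMC (anteromedial/posteromedial x medial/central).  Bone vertices
#' projected into that plane are labelled by the quadrant they fall in;
#' vertices outside the footprint rectangle (dilated by `dilate_mm`) are
#' labelled `outside`.  A vertex exactly on a split plane goes to the
#' anterior respectively medial side.
#'
#' Which end of the ML axis is medial comes from the volume axis
#' convention (+ML = medial), not from geometry.
#'
#' @param bone bone [triangle_mesh()] in the implant frame.
#' @param implant implant [triangle_mesh()].
#' @param axes axis labels of the implant frame, one of `"ML"`, `"AP"`,
#'   `"PD"` per coordinate (default `c("ML","AP","PD")`).
#' @param ap_fraction,ml_fraction split positions as fractions of the
#'   footprint extent, measured from the posterior / central edge.
#' @param dilate_mm footprint dilation tolerance (one voxel size is
#'   customary).
#' @return an object of class `compartment_labeling`: factor `labels`
#'   (`AMM`, `AMC`, `PMM`, `PMC`, `outside`) per bone vertex, plus the
#'   split-plane positions (mm).
#' @export
partition_compartments <- function(bone, implant,
                                   axes = c("ML", "AP", "PD"),
                                   ap_fraction = 0.5, ml_fraction = 0.5,
                                   dilate_mm = 1) {
  stopifnot(inherits(bone, "triangle_mesh"), inherits(implant, "triangle_mesh"))
  if (!setequal(axes, c("ML", "AP", "PD")))
    rf_stop("compartments", "axes must label ML, AP and PD")
  iml <- match("ML", axes)
  iap <- match("AP", axes)
  fp_ml <- range(implant$vertices[, iml])
  fp_ap <- range(implant$vertices[, iap])
  # +ML is medial and +AP is anterior, so the split positions sit at
  # fraction from the central / posterior (low-coordinate) edge
  ml_split <- fp_ml[1] + ml_fraction * diff(fp_ml)
  ap_split <- fp_ap[1] + ap_fraction * diff(fp_ap)
  x <- bone$vertices[, iml]
  y <- bone$vertices[, iap]
  inside <- x >= fp_ml[1] - dilate_mm & x <= fp_ml[2] + dilate_mm &
    y >= fp_ap[1] - dilate_mm & y <= fp_ap[2] + dilate_mm
  medial <- x >= ml_split   # tie -> medial
  anterior <- y >= ap_split # tie -> anterior
  lab <- rep("outside", nrow(bone$vertices))
  lab[inside & anterior & medial] <- "AMM"
  lab[inside & anterior & !medial] <- "AMC"
  lab[inside & !anterior & medial] <- "PMM"
  lab[inside & !anterior & !medial] <- "PMC"
  structure(list(
    labels = factor(lab, levels = c("AMM", "AMC", "PMM", "PMC", "outside")),
    ml_split = ml_split, ap_split = ap_split,
    footprint_ml = fp_ml, footprint_ap = fp_ap
  ), class = "compartment_labeling")
}

#' @export
print.compartment_labeling <- function(x, ...) {
  cat("<compartment_labeling>", paste(sprintf("%s=%d", levels(x$labels),
                                              tabulate(x$labels, 5)),
                                      collapse = " "), "\n")
  invisible(x)
}

#' Per-compartment maximal bone elevation
#'
#' For each compartment and each anterior/posterior half, the maximum
#' positive signed distance of bone above the implant (elevation).  Since a
#' compartment lies entirely in one AP half, its maximum in the other half
#' is zero; compartments with no positive distance score zero.  Negative
#' distances (bone below the tray surface) are clipped to zero -- only
#' elevation above the component is measured.
#'
#' @param labels a [partition_compartments()] labelling.
#' @param dm the matching [signed_distance()] map (voxel units
#'   conventionally).
#' @return an object of class `compartment_report` with the `maxima` table
#'   (rows AMM/AMC/PMM/PMC, columns anterior/posterior) and the distance
#'   unit; totals are added by [totals_and_quotient()].
#' @export
max_elevation <- function(labels, dm) {
  stopifnot(inherits(labels, "compartment_labeling"),
            inherits(dm, "distance_map"))
  if (length(labels$labels) != length(dm$values))
    rf_stop("compartments", "labelling and distance map sizes differ")
  v <- pmax(dm$values, 0)
  comps <- c("AMM", "AMC", "PMM", "PMC")
  maxima <- matrix(0, 4, 2, dimnames = list(comps, c("anterior", "posterior")))
  for (cc in comps) {
    sel <- labels$labels == cc
    half <- if (cc %in% c("AMM", "AMC")) "anterior" else "posterior"
    if (any(sel)) maxima[cc, half] <- max(v[sel], 0)
  }
  structure(list(maxima = maxima, unit = dm$unit, totals = NULL,
                 total_mismatch = NULL, quotient = NULL),
            class = "compartment_report")
}

#' Complete a compartment report: totals, total mismatch, quotient
#'
#' Per compartment, `total = anterior + posterior` maxima (exact).  The
#' total mismatch is defined here as the mean of the four compartment
#' totals.  The central-to-medial quotient is
#' `(AMC_total + PMC_total) / (AMM_total + PMM_total)`; a zero denominator
#' flags the quotient as undefined (`NA`) rather than infinite.
#'
#' @param report a [max_elevation()] report.
#' @return the completed `compartment_report` with `totals`,
#'   `total_mismatch`, `quotient` and `quotient_defined`.
#' @export
totals_and_quotient <- function(report) {
  stopifnot(inherits(report, "compartment_report"))
  totals <- rowSums(report$maxima)
  report$totals <- totals
  report$total_mismatch <- mean(totals)
  med <- totals[["AMM"]] + totals[["PMM"]]
  cen <- totals[["AMC"]] + totals[["PMC"]]
  if (med > 0) {
    report$quotient <- cen / med
    report$quotient_defined <- TRUE
  } else {
    report$quotient <- NA_real_
    report$quotient_defined <- FALSE
    rf_log("warn", "medial totals are zero: central/medial quotient undefined")
  }
  report
}

#' @export
print.compartment_report <- function(x, ...) {
  cat(sprintf("<compartment_report> (unit %s)\n", x$unit))
  print(round(x$maxima, 3))
  if (!is.null(x$totals)) {
    cat("totals:", paste(sprintf("%s=%.3f", names(x$totals), x$totals),
                         collapse = " "), "\n")
    cat(sprintf("total mismatch %.3f, central/medial quotient %s\n",
                x$total_mismatch,
                if (isTRUE(x$quotient_defined)) sprintf("%.3f", x$quotient)
                else "undefined"))
  }
  invisible(x)
}

# flatten a completed report to a named numeric row (serialisation helper)
compartment_row <- function(report) {
  stopifnot(!is.null(report$totals))
  c(
    amm_anterior = report$maxima["AMM", "anterior"],
    amm_posterior = report$maxima["AMM", "posterior"],
    amc_anterior = report$maxima["AMC", "anterior"],
    amc_posterior = report$maxima["AMC", "posterior"],
    pmm_anterior = report$maxima["PMM", "anterior"],
    pmm_posterior = report$maxima["PMM", "posterior"],
    pmc_anterior = report$maxima["PMC", "anterior"],
    pmc_posterior = report$maxima["PMC", "posterior"],
    total_amm = unname(report$totals["AMM"]),
    total_amc = unname(report$totals["AMC"]),
    total_pmm = unname(report$totals["PMM"]),
    total_pmc = unname(report$totals["PMC"]),
    total_mismatch = report$total_mismatch,
    quotient_central_medial = report$quotient
  )
}
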