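#' Structure occupancy mask on a dose-grid lattice
#'
#' @param mask Logical 3D array on the same lattice as the dose grid.
#' @param grid The [dose_grid()] the mask is aligned to (spacing defines the
#'   voxel volume).
#' @param name Structure name. Default `"structure"`.
#' @return Object of class `"structure_mask"` with `mask`, `name`,
#'   `voxel_volume_cc` and `volume_cc`.
#' @export
structure_mask <- function(mask, grid, name = "structure") {
  stopifnot(is.logical(mask), inherits(grid, "dose_grid"))
  if (!identical(dim(mask), dim(grid$values)))
    stop("mask and dose grid must share the same lattice")
  vox_cc <- prod(grid$spacing) / 1000  # mm^3 -> cc
  structure(list(mask = mask, name = name, voxel_volume_cc = vox_cc,
                 volume_cc = sum(mask) * vox_cc),
            class = "structure_mask")
}

#' Target coverage by the prescription isodose
#'
#' Ratio between the target volume inside the prescription isodose and the
#' PTV volume: `|PTV voxels with dose >= prescription| / |PTV voxels|`
#' (closed threshold).
#'
#' @param ptv A [structure_mask()] (non-empty).
#' @param dose A [dose_grid()] on the same lattice.
#' @param prescription Prescription dose, Gy.
#' @return Coverage ratio in `[0, 1]`.
#' @export
coverage_ratio <- function(ptv, dose, prescription) {
  stopifnot(inherits(ptv, "structure_mask"), inherits(dose, "dose_grid"))
  if (!any(ptv$mask)) stop("empty PTV")
  mean(dose$values[ptv$mask] >= prescription)
}

#' Low dose spillage
#'
#' Ratio between the volume (anywhere in the grid, PTV included) receiving
#' at least 50 percent of the prescription dose and the PTV volume.
#'
#' @inheritParams coverage_ratio
#' @return Spillage ratio (>= 0; typically around 3--6 for clinical plans).
#' @export
low_dose_spillage <- function(ptv, dose, prescription) {
  stopifnot(inherits(ptv, "structure_mask"), inherits(dose, "dose_grid"))
  if (!any(ptv$mask)) stop("empty PTV")
  sum(dose$values >= 0.5 * prescription) / sum(ptv$mask)
}

#' Dose-volume histogram point queries
#'
#' `D_x%` is the near-maximum convention: the dose received by the hottest
#' `x` percent of the structure volume, read off the descending sorted
#' voxel-dose curve with linear interpolation at fractional ranks. `V_xGy`
#' is the structure volume (cc) with dose at or above `x` Gy; `V_x%` the
#' same as percent of the structure volume. `D_mean` is the arithmetic mean.
#'
#' @param mask A [structure_mask()] (non-empty).
#' @param dose A [dose_grid()] on the same lattice.
#' @param query One of `"D%"`, `"VGy"`, `"V%"`, `"Dmean"`.
#' @param value Query value: percent of volume in `(0, 100]` for `"D%"`, Gy
#'   for `"VGy"`/`"V%"`; ignored for `"Dmean"`.
#' @return Gy for `"D%"`/`"Dmean"`; cc for `"VGy"`; percent for `"V%"`.
#' @export
#' @examples
#' # D_2% of 100 voxels dosed 1..100 Gy is 99 Gy (hottest-2% convention)
dvh_point <- function(mask, dose, query = c("D%", "VGy", "V%", "Dmean"),
                      value = NULL) {
  stopifnot(inherits(mask, "structure_mask"), inherits(dose, "dose_grid"))
  query <- match.arg(query)
  d <- dose$values[mask$mask]
  if (length(d) == 0) stop("empty structure")
  switch(query,
    "Dmean" = mean(d),
    "D%" = {
      if (is.null(value) || value <= 0 || value > 100)
        stop("D_x% query requires x in (0, 100]")
      s <- sort(d, decreasing = TRUE)
      k <- value / 100 * length(s)  # fractional rank on the sorted curve
      if (k <= 1) return(s[1])
      lo <- floor(k); hi <- ceiling(k)
      if (lo == hi) s[lo] else s[lo] + (k - lo) * (s[hi] - s[lo])
    },
    "VGy" = {
      if (is.null(value)) stop("V_xGy query requires a dose value")
      sum(d >= value) * mask$voxel_volume_cc
    },
    "V%" = {
      if (is.null(value)) stop("V_x% query requires a dose value")
      100 * mean(d >= value)
    })
}

#' Percent change between reference and new values
#'
#' `reduction = 100 * (ref - new) / ref`; `increase = 100 * (new - ref) /
#' ref`. Rounding (half up, as used in reports) is applied only when
#' `report = TRUE`.
#'
#' @param reference Reference value (> 0).
#' @param new New value.
#' @param mode `"reduction"` or `"increase"`.
#' @param report Round half-up to the nearest integer percent. Default
#'   `FALSE`.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(5.47, 3.44, "reduction", report = TRUE)  # 37
#' percent_change(975, 1370, "increase", report = TRUE)    # 41
percent_change <- function(reference, new, mode = c("reduction", "increase"),
                           report = FALSE) {
  mode <- match.arg(mode)
  if (!is.finite(reference) || reference <= 0)
    stop("reference must be positive")
  pc <- switch(mode,
               reduction = 100 * (reference - new) / reference,
               increase = 100 * (new - reference) / reference)
  if (report) floor(pc + 0.5) else pc
}

#' Paired two-tailed t-test between matched plan metrics
#'
#' Classical paired Student's t-test with `n - 1` degrees of freedom and a
#' two-tailed p-value, as used to compare planning techniques across matched
#' patients; `p < 0.05` is flagged as significant. All-zero (or
#' zero-variance) differences leave the statistic undefined and raise an
#' error.
#'
#' @param sample_a,sample_b Numeric vectors of equal length >= 2.
#' @param alpha Significance level. Default 0.05.
#' @return List: `t`, `df`, `p`, `significant`, `mean_difference`
#'   (`a - b`).
#' @export
paired_t_test <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) != length(sample_b) || length(sample_a) < 2)
    stop("samples must have equal length >= 2")
  d <- sample_a - sample_b
  if (stats::sd(d) == 0)
    stop("degenerate input: paired differences have zero variance, ",
         "t statistic undefined")
  ht <- stats::t.test(sample_a, sample_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha,
       mean_difference = mean(d))
}

#' Plan-quality report
#'
#' Bundles the benchmark metrics for one plan: coverage, low-dose spillage,
#' requested DVH points, MU and times.
#'
#' @param ptv A [structure_mask()].
#' @param dose A [dose_grid()].
#' @param prescription Prescription dose, Gy.
#' @param mu Total plan MU (optional).
#' @param time_min Delivery time in minutes (optional).
#' @param dvh_queries Optional named list of `list(query=, value=)` entries
#'   passed to [dvh_point()].
#' @return Object of class `"plan_metrics_report"` (a list).
#' @export
plan_metrics_report <- function(ptv, dose, prescription, mu = NA,
                                time_min = NA, dvh_queries = NULL) {
  dvh <- lapply(dvh_queries, function(q)
    dvh_point(ptv, dose, q$query, q$value))
  structure(list(coverage = coverage_ratio(ptv, dose, prescription),
                 low_dose_spillage = low_dose_spillage(ptv, dose,
                                                       prescription),
                 dvh = dvh, mu = mu, time_min = time_min,
                 prescription = prescription),
            class = "plan_metrics_report")
}

#' @export
print.plan_metrics_report <- function(x, ...) {
  cat(sprintf("Plan metrics: coverage %.3f, low-dose spillage %.2f\n",
              x$coverage, x$low_dose_spillage))
  if (length(x$dvh))
    for (nm in names(x$dvh)) cat(sprintf("  %s: %.3f\n", nm, x$dvh[[nm]]))
  if (!is.na(x$mu)) cat(sprintf("  MU: %.1f\n", x$mu))
  if (!is.na(x$time_min)) cat(sprintf("  time: %.2f min\n", x$time_min))
  invisible(x)
}
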