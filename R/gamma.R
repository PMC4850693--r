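#' Volumetric dose on a regular lattice
#'
#' @param values 3D numeric array of dose in Gy, non-negative and finite.
#' @param origin Length-3 numeric, mm: coordinates of the *center* of voxel
#'   `[1,1,1]`.
#' @param spacing Length-3 positive numeric, mm.
#' @return Object of class `"dose_grid"` with `values`, `origin`, `spacing`.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Dose grid %dx%dx%d, spacing (%g, %g, %g) mm, max %.3f Gy\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              max(x$values)))
  invisible(x)
}

# physical extent covered by interpolation (voxel centers); internal
grid_bounds <- function(grid) {
  d <- dim(grid$values)
  rbind(lo = grid$origin, hi = grid$origin + (d - 1) * grid$spacing)
}

#' Trilinear interpolation of a dose grid
#'
#' @param grid A [dose_grid()].
#' @param pts Matrix (n x 3) or length-3 vector of query coordinates, mm.
#' @return Interpolated dose in Gy; `NA` outside the voxel-center hull.
#' @export
interp_dose <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- dim(grid$values)
  f <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  out <- rep(NA_real_, nrow(pts))
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 &
        f[, 2] >= 0 & f[, 2] <= d[2] - 1 &
        f[, 3] >= 0 & f[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  i0 <- pmin(floor(f), rep(d - 2L, each = nrow(f)))
  i0 <- pmax(i0, 0)
  w <- f - i0
  v <- grid$values
  idx <- function(a, b, c) v[cbind(i0[, 1] + 1L + a, i0[, 2] + 1L + b,
                                   i0[, 3] + 1L + c)]
  out[ok] <-
    idx(0, 0, 0) * (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) +
    idx(1, 0, 0) * w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) +
    idx(0, 1, 0) * (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) +
    idx(0, 0, 1) * (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] +
    idx(1, 1, 0) * w[, 1] * w[, 2] * (1 - w[, 3]) +
    idx(1, 0, 1) * w[, 1] * (1 - w[, 2]) * w[, 3] +
    idx(0, 1, 1) * (1 - w[, 1]) * w[, 2] * w[, 3] +
    idx(1, 1, 1) * w[, 1] * w[, 2] * w[, 3]
  out
}

#' Diode measurement set on two orthogonal planes
#'
#' Diode-array phantoms measure dose at discrete points on two orthogonal
#' planes through a common axis. The set stores per-diode coordinates (mm),
#' the plane label and the measured dose (Gy).
#'
#' @param x,y,z Diode coordinates, mm.
#' @param dose Measured dose, Gy.
#' @param plane Plane label per diode (e.g. `"xz"`/`"yz"`).
#' @return Object of class `"diode_plane_set"` (a data frame).
#' @export
diode_plane_set <- function(x, y, z, dose, plane = "xz") {
  df <- data.frame(x = x, y = y, z = z, dose = dose,
                   plane = rep_len(plane, length(x)))
  if (anyDuplicated(df[c("x", "y", "z")]))
    stop("diode coordinates must be unique")
  class(df) <- c("diode_plane_set", "data.frame")
  df
}

#' Default two-plane diode geometry for a grid
#'
#' Builds diode positions on two orthogonal planes intersecting on the
#' grid's central axis (planes `y = y_c` and `x = x_c`), at a configurable
#' pitch, inset from the grid faces so every diode is interpolable.
#'
#' @param grid A [dose_grid()].
#' @param pitch Diode spacing, mm. Default 10.
#' @return A `"diode_plane_set"` with `dose` set to `NA` (geometry only).
#' @export
default_diode_geometry <- function(grid, pitch = 10) {
  b <- grid_bounds(grid)
  ctr <- colMeans(b)
  ax <- function(k) {
    lo <- b[1, k] + grid$spacing[k]; hi <- b[2, k] - grid$spacing[k]
    seq(ctr[k] - floor((ctr[k] - lo) / pitch) * pitch, hi, by = pitch)
  }
  xz <- expand.grid(x = ax(1), z = ax(3))
  yz <- expand.grid(y = ax(2), z = ax(3))
  df <- rbind(
    data.frame(x = xz$x, y = ctr[2], z = xz$z, plane = "xz"),
    data.frame(x = ctr[1], y = yz$y, z = yz$z, plane = "yz"))
  df <- df[!duplicated(df[c("x", "y", "z")]), ]
  diode_plane_set(df$x, df$y, df$z, dose = NA_real_, plane = df$plane)
}

#' Gamma-index acceptance criteria
#'
#' @param dose_tolerance Dose difference tolerance, percent of the global
#'   maximum of the planned grid. Default 3.
#' @param distance_tolerance Distance-to-agreement tolerance, mm. Default 3.
#' @param low_dose_threshold Percent of the maximum expected (planned grid)
#'   dose below which diodes are excluded from evaluation. Default 20.
#' @return Object of class `"gamma_criteria"`.
#' @export
gamma_criteria <- function(dose_tolerance = 3, distance_tolerance = 3,
                           low_dose_threshold = 20) {
  stopifnot(dose_tolerance > 0, distance_tolerance > 0,
            low_dose_threshold > 0)
  structure(list(dose_tolerance = dose_tolerance,
                 distance_tolerance = distance_tolerance,
                 low_dose_threshold = low_dose_threshold,
                 normalization = "global"),
            class = "gamma_criteria")
}

#' Sort dose pulses into control points by planned MU
#'
#' During measurement the dose pulses are binned into the plan's control
#' points according to the planned cumulative MU per CP: pulses are assigned
#' in delivery order, and a pulse straddling a CP boundary is split pro-rata.
#'
#' @param pulses Data frame with columns `mu` (MU per pulse, delivery order)
#'   and `reading` (Gy per pulse).
#' @param plan A [delivery_plan()]. Pulse MU total must match the plan total
#'   within 1 percent.
#' @return Numeric vector of per-CP reading sums (length = number of CPs).
#' @export
bin_pulses_to_cps <- function(pulses, plan) {
  stopifnot(is.data.frame(pulses), all(c("mu", "reading") %in% names(pulses)),
            inherits(plan, "delivery_plan"))
  tot_p <- sum(pulses$mu)
  if (abs(tot_p - plan$total_mu) > 0.01 * plan$total_mu)
    stop(sprintf("pulse MU total %.3f differs from plan total %.3f by > 1%%",
                 tot_p, plan$total_mu))
  bounds <- cumsum(plan$cp$mu_weight)
  bounds[length(bounds)] <- max(bounds[length(bounds)], tot_p)  # guard tail
  p_hi <- cumsum(pulses$mu)
  p_lo <- c(0, p_hi[-length(p_hi)])
  out <- numeric(nrow(plan$cp))
  b_lo <- c(0, bounds[-length(bounds)])
  for (j in seq_along(out)) {
    ov <- pmax(0, pmin(p_hi, bounds[j]) - pmax(p_lo, b_lo[j]))
    frac <- ifelse(pulses$mu > 0, ov / pulses$mu, 0)
    out[j] <- sum(frac * pulses$reading)
  }
  out
}

#' Apply per-control-point angular correction factors
#'
#' Diode response depends on beam incidence; a correction model maps
#' `(gantry, ring, plane)` to a multiplicative factor applied to each CP's
#' dose contribution before summation:
#' `corrected = sum over CPs of factor(cp) * dose(cp)`.
#'
#' @param per_cp_dose Matrix of per-diode, per-CP dose contributions
#'   (rows = diodes, columns = CPs).
#' @param plan A [delivery_plan()] supplying per-CP angles.
#' @param correction_model Function `(gantry, ring, plane) -> factor > 0`.
#'   Default [identity_correction()].
#' @param plane Plane label per diode (recycled).
#' @return Corrected per-diode dose vector.
#' @export
apply_angular_corrections <- function(per_cp_dose, plan,
                                      correction_model = identity_correction(),
                                      plane = "xz") {
  stopifnot(is.matrix(per_cp_dose), ncol(per_cp_dose) == nrow(plan$cp))
  plane <- rep_len(plane, nrow(per_cp_dose))
  fac <- outer(seq_len(nrow(per_cp_dose)), seq_len(ncol(per_cp_dose)),
               Vectorize(function(i, j)
                 correction_model(plan$cp$gantry[j], plan$cp$ring[j],
                                  plane[i])))
  if (any(fac <= 0)) stop("angular correction factors must be positive")
  rowSums(fac * per_cp_dose)
}

#' Identity angular correction model
#' @return Function returning factor 1 for every CP.
#' @export
identity_correction <- function() function(gantry, ring, plane) 1

#' Example cosine-falloff angular correction model
#'
#' Illustrative (non-vendor) model: response drops with ring tilt as
#' `1 - amplitude * (1 - cos(ring))`. Real detector factors are proprietary;
#' this stands in for them in tests and demos.
#'
#' @param amplitude Falloff amplitude in `[0, 1)`. Default 0.05.
#' @return Correction function `(gantry, ring, plane) -> factor`.
#' @export
cosine_correction <- function(amplitude = 0.05) {
  force(amplitude)
  function(gantry, ring, plane) 1 - amplitude * (1 - cos(ring * pi / 180))
}

# gamma for one diode over a candidate set; internal core.
# Candidate set (frozen convention): the diode position itself, a fine local
# lattice of step dta/10 within radius gamma0 * dta, and all voxel centers.
# exhaustive = TRUE disables pruning (oracle-style full evaluation).
gamma_one <- function(grid, pt, d_meas, dd_abs, dta, exhaustive = FALSE) {
  g0 <- abs(d_meas - interp_dose(grid, pt)) / dd_abs
  best <- g0
  eval_set <- function(pts, dist) {
    dose <- interp_dose(grid, pts)
    ok <- !is.na(dose)
    if (!any(ok)) return(invisible(NULL))
    gam <- sqrt(((d_meas - dose[ok]) / dd_abs)^2 + (dist[ok] / dta)^2)
    best <<- min(best, gam)
    invisible(NULL)
  }
  # fine local lattice; radius capped at 3*dta (a gamma above 3 is far past
  # the pass threshold, so only voxel-center resolution applies out there)
  r_max <- min(g0, 3) * dta
  if (r_max > 0) {
    step <- dta / 10
    off <- seq(-floor(r_max / step) * step, floor(r_max / step) * step,
               by = step)
    fine <- as.matrix(expand.grid(off, off, off))
    dist <- sqrt(rowSums(fine^2))
    keep <- dist <= r_max
    fine <- fine[keep, , drop = FALSE]; dist <- dist[keep]
    o <- order(dist)
    fine <- fine[o, , drop = FALSE]; dist <- dist[o]
    if (!exhaustive) {
      cut <- dist / dta < best  # distance term alone below current best
      fine <- fine[cut, , drop = FALSE]; dist <- dist[cut]
    }
    if (nrow(fine))
      eval_set(sweep(fine, 2, pt, "+"), dist)
  }
  # all voxel centers (pruned by the running best unless exhaustive)
  d <- dim(grid$values)
  ax <- lapply(1:3, function(k) grid$origin[k] + (0:(d[k] - 1)) * grid$spacing[k])
  vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  dist <- sqrt((vox[, 1] - pt[1])^2 + (vox[, 2] - pt[2])^2 +
               (vox[, 3] - pt[3])^2)
  if (!exhaustive) {
    keep <- dist / dta < best
    vox <- vox[keep, , drop = FALSE]; dist <- dist[keep]
  }
  if (nrow(vox)) {
    dose <- grid$values[cbind(
      round((vox[, 1] - grid$origin[1]) / grid$spacing[1]) + 1L,
      round((vox[, 2] - grid$origin[2]) / grid$spacing[2]) + 1L,
      round((vox[, 3] - grid$origin[3]) / grid$spacing[3]) + 1L)]
    gam <- sqrt(((d_meas - dose) / dd_abs)^2 + (dist / dta)^2)
    best <- min(best, gam)
  }
  best
}

#' Minimum 3D gamma index of diode measurements against a planned grid
#'
#' For each diode above the low-dose threshold the gamma index is the
#' minimum over search points `r` in the planned volume of
#' `sqrt((Ddiff / (dose_tol% * global max))^2 + (|r - r_diode| / dist_tol)^2)`
#' with the planned dose interpolated trilinearly (global normalization).
#' The search evaluates the diode position, a fine local lattice of step
#' `distance_tolerance/10`, and every voxel center, pruning candidates whose
#' distance term alone exceeds the running best; on small grids this equals
#' an exhaustive search of the same candidate set. Diodes below
#' `low_dose_threshold` percent of the planned-grid maximum (measured dose)
#' are excluded from the passing-rate denominator. `gamma <= 1` counts as
#' passing.
#'
#' @param measured A [diode_plane_set()] with measured `dose`.
#' @param planned A [dose_grid()] enclosing the diode planes; max > 0.
#' @param crit A [gamma_criteria()].
#' @param exhaustive Disable search pruning (for cross-checks). Default
#'   `FALSE`.
#' @return Object of class `"gamma_result"`: data frame of evaluated diodes
#'   with `gamma`, plus attributes `passing_rate` (percent) and
#'   `evaluated_count`.
#' @export
gamma_min3d <- function(measured, planned, crit = gamma_criteria(),
                        exhaustive = FALSE) {
  stopifnot(inherits(measured, "diode_plane_set"),
            inherits(planned, "dose_grid"),
            inherits(crit, "gamma_criteria"))
  dmax <- max(planned$values)
  if (dmax <= 0) stop("planned grid maximum must be positive")
  dd_abs <- crit$dose_tolerance / 100 * dmax
  thr <- crit$low_dose_threshold / 100 * dmax
  keep <- measured$dose >= thr
  if (!any(keep))
    stop("no diode above the low-dose threshold; nothing to evaluate")
  ev <- measured[keep, , drop = FALSE]
  gam <- vapply(seq_len(nrow(ev)), function(i)
    gamma_one(planned, c(ev$x[i], ev$y[i], ev$z[i]), ev$dose[i],
              dd_abs, crit$distance_tolerance, exhaustive = exhaustive),
    numeric(1))
  res <- data.frame(x = ev$x, y = ev$y, z = ev$z, plane = ev$plane,
                    dose = ev$dose, gamma = gam)
  attr(res, "passing_rate") <- 100 * mean(gam <= 1 + 1e-12)
  attr(res, "evaluated_count") <- nrow(res)
  attr(res, "criteria") <- crit
  class(res) <- c("gamma_result", "data.frame")
  res
}

#' Gamma passing rate
#'
#' Percent of evaluated diodes with `gamma <= 1` (a gamma of exactly 1
#' passes).
#'
#' @param result A `"gamma_result"` from [gamma_min3d()].
#' @return Passing rate in percent.
#' @export
passing_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  if (attr(result, "evaluated_count") == 0) stop("no evaluated diodes")
  100 * mean(result$gamma <= 1 + 1e-12)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("Gamma result: %d diodes evaluated, passing rate %.1f%%\n",
              attr(x, "evaluated_count"), passing_rate(x)))
  invisible(x)
}
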