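#' Rule set governing wave-arc trajectory geometry
#'
#' Bundles the geometric constraints a gantry--ring wave trajectory must
#' satisfy and the beam spacing used when the trajectory is discretized.
#' Defaults reproduce the vendor rule set for the O-ring system: the dominant
#' angular span of every sub-arc is a multiple of 4 degrees and at least
#' 24 degrees, the ring may rotate at most 1 degree per gantry degree, and
#' beams are generated every 24 degrees of Euclidean (gantry, ring) path
#' length.
#'
#' @param dominant_multiple Degrees; the dominant span of each sub-arc must be
#'   a multiple of this value. Default 4.
#' @param min_subarc_span Degrees; minimum dominant angular span per sub-arc.
#'   Default 24.
#' @param max_ring_per_gantry Maximum ring-span / gantry-span ratio per
#'   sub-arc (dimensionless). Default 1.
#' @param beam_spacing Degrees of Euclidean (gantry, ring) norm between
#'   consecutive beam angles. Default 24.
#' @return An object of class `"trajectory_rules"`.
#' @export
#' @examples
#' trajectory_rules()
trajectory_rules <- function(dominant_multiple = 4, min_subarc_span = 24,
                             max_ring_per_gantry = 1, beam_spacing = 24) {
  vals <- c(dominant_multiple, min_subarc_span, max_ring_per_gantry,
            beam_spacing)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all trajectory rule parameters must be positive and finite")
  structure(list(dominant_multiple = dominant_multiple,
                 min_subarc_span = min_subarc_span,
                 max_ring_per_gantry = max_ring_per_gantry,
                 beam_spacing = beam_spacing),
            class = "trajectory_rules")
}

#' Wave-arc trajectory through gantry--ring angle space
#'
#' A wave trajectory is an ordered list of manipulation points (MPs):
#' gantry--ring angle positions at which the direction of ring rotation may
#' change. Consecutive MPs bound a *sub-arc*. Clinical trajectories use 5 to 8
#' MPs; the constructor accepts any number >= 2 so that rule violations can be
#' examined with [validate_trajectory()].
#'
#' Gantry angles are in `[0, 360)` (IEC 61217 sense) and must not wrap across
#' 0/360 within a sub-arc: split such paths before constructing. The ring
#' angle (positive = clockwise viewed from above) must stay within
#' `ring_range`.
#'
#' @param gantry Numeric vector of MP gantry angles, degrees in `[0, 360)`.
#' @param ring Numeric vector of MP ring angles, degrees, same length.
#' @param ring_range Allowed symmetric ring range, degrees. Default
#'   `c(-60, 60)`.
#' @return An object of class `"wave_trajectory"` with elements `mp`
#'   (data frame of gantry/ring) and `ring_range`.
#' @export
#' @examples
#' wave_trajectory(gantry = c(180, 230, 300), ring = c(0, 30, -10))
wave_trajectory <- function(gantry, ring, ring_range = c(-60, 60)) {
  if (length(gantry) != length(ring))
    stop("gantry and ring must have the same length")
  if (length(gantry) < 2)
    stop("a wave trajectory needs at least 2 manipulation points")
  if (any(!is.finite(gantry)) || any(!is.finite(ring)))
    stop("manipulation-point angles must be finite")
  if (any(gantry < 0 | gantry >= 360))
    stop("gantry angles must lie in [0, 360)")
  if (any(ring < ring_range[1] | ring > ring_range[2]))
    stop(sprintf("ring angles must lie within [%g, %g]",
                 ring_range[1], ring_range[2]))
  structure(list(mp = data.frame(gantry = as.numeric(gantry),
                                 ring = as.numeric(ring)),
                 ring_range = as.numeric(ring_range)),
            class = "wave_trajectory")
}

#' @export
print.wave_trajectory <- function(x, ...) {
  n <- nrow(x$mp)
  cat(sprintf("Wave-arc trajectory: %d manipulation points, %d sub-arcs\n",
              n, n - 1L))
  cat(sprintf("  Euclidean path length: %.2f deg\n", path_length(x)))
  print(x$mp, ...)
  invisible(x)
}

# per sub-arc signed/absolute spans; internal
subarc_spans <- function(traj) {
  g <- traj$mp$gantry
  r <- traj$mp$ring
  data.frame(dg = diff(g), dr = diff(r),
             ag = abs(diff(g)), ar = abs(diff(r)))
}

#' Dominant axis of a sub-arc
#'
#' The dominant angle of a sub-arc is the axis (gantry or ring) with the
#' larger absolute angular span. Ties are broken in favour of the gantry, the
#' primary rotation axis (fixed convention).
#'
#' @param from,to Numeric vectors `c(gantry, ring)` (degrees) for the two
#'   manipulation points bounding the sub-arc.
#' @return `"gantry"` or `"ring"`.
#' @export
#' @examples
#' subarc_dominant_angle(c(0, 0), c(40, 12))  # "gantry"
#' subarc_dominant_angle(c(0, 0), c(8, 24))   # "ring"
subarc_dominant_angle <- function(from, to) {
  dg <- abs(to[1] - from[1])
  dr <- abs(to[2] - from[2])
  if (dg == 0 && dr == 0)
    stop("degenerate sub-arc: zero span on both axes")
  if (dg >= dr) "gantry" else "ring"
}

#' Validate a wave trajectory against the rule set
#'
#' Checks every sub-arc of `traj` against `rules` and, optionally, against a
#' list of forbidden rectangles in (gantry, ring) space standing in for the
#' vendor's ring--table collision map. Violations are returned as data, not
#' raised as errors.
#'
#' Rules checked per sub-arc: non-degenerate (consecutive MPs distinct);
#' dominant span a multiple of `dominant_multiple`; dominant span at least
#' `min_subarc_span`; ring-span/gantry-span ratio at most
#' `max_ring_per_gantry`; sub-arc segment outside every forbidden zone.
#' Trajectory-level: gantry monotone (non-reversing; only the ring may change
#' direction at MPs) and ring within the trajectory's range.
#'
#' @param traj A [wave_trajectory()].
#' @param rules A [trajectory_rules()].
#' @param forbidden_zones Optional list of rectangles, each
#'   `c(gantry_min, gantry_max, ring_min, ring_max)` in degrees.
#' @return A data frame of class `"trajectory_validation"` with columns
#'   `subarc` (index, `NA` for trajectory-level rules), `rule` and `message`;
#'   zero rows means the trajectory is valid.
#' @export
#' @examples
#' tr <- wave_trajectory(c(0, 20), c(0, 28))
#' validate_trajectory(tr)  # ring/gantry ratio 1.4 > 1: one violation
validate_trajectory <- function(traj, rules = trajectory_rules(),
                                forbidden_zones = NULL) {
  stopifnot(inherits(traj, "wave_trajectory"),
            inherits(rules, "trajectory_rules"))
  sp <- subarc_spans(traj)
  v <- list()
  add <- function(subarc, rule, message)
    v[[length(v) + 1L]] <<- data.frame(subarc = subarc, rule = rule,
                                       message = message)
  tol <- 1e-9

  dg <- diff(traj$mp$gantry)
  if (any(dg > 0) && any(dg < 0))
    add(NA_integer_, "gantry_monotone",
        "gantry reverses direction along the trajectory; only the ring may")
  out_ring <- which(traj$mp$ring < traj$ring_range[1] - tol |
                    traj$mp$ring > traj$ring_range[2] + tol)
  for (i in out_ring)
    add(NA_integer_, "ring_range",
        sprintf("MP %d ring %g outside [%g, %g]", i, traj$mp$ring[i],
                traj$ring_range[1], traj$ring_range[2]))

  for (i in seq_len(nrow(sp))) {
    if (sp$ag[i] < tol && sp$ar[i] < tol) {
      add(i, "degenerate", "consecutive manipulation points are identical")
      next
    }
    dom <- max(sp$ag[i], sp$ar[i])
    m <- dom / rules$dominant_multiple
    if (abs(m - round(m)) > tol)
      add(i, "dominant_multiple",
          sprintf("dominant span %g deg is not a multiple of %g deg",
                  dom, rules$dominant_multiple))
    if (dom < rules$min_subarc_span - tol)
      add(i, "min_span",
          sprintf("dominant span %g deg below minimum %g deg",
                  dom, rules$min_subarc_span))
    if (sp$ag[i] < tol) {
      if (sp$ar[i] > tol)
        add(i, "ring_ratio", "ring rotates with zero gantry span")
    } else if (sp$ar[i] / sp$ag[i] > rules$max_ring_per_gantry + tol) {
      add(i, "ring_ratio",
          sprintf("ring/gantry span ratio %.3f exceeds %g",
                  sp$ar[i] / sp$ag[i], rules$max_ring_per_gantry))
    }
    if (!is.null(forbidden_zones)) {
      a <- c(traj$mp$gantry[i], traj$mp$ring[i])
      b <- c(traj$mp$gantry[i + 1L], traj$mp$ring[i + 1L])
      for (z in forbidden_zones) {
        if (segment_hits_rect(a, b, z))
          add(i, "forbidden_zone",
              sprintf("sub-arc crosses forbidden zone [%g,%g]x[%g,%g]",
                      z[1], z[2], z[3], z[4]))
      }
    }
  }
  res <- if (length(v)) do.call(rbind, v) else
    data.frame(subarc = integer(), rule = character(), message = character())
  class(res) <- c("trajectory_validation", "data.frame")
  res
}

#' @export
print.trajectory_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Trajectory valid: no rule violations\n")
  } else {
    cat(sprintf("Trajectory violates %d rule(s):\n", nrow(x)))
    print.data.frame(x, row.names = FALSE, ...)
  }
  invisible(x)
}

# Liang-Barsky style segment vs axis-aligned rectangle intersection.
# rect = c(xmin, xmax, ymin, ymax); touching the boundary counts as a hit.
segment_hits_rect <- function(a, b, rect) {
  d <- b - a
  t0 <- 0; t1 <- 1
  p <- c(-d[1], d[1], -d[2], d[2])
  q <- c(a[1] - rect[1], rect[2] - a[1], a[2] - rect[3], rect[4] - a[2])
  for (k in 1:4) {
    if (abs(p[k]) < 1e-12) {
      if (q[k] < 0) return(FALSE)
    } else {
      t <- q[k] / p[k]
      if (p[k] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

#' Euclidean path length of a wave trajectory
#'
#' Total path length in degrees of combined gantry--ring motion:
#' `sum over sub-arcs of sqrt(dgantry^2 + dring^2)`. The planner spaces beams
#' along this norm rather than along the gantry span alone, so a coplanar
#' trajectory (constant ring) has path length equal to its gantry span.
#'
#' @param traj A [wave_trajectory()].
#' @return Path length in degrees (non-negative; additive over concatenation).
#' @export
#' @examples
#' path_length(wave_trajectory(c(0, 30), c(0, 40)))  # 50
path_length <- function(traj) {
  stopifnot(inherits(traj, "wave_trajectory"))
  sp <- subarc_spans(traj)
  sum(sqrt(sp$ag^2 + sp$ar^2))
}

# cumulative Euclidean norm at each MP; internal
mp_cumnorm <- function(traj) {
  sp <- subarc_spans(traj)
  c(0, cumsum(sqrt(sp$ag^2 + sp$ar^2)))
}

# angles at given cumulative norms (vectorized); linear within each sub-arc
angles_at_norm <- function(traj, u) {
  cum <- mp_cumnorm(traj)
  L <- diff(cum)
  k <- findInterval(u, cum, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(L))
  f <- (u - cum[k]) / L[k]
  f[!is.finite(f)] <- 0
  data.frame(
    gantry = traj$mp$gantry[k] + f * diff(traj$mp$gantry)[k],
    ring   = traj$mp$ring[k]   + f * diff(traj$mp$ring)[k])
}

#' Discretize a wave trajectory into beam angles
#'
#' Places beam positions along the trajectory at (near-)uniform Euclidean-norm
#' spacing per sub-arc. For a sub-arc of norm `L` the number of segments is
#' `n = max(1, round_half_up(L / beam_spacing))`, giving an actual spacing
#' `L / n` as close to `beam_spacing` as the span allows; manipulation points
#' are always beam positions, each appearing exactly once. Angles of interior
#' beams are linearly interpolated in (gantry, ring) within the sub-arc. A
#' sub-arc shorter than the spacing contributes no interior beams.
#'
#' @param traj A [wave_trajectory()].
#' @param rules A [trajectory_rules()]; `beam_spacing` is used.
#' @param validate Check `traj` against `rules` first and fail on violations.
#'   Default `TRUE`.
#' @return Object of class `"beam_set"`: a data frame with columns `gantry`,
#'   `ring`, `norm` (cumulative Euclidean norm, strictly increasing) and
#'   `subarc`, with the trajectory attached as attribute `trajectory`.
#' @export
#' @examples
#' tr <- wave_trajectory(c(0, 48), c(0, 24))  # one sub-arc of norm ~53.7
#' discretize_beams(tr)
discretize_beams <- function(traj, rules = trajectory_rules(),
                             validate = TRUE) {
  stopifnot(inherits(traj, "wave_trajectory"),
            inherits(rules, "trajectory_rules"))
  if (validate) {
    rep <- validate_trajectory(traj, rules)
    if (nrow(rep) > 0)
      stop("trajectory violates rules (",
           paste(unique(rep$rule), collapse = ", "),
           "); see validate_trajectory()")
  }
  cum <- mp_cumnorm(traj)
  L <- diff(cum)
  out <- list()
  for (k in seq_along(L)) {
    n <- max(1L, as.integer(floor(L[k] / rules$beam_spacing + 0.5)))
    u <- cum[k] + L[k] * seq(0, 1, length.out = n + 1L)
    if (k < length(L)) u <- u[-length(u)]  # shared MP kept once
    out[[k]] <- data.frame(norm = u, subarc = k)
  }
  pos <- do.call(rbind, out)
  ang <- angles_at_norm(traj, pos$norm)
  beams <- data.frame(gantry = ang$gantry, ring = ang$ring,
                      norm = pos$norm, subarc = pos$subarc)
  attr(beams, "trajectory") <- traj
  class(beams) <- c("beam_set", "data.frame")
  beams
}

#' Expand beam angles into control points
#'
#' The planner keeps exactly two control points (CPs) per beam angle,
#' distributed evenly between neighbouring beams: each beam at cumulative
#' norm `u` yields CPs at `u - gap_left/4` and `u + gap_right/4`, where
#' `gap_left`/`gap_right` are the norms to the adjacent beams (the single
#' adjacent gap at the trajectory ends), clamped to the trajectory endpoints.
#' CP angles are linearly interpolated along the trajectory.
#'
#' @param beams A `"beam_set"` from [discretize_beams()].
#' @return Data frame of class `"control_point_set"` with columns `gantry`,
#'   `ring`, `norm` (strictly increasing) and `beam` (owning beam index);
#'   `2 * nrow(beams)` rows.
#' @export
#' @examples
#' tr <- wave_trajectory(c(0, 48), c(0, 0))
#' build_control_points(discretize_beams(tr))  # beams {0,24,48} -> 6 CPs
build_control_points <- function(beams) {
  stopifnot(inherits(beams, "beam_set"), nrow(beams) >= 2)
  traj <- attr(beams, "trajectory")
  u <- beams$norm
  gaps <- diff(u)
  gl <- c(gaps[1], gaps)          # gap to the left of beam i
  gr <- c(gaps, gaps[length(gaps)])  # gap to the right
  lo <- pmax(u - gl / 4, u[1])
  hi <- pmin(u + gr / 4, u[length(u)])
  norms <- as.vector(rbind(lo, hi))
  if (any(diff(norms) <= 0))
    stop("control points are not strictly ordered; degenerate beam spacing")
  ang <- angles_at_norm(traj, norms)
  cp <- data.frame(gantry = ang$gantry, ring = ang$ring, norm = norms,
                   beam = rep(seq_len(nrow(beams)), each = 2L))
  attr(cp, "trajectory") <- traj
  class(cp) <- c("control_point_set", "data.frame")
  cp
}
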