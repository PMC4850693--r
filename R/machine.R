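#' Machine constraint set for an O-ring gantry--ring linac
#'
#' Axis-speed ranges, the discrete dose-rate look-up table and the
#' manipulation-point stop behaviour used by both delivery-time models.
#' Defaults match the published machine envelope: gantry 0.1--6 deg/s, ring
#' 0.1--2.5 deg/s, dose rate selectable from a discrete table within 150--400
#' MU/min, MLC leaf speed up to 4 cm/s at isocenter, a 0.1 s mechanical stop
#' at each manipulation point during which the dose rate dips to about
#' 100 MU/min. The exact table entries are not published beyond the range;
#' the default is a 50 MU/min grid and is fully configurable.
#'
#' @param gantry_speed Length-2 numeric, deg/s range. Default `c(0.1, 6)`.
#' @param ring_speed Length-2 numeric, deg/s range. Default `c(0.1, 2.5)`.
#' @param dose_rate_table Ascending MU/min values within \[150, 400\].
#' @param leaf_speed_max Max MLC leaf speed, cm/s at isocenter. Default 4.
#' @param mp_stop_duration Stop length at each interior MP, s. Default 0.1.
#' @param mp_ramp_dose_rate Dose rate held during an MP stop, MU/min.
#'   Default 100.
#' @return Object of class `"machine_constraints"`.
#' @export
machine_constraints <- function(gantry_speed = c(0.1, 6),
                                ring_speed = c(0.1, 2.5),
                                dose_rate_table = seq(150, 400, by = 50),
                                leaf_speed_max = 4,
                                mp_stop_duration = 0.1,
                                mp_ramp_dose_rate = 100) {
  stopifnot(length(gantry_speed) == 2, length(ring_speed) == 2,
            all(gantry_speed > 0), all(ring_speed > 0),
            gantry_speed[1] < gantry_speed[2],
            ring_speed[1] < ring_speed[2],
            length(dose_rate_table) >= 1,
            !is.unsorted(dose_rate_table, strictly = TRUE),
            all(dose_rate_table > 0),
            leaf_speed_max > 0, mp_stop_duration >= 0,
            mp_ramp_dose_rate >= 0)
  structure(list(gantry_speed = as.numeric(gantry_speed),
                 ring_speed = as.numeric(ring_speed),
                 dose_rate_table = as.numeric(dose_rate_table),
                 leaf_speed_max = leaf_speed_max,
                 mp_stop_duration = mp_stop_duration,
                 mp_ramp_dose_rate = mp_ramp_dose_rate),
            class = "machine_constraints")
}

#' Deliverable arc plan: control points, MU weights and MLC apertures
#'
#' Couples a control-point sequence on a wave trajectory with per-CP monitor
#' unit (MU) weights and, optionally, MLC apertures, forming the unit both
#' time solvers and the QA tools operate on.
#'
#' @param control_points A `"control_point_set"` from
#'   [build_control_points()] (or a data frame with `gantry`, `ring`, `norm`
#'   plus a `trajectory` attribute).
#' @param mu_weights Non-negative MU per control point; their sum is the plan
#'   total MU.
#' @param apertures Optional list of [mlc_aperture()] objects, one per CP.
#' @param constraints A [machine_constraints()] set.
#' @return Object of class `"delivery_plan"` with elements `trajectory`, `cp`
#'   (data frame incl. `mu_weight`), `apertures`, `total_mu`, `constraints`
#'   and logical `constant_mu_per_cp`.
#' @export
delivery_plan <- function(control_points, mu_weights, apertures = NULL,
                          constraints = machine_constraints()) {
  traj <- attr(control_points, "trajectory")
  if (is.null(traj)) stop("control_points must carry a trajectory attribute")
  n <- nrow(control_points)
  if (length(mu_weights) != n)
    stop("mu_weights must have one entry per control point")
  if (any(mu_weights < 0) || any(!is.finite(mu_weights)))
    stop("mu_weights must be finite and non-negative")
  if (!is.null(apertures) && length(apertures) != n)
    stop("apertures must have one entry per control point")
  cp <- as.data.frame(control_points)[c("gantry", "ring", "norm")]
  cp$mu_weight <- as.numeric(mu_weights)
  structure(list(trajectory = traj, cp = cp, apertures = apertures,
                 total_mu = sum(mu_weights), constraints = constraints,
                 constant_mu_per_cp =
                   diff(range(mu_weights)) < 1e-9 * max(mu_weights, 1)),
            class = "delivery_plan")
}

#' @export
print.delivery_plan <- function(x, ...) {
  cat(sprintf(
    "Delivery plan: %d control points on %d sub-arcs, %.1f MU total%s\n",
    nrow(x$cp), nrow(x$trajectory$mp) - 1L, x$total_mu,
    if (x$constant_mu_per_cp) " (constant MU per CP)" else ""))
  invisible(x)
}

# Per sub-arc gantry span, ring span and MU (CPs assigned to the sub-arc
# containing their cumulative norm; a CP on a boundary belongs to the
# preceding sub-arc, the very first to sub-arc 1). Internal.
plan_subarcs <- function(plan) {
  traj <- plan$trajectory
  cum <- mp_cumnorm(traj)
  sp <- subarc_spans(traj)
  k <- findInterval(plan$cp$norm, cum, rightmost.closed = TRUE,
                    left.open = TRUE)
  k <- pmin(pmax(k, 1L), nrow(sp))
  mu <- vapply(seq_len(nrow(sp)),
               function(i) sum(plan$cp$mu_weight[k == i]), numeric(1))
  data.frame(gantry_span = sp$ag, ring_span = sp$ar, mu = mu)
}

# Fastest feasible constant gantry speed given per-sub-arc ring coupling.
# Returns list(v_hi, v_lo) or stops naming the binding constraint.
constant_speed_window <- function(sub, mc) {
  if (any(sub$gantry_span <= 0))
    stop("infeasible plan: sub-arc with zero gantry span cannot be driven ",
         "at a constant gantry speed (binding constraint: gantry span)")
  ratio <- sub$ring_span / sub$gantry_span
  v_hi <- min(mc$gantry_speed[2],
              if (any(ratio > 0)) min(mc$ring_speed[2] / ratio[ratio > 0])
              else Inf)
  v_lo <- max(mc$gantry_speed[1],
              if (any(ratio > 0)) max(mc$ring_speed[1] / ratio[ratio > 0])
              else 0)
  if (v_lo > v_hi + 1e-12)
    stop("infeasible plan: no constant gantry speed satisfies both ring ",
         "speed bounds (binding constraint: ring speed range)")
  list(v_hi = v_hi, v_lo = v_lo)
}

#' Conservative planner delivery-time estimate
#'
#' Emulates the treatment planning system's time model: one constant gantry
#' speed and one constant dose rate over the whole arc (so MU per control
#' point stays constant), with only the ring speed modulated per sub-arc
#' through the fixed ring/gantry span ratio. The returned beam-on time is the
#' smallest `T` such that `v_g = total_gantry_span / T` is within the gantry
#' range, every implied ring speed `v_g * ring_span/gantry_span` is within
#' the ring range (or zero), and a dose-rate table entry `DR` with
#' `total_mu/DR*60 <= T` exists. Operationally: take the ring-coupled fastest
#' gantry speed, snap the required dose rate up to the nearest table entry,
#' and set `T = max(motion time, total_mu*60/DR)`.
#'
#' @param plan A [delivery_plan()].
#' @param mc A [machine_constraints()] set; defaults to the plan's.
#' @return Object of class `"time_estimate"`: `beam_on_time` (s),
#'   `gantry_speed` (deg/s), `dose_rate` (MU/min table entry),
#'   `ring_speeds` (deg/s per sub-arc), `motion_time`, `mu_time`.
#' @export
#' @examples
#' tr <- wave_trajectory(c(90, 270), c(0, 0))
#' cp <- build_control_points(discretize_beams(tr))
#' pl <- delivery_plan(cp, rep(300 / nrow(cp), nrow(cp)))
#' tps_time_estimate(pl)  # dose-rate limited: 45 s at 4 deg/s, 400 MU/min
tps_time_estimate <- function(plan, mc = plan$constraints) {
  stopifnot(inherits(plan, "delivery_plan"),
            inherits(mc, "machine_constraints"))
  sub <- plan_subarcs(plan)
  win <- constant_speed_window(sub, mc)
  G <- sum(sub$gantry_span)
  t_motion <- G / win$v_hi
  tab <- mc$dose_rate_table
  dr_max <- tab[length(tab)]
  needed <- plan$total_mu * 60 / t_motion
  idx <- which(tab >= needed - 1e-9)
  dr <- if (length(idx)) tab[idx[1]] else dr_max
  t_total <- max(t_motion, plan$total_mu * 60 / dr)
  v_g <- G / t_total
  if (v_g < win$v_lo - 1e-12)
    stop("infeasible plan: dose-rate-limited time pushes the gantry below ",
         "its minimum speed (binding constraint: gantry/ring minimum speed)")
  structure(list(beam_on_time = t_total, gantry_speed = v_g, dose_rate = dr,
                 ring_speeds = v_g * sub$ring_span / sub$gantry_span,
                 motion_time = t_motion,
                 mu_time = plan$total_mu * 60 / dr),
            class = "time_estimate")
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf(
    "Planner time estimate: %.2f s beam-on (gantry %.3f deg/s, %g MU/min)\n",
    x$beam_on_time, x$gantry_speed, x$dose_rate))
  invisible(x)
}

#' Fastest-delivery controller emulation
#'
#' Emulates the machine controller, which re-selects gantry speed, ring speed
#' and dose rate independently at every manipulation point so that each
#' sub-arc is delivered as fast as its own motion and MU allow: sub-arc time
#' `t = max(motion-limited time, MU*60/max dose rate)`, with the
#' motion-limited time set by the gantry cap and the ring-coupling cap. The
#' highest dose rate is selected by default and decreased (to the table entry
#' giving a simultaneous finish) when axis speed is the limiting factor.
#' Between sub-arcs the axes stop for `mp_stop_duration` seconds while the
#' dose rate ramps down to `mp_ramp_dose_rate`; MU delivered during a stop is
#' debited from the following sub-arc, so the cumulative MU of the trace
#' matches the plan. With `mp_beam_hold = TRUE` the beam is held (zero dose)
#' during stops instead.
#'
#' If a sub-arc is so MU-limited that moving at the minimum axis speeds would
#' still finish the motion early, the axes travel at their slowest in-range
#' speeds and then hold (speed exactly 0) while the beam finishes.
#'
#' @param plan A [delivery_plan()].
#' @param mc A [machine_constraints()] set; defaults to the plan's.
#' @param mp_beam_hold Hold the beam (0 MU) during MP stops. Default `FALSE`.
#' @param sample_rate Trace sampling rate, Hz. Default 100 (LogFile-style).
#' @param emit_trace Emit the sampled trace (set `FALSE` for timing-only
#'   studies). Default `TRUE`.
#' @return Object of class `"controller_result"`: `beam_on_time` (s, motion
#'   time incl. MP stops), `subarc_times`, `dose_rates` (selected table entry
#'   per sub-arc), `gantry_speeds`, `ring_speeds`, and `trace` (a
#'   `"delivery_trace"` data frame with columns `t`, `gantry`, `ring`,
#'   `gantry_speed`, `ring_speed`, `dose_rate`, `cumulative_mu`, `phase`) or
#'   `NULL`.
#' @export
controller_simulate <- function(plan, mc = plan$constraints,
                                mp_beam_hold = FALSE, sample_rate = 100,
                                emit_trace = TRUE) {
  stopifnot(inherits(plan, "delivery_plan"),
            inherits(mc, "machine_constraints"))
  sub <- plan_subarcs(plan)
  n_sub <- nrow(sub)
  tab <- mc$dose_rate_table
  dr_max <- tab[length(tab)]
  ramp_mu_full <- if (mp_beam_hold) 0 else
    mc$mp_ramp_dose_rate * mc$mp_stop_duration / 60

  segs <- list()   # t_len, vg, vr, dr_trace, mu, phase, dg, dr_ang
  times <- numeric(n_sub); sel_dr <- numeric(n_sub)
  vgs <- numeric(n_sub); vrs <- numeric(n_sub)
  for (k in seq_len(n_sub)) {
    g <- sub$gantry_span[k]; r <- sub$ring_span[k]
    mu_k <- sub$mu[k]
    if (k > 1) mu_k <- max(0, mu_k - min(ramp_mu_full, mu_k))
    # fastest in-range motion
    caps <- c(if (g > 0) g / mc$gantry_speed[2],
              if (r > 0) r / mc$ring_speed[2])
    if (is.null(caps))
      stop(sprintf("infeasible sub-arc %d: zero span on both axes", k))
    t_motion <- max(caps)
    t_mu <- mu_k * 60 / dr_max
    t_k <- max(t_motion, t_mu)
    # slowest in-range motion (for MU-limited holds)
    t_slow <- min(c(if (g > 0) g / mc$gantry_speed[1],
                    if (r > 0) r / mc$ring_speed[1]))
    t_move <- min(t_k, t_slow)
    vg <- if (g > 0) g / t_move else 0
    vr <- if (r > 0) r / t_move else 0
    if (g > 0 && (vg > mc$gantry_speed[2] + 1e-12))
      stop(sprintf("infeasible sub-arc %d: gantry speed bound", k))
    if (r > 0 && (vr > mc$ring_speed[2] + 1e-12))
      stop(sprintf("infeasible sub-arc %d: ring speed bound", k))
    dr_trace <- if (t_k > 0) mu_k * 60 / t_k else 0
    need <- dr_trace
    idx <- which(tab >= need - 1e-9)
    sel_dr[k] <- if (length(idx)) tab[idx[1]] else dr_max
    times[k] <- t_k; vgs[k] <- vg; vrs[k] <- vr
    sg <- diff(plan$trajectory$mp$gantry)[k]
    sr <- diff(plan$trajectory$mp$ring)[k]
    segs[[length(segs) + 1L]] <- data.frame(
      t_len = t_move, vg = vg, vr = vr, dr = dr_trace,
      mu = dr_trace * t_move / 60,
      dg = sg, dr_ang = sr, phase = "subarc")
    if (t_k > t_move + 1e-12) {  # MU-limited hold: axes parked, beam on
      segs[[length(segs) + 1L]] <- data.frame(
        t_len = t_k - t_move, vg = 0, vr = 0, dr = dr_trace,
        mu = dr_trace * (t_k - t_move) / 60,
        dg = 0, dr_ang = 0, phase = "subarc")
    }
    if (k < n_sub && mc$mp_stop_duration > 0) {
      stop_dr <- if (mp_beam_hold) 0 else mc$mp_ramp_dose_rate
      segs[[length(segs) + 1L]] <- data.frame(
        t_len = mc$mp_stop_duration, vg = 0, vr = 0, dr = stop_dr,
        mu = min(ramp_mu_full, sub$mu[k + 1L]),
        dg = 0, dr_ang = 0, phase = "mp_stop")
    }
  }
  segs <- do.call(rbind, segs)
  total_time <- sum(segs$t_len)
  res <- list(beam_on_time = total_time, subarc_times = times,
              dose_rates = sel_dr, gantry_speeds = vgs, ring_speeds = vrs,
              mp_stop_total = (n_sub - 1L) * mc$mp_stop_duration,
              total_mu_delivered = sum(segs$mu))
  if (emit_trace)
    res$trace <- sample_trace(segs, plan, sample_rate)
  class(res) <- "controller_result"
  res
}

# Sample piecewise-constant segments at sample_rate Hz. Internal.
sample_trace <- function(segs, plan, sample_rate) {
  t_end <- cumsum(segs$t_len)
  t_start <- c(0, t_end[-length(t_end)])
  g0 <- plan$trajectory$mp$gantry[1]
  r0 <- plan$trajectory$mp$ring[1]
  # signed angular rates per segment
  rate_g <- ifelse(segs$t_len > 0, segs$dg / segs$t_len, 0)
  rate_r <- ifelse(segs$t_len > 0, segs$dr_ang / segs$t_len, 0)
  g_start <- g0 + c(0, cumsum(segs$dg))[-nrow(segs) - 1L]
  r_start <- r0 + c(0, cumsum(segs$dr_ang))[-nrow(segs) - 1L]
  mu_start <- c(0, cumsum(segs$mu))[-nrow(segs) - 1L]
  total <- t_end[length(t_end)]
  t <- seq(0, total, by = 1 / sample_rate)
  k <- findInterval(t, t_start, rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1L), nrow(segs))
  dt <- t - t_start[k]
  tr <- data.frame(
    t = t,
    gantry = g_start[k] + rate_g[k] * dt,
    ring = r_start[k] + rate_r[k] * dt,
    gantry_speed = segs$vg[k],
    ring_speed = segs$vr[k],
    dose_rate = segs$dr[k],
    cumulative_mu = mu_start[k] + segs$dr[k] * dt / 60,
    phase = segs$phase[k])
  attr(tr, "sample_rate") <- sample_rate
  attr(tr, "total_time") <- total
  attr(tr, "total_mu") <- sum(segs$mu)
  class(tr) <- c("delivery_trace", "data.frame")
  tr
}

#' Summary statistics of a delivery trace
#'
#' Time-weighted means of axis speeds and dose rate over beam-on samples.
#' Manipulation-point stop samples are excluded from the speed and dose-rate
#' means but included in the total time; MU bookkeeping uses the exact
#' segment totals.
#'
#' @param trace A `"delivery_trace"` from [controller_simulate()].
#' @return List: `mean_gantry_speed`, `mean_ring_speed` (deg/s),
#'   `mean_dose_rate` (MU/min), `total_time` (s), `total_mu` (MU).
#' @export
summarize_trace <- function(trace) {
  stopifnot(inherits(trace, "delivery_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  on <- trace$phase == "subarc"
  list(mean_gantry_speed = mean(trace$gantry_speed[on]),
       mean_ring_speed = mean(trace$ring_speed[on]),
       mean_dose_rate = mean(trace$dose_rate[on]),
       total_time = attr(trace, "total_time"),
       total_mu = attr(trace, "total_mu"))
}

#' Planner time overestimation relative to actual delivery
#'
#' The conservative constant-speed/constant-dose-rate planner model typically
#' overestimates delivery time because the controller runs each sub-arc at
#' its own fastest settings. Returns `100 * (T_tps - T_actual) / T_tps`.
#'
#' @param tps A `"time_estimate"` or its beam-on time in seconds.
#' @param actual_time Actual beam-on time, seconds.
#' @return Overestimation in percent (negative if the planner was faster).
#' @export
#' @examples
#' time_overestimation(45, 33.3)  # 26 percent
time_overestimation <- function(tps, actual_time) {
  t_tps <- if (inherits(tps, "time_estimate")) tps$beam_on_time else tps
  stopifnot(t_tps > 0, actual_time > 0)
  100 * (t_tps - actual_time) / t_tps
}

#' MLC leaf-speed feasibility of a timed control-point sequence
#'
#' For each adjacent control-point pair and each leaf of each bank the
#' required speed is `|position change| / segment time`; leaves exceeding the
#' machine's maximum leaf speed are flagged. A zero-length segment with
#' nonzero leaf motion is an infinite-speed violation.
#'
#' @param plan A [delivery_plan()] carrying apertures.
#' @param segment_times Seconds available between consecutive CPs
#'   (length `nCP - 1`).
#' @param mc A [machine_constraints()] set; defaults to the plan's.
#' @return Data frame of violations: `gap`, `bank` ("left"/"right"), `leaf`,
#'   `required_speed` (cm/s; `Inf` for zero-time motion). Zero rows when all
#'   leaf travel is feasible.
#' @export
leaf_travel_feasibility <- function(plan, segment_times,
                                    mc = plan$constraints) {
  stopifnot(inherits(plan, "delivery_plan"))
  if (is.null(plan$apertures)) stop("plan carries no apertures")
  n <- length(plan$apertures)
  if (length(segment_times) != n - 1L)
    stop("segment_times must have one entry per control-point gap")
  out <- list()
  for (i in seq_len(n - 1L)) {
    a <- plan$apertures[[i]]; b <- plan$apertures[[i + 1L]]
    for (bank in c("left", "right")) {
      d <- abs(b[[bank]] - a[[bank]])
      spd <- if (segment_times[i] > 0) d / segment_times[i] else
        ifelse(d == 0, 0, Inf)
      bad <- which(spd > mc$leaf_speed_max)
      if (length(bad))
        out[[length(out) + 1L]] <- data.frame(
          gap = i, bank = bank, leaf = bad, required_speed = spd[bad])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gap = integer(), bank = character(), leaf = integer(),
               required_speed = numeric())
}
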