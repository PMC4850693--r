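# Seeded synthetic generators: plans, toy dose grids, pseudo-measurements.
# Everything here is a pure function of (parameters, seed); the RNG state of
# the caller is left untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded synthetic delivery plan
#'
#' Builds a rules-conformant wave trajectory (gantry spans drawn from
#' multiples of 4 degrees in \[24, 48\], ring spans multiples of 4 not
#' exceeding the gantry span, ring direction alternating at manipulation
#' points), discretizes it, attaches equal MU per control point and smoothly
#' varying MLC apertures whose inter-CP leaf travel is small enough to be
#' feasible at the machine's leaf-speed limit for any realistic segment
#' timing. `complexity = 0` produces an identical aperture at every CP (so
#' the arc's modulation complexity score is exactly 1); larger values add
#' seeded leaf-position modulation of up to ~2.4 cm at `complexity = 1`.
#'
#' @param seed Integer seed; fixed seed gives identical plans.
#' @param n_subarcs Number of sub-arcs (MPs minus one). Default 4.
#' @param mu_total Total plan MU. Default 300.
#' @param complexity Aperture modulation level in `[0, 1]`. Default 0.3.
#' @param n_leaf Leaf pairs. Default 10.
#' @param leaf_width Leaf width, cm. Default 1.
#' @param rules A [trajectory_rules()] set.
#' @param constraints A [machine_constraints()] set.
#' @return A [delivery_plan()] with apertures.
#' @export
#' @examples
#' pl <- generate_plan(seed = 42, n_subarcs = 3)
#' nrow(validate_trajectory(pl$trajectory))  # 0: valid by construction
generate_plan <- function(seed = 1, n_subarcs = 4, mu_total = 300,
                          complexity = 0.3, n_leaf = 10, leaf_width = 1,
                          rules = trajectory_rules(),
                          constraints = machine_constraints()) {
  stopifnot(n_subarcs >= 1, mu_total >= 0,
            complexity >= 0, complexity <= 1)
  with_seed(seed, {
    m <- rules$dominant_multiple
    lo <- ceiling(rules$min_subarc_span / m) * m
    budget <- 356 - 2  # keep the whole gantry path inside [0, 360)
    if (n_subarcs * lo > budget)
      stop("too many sub-arcs for the gantry range at these rules")
    g_spans <- numeric(n_subarcs)
    for (k in seq_len(n_subarcs)) {
      hi <- min(lo + 6 * m, budget - (n_subarcs - k) * lo)
      g_spans[k] <- sample(rep(seq(lo, hi, by = m), 2), 1)
      budget <- budget - g_spans[k]
    }
    gantry <- cumsum(c(2, g_spans))
    ring <- numeric(n_subarcs + 1)
    dir <- 1
    for (k in seq_len(n_subarcs)) {
      # ring span is 0 (coplanar sub-arc) or at least half the gantry span:
      # shallow nonzero tilts would force the coupled ring speed below the
      # machine minimum on dose-rate-limited arcs
      headroom <- if (dir > 0) 60 - ring[k] else ring[k] + 60
      span_max <- min(g_spans[k], headroom)
      lo_r <- ceiling(g_spans[k] / 2 / m) * m
      hi_r <- floor(span_max / m) * m
      choices <- c(0, if (hi_r >= lo_r) seq(lo_r, hi_r, by = m))
      ring[k + 1] <- ring[k] + dir * sample(rep(choices, 2), 1)
      dir <- -dir
    }
    traj <- wave_trajectory(gantry, ring)
    cp <- build_control_points(discretize_beams(traj, rules))
    n_cp <- nrow(cp)
    mu_w <- rep(mu_total / n_cp, n_cp)
    # apertures: baseline rectangle, seeded smooth modulation; per-CP leaf
    # travel stays within ~0.6 cm * complexity so leaf speed is never binding
    base_l <- rep(-3, n_leaf); base_r <- rep(3, n_leaf)
    phase_l <- stats::runif(n_leaf, 0, 2 * pi)
    phase_r <- stats::runif(n_leaf, 0, 2 * pi)
    amp <- 1.2 * complexity
    aps <- lapply(seq_len(n_cp), function(i) {
      th <- 2 * pi * i / n_cp
      l <- base_l + amp * sin(3 * th + phase_l)
      r <- base_r + amp * sin(3 * th + phase_r)
      r <- pmax(r, l + 0.5)  # keep every pair open
      mlc_aperture(l, r, leaf_width)
    })
    delivery_plan(cp, mu_w, apertures = aps, constraints = constraints)
  })
}

#' Toy dose engine for synthetic plans
#'
#' Deliberately non-physical stand-alone dose model used only to make the QA
#' chain testable end to end: for each control point the MLC aperture is
#' projected along the beam direction given by its gantry/ring angles, edges
#' are smoothed with a Gaussian penumbra, attenuated exponentially with depth
#' along the beam axis, scaled by the CP's MU and summed. Dose is linear in
#' MU and rotates rigidly with the plan's angles. It is **not** a clinical
#' dose algorithm (no scatter, heterogeneity or source model).
#'
#' @param plan A [delivery_plan()] with apertures.
#' @param shape Grid shape (voxels per axis). Default `c(21, 21, 21)`.
#' @param spacing Voxel spacing, mm. Default `c(5, 5, 5)`.
#' @param sigma Penumbra sigma, mm. Default 6.
#' @param mu_atten Attenuation coefficient, 1/mm. Default 0.004.
#' @param dose_per_mu Gy per MU on the central axis. Default 0.01.
#' @return A [dose_grid()] centered on the isocenter (origin at the grid
#'   corner so the isocenter is the grid center).
#' @export
toy_dose_engine <- function(plan, shape = c(21, 21, 21),
                            spacing = c(5, 5, 5), sigma = 6,
                            mu_atten = 0.004, dose_per_mu = 0.01) {
  stopifnot(inherits(plan, "delivery_plan"))
  if (is.null(plan$apertures)) stop("plan carries no apertures")
  half <- (shape - 1) / 2 * spacing
  origin <- -half
  ax <- lapply(1:3, function(k) origin[k] + (0:(shape[k] - 1)) * spacing[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- numeric(nrow(pts))
  for (i in seq_len(nrow(plan$cp))) {
    mu_i <- plan$cp$mu_weight[i]
    if (mu_i == 0) next
    g <- plan$cp$gantry[i] * pi / 180
    r <- plan$cp$ring[i] * pi / 180
    # frame: beam axis b plus transverse axes (leaf travel e1, leaf width e2)
    Rg <- matrix(c(cos(g), 0, sin(g), 0, 1, 0, -sin(g), 0, cos(g)), 3, 3)
    Rr <- matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3)
    R <- Rr %*% Rg
    e1 <- R %*% c(1, 0, 0); e2 <- R %*% c(0, 1, 0); b <- R %*% c(0, 0, 1)
    xb <- pts %*% e1; yb <- pts %*% e2; zb <- pts %*% b
    ap <- plan$apertures[[i]]
    w <- ap$widths * 10  # cm -> mm
    y_edges <- c(0, cumsum(w)) - sum(w) / 2
    flu <- numeric(nrow(pts))
    for (j in which(ap$open)) {
      fx <- stats::pnorm((xb - ap$left[j] * 10) / sigma) -
            stats::pnorm((xb - ap$right[j] * 10) / sigma)
      fy <- stats::pnorm((yb - y_edges[j]) / sigma) -
            stats::pnorm((yb - y_edges[j + 1]) / sigma)
      flu <- flu + fx * fy
    }
    vals <- vals + mu_i * dose_per_mu * flu * exp(-mu_atten * (zb + half[3]))
  }
  dose_grid(array(vals, dim = shape), origin = origin, spacing = spacing)
}

#' Perturb planned dose into a pseudo-measurement
#'
#' Samples the planned grid at the diode positions (optionally displaced by
#' a rigid systematic shift), applies a global scale error and adds seeded
#' Gaussian noise expressed as a percent of the grid maximum. The zero-noise
#' identity model returns the exact planned samples, so the gamma chain's
#' null case is available by construction.
#'
#' @param planned A [dose_grid()].
#' @param diodes A `"diode_plane_set"` geometry (dose column ignored).
#' @param shift_mm Length-3 rigid shift applied to the sampling positions,
#'   mm. Default `c(0, 0, 0)`.
#' @param scale_pct Global scale error, percent. Default 0.
#' @param noise_sd_pct Gaussian noise SD, percent of grid max. Default 0.
#' @param seed Seed for the noise draw. Default 1.
#' @return A [diode_plane_set()] with measured `dose`.
#' @export
perturb_measurement <- function(planned, diodes, shift_mm = c(0, 0, 0),
                                scale_pct = 0, noise_sd_pct = 0, seed = 1) {
  stopifnot(inherits(planned, "dose_grid"),
            inherits(diodes, "diode_plane_set"))
  pts <- cbind(diodes$x + shift_mm[1], diodes$y + shift_mm[2],
               diodes$z + shift_mm[3])
  d <- interp_dose(planned, pts)
  if (any(is.na(d)))
    stop("diode (after shift) falls outside the planned grid")
  d <- d * (1 + scale_pct / 100)
  if (noise_sd_pct > 0)
    d <- d + with_seed(seed, stats::rnorm(length(d))) *
      noise_sd_pct / 100 * max(planned$values)
  diode_plane_set(diodes$x, diodes$y, diodes$z, dose = pmax(d, 0),
                  plane = diodes$plane)
}
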