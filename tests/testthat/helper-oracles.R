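# Independent oracles, written straight from the defining formulas with
# plain loops; deliberately share no code with the package internals.

# --- modulation complexity ------------------------------------------------

oracle_lsv_bank <- function(p) {
  n <- length(p)
  if (n < 2) return(1)
  pm <- max(p) - min(p)
  if (pm == 0) return(1)
  s <- 0
  for (i in 1:(n - 1)) s <- s + (pm - abs(p[i + 1] - p[i]))
  s / ((n - 1) * pm)
}

# apertures: list of list(left, right, widths); mu_between length n-1
oracle_mcs <- function(apertures, mu_between) {
  n <- length(apertures)
  nl <- length(apertures[[1]]$left)
  # arc maximal aperture (denominator)
  den <- 0
  for (j in 1:nl) {
    open_any <- FALSE; rmax <- -Inf; lmin <- Inf
    for (i in 1:n) {
      a <- apertures[[i]]
      if (a$right[j] > a$left[j]) open_any <- TRUE
      rmax <- max(rmax, a$right[j]); lmin <- min(lmin, a$left[j])
    }
    if (open_any) den <- den + (rmax - lmin) * apertures[[1]]$widths[j]
  }
  lsvs <- numeric(n); aavs <- numeric(n)
  for (i in 1:n) {
    a <- apertures[[i]]
    open <- which(a$right > a$left)
    if (length(open) == 0) { lsvs[i] <- 1; aavs[i] <- 0; next }
    lsvs[i] <- oracle_lsv_bank(a$left[open]) * oracle_lsv_bank(a$right[open])
    num <- 0
    for (j in open) num <- num + (a$right[j] - a$left[j]) * a$widths[j]
    aavs[i] <- num / den
  }
  mu_total <- sum(mu_between)
  s <- 0
  for (i in 1:(n - 1))
    s <- s + (aavs[i] + aavs[i + 1]) / 2 * (lsvs[i] + lsvs[i + 1]) / 2 *
      mu_between[i] / mu_total
  s
}

# seeded random dynamic-MLC arc for oracle-agreement checks
random_arc_fixture <- function(seed) {
  set.seed(seed)
  n_cp <- sample(3:8, 1)
  n_leaf <- sample(4:12, 1)
  w <- stats::runif(1, 0.5, 1.5)
  aps <- lapply(seq_len(n_cp), function(i) {
    left <- stats::runif(n_leaf, -5, 0)
    gap <- pmax(0, stats::runif(n_leaf, -1, 4))  # some pairs closed
    if (all(gap == 0)) gap[1] <- 1
    list(left = left, right = left + gap, widths = rep(w, n_leaf))
  })
  mu <- stats::runif(n_cp - 1, 0.1, 20)
  list(apertures = aps, mu_between = mu)
}

# --- delivery-time exhaustive search --------------------------------------

# planner model: one constant gantry speed from a 0.001 deg/s grid, ring
# speed coupled per sub-arc, dose rate from the table
oracle_tps_time <- function(plan, mc) {
  sub <- wavearc:::plan_subarcs(plan)
  G <- sum(sub$gantry_span)
  v <- seq(mc$gantry_speed[1], mc$gantry_speed[2], by = 0.001)
  ok <- rep(TRUE, length(v))
  for (k in seq_len(nrow(sub))) {
    if (sub$ring_span[k] > 0) {
      vr <- v * sub$ring_span[k] / sub$gantry_span[k]
      ok <- ok & vr >= mc$ring_speed[1] & vr <= mc$ring_speed[2]
    }
  }
  v <- v[ok]
  best <- Inf
  for (dr in mc$dose_rate_table)
    best <- min(best, max(G / max(v), plan$total_mu * 60 / dr))
  best
}

# controller model: each sub-arc independently picks gantry speed, ring
# speed and table dose rate minimizing max(motion, MU) time
oracle_controller_time <- function(plan, mc) {
  sub <- wavearc:::plan_subarcs(plan)
  ramp_mu <- mc$mp_ramp_dose_rate * mc$mp_stop_duration / 60
  total <- 0
  for (k in seq_len(nrow(sub))) {
    mu_k <- sub$mu[k]
    if (k > 1) mu_k <- max(0, mu_k - min(ramp_mu, mu_k))
    vg <- seq(mc$gantry_speed[1], mc$gantry_speed[2], by = 0.001)
    vr <- seq(mc$ring_speed[1], mc$ring_speed[2], by = 0.001)
    tg <- if (sub$gantry_span[k] > 0) min(sub$gantry_span[k] / vg) else 0
    tr <- if (sub$ring_span[k] > 0) min(sub$ring_span[k] / vr) else 0
    best <- Inf
    for (dr in mc$dose_rate_table)
      best <- min(best, max(tg, tr, mu_k * 60 / dr))
    total <- total + best
  }
  total + (nrow(sub) - 1) * mc$mp_stop_duration
}

# --- gamma exhaustive evaluation is exercised through the package's own
#     exhaustive = TRUE switch plus this voxel-only brute force -------------

oracle_gamma_voxels_only <- function(grid, pt, d_meas, dd_abs, dta) {
  d <- dim(grid$values)
  best <- abs(d_meas - wavearc::interp_dose(grid, pt)) / dd_abs
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    r <- c(grid$origin[1] + (i - 1) * grid$spacing[1],
           grid$origin[2] + (j - 1) * grid$spacing[2],
           grid$origin[3] + (k - 1) * grid$spacing[3])
    g <- sqrt(((d_meas - grid$values[i, j, k]) / dd_abs)^2 +
              sum((r - pt)^2) / dta^2)
    best <- min(best, g)
  }
  best
}

# --- small shared fixtures ------------------------------------------------

coplanar_plan <- function(gantry = c(90, 270), mu_total = 300) {
  tr <- wave_trajectory(gantry, rep(0, length(gantry)))
  cp <- build_control_points(discretize_beams(tr))
  delivery_plan(cp, rep(mu_total / nrow(cp), nrow(cp)))
}

gaussian_grid <- function(shape = c(21, 21, 21), spacing = c(5, 5, 5),
                          peak = 2, sigma = 30) {
  org <- -(shape - 1) / 2 * spacing
  ax <- lapply(1:3, function(k) org[k] + (0:(shape[k] - 1)) * spacing[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- peak * exp(-rowSums(pts^2) / (2 * sigma^2))
  dose_grid(array(vals, dim = shape), origin = org, spacing = spacing)
}
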