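# File formats: plans as versioned YAML, dose grids as text with an
# origin/spacing header, structure masks as run-length-encoded text, traces
# and diode sets as CSV. Angles are stored in degrees, lengths in mm except
# MLC positions (cm at isocenter, the aperture interface unit).

PLAN_SCHEMA_VERSION <- 1L

#' Write a delivery plan to a YAML plan file
#'
#' Canonical, versioned, human-readable representation: trajectory block
#' (MPs, ring range), rules block, machine block, per-CP records (gantry,
#' ring, norm, MU weight, left/right banks in cm) and leaf widths.
#' `read_plan(write_plan(x))` reproduces the plan, and re-writing the
#' re-read plan is byte-identical.
#'
#' @param plan A [delivery_plan()].
#' @param path Output path.
#' @param rules Optional [trajectory_rules()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path, rules = trajectory_rules()) {
  stopifnot(inherits(plan, "delivery_plan"))
  doc <- list(
    schema_version = PLAN_SCHEMA_VERSION,
    trajectory = list(
      ring_range = as.list(plan$trajectory$ring_range),
      manipulation_points = lapply(seq_len(nrow(plan$trajectory$mp)),
        function(i) list(gantry = plan$trajectory$mp$gantry[i],
                         ring = plan$trajectory$mp$ring[i]))),
    rules = unclass(rules),
    machine = lapply(unclass(plan$constraints), function(x)
      if (length(x) > 1) as.list(x) else x),
    leaf_widths = if (is.null(plan$apertures)) NULL else
      as.list(plan$apertures[[1]]$widths),
    control_points = lapply(seq_len(nrow(plan$cp)), function(i) {
      rec <- list(gantry = plan$cp$gantry[i], ring = plan$cp$ring[i],
                  norm = plan$cp$norm[i], mu_weight = plan$cp$mu_weight[i])
      if (!is.null(plan$apertures)) {
        rec$left <- as.list(plan$apertures[[i]]$left)
        rec$right <- as.list(plan$apertures[[i]]$right)
      }
      rec
    }))
  doc <- doc[!vapply(doc, is.null, logical(1))]
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a delivery plan from a YAML plan file
#'
#' Validates the schema on load: every missing or malformed field is
#' collected and reported in a single error. Control-point angles are
#' checked to lie on the stored trajectory (interpolated at the stored
#' cumulative norm) within `tolerance` degrees.
#'
#' @param path Path to a plan file written by [write_plan()].
#' @param tolerance Max CP off-trajectory angle, degrees. Default 1e-6.
#' @return A [delivery_plan()].
#' @export
read_plan <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  doc <- yaml::read_yaml(path)
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(!is.null(doc$schema_version), "missing field: schema_version")
  need(!is.null(doc$trajectory$manipulation_points),
       "missing field: trajectory/manipulation_points")
  need(!is.null(doc$control_points), "missing field: control_points")
  if (!is.null(doc$control_points)) {
    for (i in seq_along(doc$control_points)) {
      rec <- doc$control_points[[i]]
      for (f in c("gantry", "ring", "norm", "mu_weight"))
        need(!is.null(rec[[f]]),
             sprintf("control_points[%d]: missing field: %s", i, f))
    }
  }
  if (length(errs))
    stop("plan file schema violations:\n  ", paste(errs, collapse = "\n  "))

  mp <- do.call(rbind, lapply(doc$trajectory$manipulation_points,
                              as.data.frame))
  traj <- wave_trajectory(mp$gantry, mp$ring,
                          ring_range = unlist(doc$trajectory$ring_range))
  cps <- doc$control_points
  cp <- data.frame(
    gantry = vapply(cps, `[[`, numeric(1), "gantry"),
    ring = vapply(cps, `[[`, numeric(1), "ring"),
    norm = vapply(cps, `[[`, numeric(1), "norm"))
  ref <- angles_at_norm(traj, cp$norm)
  off <- pmax(abs(ref$gantry - cp$gantry), abs(ref$ring - cp$ring))
  if (any(off > tolerance))
    stop(sprintf("control point(s) %s lie off the trajectory by up to %g deg",
                 paste(which(off > tolerance), collapse = ", "), max(off)))
  attr(cp, "trajectory") <- traj
  class(cp) <- c("control_point_set", "data.frame")
  aps <- NULL
  if (!is.null(cps[[1]]$left)) {
    widths <- unlist(doc$leaf_widths)
    aps <- lapply(cps, function(rec)
      mlc_aperture(unlist(rec$left), unlist(rec$right), widths))
  }
  mc <- do.call(machine_constraints,
                lapply(doc$machine, function(x) unlist(x)))
  delivery_plan(cp, vapply(cps, `[[`, numeric(1), "mu_weight"),
                apertures = aps, constraints = mc)
}

#' Write / read a dose grid as header + values text
#'
#' Plain-text grid format: `# wavearc dose grid v1`, then `shape`, `origin`
#' (mm, first-voxel center), `spacing` (mm), `unit Gy` header lines, then
#' one value per line in column-major (R array) order.
#'
#' @param grid A [dose_grid()].
#' @param path File path.
#' @return `path` invisibly (write); a [dose_grid()] (read).
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# wavearc dose grid v1",
               paste("shape", paste(dim(grid$values), collapse = " ")),
               paste("origin", paste(format(grid$origin, digits = 15),
                                     collapse = " ")),
               paste("spacing", paste(format(grid$spacing, digits = 15),
                                      collapse = " ")),
               "unit Gy"), con)
  writeLines(format(as.vector(grid$values), digits = 15, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# wavearc dose grid"))
    stop("not a wavearc dose grid file")
  hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines[1:5], value = TRUE)
    as.numeric(strsplit(ln, " ")[[1]][-1])
  }
  shape <- hdr("shape"); origin <- hdr("origin"); spacing <- hdr("spacing")
  vals <- as.numeric(lines[-(1:5)])
  dose_grid(array(vals, dim = shape), origin = origin, spacing = spacing)
}

#' Write / read a structure mask as run-length-encoded text
#'
#' Header (`shape`, `name`) followed by `value count` pairs over the
#' column-major flattened mask.
#'
#' @param mask A [structure_mask()].
#' @param path File path.
#' @param grid The aligned [dose_grid()] (read; defines the lattice).
#' @return `path` invisibly (write); a [structure_mask()] (read).
#' @export
write_structure_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  r <- rle(as.vector(mask$mask))
  writeLines(c("# wavearc structure mask v1",
               paste("shape", paste(dim(mask$mask), collapse = " ")),
               paste("name", mask$name),
               paste(as.integer(r$values), r$lengths)), path)
  invisible(path)
}

#' @rdname write_structure_mask
#' @export
read_structure_mask <- function(path, grid) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# wavearc structure mask"))
    stop("not a wavearc structure mask file")
  shape <- as.integer(strsplit(lines[2], " ")[[1]][-1])
  name <- sub("^name ", "", lines[3])
  pairs <- do.call(rbind, strsplit(lines[-(1:3)], " "))
  flat <- inverse.rle(list(values = as.integer(pairs[, 1]) == 1L,
                           lengths = as.integer(pairs[, 2])))
  structure_mask(array(flat, dim = shape), grid, name = name)
}

#' Export a delivery trace or diode set as CSV
#'
#' @param x A `"delivery_trace"` or `"diode_plane_set"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a delivery trace CSV written by [write_trace_csv()]
#' @param path File path.
#' @param sample_rate Hz (restored as attribute). Default 100.
#' @return A `"delivery_trace"` data frame.
#' @export
read_trace_csv <- function(path, sample_rate = 100) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(tr, "sample_rate") <- sample_rate
  attr(tr, "total_time") <- max(tr$t)
  attr(tr, "total_mu") <- max(tr$cumulative_mu)
  class(tr) <- c("delivery_trace", "data.frame")
  tr
}
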