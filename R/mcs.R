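#' MLC aperture at a control point
#'
#' Opposing-bank leaf positions in cm at isocenter. A leaf pair is *open*
#' when its right position strictly exceeds its left; closed pairs carry no
#' area and are excluded from the leaf-sequence position sets.
#'
#' @param left,right Numeric vectors of per-leaf bank positions, cm at
#'   isocenter, equal length. `right >= left` pairwise.
#' @param widths Leaf-pair widths, cm; recycled if scalar. Default 1.
#' @return Object of class `"mlc_aperture"` with elements `left`, `right`,
#'   `widths`, `open` (logical).
#' @export
mlc_aperture <- function(left, right, widths = 1) {
  if (length(left) != length(right))
    stop("left and right banks must have equal length")
  if (any(right < left))
    stop("right bank positions must not be below left bank positions")
  widths <- rep_len(as.numeric(widths), length(left))
  if (any(widths <= 0)) stop("leaf widths must be positive")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 widths = widths, open = right > left),
            class = "mlc_aperture")
}

#' Dynamic-MLC arc sequence
#'
#' The aperture-per-control-point sequence and the MU delivered between
#' consecutive control points, as consumed by the modulation complexity
#' score.
#'
#' @param apertures List of [mlc_aperture()] objects, one per CP (>= 2).
#' @param mu_between Non-negative MU delivered between consecutive CPs,
#'   length `length(apertures) - 1`.
#' @return Object of class `"arc_sequence"` with `apertures`, `mu_between`,
#'   `mu_total`.
#' @export
arc_sequence <- function(apertures, mu_between) {
  if (length(apertures) < 2) stop("an arc needs at least 2 control points")
  if (length(mu_between) != length(apertures) - 1L)
    stop("mu_between must have length(apertures) - 1 entries")
  if (any(mu_between < 0)) stop("mu_between must be non-negative")
  structure(list(apertures = apertures,
                 mu_between = as.numeric(mu_between),
                 mu_total = sum(mu_between)),
            class = "arc_sequence")
}

#' Convert a delivery plan to an arc sequence
#'
#' Per-gap MU is taken as the midpoint of the adjacent control points' MU
#' weights, rescaled so the gaps carry the plan's total MU (for
#' constant-MU-per-CP plans this is simply uniform weighting).
#'
#' @param plan A [delivery_plan()] carrying apertures.
#' @return An [arc_sequence()].
#' @export
as_arc_sequence <- function(plan) {
  stopifnot(inherits(plan, "delivery_plan"))
  if (is.null(plan$apertures)) stop("plan carries no apertures")
  w <- plan$cp$mu_weight
  mid <- (w[-length(w)] + w[-1]) / 2
  if (sum(mid) > 0) mid <- mid * plan$total_mu / sum(mid)
  arc_sequence(plan$apertures, mid)
}

# Per-bank leaf-sequence variability score; p are the positions of the open
# leaves in index order. Degenerate spreads (N < 2 or all aligned) score 1.
lsv_bank <- function(p) {
  n <- length(p)
  if (n < 2) return(1)
  pos_max <- max(p) - min(p)
  if (pos_max == 0) return(1)
  sum(pos_max - abs(diff(p))) / ((n - 1) * pos_max)
}

#' Leaf sequence variability (LSV)
#'
#' Measures how smoothly leaf positions vary along each bank across the open
#' region. With `p_i` the positions of the `N` open leaves of a bank and
#' `pos_max = max(p) - min(p)`:
#' `LSV_bank = sum_{i<N} (pos_max - |p_{i+1} - p_i|) / ((N-1) * pos_max)`,
#' and `LSV = LSV_left * LSV_right`. A bank with all leaves aligned
#' (`pos_max = 0`) scores 1 by convention. Multiple disjoint open runs are
#' concatenated in leaf-index order.
#'
#' @param aperture An [mlc_aperture()] with at least one open pair.
#' @return LSV in `[0, 1]`.
#' @export
#' @examples
#' lsv(mlc_aperture(left = c(0, 5, 10), right = c(12, 12, 12)))  # 0.5
lsv <- function(aperture) {
  stopifnot(inherits(aperture, "mlc_aperture"))
  if (!any(aperture$open))
    stop("LSV undefined: aperture has no open leaf pair")
  lsv_bank(aperture$left[aperture$open]) *
    lsv_bank(aperture$right[aperture$open])
}

#' Aperture area variability (AAV)
#'
#' Ratio of a control point's open aperture area to the arc's maximal
#' aperture: `sum over open pairs of (right - left) * width` divided by
#' `sum over pairs open anywhere in the arc of
#' (max over CPs of right - min over CPs of left) * width`.
#'
#' @param aperture An [mlc_aperture()] belonging to `arc`.
#' @param arc An [arc_sequence()]; defines the maximal-aperture denominator.
#' @return AAV in `[0, 1]`.
#' @export
aav <- function(aperture, arc) {
  stopifnot(inherits(aperture, "mlc_aperture"),
            inherits(arc, "arc_sequence"))
  den <- arc_max_aperture_area(arc)
  if (den <= 0) stop("AAV undefined: no leaf pair opens anywhere in the arc")
  num <- sum((aperture$right - aperture$left)[aperture$open] *
             aperture$widths[aperture$open])
  num / den
}

# arc-level maximal aperture area (AAV denominator); internal
arc_max_aperture_area <- function(arc) {
  left <- do.call(cbind, lapply(arc$apertures, `[[`, "left"))
  right <- do.call(cbind, lapply(arc$apertures, `[[`, "right"))
  open_any <- apply(do.call(cbind, lapply(arc$apertures, `[[`, "open")),
                    1, any)
  w <- arc$apertures[[1]]$widths
  if (!any(open_any)) return(0)
  env <- apply(right, 1, max) - apply(left, 1, min)
  sum(env[open_any] * w[open_any])
}

#' Modulation complexity score (MCS) of an arc
#'
#' Combines leaf-sequence variability and aperture-area variability over the
#' arc, weighting each control-point gap by its relative MU:
#' `MCS = sum_i ((AAV_i + AAV_{i+1})/2) * ((LSV_i + LSV_{i+1})/2) *
#' mu_between_i / mu_total`. MCS lies in `[0, 1]`; 1 means no modulation
#' (e.g. an identical open rectangle at every CP), lower values mean greater
#' complexity. A CP with every pair closed contributes zero area (AAV 0, LSV
#' taken as the degenerate 1).
#'
#' @param arc An [arc_sequence()] with positive total MU.
#' @return MCS in `[0, 1]`.
#' @export
#' @examples
#' ap <- mlc_aperture(left = rep(-2, 5), right = rep(2, 5))
#' mcs_arc(arc_sequence(rep(list(ap), 4), mu_between = c(10, 20, 30)))  # 1
mcs_arc <- function(arc) {
  stopifnot(inherits(arc, "arc_sequence"))
  if (arc$mu_total <= 0) stop("MCS undefined for an arc with zero total MU")
  lsvs <- vapply(arc$apertures,
                 function(a) if (any(a$open)) lsv(a) else 1, numeric(1))
  aavs <- vapply(arc$apertures, aav, numeric(1), arc = arc)
  n <- length(arc$apertures)
  sum(((aavs[-n] + aavs[-1]) / 2) * ((lsvs[-n] + lsvs[-1]) / 2) *
        arc$mu_between / arc$mu_total)
}
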