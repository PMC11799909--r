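# Data model for VMAT plans: control points, beams, machine limits, plans,
# dose grids and structure sets. All geometry is IEC 61217: leaf tips move
# along IEC-X (mm), leaf-pair boundaries lie on IEC-Y, the pair gap is
# bank_b - bank_a and must be non-negative up to a small tolerance.

#' Interdigitation tolerance for the leaf-gap non-negativity check (mm)
#' @keywords internal
INTERDIGITATION_TOL <- 0.01

#' Machine delivery limits
#'
#' Kinematic limits of the treatment machine used by the segment-time model.
#' Defaults correspond to a TrueBeam-class linac.
#'
#' @param max_gantry_speed maximum gantry rotation speed, deg/s
#' @param max_dose_rate maximum dose rate, MU/min
#' @param max_leaf_speed maximum MLC leaf speed, mm/s
#' @return object of class `machine_limits`
#' @export
machine_limits <- function(max_gantry_speed = 4.8, max_dose_rate = 600,
                           max_leaf_speed = 25) {
  stopifnot(max_gantry_speed > 0, max_dose_rate > 0, max_leaf_speed > 0)
  structure(list(max_gantry_speed = max_gantry_speed,
                 max_dose_rate = max_dose_rate,
                 max_leaf_speed = max_leaf_speed),
            class = "machine_limits")
}

#' Control point of a VMAT arc
#'
#' One sampled machine state: gantry angle, cumulative meterset weight and
#' the positions of both MLC leaf banks plus the jaws.
#'
#' @param index ordinal (0-based, as in DICOM)
#' @param cumulative_meterset_weight fraction of beam MU delivered so far,
#'   in \[0, 1\]
#' @param gantry_angle degrees, in \[0, 360)
#' @param bank_a_positions,bank_b_positions per-leaf tip coordinates (mm,
#'   IEC-X); the pair gap is `bank_b - bank_a`
#' @param jaw_x,jaw_y length-2 numeric, (x1, x2) / (y1, y2) jaw positions mm
#' @return object of class `control_point`
#' @export
control_point <- function(index, cumulative_meterset_weight, gantry_angle,
                          bank_a_positions, bank_b_positions,
                          jaw_x = c(-200, 200), jaw_y = c(-200, 200)) {
  if (length(bank_a_positions) != length(bank_b_positions)) {
    stop("bank A and bank B must have the same number of leaves")
  }
  gap <- bank_b_positions - bank_a_positions
  if (any(gap < -INTERDIGITATION_TOL)) {
    stop("negative leaf-pair gap at control point ", index,
         " (bank B tip left of bank A tip)")
  }
  structure(list(index = index,
                 cumulative_meterset_weight = cumulative_meterset_weight,
                 gantry_angle = gantry_angle %% 360,
                 bank_a_positions = as.numeric(bank_a_positions),
                 bank_b_positions = as.numeric(bank_b_positions),
                 jaw_x = as.numeric(jaw_x), jaw_y = as.numeric(jaw_y)),
            class = "control_point")
}

#' VMAT arc beam
#'
#' @param beam_mu monitor units delivered by this beam
#' @param control_points ordered list of [control_point()] objects;
#'   cumulative meterset weights must be non-decreasing, starting at 0 and
#'   ending at 1 (within 1e-6)
#' @param leaf_boundaries `n_leaf_pairs + 1` leaf-edge coordinates (mm,
#'   IEC-Y), strictly increasing
#' @param arc_direction `"CW"` or `"CCW"`
#' @param limits [machine_limits()]
#' @param name optional beam label
#' @return object of class `rt_beam`
#' @export
rt_beam <- function(beam_mu, control_points, leaf_boundaries,
                    arc_direction = "CW", limits = machine_limits(),
                    name = "arc") {
  stopifnot(beam_mu > 0, length(control_points) >= 2)
  n_pairs <- length(control_points[[1]]$bank_a_positions)
  if (length(leaf_boundaries) != n_pairs + 1) {
    stop("leaf_boundaries must have n_leaf_pairs + 1 entries")
  }
  if (any(diff(leaf_boundaries) <= 0)) stop("leaf widths must be positive")
  w <- vapply(control_points, function(cp) cp$cumulative_meterset_weight,
              numeric(1))
  if (any(diff(w) < -1e-9)) {
    stop("cumulative meterset weights must be non-decreasing")
  }
  if (abs(w[1]) > 1e-6 || abs(w[length(w)] - 1) > 1e-6) {
    stop("cumulative meterset weights must run from 0 to 1")
  }
  structure(list(beam_mu = beam_mu, control_points = control_points,
                 leaf_boundaries = as.numeric(leaf_boundaries),
                 arc_direction = match.arg(arc_direction, c("CW", "CCW")),
                 machine_limits = limits, name = name),
            class = "rt_beam")
}

#' Treatment plan
#'
#' @param plan_id label
#' @param beams list of [rt_beam()] objects (at least one)
#' @param prescription_dose prescription dose over all fractions, Gy
#' @param n_fractions number of fractions
#' @return object of class `rt_plan`
#' @export
rt_plan <- function(plan_id, beams, prescription_dose = 70,
                    n_fractions = 33) {
  stopifnot(length(beams) >= 1, prescription_dose > 0, n_fractions >= 1)
  structure(list(plan_id = plan_id, beams = beams,
                 prescription_dose = prescription_dose,
                 n_fractions = as.integer(n_fractions)),
            class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan '%s'>  %d beam(s), %.1f Gy in %d fx\n", x$plan_id,
              length(x$beams), x$prescription_dose, x$n_fractions))
  for (b in x$beams) {
    cat(sprintf("  %s: %.1f MU, %d control points, %d leaf pairs (%s)\n",
                b$name, b$beam_mu, length(b$control_points),
                length(b$leaf_boundaries) - 1L, b$arc_direction))
  }
  invisible(x)
}

#' 3D dose grid
#'
#' Dose values on a regular grid in patient coordinates. The array is
#' stored with dimensions `c(nx, ny, nz)` (x varies fastest, the natural R
#' layout); `origin` is the patient-coordinate position of the center of
#' voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array, Gy, non-negative
#' @param origin length-3 numeric (x, y, z), mm
#' @param spacing length-3 numeric (dx, dy, dz), mm, all positive
#' @return object of class `dose_grid`
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  stopifnot(length(dim(values)) == 3, all(spacing > 0))
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "dose_grid")
}

#' Structure set
#'
#' Named planar contours. Each structure is a list of contours; each contour
#' is a list with `z` (slice position, mm) and `xy` (n x 2 matrix of vertex
#' coordinates, mm, implicitly closed). Contours with an explicit repeated
#' closing vertex are normalized on construction.
#'
#' @param structures named list: structure name -> list of contours
#' @return object of class `structure_set`; structures with zero contours
#'   are kept and listed in `attr(, "empty")`
#' @export
structure_set <- function(structures) {
  stopifnot(is.list(structures), !is.null(names(structures)))
  structures <- lapply(structures, function(ctrs) {
    lapply(ctrs, function(ct) {
      xy <- ct$xy
      if (nrow(xy) >= 2 && all(xy[1, ] == xy[nrow(xy), ])) {
        xy <- xy[-nrow(xy), , drop = FALSE]
      }
      if (nrow(xy) < 3) stop("contour must have at least 3 vertices")
      list(z = ct$z, xy = xy)
    })
  })
  empty <- names(structures)[vapply(structures, length, integer(1)) == 0L]
  structure(list(structures = structures),
            class = "structure_set", empty = empty)
}

#' Per-segment delivery times of a VMAT beam
#'
#' DICOM VMAT plans carry no timestamps; the duration of the segment between
#' consecutive control points is modeled as the maximum of the
#' gantry-limited, dose-rate-limited and leaf-speed-limited times (the
#' standard delivery-time model). Gantry deltas are taken as the absolute
#' shortest arc, so the result is invariant to arc direction.
#'
#' @param beam an [rt_beam()]
#' @param limits [machine_limits()]; defaults to the beam's own
#' @return numeric vector of length `n_cp - 1`, seconds
#' @export
segment_times <- function(beam, limits = beam$machine_limits) {
  cps <- beam$control_points
  n <- length(cps)
  g <- vapply(cps, function(cp) cp$gantry_angle, numeric(1))
  w <- vapply(cps, function(cp) cp$cumulative_meterset_weight, numeric(1))
  dg <- abs(((diff(g) + 180) %% 360) - 180)
  dmu <- diff(w) * beam$beam_mu
  travel <- vapply(seq_len(n - 1L), function(i) {
    max(abs(cps[[i + 1L]]$bank_a_positions - cps[[i]]$bank_a_positions),
        abs(cps[[i + 1L]]$bank_b_positions - cps[[i]]$bank_b_positions))
  }, numeric(1))
  pmax(dg / limits$max_gantry_speed,
       dmu / (limits$max_dose_rate / 60),
       travel / limits$max_leaf_speed)
}
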