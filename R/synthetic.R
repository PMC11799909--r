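# Synthetic VMAT fixtures with known ground truth: plans with programmed
# aperture statistics, simultaneous-integrated-boost-like dose/structure
# phantoms with analytic CN/HI, dose-image pairs for gamma analysis, and
# paired metric cohorts. Every generator is a pure function of its seed.

# reflect values into [lo, hi] (folding); vectorized over x, lo, hi
.reflect <- function(x, lo, hi) {
  span <- 2 * (hi - lo)
  z <- (x - lo) %% span
  y <- lo + ifelse(z > (hi - lo), span - z, z)
  y[span <= 0] <- lo[span <= 0]
  y
}

#' Synthetic VMAT plan with programmed aperture statistics
#'
#' Builds an arc plan whose cross-axis, closed-leaf and small-aperture
#' fractions are set by construction: each leaf pair is assigned a fixed
#' role (closed / small-gap / open; crossing or midline-straddling) and a
#' constant gap, while the pair center performs a bounded random walk whose
#' per-segment steps follow the programmed leaf-speed profile under the
#' machine limits. Leaf positions are quantized to 0.01 mm, meterset
#' weights to 1e-6 and gantry angles to 1e-4 degrees, so a DICOM round trip
#' is lossless.
#'
#' @param seed integer RNG seed; the same seed always yields an identical
#'   plan
#' @param n_arcs number of full arcs (the head-and-neck cohorts use 3 or 4)
#' @param n_cp_per_arc control points per arc (178, a 2-degree-spaced
#'   TrueBeam full arc)
#' @param n_leaf_pairs leaf pairs per bank
#' @param leaf_width leaf width, mm
#' @param crossing_fraction target fraction of leaves (out of `2 *
#'   n_leaf_pairs`) crossing the central axis; at most 0.5, since a pair
#'   with a non-negative gap can contribute at most one crossing leaf
#' @param closed_fraction target fraction of closed leaf pairs
#' @param small_aperture_fraction target fraction (of all pairs) with a gap
#'   between the closed tolerance and `small_gap_threshold`
#' @param small_gap_threshold the small-aperture gap threshold, mm
#' @param aperture_mean,aperture_sd gap distribution of the remaining open
#'   pairs, mm
#' @param speed_range programmed leaf speeds are drawn uniformly from this
#'   range, mm/s; the upper end must not exceed the machine leaf-speed
#'   limit
#' @param total_mu total plan monitor units (default: 1 MU per control
#'   point)
#' @param limits [machine_limits()]
#' @param closed_tolerance closed-gap tolerance used in the construction
#'   (must match the scoring configuration)
#' @return list with `plan` (an [rt_plan()]) and `expected`, the per-beam
#'   ground-truth map: `CAS`, `CLS`, `SAS` (percent, at
#'   `small_gap_threshold`), `MFA` (mm^2, exact since gaps are constant)
#'   and `MU_per_CP`
#' @export
synth_plan <- function(seed, n_arcs = 4, n_cp_per_arc = 178,
                       n_leaf_pairs = 60, leaf_width = 5,
                       crossing_fraction = 0.3, closed_fraction = 0.2,
                       small_aperture_fraction = 0.4,
                       small_gap_threshold = 1,
                       aperture_mean = 30, aperture_sd = 8,
                       speed_range = c(0, 24), total_mu = NULL,
                       limits = machine_limits(),
                       closed_tolerance = 0.5) {
  f <- crossing_fraction; cc <- closed_fraction
  s <- small_aperture_fraction
  stopifnot(f >= 0, cc >= 0, s >= 0, f + cc <= 1, cc + s <= 1)
  if (f > 0.5) {
    stop("crossing_fraction above 0.5 is infeasible with non-negative gaps")
  }
  if (max(speed_range) > limits$max_leaf_speed) {
    stop("programmed leaf speed exceeds the machine leaf-speed limit")
  }
  if (is.null(total_mu)) total_mu <- n_arcs * n_cp_per_arc
  set.seed(seed)
  n <- n_leaf_pairs
  n_closed <- round(cc * n)
  n_small <- round(s * n)
  n_cross <- round(f * 2 * n)
  tol <- closed_tolerance
  boundaries <- round(leaf_width * (0:n) - leaf_width * n / 2, 2)
  n_seg <- n_cp_per_arc - 1L
  # nominal (gantry/dose-rate limited) segment time; leaf steps are capped
  # by speed_range <= max_leaf_speed so this is the realized time
  dgantry <- 360 / n_seg
  dmu <- (total_mu / n_arcs) / n_seg
  t_nom <- max(dgantry / limits$max_gantry_speed,
               dmu / (limits$max_dose_rate / 60))
  w <- round((0:n_seg) / n_seg, 6)
  w[n_seg + 1L] <- 1
  gantry <- round((180 + dgantry * (0:n_seg)) %% 360, 4)
  jaw_x <- c(-140, 140); jaw_y <- round(c(boundaries[1] - 2,
                                          boundaries[n + 1] + 2), 2)
  margin <- 2
  beams <- vector("list", n_arcs)
  for (bi in seq_len(n_arcs)) {
    # roles
    idx <- sample.int(n)
    closed_idx <- idx[seq_len(n_closed)]
    small_idx <- idx[n_closed + seq_len(n_small)]
    cross_idx <- sample.int(n, n_cross)
    cross_side <- sample(c("A", "B"), n_cross, replace = TRUE)
    gap <- numeric(n)
    gap[closed_idx] <- 0
    if (n_small > 0) {
      span <- small_gap_threshold - tol
      gap[small_idx] <- round(stats::runif(n_small, tol + 0.05 * span,
                                           small_gap_threshold -
                                             0.05 * span), 2)
    }
    large_idx <- setdiff(seq_len(n), c(closed_idx, small_idx))
    if (length(large_idx) > 0) {
      gap[large_idx] <- round(pmax(1.2 * small_gap_threshold,
                                   stats::rnorm(length(large_idx),
                                                aperture_mean,
                                                aperture_sd)), 2)
    }
    # allowed center interval per pair
    lo <- numeric(n); hi <- numeric(n)
    for (p in seq_len(n)) {
      ci <- match(p, cross_idx)
      if (!is.na(ci)) {
        if (cross_side[ci] == "A") {         # both tips right of midline
          lo[p] <- gap[p] / 2 + margin; hi[p] <- 100
        } else {                             # both tips left of midline
          lo[p] <- -100; hi[p] <- -gap[p] / 2 - margin
        }
      } else {                               # gap straddles the midline
        half <- max(gap[p] / 2 - 0.05, 0)
        lo[p] <- -half; hi[p] <- half
      }
    }
    centers <- matrix(0, n, n_cp_per_arc)
    centers[, 1] <- stats::runif(n, lo, hi)
    for (j in seq_len(n_seg)) {
      v <- stats::runif(n, speed_range[1], speed_range[2])
      step <- sample(c(-1, 1), n, replace = TRUE) * v * t_nom
      centers[, j + 1L] <- .reflect(centers[, j] + step, lo, hi)
    }
    half_gap <- gap / 2
    cps <- lapply(seq_len(n_cp_per_arc), function(j) {
      control_point(j - 1L, w[j], gantry[j],
                    bank_a_positions = round(centers[, j] - half_gap, 2),
                    bank_b_positions = round(centers[, j] + half_gap, 2),
                    jaw_x = jaw_x, jaw_y = jaw_y)
    })
    beams[[bi]] <- rt_beam(round(total_mu / n_arcs, 4), cps, boundaries,
                           arc_direction = "CW", limits,
                           name = sprintf("arc%d", bi))
  }
  expected <- list(
    CAS = n_cross / (2 * n),
    CLS = n_closed / n,
    SAS = if (n > n_closed) 100 * n_small / (n - n_closed) else 0,
    SAS_threshold = small_gap_threshold,
    MU_per_CP = (total_mu / n_arcs) / n_cp_per_arc
  )
  plan <- rt_plan(sprintf("synth-%d", seed), beams)
  # constant per-pair gaps make the aperture area constant per beam
  expected$MFA_per_beam <- vapply(beams, function(b) {
    aperture_area(b$control_points[[1]], b$leaf_boundaries)
  }, numeric(1))
  list(plan = plan, expected = expected)
}

# circle contour at height dz above a sphere's center
.sphere_contours <- function(center, radius, zs, n_vertices = 72) {
  ctrs <- list()
  for (z in zs) {
    dz <- z - center[3]
    if (abs(dz) >= radius) next
    r <- sqrt(radius^2 - dz^2)
    if (r < 1) next
    th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
    ctrs[[length(ctrs) + 1L]] <- list(
      z = round(z, 2),
      xy = cbind(round(center[1] + r * cos(th), 2),
                 round(center[2] + r * sin(th), 2)))
  }
  ctrs
}

#' Synthetic dose/structure phantom with analytic conformity ground truth
#'
#' A simultaneous-integrated-boost-like geometry: nested spherical target
#' shells (high/intermediate/low risk), spherical organs at risk and a body
#' sphere on a regular dose grid. The dose is radial: inside the
#' prescription isodose sphere it ramps linearly from `hotspot_pct` above
#' the prescription at the center down to exactly the prescription at the
#' isodose radius, then falls off as a Gaussian of width `falloff_mm`. The
#' prescription isodose surface is therefore exactly a sphere of radius
#' `r_high * coverage^(1/3)`, giving a closed-form conformity number; with
#' full coverage the heterogeneity index of the boost target is also
#' closed-form. Dose values are quantized to the DICOM scaling quantum so a
#' write/read round trip is lossless.
#'
#' @param seed integer seed (reserved; the phantom itself is deterministic)
#' @param grid_size voxels per axis (length 1 or 3)
#' @param spacing voxel spacing, mm (length 1 or 3)
#' @param ptv_radii ascending radii (mm) of the high/intermediate/low-risk
#'   target spheres
#' @param prescription prescription dose to the boost volume, Gy
#' @param coverage fraction of the boost target volume covered by the
#'   prescription isodose, in (0, 1]
#' @param falloff_mm Gaussian falloff width outside the isodose sphere, mm
#' @param hotspot_pct central hot spot above the prescription, percent
#' @param oars named list of organs at risk, each `list(center=, radius=)`
#'   in mm
#' @param body_radius body sphere radius, mm
#' @return list with `grid` (a [dose_grid()]), `structures` (a
#'   [structure_set()] with PTV shells, OARs and BODY) and `expected`:
#'   analytic `CN`, `HI` (NA when `coverage < 1`), `r_iso` and the analytic
#'   target volume `ptv_cc`
#' @export
synth_case <- function(seed = 1, grid_size = 128, spacing = 1,
                       ptv_radii = c(high = 25, intermediate = 35,
                                     low = 45),
                       prescription = 70, coverage = 1,
                       falloff_mm = 8, hotspot_pct = 5,
                       oars = list(
                         spinal_cord = list(center = c(0, 52, 0),
                                            radius = 6),
                         brain_stem = list(center = c(0, 40, 35),
                                           radius = 9),
                         parotid_l = list(center = c(-45, 0, 0),
                                          radius = 10),
                         parotid_r = list(center = c(45, 0, 0),
                                          radius = 10)),
                       body_radius = 60) {
  if (length(grid_size) == 1) grid_size <- rep(grid_size, 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(all(diff(ptv_radii) > 0), coverage > 0, coverage <= 1,
            prescription > 0)
  half_span <- (grid_size - 1) * spacing / 2
  if (max(ptv_radii) > min(half_span)) {
    stop("target spheres are not contained in the dose grid")
  }
  origin <- round(-half_span, 4)
  spacing <- round(spacing, 4)
  xs <- origin[1] + (seq_len(grid_size[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(grid_size[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(grid_size[3]) - 1) * spacing[3]
  r_ptv <- ptv_radii[[1]]
  r_iso <- r_ptv * coverage^(1 / 3)
  h <- 1 + hotspot_pct / 100
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  r <- sqrt(r2)
  dose <- ifelse(
    r <= r_iso,
    prescription * (1 + (h - 1) * (1 - r / r_iso)),
    prescription * exp(-(r - r_iso)^2 / (2 * falloff_mm^2)))
  scaling <- .dose_scaling(max(dose))
  dose <- round(dose / scaling) * scaling
  grid <- dose_grid(dose, origin = origin, spacing = spacing)
  structs <- list(
    PTV_high = .sphere_contours(c(0, 0, 0), ptv_radii[[1]], zs),
    PTV_intermediate = .sphere_contours(c(0, 0, 0), ptv_radii[[2]], zs),
    PTV_low = .sphere_contours(c(0, 0, 0), ptv_radii[[3]], zs),
    BODY = .sphere_contours(c(0, 0, 0), body_radius, zs)
  )
  for (nm in names(oars)) {
    structs[[nm]] <- .sphere_contours(oars[[nm]]$center,
                                      oars[[nm]]$radius, zs)
  }
  v_min <- min(r_ptv, r_iso)^3
  expected <- list(
    CN = (v_min / r_ptv^3) * (v_min / r_iso^3),
    HI = if (coverage >= 1) {
      dq <- function(q) {
        prescription * (1 + (h - 1) * (1 - (q / 100)^(1 / 3)))
      }
      (dq(2) - dq(98)) / dq(50)
    } else NA_real_,
    r_iso = r_iso,
    ptv_cc = 4 / 3 * pi * r_ptv^3 / 1000
  )
  list(grid = grid, structures = structure_set(structs),
       expected = expected)
}

# separable Gaussian smoothing (reflected edges) for correlated noise
.smooth2d <- function(M, sigma_px) {
  if (sigma_px <= 0) return(M)
  k <- ceiling(3 * sigma_px)
  kern <- stats::dnorm(-k:k, sd = sigma_px)
  kern <- kern / sum(kern)
  pad_filter <- function(v) {
    vp <- c(rev(v[seq_len(k)]), v, rev(v[length(v) - seq_len(k) + 1L]))
    stats::filter(vp, kern, sides = 2)[(k + 1L):(k + length(v))]
  }
  M <- apply(M, 2, pad_filter)
  t(apply(t(M), 2, pad_filter))
}

#' Synthetic dose-image pair for gamma analysis
#'
#' The reference is a smooth multi-lobe field (sum of Gaussian lobes); the
#' evaluated image is the same analytic field scaled, rigidly shifted and
#' overlaid with spatially correlated Gaussian noise (smoothed white noise,
#' mimicking EPID measurement noise). Because the shift is applied
#' analytically, the pure-shift case carries no interpolation error.
#'
#' @param seed integer seed (used by the noise only)
#' @param shift rigid shift of the evaluated image, mm (length 1 or 2)
#' @param scale_pct uniform dose scaling of the evaluated image, percent
#' @param noise_pct correlated-noise amplitude, percent of the maximum
#'   reference dose
#' @param n image size in pixels (n x n)
#' @param spacing pixel spacing, mm
#' @return list with `reference` and `evaluated` [dose_image()] objects
#' @export
synth_dose_pair <- function(seed = 1, shift = c(0, 0), scale_pct = 0,
                            noise_pct = 0, n = 64, spacing = 1) {
  if (length(shift) == 1) shift <- c(shift, 0)
  set.seed(seed)
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  lobes <- list(c(x = -0.18 * n * spacing, y = -0.10 * n * spacing,
                  a = 1.0, s = 0.16 * n * spacing),
                c(x = 0.15 * n * spacing, y = 0.12 * n * spacing,
                  a = 0.8, s = 0.13 * n * spacing),
                c(x = 0.02 * n * spacing, y = -0.20 * n * spacing,
                  a = 0.6, s = 0.10 * n * spacing))
  field <- function(ox, oy) {
    M <- matrix(0, n, n)
    for (lb in lobes) {
      M <- M + lb["a"] * outer(
        exp(-(xs - ox - lb["x"])^2 / (2 * lb["s"]^2)),
        exp(-(xs - oy - lb["y"])^2 / (2 * lb["s"]^2)))
    }
    M
  }
  ref <- field(0, 0)
  ev <- field(shift[1], shift[2]) * (1 + scale_pct / 100)
  if (noise_pct > 0) {
    noise <- .smooth2d(matrix(stats::rnorm(n * n), n, n), 2)
    noise <- noise / stats::sd(noise) * noise_pct / 100 * max(ref)
    ev <- pmax(ev + noise, 0)
  }
  list(reference = dose_image(ref, c(spacing, spacing)),
       evaluated = dose_image(ev, c(spacing, spacing)))
}

# metric scales typical of head-and-neck VMAT plan cohorts
.default_cohort_baseline <- function() {
  list(
    "LS_A16-20" = c(0.20, 0.03), "LS_B16-20" = c(0.21, 0.03),
    "LA_A160-200" = c(0.23, 0.04), "LA_B160-200" = c(0.23, 0.03),
    MFA = c(6300, 1600), CAS = c(0.85, 0.45), CLS = c(0.07, 0.04),
    SAS_1mm = c(64, 12), SAS_2mm = c(66, 12), SAS_5mm = c(73, 11),
    SAS_10mm = c(87, 10), MU_per_CP = c(1.0, 0.2)
  )
}

#' Synthetic paired metric cohort
#'
#' Draws per-patient plan-metric values for a baseline cohort and derives
#' the paired cohort by adding the specified per-metric shift plus Gaussian
#' noise. Metrics without an entry in `effects` are carried over unchanged
#' (plan metrics are deterministic recomputations, so an untouched metric
#' yields an exactly zero paired difference and is reported as not tested
#' by [compare_cohorts()]).
#'
#' @param seed integer seed
#' @param n_patients number of paired patients (the emulated cohort has 20)
#' @param effects named list: metric -> `list(shift=, sd=)` applied to the
#'   second cohort
#' @param baseline named list: metric -> `c(mean, sd)` of the first cohort;
#'   defaults to head-and-neck complexity-score scales
#' @param cohort_labels length-2 character, first = baseline cohort
#' @return list with `table` (long-format data frame: `patient_id`,
#'   `cohort`, `metric`, `value`) and `manifest` (per-patient arc counts
#'   drawn with the 3-vs-4-arc proportions of the emulated cohort)
#' @export
synth_cohort <- function(seed, n_patients = 20, effects = list(),
                         baseline = .default_cohort_baseline(),
                         cohort_labels = c("manual", "automated")) {
  stopifnot(n_patients >= 2, length(cohort_labels) == 2)
  set.seed(seed)
  ids <- sprintf("pt%02d", seq_len(n_patients))
  rows <- list()
  for (m in names(baseline)) {
    mu <- baseline[[m]][1]; sdv <- baseline[[m]][2]
    va <- pmax(stats::rnorm(n_patients, mu, sdv), 0)
    eff <- effects[[m]]
    vb <- if (is.null(eff)) va else {
      pmax(va + eff$shift + stats::rnorm(n_patients, 0, eff$sd), 0)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = rep(ids, 2),
      cohort = rep(cohort_labels, each = n_patients),
      metric = m, value = c(va, vb), stringsAsFactors = FALSE)
  }
  manifest <- data.frame(
    patient_id = ids,
    n_arcs = sample(c(3, 4), n_patients, replace = TRUE,
                    prob = c(9, 11) / 20),
    stringsAsFactors = FALSE)
  list(table = do.call(rbind, rows), manifest = manifest)
}
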