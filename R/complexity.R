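# MLC beam-complexity scores: leaf speed/acceleration fractions, mean field
# area (MFA), cross-axis score (CAS), closed leaf score (CLS), small
# aperture scores (SAS) and MU per control point.

#' Configuration for beam-complexity scoring
#'
#' @param speed_range headline leaf-speed band (mm/s) reported as
#'   `LS_A`/`LS_B`; the clinically observed band is 16-20 mm/s
#' @param accel_range headline leaf-acceleration band (mm/s^2); 160-200
#' @param speed_bins,accel_bins full bin partitions (list of `c(lo, hi)`,
#'   half-open, ordered, non-overlapping) used by [fraction_in_range()]
#'   summaries; defaults are 4 mm/s bins over 0-20 plus an overflow bin, and
#'   40 mm/s^2 bins over 0-200 plus overflow
#' @param sas_thresholds small-aperture gap thresholds, mm, ascending
#' @param closed_tolerance gap at or below which a leaf pair counts as
#'   closed, mm; must be smaller than the smallest SAS threshold
#' @param mu_weighted if `TRUE` (default) per-beam aperture scores are
#'   delta-MU-weighted over segments; if `FALSE`, plain segment means
#' @param plan_aggregation `"sum"` (default) sums CAS/CLS/SAS over beams
#'   (per-arc scores add, so plan values may exceed 1 or 100%);
#'   `"mu_weighted_mean"` keeps plan values on the per-beam scale
#' @return object of class `complexity_config`
#' @export
complexity_config <- function(speed_range = c(16, 20),
                              accel_range = c(160, 200),
                              speed_bins = NULL, accel_bins = NULL,
                              sas_thresholds = c(1, 2, 5, 10),
                              closed_tolerance = 0.5,
                              mu_weighted = TRUE,
                              plan_aggregation = c("sum",
                                                   "mu_weighted_mean")) {
  if (is.null(speed_bins)) {
    speed_bins <- c(lapply(seq(0, 16, 4), function(lo) c(lo, lo + 4)),
                    list(c(20, Inf)))
  }
  if (is.null(accel_bins)) {
    accel_bins <- c(lapply(seq(0, 160, 40), function(lo) c(lo, lo + 40)),
                    list(c(200, Inf)))
  }
  .check_bins <- function(bins) {
    lo <- vapply(bins, `[`, numeric(1), 1)
    hi <- vapply(bins, `[`, numeric(1), 2)
    stopifnot(all(lo < hi), all(diff(lo) > 0), all(hi[-length(hi)] <= lo[-1]))
  }
  .check_bins(speed_bins); .check_bins(accel_bins)
  stopifnot(all(diff(sas_thresholds) > 0),
            closed_tolerance < min(sas_thresholds), closed_tolerance >= 0)
  structure(list(speed_range = speed_range, accel_range = accel_range,
                 speed_bins = speed_bins, accel_bins = accel_bins,
                 sas_thresholds = sas_thresholds,
                 closed_tolerance = closed_tolerance,
                 mu_weighted = mu_weighted,
                 plan_aggregation = match.arg(plan_aggregation)),
            class = "complexity_config")
}

# per-beam arrays: leaf banks (n_pairs x n_cp), gaps, meterset weights,
# per-control-point in-jaw pair mask, leaf widths
.beam_arrays <- function(beam) {
  cps <- beam$control_points
  A <- vapply(cps, `[[`, numeric(length(cps[[1]]$bank_a_positions)),
              "bank_a_positions")
  B <- vapply(cps, `[[`, numeric(nrow(A)), "bank_b_positions")
  A <- matrix(A, nrow = length(beam$leaf_boundaries) - 1L)
  B <- matrix(B, nrow = nrow(A))
  w <- vapply(cps, `[[`, numeric(1), "cumulative_meterset_weight")
  lo <- beam$leaf_boundaries[-length(beam$leaf_boundaries)]
  hi <- beam$leaf_boundaries[-1]
  in_jaw <- vapply(cps, function(cp) {
    !(hi <= cp$jaw_y[1] | lo >= cp$jaw_y[2])
  }, logical(nrow(A)))
  in_jaw <- matrix(in_jaw, nrow = nrow(A))
  list(A = A, B = B, gap = B - A, w = w, in_jaw = in_jaw,
       widths = hi - lo, cps = cps)
}

# delta-MU-weighted mean of a per-control-point score over segments
# (segment score = mean of its two bounding control points)
.segment_weighted_mean <- function(per_cp, w, mu_weighted = TRUE) {
  n <- length(per_cp)
  seg <- (per_cp[-n] + per_cp[-1]) / 2
  wt <- if (mu_weighted) diff(w) else rep(1, n - 1L)
  if (sum(wt) <= 0) stop("all segment meterset increments are zero")
  sum(seg * wt) / sum(wt)
}

#' Leaf speeds and accelerations of a beam
#'
#' Per-leaf, per-segment speed is the absolute tip travel divided by the
#' segment duration; the acceleration at interior control point j is the
#' absolute speed change between the two adjacent segments divided by the
#' mean of their durations.
#'
#' @param beam an [rt_beam()]
#' @param times per-segment durations (s) from [segment_times()]
#' @return list with `speed_a`, `speed_b` (`n_pairs x n_segments`, mm/s)
#'   and `accel_a`, `accel_b` (`n_pairs x (n_segments - 1)`, mm/s^2; empty
#'   when the beam has fewer than 3 control points)
#' @export
leaf_kinematics <- function(beam, times = segment_times(beam)) {
  arr <- .beam_arrays(beam)
  n_cp <- ncol(arr$A)
  speed <- function(M) {
    d <- abs(M[, -1, drop = FALSE] - M[, -n_cp, drop = FALSE])
    s <- sweep(d, 2, times, "/")
    s[, times == 0] <- 0
    s
  }
  sa <- speed(arr$A); sb <- speed(arr$B)
  accel <- function(s) {
    if (ncol(s) < 2) {
      return(matrix(numeric(0), nrow = nrow(s), ncol = 0))
    }
    dt <- (times[-length(times)] + times[-1]) / 2
    a <- abs(s[, -1, drop = FALSE] - s[, -ncol(s), drop = FALSE])
    a <- sweep(a, 2, dt, "/")
    a[, dt == 0] <- 0
    a
  }
  list(speed_a = sa, speed_b = sb, accel_a = accel(sa), accel_b = accel(sb))
}

#' Fraction of values within a half-open range
#'
#' Counts `lo <= v < hi` over all supplied samples (moving and static
#' leaves alike).
#'
#' @param values numeric vector or matrix of samples
#' @param lo,hi range bounds, `lo < hi`
#' @return fraction in \[0, 1\]
#' @export
fraction_in_range <- function(values, lo, hi) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("fraction undefined for empty input")
  stopifnot(lo < hi, all(is.finite(values)))
  mean(values >= lo & values < hi)
}

#' Aperture area of one control point
#'
#' Sum over leaf pairs of the open gap length clipped to the X jaws times
#' the leaf width; pairs whose leaf strip lies entirely outside the Y jaws
#' are excluded.
#'
#' @param cp a [control_point()]
#' @param leaf_boundaries leaf edges, mm (IEC-Y)
#' @return area in mm^2
#' @export
aperture_area <- function(cp, leaf_boundaries) {
  lo <- leaf_boundaries[-length(leaf_boundaries)]
  hi <- leaf_boundaries[-1]
  in_jaw <- !(hi <= cp$jaw_y[1] | lo >= cp$jaw_y[2])
  open_len <- pmax(0, pmin(cp$bank_b_positions, cp$jaw_x[2]) -
                      pmax(cp$bank_a_positions, cp$jaw_x[1]))
  sum((open_len * (hi - lo))[in_jaw])
}

#' Mean field area of a beam
#'
#' MU-weighted mean of the aperture area over segments; each segment's area
#' is the mean of its two bounding control-point areas.
#'
#' @param beam an [rt_beam()]
#' @param config [complexity_config()]
#' @return MFA in mm^2
#' @export
mfa <- function(beam, config = complexity_config()) {
  areas <- vapply(beam$control_points, aperture_area,
                  numeric(1), beam$leaf_boundaries)
  w <- vapply(beam$control_points, `[[`, numeric(1),
              "cumulative_meterset_weight")
  .segment_weighted_mean(areas, w, mu_weighted = TRUE)
}

# per-control-point aperture scores shared by cas/cls/sas
.per_cp_score <- function(beam, fn) {
  arr <- .beam_arrays(beam)
  vapply(seq_len(ncol(arr$A)), function(j) {
    keep <- arr$in_jaw[, j]
    fn(arr$A[keep, j], arr$B[keep, j], arr$gap[keep, j])
  }, numeric(1))
}

#' Cross-axis score of a beam
#'
#' Per control point, the fraction of leaves whose tip crosses the beam
#' central axis (bank A tip strictly right of x = 0, bank B tip strictly
#' left of it), out of `2 * n_pairs` leaves inside the Y jaws; the per-beam
#' score is the delta-MU-weighted mean over segments.
#'
#' @inheritParams mfa
#' @return CAS in \[0, 1\]
#' @export
cas <- function(beam, config = complexity_config()) {
  per_cp <- .per_cp_score(beam, function(a, b, gap) {
    if (length(a) == 0) return(0)
    (sum(a > 0) + sum(b < 0)) / (2 * length(a))
  })
  w <- vapply(beam$control_points, `[[`, numeric(1),
              "cumulative_meterset_weight")
  .segment_weighted_mean(per_cp, w, config$mu_weighted)
}

#' Closed leaf score of a beam
#'
#' Fraction of leaf pairs whose gap is at most `closed_tolerance`, per
#' control point (pairs inside the Y jaws), delta-MU-weighted over segments.
#'
#' @inheritParams mfa
#' @return CLS in \[0, 1\]
#' @export
cls <- function(beam, config = complexity_config()) {
  tol <- config$closed_tolerance
  per_cp <- .per_cp_score(beam, function(a, b, gap) {
    if (length(gap) == 0) return(0)
    mean(gap <= tol)
  })
  w <- vapply(beam$control_points, `[[`, numeric(1),
              "cumulative_meterset_weight")
  .segment_weighted_mean(per_cp, w, config$mu_weighted)
}

#' Small aperture score of a beam
#'
#' Per control point, the percentage of open leaf pairs (gap above
#' `closed_tolerance`) whose gap is below `threshold_mm`; control points
#' with no open pair contribute 0. Delta-MU-weighted over segments.
#'
#' @inheritParams mfa
#' @param threshold_mm aperture threshold, mm (must exceed
#'   `closed_tolerance`)
#' @return SAS in \[0, 100\] (percent)
#' @export
sas <- function(beam, threshold_mm, config = complexity_config()) {
  tol <- config$closed_tolerance
  stopifnot(threshold_mm > tol)
  per_cp <- .per_cp_score(beam, function(a, b, gap) {
    open <- gap > tol
    if (!any(open)) return(0)
    mean(gap[open] < threshold_mm)
  })
  w <- vapply(beam$control_points, `[[`, numeric(1),
              "cumulative_meterset_weight")
  100 * .segment_weighted_mean(per_cp, w, config$mu_weighted)
}

#' Monitor units per control point
#'
#' For a beam, `beam_mu / n_control_points`; for a plan, total MU over
#' total control points (pooled, not the mean of per-beam ratios).
#'
#' @param x an [rt_beam()] or [rt_plan()]
#' @return MU/CP
#' @export
mu_per_cp <- function(x) {
  if (inherits(x, "rt_beam")) {
    return(x$beam_mu / length(x$control_points))
  }
  stopifnot(inherits(x, "rt_plan"))
  sum(vapply(x$beams, `[[`, numeric(1), "beam_mu")) /
    sum(vapply(x$beams, function(b) length(b$control_points), numeric(1)))
}

#' Full complexity report for a plan
#'
#' Computes every complexity score per beam and aggregated per plan. With
#' the default `"sum"` aggregation, CAS/CLS/SAS are summed over beams (so
#' 3-4-arc plans can exceed 1, or 100% for SAS); MFA is the MU-weighted
#' mean over beams; leaf speed/acceleration fractions pool all leaf-segment
#' samples across beams; MU/CP pools total MU over total control points.
#'
#' @param plan an [rt_plan()]
#' @param config [complexity_config()]
#' @return object of class `complexity_report`: list with `per_beam` (one
#'   row per beam) and `per_plan` (one-row data frame); metric columns are
#'   named `LS_A16-20`, `LS_B16-20`, `LA_A160-200`, `LA_B160-200`, `MFA`,
#'   `CAS`, `CLS`, `SAS_1mm` ... and `MU_per_CP`
#' @export
plan_complexity_report <- function(plan, config = complexity_config()) {
  sr <- config$speed_range; ar <- config$accel_range
  ls_keys <- sprintf("LS_%s%g-%g", c("A", "B"), sr[1], sr[2])
  la_keys <- sprintf("LA_%s%g-%g", c("A", "B"), ar[1], ar[2])
  sas_keys <- sprintf("SAS_%gmm", config$sas_thresholds)
  kin <- lapply(plan$beams, function(b) leaf_kinematics(b))
  rows <- lapply(seq_along(plan$beams), function(i) {
    b <- plan$beams[[i]]
    k <- kin[[i]]
    vals <- c(
      fraction_in_range(k$speed_a, sr[1], sr[2]),
      fraction_in_range(k$speed_b, sr[1], sr[2]),
      if (length(k$accel_a)) fraction_in_range(k$accel_a, ar[1], ar[2])
      else NA_real_,
      if (length(k$accel_b)) fraction_in_range(k$accel_b, ar[1], ar[2])
      else NA_real_,
      mfa(b, config), cas(b, config), cls(b, config),
      vapply(config$sas_thresholds, function(th) sas(b, th, config),
             numeric(1)),
      mu_per_cp(b)
    )
    stats::setNames(vals, c(ls_keys, la_keys, "MFA", "CAS", "CLS",
                            sas_keys, "MU_per_CP"))
  })
  per_beam <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(as.list(r), check.names = FALSE)
  }))
  per_beam <- cbind(
    data.frame(beam = vapply(plan$beams, `[[`, character(1), "name"),
               stringsAsFactors = FALSE),
    per_beam)
  mu <- vapply(plan$beams, `[[`, numeric(1), "beam_mu")
  agg_keys <- c("CAS", "CLS", sas_keys)
  per_plan <- per_beam[1, -1, drop = FALSE]
  for (key in agg_keys) {
    per_plan[[key]] <- if (config$plan_aggregation == "sum") {
      sum(per_beam[[key]])
    } else {
      sum(per_beam[[key]] * mu) / sum(mu)
    }
  }
  per_plan[["MFA"]] <- sum(per_beam[["MFA"]] * mu) / sum(mu)
  pool <- function(field) {
    as.numeric(unlist(lapply(kin, `[[`, field)))
  }
  per_plan[[ls_keys[1]]] <- fraction_in_range(pool("speed_a"), sr[1], sr[2])
  per_plan[[ls_keys[2]]] <- fraction_in_range(pool("speed_b"), sr[1], sr[2])
  acc_a <- pool("accel_a"); acc_b <- pool("accel_b")
  per_plan[[la_keys[1]]] <- if (length(acc_a)) {
    fraction_in_range(acc_a, ar[1], ar[2])
  } else NA_real_
  per_plan[[la_keys[2]]] <- if (length(acc_b)) {
    fraction_in_range(acc_b, ar[1], ar[2])
  } else NA_real_
  per_plan[["MU_per_CP"]] <- mu_per_cp(plan)
  rownames(per_plan) <- NULL
  structure(list(per_beam = per_beam, per_plan = per_plan,
                 plan_id = plan$plan_id, config = config),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report '%s'> (%d beams, aggregation: %s)\n",
              x$plan_id, nrow(x$per_beam), x$config$plan_aggregation))
  print(cbind(metric = names(x$per_plan),
              value = round(as.numeric(x$per_plan[1, ]), 4)), quote = FALSE)
  invisible(x)
}
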