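# DVH construction and plan-quality statistics: conformity number (CN),
# heterogeneity index (HI), Dmax/Dmean/D1cc/Dx% and evaluation against a
# head-and-neck organ-at-risk dose-constraint protocol.

# even-odd point-in-polygon (ray casting), vectorized over query points
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) / (vy[j] - vy[i]) *
        (vx[j] - vx[i])
      idx <- which(crosses)
      flip <- px[idx] < xint
      inside[idx[flip]] <- !inside[idx[flip]]
    }
    j <- i
  }
  inside
}

#' Rasterize a structure onto a dose grid
#'
#' A voxel is included when its center lies inside the contour(s) of the
#' nearest contour slice (|dz| at most half the grid z-spacing). Multiple
#' contours on one slice combine by the even-odd rule, so nested contours
#' produce holes.
#'
#' @param contours list of contours (each `list(z, xy)`) as stored in a
#'   [structure_set()]
#' @param grid a [dose_grid()]
#' @return logical array with the grid's dimensions; warns and returns an
#'   all-`FALSE` mask when no contour overlaps the grid
#' @export
rasterize_structure <- function(contours, grid) {
  dims <- dim(grid$values)
  mask <- array(FALSE, dim = dims)
  if (length(contours) == 0) {
    warning("structure has no contours; empty mask")
    return(mask)
  }
  xs <- grid$origin[1] + (seq_len(dims[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(dims[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(dims[3]) - 1) * grid$spacing[3]
  ctr_z <- vapply(contours, `[[`, numeric(1), "z")
  any_hit <- FALSE
  for (k in seq_len(dims[3])) {
    near <- which(abs(ctr_z - zs[k]) <= grid$spacing[3] / 2 + 1e-9)
    if (length(near) == 0) next
    # all contours of the nearest populated slice, even-odd combined
    best_z <- ctr_z[near[which.min(abs(ctr_z[near] - zs[k]))]]
    slice <- array(FALSE, dim = dims[1:2])
    for (ci in which(abs(ctr_z - best_z) < 1e-9)) {
      xy <- contours[[ci]]$xy
      ix <- which(xs >= min(xy[, 1]) - 1e-9 & xs <= max(xy[, 1]) + 1e-9)
      iy <- which(ys >= min(xy[, 2]) - 1e-9 & ys <= max(xy[, 2]) + 1e-9)
      if (length(ix) == 0 || length(iy) == 0) next
      pts <- expand.grid(x = xs[ix], y = ys[iy])
      inside <- .points_in_polygon(pts$x, pts$y, xy[, 1], xy[, 2])
      slice[ix, iy] <- xor(slice[ix, iy],
                           matrix(inside, nrow = length(ix)))
    }
    if (any(slice)) any_hit <- TRUE
    mask[, , k] <- slice
  }
  if (!any_hit) warning("no contour overlaps the dose grid; empty mask")
  mask
}

#' Cumulative dose-volume histogram
#'
#' @param grid a [dose_grid()]
#' @param mask logical array selecting the structure's voxels (nonempty)
#' @param bin_width histogram bin width, Gy
#' @return object of class `dvh`: list with `dose_axis` (Gy, ascending),
#'   `cum_volume` (fraction of structure volume receiving at least that
#'   dose; starts at 1, ends at 0), `volume_cc`, and raw summary doses
#'   `d_max`, `d_mean`, `d_min`
#' @export
cumulative_dvh <- function(grid, mask, bin_width = 0.01) {
  doses <- grid$values[mask]
  if (length(doses) == 0) stop("empty mask: DVH undefined")
  voxel_cc <- prod(grid$spacing) / 1000
  edges <- seq(0, max(doses) + bin_width, by = bin_width)
  cum <- vapply(edges, function(d) mean(doses >= d), numeric(1))
  structure(list(dose_axis = edges, cum_volume = cum,
                 volume_cc = length(doses) * voxel_cc,
                 d_max = max(doses), d_mean = mean(doses),
                 d_min = min(doses)),
            class = "dvh")
}

#' Dose covering a given volume
#'
#' `dose_at_volume(dvh, q_percent = 2)` is D2: the largest dose received by
#' at least 2% of the structure volume, with linear interpolation between
#' DVH bins. `q_cc` selects an absolute volume (e.g. 1 for D_1cc).
#'
#' @param dvh a [cumulative_dvh()]
#' @param q_percent volume fraction in percent, `0 < q <= 100`
#' @param q_cc absolute volume in cm^3 (alternative to `q_percent`)
#' @return dose in Gy
#' @export
dose_at_volume <- function(dvh, q_percent = NULL, q_cc = NULL) {
  if (!is.null(q_cc)) {
    if (q_cc > dvh$volume_cc) {
      stop("requested volume exceeds structure volume")
    }
    q_percent <- 100 * q_cc / dvh$volume_cc
  }
  stopifnot(q_percent > 0, q_percent <= 100)
  q <- q_percent / 100
  cum <- dvh$cum_volume; d <- dvh$dose_axis
  idx <- which(cum >= q)
  i <- idx[length(idx)]  # last bin still covering q
  if (i == length(cum) || cum[i] == q) return(d[i])
  # interpolate between (d[i], cum[i]) and (d[i+1], cum[i+1])
  d[i] + (cum[i] - q) / (cum[i] - cum[i + 1]) * (d[i + 1] - d[i])
}

#' Conformity number
#'
#' `CN = (PTV_PD / PTV) * (PTV_PD / PIV)`, where PTV_PD is the target
#' volume receiving at least the prescription dose and PIV the total volume
#' (body if a body mask is given, otherwise the whole grid) receiving at
#' least the prescription dose. Returns 0 when PIV is empty.
#'
#' @param grid a [dose_grid()]
#' @param ptv_mask logical array (nonempty) of the target
#' @param prescription prescription dose, Gy
#' @param body_mask optional logical array limiting the irradiated-volume
#'   search
#' @return CN in \[0, 1\]
#' @export
conformity_number <- function(grid, ptv_mask, prescription,
                              body_mask = NULL) {
  stopifnot(prescription > 0)
  if (!any(ptv_mask)) stop("empty PTV mask")
  hot <- grid$values >= prescription
  ptv_pd <- sum(hot & ptv_mask)
  piv <- if (is.null(body_mask)) sum(hot) else sum(hot & body_mask)
  if (piv == 0) return(0)
  (ptv_pd / sum(ptv_mask)) * (ptv_pd / piv)
}

#' Heterogeneity index
#'
#' `HI = (D2 - D98) / D50` of the target DVH; 0 for a perfectly uniform
#' dose, larger for more heterogeneous coverage.
#'
#' @param dvh a [cumulative_dvh()] of the target
#' @return HI (non-negative for any monotone DVH)
#' @export
heterogeneity_index <- function(dvh) {
  d50 <- dose_at_volume(dvh, 50)
  if (d50 == 0) stop("D50 is zero: HI undefined")
  (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) / d50
}

#' Head-and-neck organ-at-risk constraint protocol
#'
#' The default protocol used for head-and-neck VMAT plans (RTOG 0225/0615
#' style): serial-organ maximum-dose limits with D1% alternates, mean-dose
#' limits for parallel organs, and the paired-parotid sparing rule (mean
#' below 26 Gy, or at least one side below 30 Gy). Structure matching is by
#' case-insensitive regular expression.
#'
#' @param path optional YAML file describing the rules; defaults to the
#'   protocol shipped with the package
#' @return data frame of rules with columns `organ`, `pattern`,
#'   `statistic`, `limit`, `alt_statistic`, `alt_limit`, `alt_scope`
#' @export
hn_constraint_protocol <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hn_protocol.yaml",
                        package = "planscope")
  }
  y <- yaml::read_yaml(path)
  rules <- lapply(y$rules, function(r) {
    data.frame(organ = r$organ, pattern = r$pattern,
               statistic = r$statistic, limit = as.numeric(r$limit),
               alt_statistic = if (is.null(r$alt_statistic)) NA_character_
                               else r$alt_statistic,
               alt_limit = if (is.null(r$alt_limit)) NA_real_
                           else as.numeric(r$alt_limit),
               alt_scope = if (is.null(r$alt_scope)) NA_character_
                           else r$alt_scope,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rules)
}

#' Per-structure dose statistics
#'
#' @param grid a [dose_grid()]
#' @param masks named list of logical masks (one per structure)
#' @return data frame with one row per structure: `Dmax`, `Dmean`, `D1cc`
#'   (NA when the structure is smaller than 1 cm^3) and `D1pct`, all in Gy
#' @export
structure_dose_stats <- function(grid, masks) {
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!any(m)) {
      return(data.frame(structure = nm, Dmax = NA_real_, Dmean = NA_real_,
                        D1cc = NA_real_, D1pct = NA_real_,
                        stringsAsFactors = FALSE))
    }
    dvh <- cumulative_dvh(grid, m)
    data.frame(structure = nm, Dmax = dvh$d_max, Dmean = dvh$d_mean,
               D1cc = if (dvh$volume_cc >= 1) {
                 dose_at_volume(dvh, q_cc = 1)
               } else NA_real_,
               D1pct = dose_at_volume(dvh, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a constraint protocol against structure dose statistics
#'
#' Each rule is evaluated on its named statistic with a strict `<`
#' comparison. A rule with an alternate clause passes when either clause
#' passes; with `alt_scope: either_side` (paired organs) the alternate
#' passes when at least one matched structure meets the alternate limit.
#' Rules whose pattern matches no structure are reported as not evaluated.
#'
#' @param stats data frame from [structure_dose_stats()]
#' @param protocol data frame from [hn_constraint_protocol()]
#' @return data frame: one row per (rule, matched structure) with the
#'   evaluated value, `pass` (logical, NA when not evaluated) and `margin`
#'   (limit minus value, Gy)
#' @export
evaluate_constraints <- function(stats, protocol) {
  out <- list()
  for (ri in seq_len(nrow(protocol))) {
    rule <- protocol[ri, ]
    hits <- grepl(rule$pattern, stats$structure, ignore.case = TRUE)
    if (!any(hits)) {
      out[[length(out) + 1L]] <- data.frame(
        organ = rule$organ, structure = NA_character_,
        statistic = rule$statistic, value = NA_real_, limit = rule$limit,
        pass = NA, margin = NA_real_, evaluated = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    sub <- stats[hits, , drop = FALSE]
    main_vals <- sub[[rule$statistic]]
    alt_ok_side <- FALSE
    if (!is.na(rule$alt_statistic) &&
        identical(rule$alt_scope, "either_side")) {
      av <- sub[[rule$alt_statistic]]
      alt_ok_side <- any(av < rule$alt_limit, na.rm = TRUE)
    }
    for (si in seq_len(nrow(sub))) {
      v <- main_vals[si]
      pass <- !is.na(v) && v < rule$limit
      if (!pass && !is.na(rule$alt_statistic)) {
        if (identical(rule$alt_scope, "either_side")) {
          pass <- alt_ok_side
        } else {
          av <- sub[[rule$alt_statistic]][si]
          pass <- !is.na(av) && av < rule$alt_limit
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        organ = rule$organ, structure = sub$structure[si],
        statistic = rule$statistic, value = v, limit = rule$limit,
        pass = pass, margin = rule$limit - v, evaluated = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Global hot spot and plan normalization factor
#'
#' The hot spot is the maximum body dose as a percentage of the
#' prescription; clinical practice requires it not to exceed 110% (strict).
#' The normalization scale rescales dose so that 95% of the target volume
#' receives the full prescription (`scale = prescription / D95(PTV)`); it
#' is returned, not applied.
#'
#' @param grid a [dose_grid()]
#' @param ptv_mask logical array of the target
#' @param prescription prescription dose, Gy
#' @param body_mask optional logical array of the body (defaults to the
#'   whole grid)
#' @return list with `hotspot_pct`, `scale`, `v100_pct` (target volume
#'   percentage at or above the prescription), and flags `hotspot_exceeded`
#'   (hotspot strictly above 110) and `coverage_low` (V100 below 95)
#' @export
hot_spot_and_normalization <- function(grid, ptv_mask, prescription,
                                       body_mask = NULL) {
  body_max <- if (is.null(body_mask)) max(grid$values)
              else max(grid$values[body_mask])
  hotspot <- 100 * body_max / prescription
  dvh <- cumulative_dvh(grid, ptv_mask)
  d95 <- dose_at_volume(dvh, 95)
  v100 <- 100 * mean(grid$values[ptv_mask] >= prescription)
  list(hotspot_pct = hotspot, scale = prescription / d95,
       v100_pct = v100,
       hotspot_exceeded = hotspot > 110,
       coverage_low = v100 < 95)
}
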