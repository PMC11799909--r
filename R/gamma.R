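# 2D gamma-index comparison of dose images (portal-dosimetry style
# patient-specific QA). Global normalization to the maximum reference dose;
# the low-dose threshold excludes reference pixels from both numerator and
# denominator of the passing rate.

#' Dose image
#'
#' @param values 2D numeric matrix (dose, consistent units), non-negative
#' @param spacing length-2 numeric `(dx, dy)` pixel spacing, mm
#' @return object of class `dose_image`
#' @export
dose_image <- function(values, spacing = c(1, 1)) {
  stopifnot(is.matrix(values), all(spacing > 0))
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "dose_image")
}

#' Gamma criterion
#'
#' @param dose_diff dose-difference criterion, percent of the normalization
#'   (maximum reference) dose
#' @param dta distance-to-agreement criterion, mm
#' @param threshold low-dose threshold, percent of maximum reference dose;
#'   reference pixels below it are not evaluated
#' @return object of class `gamma_criterion`
#' @export
gamma_criterion <- function(dose_diff = 3, dta = 2, threshold = 10) {
  stopifnot(dose_diff > 0, dta > 0, threshold > 0)
  structure(list(dose_diff = dose_diff, dta = dta, threshold = threshold),
            class = "gamma_criterion")
}

# bilinear sample of matrix M at fractional pixel offsets (constant shift);
# returns matrix of M's size with NA outside the domain
.shift_bilinear <- function(M, di, dj) {
  nr <- nrow(M); nc <- ncol(M)
  i0 <- floor(di); j0 <- floor(dj)
  fi <- di - i0; fj <- dj - j0
  get_shift <- function(si, sj) {
    out <- matrix(NA_real_, nr, nc)
    ri <- seq_len(nr) + si; rj <- seq_len(nc) + sj
    ok_i <- ri >= 1L & ri <= nr; ok_j <- rj >= 1L & rj <= nc
    out[ok_i, ok_j] <- M[ri[ok_i], rj[ok_j]]
    out
  }
  # zero-weight corners must not contribute NA (integer-pixel offsets)
  acc <- matrix(0, nr, nc)
  wts <- c((1 - fi) * (1 - fj), fi * (1 - fj), (1 - fi) * fj, fi * fj)
  sis <- c(i0, i0 + 1L, i0, i0 + 1L)
  sjs <- c(j0, j0, j0 + 1L, j0 + 1L)
  for (q in 1:4) {
    if (wts[q] > 0) acc <- acc + wts[q] * get_shift(sis[q], sjs[q])
  }
  acc
}

#' Gamma map and passing rate for a dose-image pair
#'
#' For every reference pixel at or above the low-dose threshold, the gamma
#' index is the minimum over a search disc of
#' `sqrt((dose difference / DD)^2 + (distance / DTA)^2)`, with the dose
#' difference normalized globally to the maximum reference dose. The
#' evaluated image is sampled by bilinear interpolation on a grid of step
#' `dta / step_divisor` out to `search_radius_dta * dta`; offsets are
#' visited in order of increasing distance, with early termination once the
#' distance term alone exceeds every pixel's current minimum.
#'
#' @param reference,evaluated [dose_image()] objects on the same grid
#' @param criterion a [gamma_criterion()]
#' @param search_radius_dta search disc radius in units of DTA
#' @param step_divisor interpolation step is `dta / step_divisor`
#' @return object of class `gamma_result`: list with `gamma_map` (matrix,
#'   NA below threshold), `passing_rate` (percent of evaluated pixels with
#'   gamma at most 1), `n_evaluated` and the criterion
#' @export
gamma_map <- function(reference, evaluated,
                      criterion = gamma_criterion(),
                      search_radius_dta = 3, step_divisor = 10) {
  R <- reference$values; E <- evaluated$values
  stopifnot(all(dim(R) == dim(E)),
            all(abs(reference$spacing - evaluated$spacing) < 1e-9))
  dmax <- max(R)
  if (dmax <= 0) stop("maximum reference dose is zero")
  dd_abs <- criterion$dose_diff / 100 * dmax
  dta <- criterion$dta
  eval_mask <- R >= criterion$threshold / 100 * dmax
  if (!any(eval_mask)) stop("no reference pixel above the dose threshold")
  step <- dta / step_divisor
  radius <- search_radius_dta * dta
  k <- floor(radius / step)
  offs <- expand.grid(ox = (-k:k) * step, oy = (-k:k) * step)
  offs$r2 <- offs$ox^2 + offs$oy^2
  offs <- offs[offs$r2 <= radius^2 + 1e-12, ]
  offs <- offs[order(offs$r2), ]
  g2 <- matrix(Inf, nrow(R), ncol(R))
  dx <- reference$spacing[1]; dy <- reference$spacing[2]
  worst <- Inf
  for (t in seq_len(nrow(offs))) {
    dist2 <- offs$r2[t] / dta^2
    if (dist2 >= worst) break  # no pixel can improve further
    Es <- .shift_bilinear(E, offs$ox[t] / dx, offs$oy[t] / dy)
    cand <- ((Es - R) / dd_abs)^2 + dist2
    better <- !is.na(cand) & cand < g2
    g2[better] <- cand[better]
    worst <- max(g2[eval_mask])
  }
  gmap <- sqrt(g2)
  gmap[!eval_mask] <- NA_real_
  n_eval <- sum(eval_mask)
  structure(list(gamma_map = gmap,
                 passing_rate = 100 * sum(gmap[eval_mask] <= 1) / n_eval,
                 n_evaluated = n_eval, criterion = criterion),
            class = "gamma_result")
}

#' Gamma passing-rate table over a cohort of image pairs
#'
#' @param pairs list of `list(reference=, evaluated=)` [dose_image()] pairs
#' @param criteria list of [gamma_criterion()] objects
#' @param ... passed to [gamma_map()]
#' @return list with `rates` (data frame: pair, criterion label, rate) and
#'   `summary` (per criterion: Max, Min, Mean, SD and n; SD is 0 with
#'   `n_flagged = TRUE` when only one pair is supplied)
#' @export
passing_rate_table <- function(pairs, criteria, ...) {
  stopifnot(length(pairs) >= 1, length(criteria) >= 1)
  lab <- vapply(criteria, function(cr) {
    sprintf("%g%%/%g mm", cr$dose_diff, cr$dta)
  }, character(1))
  rows <- list()
  for (ci in seq_along(criteria)) {
    for (pi in seq_along(pairs)) {
      res <- gamma_map(pairs[[pi]]$reference, pairs[[pi]]$evaluated,
                       criteria[[ci]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pi, criterion = lab[ci], rate = res$passing_rate,
        stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(lab, function(l) {
    r <- rates$rate[rates$criterion == l]
    data.frame(criterion = l, Max = max(r), Min = min(r), Mean = mean(r),
               SD = if (length(r) > 1) stats::sd(r) else 0,
               n = length(r), n_flagged = length(r) == 1,
               stringsAsFactors = FALSE)
  }))
  list(rates = rates, summary = summ)
}
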