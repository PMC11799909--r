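# Independent brute-force oracles used to validate the vectorized
# implementations. All are deliberately written as plain scalar loops.

# loop-based complexity metrics for one beam
oracle_beam_metrics <- function(beam, config = complexity_config()) {
  nb <- length(beam$leaf_boundaries) - 1L
  cps <- beam$control_points
  ncp <- length(cps)
  th <- config$sas_thresholds
  area <- numeric(ncp); casv <- numeric(ncp); clsv <- numeric(ncp)
  sasv <- matrix(0, ncp, length(th))
  for (t in seq_len(ncp)) {
    cp <- cps[[t]]
    n_in <- 0L; n_cross <- 0L; n_closed <- 0L; n_open <- 0L
    small <- numeric(length(th)); a_sum <- 0
    for (p in seq_len(nb)) {
      lo <- beam$leaf_boundaries[p]; hi <- beam$leaf_boundaries[p + 1L]
      if (hi <= cp$jaw_y[1] || lo >= cp$jaw_y[2]) next
      n_in <- n_in + 1L
      a <- cp$bank_a_positions[p]; b <- cp$bank_b_positions[p]
      left <- max(a, cp$jaw_x[1]); right <- min(b, cp$jaw_x[2])
      if (right > left) a_sum <- a_sum + (right - left) * (hi - lo)
      if (a > 0) n_cross <- n_cross + 1L
      if (b < 0) n_cross <- n_cross + 1L
      gap <- b - a
      if (gap <= config$closed_tolerance) {
        n_closed <- n_closed + 1L
      } else {
        n_open <- n_open + 1L
        for (k in seq_along(th)) {
          if (gap < th[k]) small[k] <- small[k] + 1
        }
      }
    }
    area[t] <- a_sum
    casv[t] <- if (n_in > 0) n_cross / (2 * n_in) else 0
    clsv[t] <- if (n_in > 0) n_closed / n_in else 0
    sasv[t, ] <- if (n_open > 0) 100 * small / n_open else 0
  }
  w <- vapply(cps, function(cp) cp$cumulative_meterset_weight, numeric(1))
  wmean <- function(v) {
    s <- 0; tot <- 0
    for (t in seq_len(ncp - 1L)) {
      dw <- w[t + 1L] - w[t]
      s <- s + (v[t] + v[t + 1L]) / 2 * dw
      tot <- tot + dw
    }
    s / tot
  }
  list(MFA = wmean(area), CAS = wmean(casv), CLS = wmean(clsv),
       SAS = apply(sasv, 2, wmean),
       MU_per_CP = beam$beam_mu / ncp)
}

# loop-based leaf speeds/accelerations for one bank
oracle_kinematics <- function(positions, times) {
  n_leaves <- nrow(positions); n_cp <- ncol(positions)
  sp <- matrix(0, n_leaves, n_cp - 1L)
  for (l in seq_len(n_leaves)) {
    for (t in seq_len(n_cp - 1L)) {
      if (times[t] > 0) {
        sp[l, t] <- abs(positions[l, t + 1L] - positions[l, t]) / times[t]
      }
    }
  }
  acc <- matrix(0, n_leaves, max(n_cp - 2L, 0L))
  if (n_cp >= 3L) {
    for (l in seq_len(n_leaves)) {
      for (t in seq_len(n_cp - 2L)) {
        dt <- (times[t] + times[t + 1L]) / 2
        if (dt > 0) acc[l, t] <- abs(sp[l, t + 1L] - sp[l, t]) / dt
      }
    }
  }
  list(speed = sp, accel = acc)
}

# random tiny beam for oracle-equivalence checks: few control points, few
# leaf pairs, gaps possibly closed, jaws possibly clipping
random_tiny_beam <- function(seed) {
  set.seed(seed)
  n_pairs <- 4L
  n_cp <- sample(3:5, 1)
  boundaries <- seq(-10, 10, length.out = n_pairs + 1L)
  w <- sort(c(0, runif(n_cp - 2L), 1))
  jaw_x <- c(runif(1, -40, -10), runif(1, 10, 40))
  jaw_y <- c(runif(1, -12, -2), runif(1, 2, 12))
  cps <- lapply(seq_len(n_cp), function(j) {
    a <- runif(n_pairs, -30, 10)
    gap <- ifelse(runif(n_pairs) < 0.3, 0, runif(n_pairs, 0, 40))
    control_point(j - 1L, w[j], (j * 7) %% 360, a, a + gap, jaw_x, jaw_y)
  })
  rt_beam(runif(1, 50, 400), cps, boundaries)
}

# brute-force gamma passing rate: upsample the evaluated image to a fine
# grid once, then take per-pixel minima over a square search window
oracle_gamma_rate <- function(reference, evaluated, criterion,
                              step_divisor = 10, search_radius_dta = 3) {
  R <- reference$values
  sp <- reference$spacing
  dmax <- max(R)
  dd <- criterion$dose_diff / 100 * dmax
  dta <- criterion$dta
  step <- dta / step_divisor
  stopifnot(abs(sp[1] / step - round(sp[1] / step)) < 1e-9)
  ratio <- round(sp[1] / step)
  nx <- nrow(R); ny <- ncol(R)
  fx <- seq(0, (nx - 1) * sp[1], by = step)
  fy <- seq(0, (ny - 1) * sp[2], by = step)
  # independent bilinear upsample
  ex_i <- pmin(fx / sp[1] + 1, nx); ey_j <- pmin(fy / sp[2] + 1, ny)
  i0 <- pmin(floor(ex_i), nx - 1L); j0 <- pmin(floor(ey_j), ny - 1L)
  fi <- ex_i - i0; fj <- ey_j - j0
  E <- evaluated$values
  Ef <- matrix(0, length(fx), length(fy))
  for (jj in seq_along(fy)) {
    c0 <- E[, j0[jj]]; c1 <- E[, j0[jj] + 1L]
    col <- c0 * (1 - fj[jj]) + c1 * fj[jj]
    Ef[, jj] <- col[i0] * (1 - fi) + col[i0 + 1L] * fi
  }
  k <- search_radius_dta * step_divisor
  off <- (-k:k) * step
  dist2 <- outer(off^2, off^2, "+") / dta^2
  dist2[dist2 > search_radius_dta^2 + 1e-12] <- Inf
  mask <- R >= criterion$threshold / 100 * dmax
  n_pass <- 0L; n_eval <- 0L
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (!mask[i, j]) next
      n_eval <- n_eval + 1L
      ci <- (i - 1L) * ratio + 1L; cj <- (j - 1L) * ratio + 1L
      ri <- max(1L, ci - k):min(length(fx), ci + k)
      rj <- max(1L, cj - k):min(length(fy), cj + k)
      sub <- Ef[ri, rj, drop = FALSE]
      d2 <- dist2[ri - ci + k + 1L, rj - cj + k + 1L, drop = FALSE]
      g2 <- min(((sub - R[i, j]) / dd)^2 + d2)
      if (g2 <= 1) n_pass <- n_pass + 1L
    }
  }
  100 * n_pass / n_eval
}

# exhaustive 2^n sign-flip enumeration for the signed-rank p-value
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    sum(r[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}
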