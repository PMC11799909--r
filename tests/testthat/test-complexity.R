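test_that("leaf kinematics match a scalar-loop oracle", {
  for (seed in 1:8) {
    b <- random_tiny_beam(seed)
    times <- segment_times(b)
    k <- leaf_kinematics(b, times)
    arr <- planscope:::.beam_arrays(b)
    oa <- oracle_kinematics(arr$A, times)
    ob <- oracle_kinematics(arr$B, times)
    expect_equal(k$speed_a, oa$speed, tolerance = 1e-12)
    expect_equal(k$speed_b, ob$speed, tolerance = 1e-12)
    expect_equal(k$accel_a, oa$accel, tolerance = 1e-12)
    expect_equal(k$accel_b, ob$accel, tolerance = 1e-12)
  }
})

test_that("fraction_in_range is half-open and partitions sum to one", {
  v <- c(0, 3.999, 4, 16, 19.999, 20, 25)
  expect_equal(fraction_in_range(v, 0, 4), 2 / 7)
  expect_equal(fraction_in_range(v, 16, 20), 2 / 7)
  cfg <- complexity_config()
  total <- sum(vapply(cfg$speed_bins, function(bin) {
    fraction_in_range(v, bin[1], bin[2])
  }, numeric(1)))
  expect_equal(total, 1)
  expect_error(fraction_in_range(numeric(0), 0, 1), "empty")
})

test_that("aperture_area follows hand-computed jaw clipping", {
  boundaries <- c(0, 5, 10)
  cp <- control_point(0, 0, 180, c(-10, -2), c(10, 4),
                      jaw_x = c(-5, 8), jaw_y = c(0, 10))
  # pair 1: [-5, 8] x 5 mm = 65; pair 2: [-2, 4] x 5 mm = 30
  expect_equal(aperture_area(cp, boundaries), 95)
  # y jaws excluding the first leaf strip
  cp2 <- control_point(0, 0, 180, c(-10, -2), c(10, 4),
                       jaw_x = c(-5, 8), jaw_y = c(5, 10))
  expect_equal(aperture_area(cp2, boundaries), 30)
  # closed pair contributes zero
  cp3 <- control_point(0, 0, 180, c(3, -2), c(3, 4), jaw_x = c(-50, 50),
                       jaw_y = c(0, 10))
  expect_equal(aperture_area(cp3, boundaries), 30)
})

test_that("per-control-point scores count crossings, closures and gaps", {
  boundaries <- c(-10, -5, 0, 5, 10)
  # pair 1 crosses with bank A (both tips > 0), pair 2 closed at the axis,
  # pair 3 small gap (0.8), pair 4 wide open
  mk <- function(w) control_point(0, w, 180,
                                  c(2, 0, -0.4, -15), c(6, 0, 0.4, 15),
                                  jaw_x = c(-100, 100), jaw_y = c(-12, 12))
  b <- rt_beam(10, list(mk(0), mk(1)), boundaries)
  expect_equal(cas(b), 1 / 8)        # 1 crossing leaf of 8
  expect_equal(cls(b), 1 / 4)        # 1 closed pair of 4
  expect_equal(sas(b, 1), 100 / 3)   # 1 small of 3 open pairs
  expect_equal(sas(b, 10), 200 / 3)  # gaps 4 and 0.8 below 10 mm
  expect_equal(mfa(b), 4 * 5 + 0.8 * 5 + 30 * 5)
})

test_that("a control point with no open pair scores SAS 0", {
  boundaries <- c(-5, 0, 5)
  closed <- control_point(0, 0, 180, c(0, 1), c(0, 1))
  open_cp <- control_point(1, 1, 182, c(-0.3, 1), c(0.4, 1.8))
  b <- rt_beam(10, list(closed, open_cp), boundaries)
  # segment mean of per-control-point scores (0 + 100)/2
  expect_equal(sas(b, 1), 50)
})

test_that("aperture scores are delta-MU weighted over segments", {
  wm <- planscope:::.segment_weighted_mean
  expect_equal(wm(c(0, 0, 1), c(0, 0.8, 1)), 0.1)
  expect_equal(wm(c(0, 0, 1), c(0, 0.8, 1), mu_weighted = FALSE), 0.25)
  expect_error(wm(c(1, 2), c(0.5, 0.5)), "increments are zero")
})

test_that("complexity scores equal the brute-force oracle on tiny beams", {
  cfg <- complexity_config()
  for (seed in 101:110) {
    b <- random_tiny_beam(seed)
    o <- oracle_beam_metrics(b, cfg)
    expect_equal(mfa(b, cfg), o$MFA, tolerance = 1e-12)
    expect_equal(cas(b, cfg), o$CAS, tolerance = 1e-12)
    expect_equal(cls(b, cfg), o$CLS, tolerance = 1e-12)
    for (k in seq_along(cfg$sas_thresholds)) {
      expect_equal(sas(b, cfg$sas_thresholds[k], cfg), o$SAS[k],
                   tolerance = 1e-12)
    }
    expect_equal(mu_per_cp(b), o$MU_per_CP)
  }
})

test_that("mu_per_cp pools MU and control points at plan level", {
  res1 <- synth_plan(21, n_arcs = 1, n_cp_per_arc = 10, n_leaf_pairs = 4,
                     total_mu = 100)
  res2 <- synth_plan(22, n_arcs = 1, n_cp_per_arc = 30, n_leaf_pairs = 4,
                     total_mu = 60)
  plan <- rt_plan("pooled", c(res1$plan$beams, res2$plan$beams))
  expect_equal(mu_per_cp(plan), 160 / 40)
  # pooled, not the mean of per-beam ratios
  expect_false(isTRUE(all.equal(mu_per_cp(plan), mean(c(10, 2)))))
})

test_that("plan aggregation sums CAS/CLS/SAS and MU-weights MFA", {
  res <- synth_plan(23, n_arcs = 3, n_cp_per_arc = 20, n_leaf_pairs = 10)
  rep <- plan_complexity_report(res$plan)
  pb <- rep$per_beam
  expect_equal(rep$per_plan$CAS, sum(pb$CAS))
  expect_equal(rep$per_plan$CLS, sum(pb$CLS))
  expect_equal(rep$per_plan$SAS_1mm, sum(pb$SAS_1mm))
  mu <- vapply(res$plan$beams, `[[`, numeric(1), "beam_mu")
  expect_equal(rep$per_plan$MFA, sum(pb$MFA * mu) / sum(mu))
  expect_named(rep$per_plan,
               c("LS_A16-20", "LS_B16-20", "LA_A160-200", "LA_B160-200",
                 "MFA", "CAS", "CLS", "SAS_1mm", "SAS_2mm", "SAS_5mm",
                 "SAS_10mm", "MU_per_CP"),
               ignore.order = TRUE)
  cfg2 <- complexity_config(plan_aggregation = "mu_weighted_mean")
  rep2 <- plan_complexity_report(res$plan, cfg2)
  expect_lte(rep2$per_plan$CAS, max(pb$CAS) + 1e-12)
  expect_gte(rep2$per_plan$CAS, min(pb$CAS) - 1e-12)
})

test_that("plan-level speed fractions pool samples across beams", {
  res <- synth_plan(24, n_arcs = 2, n_cp_per_arc = 15, n_leaf_pairs = 6)
  rep <- plan_complexity_report(res$plan)
  pooled <- unlist(lapply(res$plan$beams, function(b) {
    leaf_kinematics(b)$speed_a
  }))
  expect_equal(rep$per_plan[["LS_A16-20"]],
               fraction_in_range(pooled, 16, 20))
})

test_that("complexity_config validates bins and thresholds", {
  expect_error(complexity_config(sas_thresholds = c(2, 1)))
  expect_error(complexity_config(closed_tolerance = 1.5))
  expect_error(complexity_config(
    speed_bins = list(c(0, 4), c(3, 8))))
})
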