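test_that("rasterization counts voxel centers inside polygons", {
  g <- dose_grid(array(1, c(21, 21, 3)), origin = c(-10, -10, -1))
  sq <- function(h) cbind(c(-h, h, h, -h), c(-h, -h, h, h))
  m <- rasterize_structure(list(list(z = 0, xy = sq(4.5))), g)
  expect_equal(sum(m), 81)          # centers -4..4 on the z = 0 slice only
  expect_true(all(which(m, arr.ind = TRUE)[, 3] == 2))
  # nested contours on one slice punch a hole (even-odd rule)
  m2 <- rasterize_structure(list(list(z = 0, xy = sq(4.5)),
                                 list(z = 0, xy = sq(1.5))), g)
  expect_equal(sum(m2), 81 - 9)
  # a contour within half a slice spacing maps to the nearest slice
  m3 <- rasterize_structure(list(list(z = 0.4, xy = sq(4.5))), g)
  expect_equal(m3, m)
  expect_warning(rasterize_structure(list(), g), "no contours")
  expect_warning(
    rasterize_structure(list(list(z = 50, xy = sq(4.5))), g),
    "no contour overlaps")
})

test_that("cumulative DVH starts at 1, ends at 0 and matches raw stats", {
  vals <- array(0, c(10, 10, 1))
  vals[1:4, 1, 1] <- c(10, 20, 30, 40)
  g <- dose_grid(vals, spacing = c(2, 2, 2))
  mask <- array(FALSE, dim(vals)); mask[1:4, 1, 1] <- TRUE
  dvh <- cumulative_dvh(g, mask)
  expect_equal(dvh$cum_volume[1], 1)
  expect_equal(dvh$cum_volume[length(dvh$cum_volume)], 0)
  expect_true(all(diff(dvh$cum_volume) <= 0))
  expect_equal(dvh$d_max, 40)
  expect_equal(dvh$d_mean, 25)
  expect_equal(dvh$volume_cc, 4 * 8 / 1000)
  # largest dose covering at least half the volume
  expect_equal(dose_at_volume(dvh, 50), 30)
  expect_equal(dose_at_volume(dvh, 100), 10)
  # absolute-volume query: 1 cc of 0.032 cc is impossible
  expect_error(dose_at_volume(dvh, q_cc = 1), "exceeds structure volume")
  expect_equal(dose_at_volume(dvh, q_cc = 0.016), 30)
  expect_error(cumulative_dvh(g, array(FALSE, dim(vals))), "empty mask")
})

test_that("dose_at_volume interpolates within a bin width", {
  vals <- array(50, c(5, 5, 1))
  g <- dose_grid(vals)
  dvh <- cumulative_dvh(g, array(TRUE, dim(vals)))
  expect_lt(abs(dose_at_volume(dvh, 95) - 50), 0.01)
  expect_lt(abs(dose_at_volume(dvh, 2) - 50), 0.01)
})

test_that("conformity number follows its defining ratio product", {
  vals <- array(0, c(4, 1, 1))
  vals[, 1, 1] <- c(10, 10, 10, 0)
  g <- dose_grid(vals)
  ptv <- array(FALSE, dim(vals)); ptv[1:2, 1, 1] <- TRUE
  # PTV_PD = 2, PTV = 2, PIV = 3
  expect_equal(conformity_number(g, ptv, 10), (2 / 2) * (2 / 3))
  # body mask excludes the third hot voxel
  body <- array(FALSE, dim(vals)); body[1:2, 1, 1] <- TRUE
  expect_equal(conformity_number(g, ptv, 10, body), 1)
  # nothing reaches the prescription
  expect_equal(conformity_number(g, ptv, 50), 0)
  expect_error(conformity_number(g, array(FALSE, dim(vals)), 10),
               "empty PTV")
})

test_that("heterogeneity index is near zero for uniform dose", {
  vals <- array(70, c(6, 6, 1))
  g <- dose_grid(vals)
  dvh <- cumulative_dvh(g, array(TRUE, dim(vals)))
  expect_lt(heterogeneity_index(dvh), 0.001)
})

test_that("structure_dose_stats reports D1cc only above 1 cc", {
  vals <- array(seq(1, 8), c(2, 2, 2))
  g <- dose_grid(vals, spacing = c(10, 10, 10))  # 1 cc voxels
  big <- array(TRUE, dim(vals))
  small <- array(FALSE, dim(vals)); small[1, 1, 1] <- TRUE
  # 1 cc voxels: the small structure is exactly 1 cc, the big one 8 cc
  st <- structure_dose_stats(g, list(big = big, small = small))
  expect_equal(st$Dmax, c(8, 1))
  expect_equal(st$Dmean, c(4.5, 1))
  expect_false(is.na(st$D1cc[1]))
  g2 <- dose_grid(vals, spacing = c(5, 5, 5))
  st2 <- structure_dose_stats(g2, list(small = small))
  expect_true(is.na(st2$D1cc))     # 0.125 cc structure
})

test_that("constraint evaluation applies strict limits and alternates", {
  protocol <- hn_constraint_protocol()
  stats <- data.frame(
    structure = c("spinal_cord", "brain_stem", "parotid_l", "parotid_r"),
    Dmax = c(44.9, 56, 60, 60),
    Dmean = c(30, 40, 28, 29.5),
    D1cc = c(40, 50, 55, 55),
    D1pct = c(42, 58, 58, 58),
    stringsAsFactors = FALSE)
  ev <- evaluate_constraints(stats, protocol)
  cord <- ev[ev$organ == "Spinal cord", ]
  expect_true(cord$pass)
  expect_equal(cord$margin, 45 - 44.9)
  # brain stem fails Dmax < 54 but passes the D1pct < 60 alternate
  bs <- ev[ev$organ == "Brain stem" & ev$evaluated, ]
  expect_true(bs$pass)
  # parotids: both means over 26, but one side under 30 rescues both rows
  par <- ev[ev$organ == "Parotid" & ev$evaluated, ]
  expect_equal(nrow(par), 2)
  expect_true(all(par$pass))
  # organs absent from the case are reported as not evaluated
  chiasm <- ev[ev$organ == "Chiasm", ]
  expect_false(chiasm$evaluated)
  expect_true(is.na(chiasm$pass))
  # strict comparison: a value exactly at the limit fails
  stats2 <- stats
  stats2$Dmax[1] <- 45
  ev2 <- evaluate_constraints(stats2, protocol)
  expect_false(ev2[ev2$organ == "Spinal cord", "pass"])
})

test_that("both parotids failing leaves the paired rule failed", {
  protocol <- hn_constraint_protocol()
  stats <- data.frame(structure = c("parotid_l", "parotid_r"),
                      Dmax = c(60, 60), Dmean = c(31, 33),
                      D1cc = c(55, 55), D1pct = c(58, 58),
                      stringsAsFactors = FALSE)
  ev <- evaluate_constraints(stats, protocol)
  par <- ev[ev$organ == "Parotid" & ev$evaluated, ]
  expect_false(any(par$pass))
})

test_that("hot spot flag is strict at 110% and scale renormalizes D95", {
  vals <- array(70, c(8, 8, 1))
  vals[1, 1, 1] <- 77       # exactly 110%
  g <- dose_grid(vals)
  ptv <- array(TRUE, dim(vals))
  hs <- hot_spot_and_normalization(g, ptv, 70)
  expect_equal(hs$hotspot_pct, 110)
  expect_false(hs$hotspot_exceeded)
  vals[1, 1, 1] <- 77.1
  hs2 <- hot_spot_and_normalization(dose_grid(vals), ptv, 70)
  expect_true(hs2$hotspot_exceeded)
  expect_equal(hs2$v100_pct, 100)
  expect_false(hs2$coverage_low)
  expect_equal(hs2$scale, 70 / dose_at_volume(cumulative_dvh(
    dose_grid(vals), ptv), 95))
})
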