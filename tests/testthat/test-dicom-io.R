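test_that("the low-level codec round-trips mixed-VR datasets", {
  ds <- list(
    "00080016" = planscope:::dcm_el("UI", "1.2.840.10008.5.1.4.1.1.481.5"),
    "00080018" = planscope:::dcm_el("UI", "2.25.1"),
    "00080060" = planscope:::dcm_el("CS", "RTPLAN"),
    "00280010" = planscope:::dcm_el("US", 513L),
    "00280008" = planscope:::dcm_el("IS", "12"),
    "30040010" = planscope:::dcm_el("SQ", list(
      list("300A0026" = planscope:::dcm_el("DS", "70.0000")),
      list("300A0026" = planscope:::dcm_el("DS", "54.0000"))
    )),
    "7FE00010" = planscope:::dcm_el("OW", as.raw(c(1, 2, 3, 255)))
  )
  path <- withr::local_tempfile(fileext = ".dcm")
  planscope:::dcm_write(ds, path)
  back <- planscope:::dcm_read(path)$data
  expect_equal(planscope:::dcm_str(back, "00080060"), "RTPLAN")
  expect_identical(planscope:::dcm_get(back, "00280010"), 513L)
  expect_equal(length(planscope:::dcm_get(back, "30040010")), 2)
  expect_equal(planscope:::dcm_num(
    planscope:::dcm_get(back, "30040010")[[2]], "300A0026"), 54)
  expect_identical(planscope:::dcm_get(back, "7FE00010"),
                   as.raw(c(1, 2, 3, 255)))
  expect_error(planscope:::dcm_read(
    withr::local_tempfile(lines = "not dicom")), "DICM magic")
})

test_that("RT Plan write/read restores every plan field and is byte-stable", {
  res <- synth_plan(5, n_arcs = 2, n_cp_per_arc = 30, n_leaf_pairs = 12)
  plan <- res$plan
  p1 <- withr::local_tempfile(fileext = ".dcm")
  p2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, p1)
  back <- read_rtplan(p1)
  expect_identical(back$plan_id, plan$plan_id)
  expect_identical(back$prescription_dose, plan$prescription_dose)
  expect_identical(back$n_fractions, plan$n_fractions)
  for (bi in seq_along(plan$beams)) {
    b0 <- plan$beams[[bi]]; b1 <- back$beams[[bi]]
    expect_identical(b1$beam_mu, b0$beam_mu)
    expect_identical(b1$leaf_boundaries, b0$leaf_boundaries)
    expect_identical(b1$arc_direction, b0$arc_direction)
    for (k in seq_along(b0$control_points)) {
      expect_identical(b1$control_points[[k]], b0$control_points[[k]])
    }
  }
  write_rtplan(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("RT Dose write/read is exact for quantized grids", {
  case <- synth_case(grid_size = 32, spacing = 3, ptv_radii = c(10, 20, 30),
                     body_radius = 40)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(case$grid, path)
  back <- read_rtdose(path)
  expect_identical(back$values, case$grid$values)
  expect_identical(back$origin, case$grid$origin)
  expect_identical(back$spacing, case$grid$spacing)
})

test_that("unquantized dose round-trips within one scaling quantum", {
  set.seed(1)
  vals <- array(runif(4^3, 0, 70), c(4, 4, 4))
  g <- dose_grid(vals)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, path)
  back <- read_rtdose(path)
  quantum <- planscope:::.dose_scaling(max(vals))
  expect_lt(max(abs(back$values - vals)), quantum)
})

test_that("RT Structure Set write/read preserves names and contours", {
  case <- synth_case(grid_size = 16, spacing = 6, ptv_radii = c(10, 20, 30),
                     body_radius = 40)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(case$structures, path)
  back <- read_rtstruct(path)
  expect_identical(names(back$structures), names(case$structures$structures))
  expect_identical(back$structures, case$structures$structures)
})

test_that("malformed RT files produce clear errors", {
  # plan without a BeamSequence
  ds <- list(
    "00080016" = planscope:::dcm_el("UI", planscope:::UID_RTPLAN),
    "00080018" = planscope:::dcm_el("UI", "2.25.2"),
    "300A0002" = planscope:::dcm_el("SH", "broken")
  )
  p <- withr::local_tempfile(fileext = ".dcm")
  planscope:::dcm_write(ds, p)
  expect_error(read_rtplan(p), "BeamSequence \\(300A,00B0\\)")

  # dose with a non-uniform GridFrameOffsetVector
  case <- synth_case(grid_size = 8, spacing = 10, ptv_radii = c(8, 15, 25),
                     body_radius = 35)
  pd <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(case$grid, pd)
  raw_ds <- planscope:::dcm_read(pd)$data
  raw_ds[["3004000C"]]$value <- paste(
    c("0.0", "10.0", "25.0", "30.0", "40.0", "50.0", "60.0", "70.0"),
    collapse = "\\")
  planscope:::dcm_write(raw_ds, pd)
  expect_error(read_rtdose(pd), "non-uniform GridFrameOffsetVector")

  # dose without DoseGridScaling
  pd2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(case$grid, pd2)
  raw_ds2 <- planscope:::dcm_read(pd2)$data
  raw_ds2[["3004000E"]] <- NULL
  planscope:::dcm_write(raw_ds2, pd2)
  expect_error(read_rtdose(pd2), "DoseGridScaling")
})

test_that("setup fields are skipped and decreasing weights rejected", {
  res <- synth_plan(6, n_arcs = 1, n_cp_per_arc = 10, n_leaf_pairs = 6)
  p <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(res$plan, p)
  raw_ds <- planscope:::dcm_read(p)$data
  # append a jaw-only setup field
  setup <- list(
    "300A00C0" = planscope:::dcm_el("IS", "99"),
    "300A00C2" = planscope:::dcm_el("LO", "SETUP"),
    "300A00CE" = planscope:::dcm_el("CS", "SETUP"),
    "300A00B6" = planscope:::dcm_el("SQ", list(
      list("300A00B8" = planscope:::dcm_el("CS", "ASYMX"),
           "300A00BC" = planscope:::dcm_el("IS", "1"))))
  )
  raw_ds[["300A00B0"]]$value <- c(raw_ds[["300A00B0"]]$value, list(setup))
  planscope:::dcm_write(raw_ds, p)
  expect_warning(plan2 <- read_rtplan(p), "skipping non-MLC or setup")
  expect_equal(length(plan2$beams), 1)

  # corrupt one cumulative weight so the sequence decreases
  raw_ds[["300A00B0"]]$value[[1]][["300A0111"]]$value[[5]][["300A0134"]] <-
    planscope:::dcm_el("DS", "0.900000")
  planscope:::dcm_write(raw_ds, p)
  expect_error(read_rtplan(p), "non-monotonic")
})

test_that("omitted control-point attributes inherit the previous value", {
  res <- synth_plan(7, n_arcs = 1, n_cp_per_arc = 4, n_leaf_pairs = 4)
  plan <- res$plan
  p <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, p)
  raw_ds <- planscope:::dcm_read(p)$data
  cp_seq <- raw_ds[["300A00B0"]]$value[[1]][["300A0111"]]$value
  # strip gantry and device positions from an interior control point
  cp_seq[[2]][["300A011E"]] <- NULL
  cp_seq[[2]][["300A011A"]] <- NULL
  raw_ds[["300A00B0"]]$value[[1]][["300A0111"]]$value <- cp_seq
  planscope:::dcm_write(raw_ds, p)
  back <- read_rtplan(p)
  cp1 <- back$beams[[1]]$control_points[[1]]
  cp2 <- back$beams[[1]]$control_points[[2]]
  expect_identical(cp2$gantry_angle, cp1$gantry_angle)
  expect_identical(cp2$bank_a_positions, cp1$bank_a_positions)
  expect_identical(cp2$jaw_x, cp1$jaw_x)
})

test_that("cumulative weights are normalized by the final weight", {
  res <- synth_plan(8, n_arcs = 1, n_cp_per_arc = 5, n_leaf_pairs = 4)
  p <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(res$plan, p)
  raw_ds <- planscope:::dcm_read(p)$data
  beam <- raw_ds[["300A00B0"]]$value[[1]]
  cp_seq <- beam[["300A0111"]]$value
  for (k in seq_along(cp_seq)) {
    w <- planscope:::dcm_num(cp_seq[[k]], "300A0134")
    cp_seq[[k]][["300A0134"]] <-
      planscope:::dcm_el("DS", sprintf("%.6f", 2 * w))
  }
  beam[["300A0111"]]$value <- cp_seq
  beam[["300A010E"]] <- planscope:::dcm_el("DS", "2.000000")
  raw_ds[["300A00B0"]]$value[[1]] <- beam
  planscope:::dcm_write(raw_ds, p)
  back <- read_rtplan(p)
  w <- vapply(back$beams[[1]]$control_points, `[[`, numeric(1),
              "cumulative_meterset_weight")
  w0 <- vapply(res$plan$beams[[1]]$control_points, `[[`, numeric(1),
               "cumulative_meterset_weight")
  expect_equal(w, w0)
})

test_that("duplicated ROI names are deduplicated with a warning", {
  sq <- cbind(c(-3, 3, 3, -3), c(-3, -3, 3, 3))
  ss <- structure_set(list(A = list(list(z = 0, xy = sq)),
                           B = list(list(z = 2, xy = sq))))
  p <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(ss, p)
  raw_ds <- planscope:::dcm_read(p)$data
  raw_ds[["30060020"]]$value[[2]][["30060026"]]$value <- "A"
  planscope:::dcm_write(raw_ds, p)
  expect_warning(back <- read_rtstruct(p), "deduplicated")
  expect_setequal(names(back$structures), c("A", "A_1"))
})
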