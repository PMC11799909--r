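# DICOM-RT readers and writers for the plan/dose/structure data model.
# Explicit VR little endian only; MLCX-type MLC, one fraction group.

UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

#' Write a plan to a DICOM RT Plan file
#'
#' Leaf/jaw positions are stored to 0.01 mm, meterset weights to 1e-6 and
#' gantry angles to 1e-4 degrees (the DS quanta of the writer); reading the
#' file back reproduces fields already quantized to those grids exactly.
#' Output is deterministic: the same plan always yields the same bytes.
#'
#' @param plan an [rt_plan()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rtplan <- function(plan, path) {
  beam_items <- list()
  ref_beam_items <- list()
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    n_pairs <- length(b$leaf_boundaries) - 1L
    cp_items <- lapply(b$control_points, function(cp) {
      list(
        "300A0112" = dcm_el("IS", as.character(cp$index)),
        "300A0134" = dcm_el("DS", .ds_fmt(cp$cumulative_meterset_weight, 6L)),
        "300A011E" = dcm_el("DS", .ds_fmt(cp$gantry_angle, 4L)),
        "300A011F" = dcm_el("CS",
                            if (b$arc_direction == "CW") "CW" else "CC"),
        "300A011A" = dcm_el("SQ", list(
          list("300A00B8" = dcm_el("CS", "ASYMX"),
               "300A011C" = dcm_el("DS", .ds_fmt(cp$jaw_x, 2L))),
          list("300A00B8" = dcm_el("CS", "ASYMY"),
               "300A011C" = dcm_el("DS", .ds_fmt(cp$jaw_y, 2L))),
          list("300A00B8" = dcm_el("CS", "MLCX"),
               "300A011C" = dcm_el("DS", .ds_fmt(
                 c(cp$bank_a_positions, cp$bank_b_positions), 2L)))
        ))
      )
    })
    beam_items[[bi]] <- list(
      "300A00C0" = dcm_el("IS", as.character(bi)),
      "300A00C2" = dcm_el("LO", b$name),
      "300A00C4" = dcm_el("CS", "DYNAMIC"),
      "300A00CE" = dcm_el("CS", "TREATMENT"),
      "300A00B6" = dcm_el("SQ", list(
        list("300A00B8" = dcm_el("CS", "ASYMX"),
             "300A00BC" = dcm_el("IS", "1")),
        list("300A00B8" = dcm_el("CS", "ASYMY"),
             "300A00BC" = dcm_el("IS", "1")),
        list("300A00B8" = dcm_el("CS", "MLCX"),
             "300A00BC" = dcm_el("IS", as.character(n_pairs)),
             "300A00BE" = dcm_el("DS", .ds_fmt(b$leaf_boundaries, 2L)))
      )),
      "300A010E" = dcm_el("DS", "1.000000"),
      "300A0110" = dcm_el("IS", as.character(length(b$control_points))),
      "300A0111" = dcm_el("SQ", cp_items)
    )
    ref_beam_items[[bi]] <- list(
      "300A0086" = dcm_el("DS", .ds_fmt(b$beam_mu, 4L)),
      "300C0006" = dcm_el("IS", as.character(bi))
    )
  }
  ds <- list(
    "00080016" = dcm_el("UI", UID_RTPLAN),
    "00080018" = dcm_el("UI", .dcm_uid(paste0("plan:", plan$plan_id))),
    "00080060" = dcm_el("CS", "RTPLAN"),
    "300A0002" = dcm_el("SH", plan$plan_id),
    "300A0010" = dcm_el("SQ", list(list(
      "300A0026" = dcm_el("DS", .ds_fmt(plan$prescription_dose, 4L))
    ))),
    "300A0070" = dcm_el("SQ", list(list(
      "300A0078" = dcm_el("IS", as.character(plan$n_fractions)),
      "300A0080" = dcm_el("IS", as.character(length(plan$beams))),
      "300C0004" = dcm_el("SQ", ref_beam_items)
    ))),
    "300A00B0" = dcm_el("SQ", beam_items)
  )
  dcm_write(ds, path)
}

#' Read a DICOM RT Plan file
#'
#' Arc beams with an MLCX device are imported; setup fields and beams
#' without an MLC are skipped with a warning. Control-point attributes
#' omitted after the first control point (gantry angle, jaws, leaf
#' positions) inherit the previous value, per DICOM convention. Cumulative
#' meterset weights are normalized so the final value is 1.
#'
#' @param path file path
#' @param limits [machine_limits()] to attach to each beam
#' @return an [rt_plan()]
#' @export
read_rtplan <- function(path, limits = machine_limits()) {
  d <- dcm_read(path)$data
  beam_seq <- dcm_get(d, "300A00B0")
  if (is.null(beam_seq)) stop("RT Plan is missing BeamSequence (300A,00B0)")
  # beam MU by referenced beam number, from the (single) fraction group
  fg <- dcm_get(d, "300A0070")
  mu_map <- list()
  if (!is.null(fg) && length(fg) >= 1) {
    for (rb in dcm_get(fg[[1]], "300C0004")) {
      num <- dcm_str(rb, "300C0006")
      mu_map[[num]] <- dcm_num(rb, "300A0086")
    }
  }
  rx <- NA_real_
  dr <- dcm_get(d, "300A0010")
  if (!is.null(dr) && length(dr) >= 1) {
    v <- dcm_num(dr[[1]], "300A0026")
    if (!is.null(v)) rx <- v
  }
  nfx <- 1L
  if (!is.null(fg) && length(fg) >= 1) {
    v <- dcm_num(fg[[1]], "300A0078")
    if (!is.null(v)) nfx <- as.integer(v)
  }
  beams <- list()
  for (bds in beam_seq) {
    bname <- dcm_str(bds, "300A00C2")
    if (is.null(bname)) bname <- paste0("beam", length(beams) + 1L)
    delivery <- dcm_str(bds, "300A00CE")
    bld <- dcm_get(bds, "300A00B6")
    mlc <- NULL
    for (dev in bld) {
      if (identical(dcm_str(dev, "300A00B8"), "MLCX")) mlc <- dev
    }
    if (is.null(mlc) || (!is.null(delivery) && delivery != "TREATMENT")) {
      warning("skipping non-MLC or setup beam '", bname, "'")
      next
    }
    cp_seq <- dcm_get(bds, "300A0111")
    if (is.null(cp_seq)) {
      stop("beam '", bname,
           "' is missing ControlPointSequence (300A,0111)")
    }
    boundaries <- dcm_num(mlc, "300A00BE")
    n_pairs <- length(boundaries) - 1L
    gantry <- NA_real_; jaw_x <- c(-200, 200); jaw_y <- c(-200, 200)
    bank_a <- NULL; bank_b <- NULL; arc_dir <- "CW"
    cps <- vector("list", length(cp_seq))
    for (k in seq_along(cp_seq)) {
      cpd <- cp_seq[[k]]
      g <- dcm_num(cpd, "300A011E"); if (!is.null(g)) gantry <- g
      rot <- dcm_str(cpd, "300A011F")
      if (!is.null(rot) && rot != "NONE") {
        arc_dir <- if (rot == "CC") "CCW" else "CW"
      }
      for (dev in dcm_get(cpd, "300A011A")) {
        typ <- dcm_str(dev, "300A00B8")
        pos <- dcm_num(dev, "300A011C")
        if (typ == "ASYMX" || typ == "X") jaw_x <- pos
        else if (typ == "ASYMY" || typ == "Y") jaw_y <- pos
        else if (typ == "MLCX") {
          bank_a <- pos[seq_len(n_pairs)]
          bank_b <- pos[n_pairs + seq_len(n_pairs)]
        }
      }
      w <- dcm_num(cpd, "300A0134")
      if (is.null(w) || is.null(bank_a)) {
        stop("control point ", k, " of beam '", bname,
             "' lacks meterset weight or MLC positions")
      }
      cps[[k]] <- list(w = w, g = gantry, a = bank_a, b = bank_b,
                       jx = jaw_x, jy = jaw_y)
    }
    w <- vapply(cps, `[[`, numeric(1), "w")
    if (any(diff(w) < -1e-9)) {
      stop("non-monotonic cumulative meterset weights in beam '", bname, "'")
    }
    final <- dcm_num(bds, "300A010E")
    if (is.null(final) || final <= 0) final <- w[length(w)]
    w <- w / final
    cp_objs <- lapply(seq_along(cps), function(k) {
      control_point(k - 1L, w[k], cps[[k]]$g, cps[[k]]$a, cps[[k]]$b,
                    cps[[k]]$jx, cps[[k]]$jy)
    })
    mu <- mu_map[[dcm_str(bds, "300A00C0")]]
    if (is.null(mu)) stop("no BeamMeterset for beam '", bname, "'")
    beams[[length(beams) + 1L]] <-
      rt_beam(mu, cp_objs, boundaries, arc_dir, limits, name = bname)
  }
  if (length(beams) == 0) stop("RT Plan contains no usable arc beams")
  plan_id <- dcm_str(d, "300A0002")
  if (is.null(plan_id)) plan_id <- "plan"
  rt_plan(plan_id, beams,
          prescription_dose = if (is.na(rx)) 70 else rx,
          n_fractions = nfx)
}

# power-of-two dose grid scaling, exact in both binary and decimal
.dose_scaling <- function(max_dose) {
  k <- if (max_dose <= 0) -10L else ceiling(log2(max_dose / 65535))
  2^max(min(k, 5L), -15L)
}

#' Write a dose grid to a DICOM RT Dose file
#'
#' Dose is stored as 16-bit unsigned integers with a power-of-two
#' `DoseGridScaling`, so values already quantized to that scaling round-trip
#' exactly; otherwise the round-trip error is at most one scaling quantum.
#'
#' @param grid a [dose_grid()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rtdose <- function(grid, path) {
  dims <- dim(grid$values)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  scaling <- .dose_scaling(max(grid$values))
  ints <- as.integer(round(as.vector(grid$values) / scaling))
  pix <- writeBin(ifelse(ints > 32767L, ints - 65536L, ints), raw(),
                  size = 2L, endian = "little")
  ds <- list(
    "00080016" = dcm_el("UI", UID_RTDOSE),
    "00080018" = dcm_el("UI", .dcm_uid(sprintf("dose:%d:%d:%d:%.6g",
                                               nx, ny, nz, sum(ints)))),
    "00080060" = dcm_el("CS", "RTDOSE"),
    "00200032" = dcm_el("DS", .ds_fmt(grid$origin, 4L)),
    "00200037" = dcm_el("DS", paste(c("1", "0", "0", "0", "1", "0"),
                                    collapse = "\\")),
    "00280002" = dcm_el("US", 1L),
    "00280004" = dcm_el("CS", "MONOCHROME2"),
    "00280008" = dcm_el("IS", as.character(nz)),
    "00280010" = dcm_el("US", ny),
    "00280011" = dcm_el("US", nx),
    "00280030" = dcm_el("DS", .ds_fmt(grid$spacing[c(2, 1)], 4L)),
    "00280100" = dcm_el("US", 16L),
    "00280101" = dcm_el("US", 16L),
    "00280102" = dcm_el("US", 15L),
    "00280103" = dcm_el("US", 0L),
    "30040002" = dcm_el("CS", "GY"),
    "30040004" = dcm_el("CS", "PHYSICAL"),
    "3004000A" = dcm_el("CS", "PLAN"),
    "3004000C" = dcm_el("DS", paste(
      sprintf("%.4f", (seq_len(nz) - 1) * grid$spacing[3]),
      collapse = "\\")),
    "3004000E" = dcm_el("DS", sprintf("%.10e", scaling)),
    "7FE00010" = dcm_el("OW", pix)
  )
  dcm_write(ds, path)
}

#' Read a DICOM RT Dose file
#'
#' @param path file path
#' @return a [dose_grid()]; values are pixel data times `DoseGridScaling`
#' @export
read_rtdose <- function(path) {
  d <- dcm_read(path)$data
  scaling <- dcm_num(d, "3004000E")
  if (is.null(scaling)) {
    stop("RT Dose is missing DoseGridScaling (3004,000E)")
  }
  nx <- dcm_get(d, "00280011"); ny <- dcm_get(d, "00280010")
  nz <- as.integer(dcm_num(d, "00280008"))
  offsets <- dcm_num(d, "3004000C")
  dz <- if (length(offsets) >= 2) diff(offsets) else 1
  if (length(dz) > 1 && diff(range(dz)) > 1e-6) {
    stop("unsupported RT Dose dialect: non-uniform GridFrameOffsetVector")
  }
  dz <- dz[1]
  ps <- dcm_num(d, "00280030")  # (row spacing = dy, column spacing = dx)
  pix <- dcm_get(d, "7FE00010")
  vals <- readBin(pix, "integer", n = nx * ny * nz, size = 2L,
                  signed = FALSE, endian = "little")
  arr <- array(vals * scaling, dim = c(nx, ny, nz))
  dose_grid(arr, origin = dcm_num(d, "00200032"),
            spacing = c(ps[2], ps[1], dz))
}

#' Write a structure set to a DICOM RT Structure Set file
#'
#' @param ss a [structure_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rtstruct <- function(ss, path) {
  nms <- names(ss$structures)
  roi_items <- lapply(seq_along(nms), function(i) {
    list("30060022" = dcm_el("IS", as.character(i)),
         "30060026" = dcm_el("LO", nms[i]))
  })
  contour_items <- lapply(seq_along(nms), function(i) {
    ctrs <- ss$structures[[i]]
    item <- list("30060084" = dcm_el("IS", as.character(i)))
    if (length(ctrs) > 0) {
      item[["30060040"]] <- dcm_el("SQ", lapply(ctrs, function(ct) {
        pts <- cbind(ct$xy, ct$z)  # x y z per vertex
        list("30060042" = dcm_el("CS", "CLOSED_PLANAR"),
             "30060046" = dcm_el("IS", as.character(nrow(pts))),
             "30060050" = dcm_el("DS", .ds_fmt(as.vector(t(pts)), 2L)))
      }))
    }
    item
  })
  ds <- list(
    "00080016" = dcm_el("UI", UID_RTSTRUCT),
    "00080018" = dcm_el("UI", .dcm_uid(paste0("struct:",
                                              paste(nms, collapse = ",")))),
    "00080060" = dcm_el("CS", "RTSTRUCT"),
    "30060020" = dcm_el("SQ", roi_items),
    "30060039" = dcm_el("SQ", contour_items)
  )
  dcm_write(ds, path)
}

#' Read a DICOM RT Structure Set file
#'
#' Structure names are preserved verbatim; duplicated ROI names are
#' deduplicated with a numeric suffix (with a warning). Contours are grouped
#' per structure and sorted by slice z. Structures without contour data are
#' retained and listed in `attr(, "empty")`.
#'
#' @param path file path
#' @return a [structure_set()]
#' @export
read_rtstruct <- function(path) {
  d <- dcm_read(path)$data
  rois <- dcm_get(d, "30060020")
  if (is.null(rois)) {
    stop("RT Structure Set is missing StructureSetROISequence (3006,0020)")
  }
  names_by_num <- list()
  for (r in rois) {
    names_by_num[[dcm_str(r, "30060022")]] <- dcm_str(r, "30060026")
  }
  nms <- unlist(names_by_num, use.names = FALSE)
  if (anyDuplicated(nms)) {
    warning("duplicated ROI names deduplicated with suffix")
    nms <- make.unique(nms, sep = "_")
    names_by_num[] <- as.list(nms)
  }
  out <- stats::setNames(
    rep(list(list()), length(names_by_num)),
    unlist(names_by_num, use.names = FALSE))
  for (rc in dcm_get(d, "30060039")) {
    nm <- names_by_num[[dcm_str(rc, "30060084")]]
    ctrs <- list()
    for (ct in dcm_get(rc, "30060040")) {
      pts <- matrix(dcm_num(ct, "30060050"), ncol = 3L, byrow = TRUE)
      ctrs[[length(ctrs) + 1L]] <-
        list(z = pts[1, 3], xy = pts[, 1:2, drop = FALSE])
    }
    if (length(ctrs) > 0) {
      ctrs <- ctrs[order(vapply(ctrs, `[[`, numeric(1), "z"))]
    }
    out[[nm]] <- ctrs
  }
  structure_set(out)
}
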