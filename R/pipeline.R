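# Configuration loading, plain-text dose-image I/O and the end-to-end
# cohort pipeline tying complexity, quality, gamma and comparison together.

#' Load a run configuration
#'
#' One YAML file holds the machine limits, complexity-scoring settings,
#' organ-at-risk protocol, gamma criteria and significance level. Defaults
#' (shipped with the package) reproduce the head-and-neck evaluation
#' settings: the Table-style OAR protocol, gamma criteria 3%/2 mm, 2%/2 mm
#' and 1%/1 mm at a 10% threshold, and alpha = 0.05.
#'
#' @param path YAML file; `NULL` loads the packaged defaults
#' @return list with `machine_limits`, `complexity` (a
#'   [complexity_config()]), `protocol` (data frame), `gamma_criteria`
#'   (list of [gamma_criterion()]), `alpha` and `prescription`
#' @export
run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "planscope")
  }
  y <- yaml::read_yaml(path)
  ml <- do.call(machine_limits, y$machine_limits)
  cx <- y$complexity
  cc <- complexity_config(
    speed_range = unlist(cx$speed_range),
    accel_range = unlist(cx$accel_range),
    sas_thresholds = unlist(cx$sas_thresholds),
    closed_tolerance = cx$closed_tolerance,
    plan_aggregation = cx$plan_aggregation)
  crits <- lapply(y$gamma_criteria, function(g) {
    gamma_criterion(g$dose_diff, g$dta, g$threshold)
  })
  protocol <- if (is.null(y$protocol_file)) {
    hn_constraint_protocol()
  } else {
    hn_constraint_protocol(y$protocol_file)
  }
  list(machine_limits = ml, complexity = cc, protocol = protocol,
       gamma_criteria = crits, alpha = y$alpha,
       prescription = y$prescription)
}

#' Read a 2D dose image
#'
#' Accepts either a single-frame DICOM RT Dose file or a plain-text grid:
#' two header lines (`nx ny`, then `dx dy` in mm) followed by `ny` rows of
#' `nx` whitespace-separated values.
#'
#' @param path file path
#' @return a [dose_image()]
#' @export
read_dose_image <- function(path) {
  magic <- readBin(path, "raw", n = 132L)
  if (length(magic) >= 132L && rawToChar(magic[129:132]) == "DICM") {
    g <- read_rtdose(path)
    return(dose_image(g$values[, , 1], g$spacing[1:2]))
  }
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  sp <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- scan(text = lines[-(1:2)], quiet = TRUE)
  # rows of the text grid are y, columns x
  dose_image(matrix(vals, nrow = dims[1], ncol = dims[2]), sp)
}

#' Write a 2D dose image as a plain-text grid
#'
#' @param img a [dose_image()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dose_image <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(img$values), ncol(img$values)), con)
  writeLines(sprintf("%.6g %.6g", img$spacing[1], img$spacing[2]), con)
  for (j in seq_len(ncol(img$values))) {
    writeLines(paste(sprintf("%.8g", img$values[, j]), collapse = " "),
               con)
  }
  invisible(path)
}

# quality metrics for one (dose, structures) case
.case_quality <- function(grid, ss, prescription, protocol,
                          ptv_pattern = "^PTV", body_name = "BODY") {
  masks <- lapply(ss$structures, rasterize_structure, grid = grid)
  stats <- structure_dose_stats(grid, masks)
  constraints <- evaluate_constraints(stats, protocol)
  body_mask <- masks[[body_name]]
  ptv_names <- grep(ptv_pattern, names(masks), value = TRUE)
  ptv_rows <- lapply(ptv_names, function(nm) {
    if (!any(masks[[nm]])) return(NULL)
    dvh <- cumulative_dvh(grid, masks[[nm]])
    data.frame(structure = nm,
               CN = conformity_number(grid, masks[[nm]], prescription,
                                      body_mask),
               HI = heterogeneity_index(dvh),
               stringsAsFactors = FALSE)
  })
  hs <- if (length(ptv_names) > 0 && any(masks[[ptv_names[1]]])) {
    hot_spot_and_normalization(grid, masks[[ptv_names[1]]], prescription,
                               body_mask)
  } else NULL
  list(stats = stats, constraints = constraints,
       ptv = do.call(rbind, ptv_rows), hotspot = hs)
}

#' Run the full analysis pipeline over a cohort manifest
#'
#' The manifest (data frame or CSV path) lists one row per patient and
#' cohort with columns `patient_id`, `cohort`, `rtplan` and optionally
#' `rtdose`, `rtstruct`, `ref_image`, `eval_image` (file paths; empty or NA
#' entries skip the corresponding analysis). Per-patient failures are
#' caught, recorded in the error table and do not stop the run. When the
#' manifest holds exactly two cohorts, complexity metrics are compared
#' pairwise across them.
#'
#' @param manifest data frame or path to a manifest CSV
#' @param config a [run_config()]
#' @return list with `complexity` (per plan), `quality` (per case PTV
#'   metrics), `constraints`, `gamma` (per pair and criterion),
#'   `comparison` (paired cohort table or NULL) and `errors`
#' @export
run_pipeline <- function(manifest, config = run_config()) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (nrow(manifest) == 0) stop("empty manifest")
  stopifnot(all(c("patient_id", "cohort", "rtplan") %in% names(manifest)))
  has <- function(row, col) {
    col %in% names(manifest) && !is.na(row[[col]]) && nzchar(row[[col]])
  }
  complexity <- list(); quality <- list(); constraints <- list()
  gamma <- list(); errors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      plan <- read_rtplan(row$rtplan, limits = config$machine_limits)
      rep <- plan_complexity_report(plan, config$complexity)
      out <- cbind(data.frame(patient_id = row$patient_id,
                              cohort = row$cohort,
                              stringsAsFactors = FALSE),
                   rep$per_plan)
      complexity[[length(complexity) + 1L]] <- out
      if (has(row, "rtdose") && has(row, "rtstruct")) {
        q <- .case_quality(read_rtdose(row$rtdose),
                           read_rtstruct(row$rtstruct),
                           config$prescription, config$protocol)
        if (!is.null(q$ptv)) {
          quality[[length(quality) + 1L]] <- cbind(
            data.frame(patient_id = row$patient_id, cohort = row$cohort,
                       stringsAsFactors = FALSE), q$ptv)
        }
        constraints[[length(constraints) + 1L]] <- cbind(
          data.frame(patient_id = row$patient_id, cohort = row$cohort,
                     stringsAsFactors = FALSE), q$constraints)
      }
      if (has(row, "ref_image") && has(row, "eval_image")) {
        pr <- list(list(reference = read_dose_image(row$ref_image),
                        evaluated = read_dose_image(row$eval_image)))
        tab <- passing_rate_table(pr, config$gamma_criteria)
        gamma[[length(gamma) + 1L]] <- cbind(
          data.frame(patient_id = row$patient_id, cohort = row$cohort,
                     stringsAsFactors = FALSE),
          tab$rates[, c("criterion", "rate")])
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errors[[length(errors) + 1L]] <- data.frame(
        patient_id = row$patient_id, cohort = row$cohort, error = res,
        stringsAsFactors = FALSE)
    }
  }
  complexity <- if (length(complexity)) do.call(rbind, complexity) else NULL
  comparison <- NULL
  if (!is.null(complexity) &&
      length(unique(complexity$cohort)) == 2) {
    metric_cols <- setdiff(names(complexity), c("patient_id", "cohort"))
    long <- do.call(rbind, lapply(metric_cols, function(m) {
      data.frame(patient_id = complexity$patient_id,
                 cohort = complexity$cohort, metric = m,
                 value = complexity[[m]], stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$value), ]
    comparison <- compare_cohorts(long, alpha = config$alpha)
  }
  list(complexity = complexity,
       quality = if (length(quality)) do.call(rbind, quality) else NULL,
       constraints = if (length(constraints)) {
         do.call(rbind, constraints)
       } else NULL,
       gamma = if (length(gamma)) do.call(rbind, gamma) else NULL,
       comparison = comparison,
       errors = if (length(errors)) do.call(rbind, errors) else NULL)
}

#' Write a pipeline report bundle to disk
#'
#' JSON is the canonical output; each table is mirrored as CSV. Output is
#' deterministic (no timestamps).
#'
#' @param bundle result of [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    jsonlite::write_json(tab, file.path(dir, paste0(nm, ".json")),
                         dataframe = "rows", digits = NA, na = "null")
    utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
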