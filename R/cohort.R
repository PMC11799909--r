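# Paired two-cohort comparison: Wilcoxon signed-rank tests (exact by
# default for small n, including tied ranks) and mean +/- SD (min-max)
# summary tables.

# exact null distribution of the positive-rank sum for given |d| ranks:
# dynamic program over doubled ranks (mid-ranks are half-integers), giving
# P(W+ = w) over all 2^n equally likely sign assignments
.signrank_exact_p <- function(w_plus, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] ~ number of subsets, sum s
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- round(2 * w_plus)
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped (Wilcoxon's convention; `zero_method =
#' "pratt"` keeps them in the ranking and removes their ranks from the
#' statistic). Tied absolute differences receive mid-ranks. For `n <= 25`
#' nonzero differences the p-value is computed by exact enumeration of the
#' null distribution (valid with ties); for larger n, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x paired differences, or first cohort values if `y` is given
#' @param y optional second cohort values (`x - y` is tested)
#' @param exact `"auto"` (exact for n <= 25), `TRUE` or `FALSE`
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`
#' @return list with `statistic` (positive-rank sum W+), `n` (nonzero
#'   differences used), `p_value` and `method`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact = "auto",
                                 zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  stopifnot(all(is.finite(d)))
  nz <- d != 0
  if (!any(nz)) stop("all differences are zero: test undefined")
  if (zero_method == "wilcox") {
    d <- d[nz]
    ranks <- rank(abs(d))
    use <- rep(TRUE, length(d))
  } else {
    ranks <- rank(abs(d))
    use <- d != 0
  }
  n <- sum(use)
  w_plus <- sum(ranks[use & d > 0])
  do_exact <- isTRUE(exact) || (identical(exact, "auto") && n <= 25)
  if (do_exact) {
    p <- .signrank_exact_p(w_plus, ranks[use])
    method <- "exact"
  } else {
    r_use <- ranks[use]
    mu <- sum(r_use) / 2
    # sum(r^2)/4 over mid-ranks equals n(n+1)(2n+1)/24 - sum(t^3 - t)/48,
    # i.e. the tie-corrected variance
    sigma2 <- sum(r_use^2) / 4
    z_num <- w_plus - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = w_plus, n = n, p_value = min(1, p), method = method)
}

#' Mean, SD, min and max of a metric
#'
#' @param values numeric vector (at least one value)
#' @return list with `mean`, `sd` (sample SD, n-1 denominator; 0 with
#'   `sd_flagged = TRUE` when n = 1), `min`, `max`, `n`
#' @export
summarize_metric <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("no values to summarize")
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0,
       min = min(values), max = max(values), n = length(values),
       sd_flagged = length(values) == 1)
}

#' Paired comparison of two cohorts over all metrics
#'
#' For every metric in a long-format cohort table, patients present in both
#' cohorts are paired and compared with the two-sided Wilcoxon signed-rank
#' test; no multiplicity correction is applied. Metrics whose paired
#' differences are all zero (or with no complete pair) are reported as not
#' tested.
#'
#' @param table data frame with columns `patient_id`, `cohort`, `metric`,
#'   `value`; exactly two cohort labels
#' @param alpha significance level (default 0.05)
#' @param ... passed to [wilcoxon_signed_rank()]
#' @return data frame with one row per metric: summary statistics of both
#'   cohorts (`mean_a`, `sd_a`, `min_a`, `max_a`, and `_b` analogues, with
#'   cohort labels sorted alphabetically as a/b), `n` pairs used,
#'   `n_dropped` incomplete pairs, `p_value`, `significant` (p < alpha) and
#'   `tested`
#' @export
compare_cohorts <- function(table, alpha = 0.05, ...) {
  stopifnot(all(c("patient_id", "cohort", "metric", "value") %in%
                  names(table)))
  cohorts <- sort(unique(as.character(table$cohort)))
  if (length(cohorts) != 2) stop("exactly two cohorts are required")
  metrics <- unique(as.character(table$metric))
  rows <- lapply(metrics, function(m) {
    sub <- table[table$metric == m, ]
    a <- sub[sub$cohort == cohorts[1], ]
    b <- sub[sub$cohort == cohorts[2], ]
    ids <- intersect(a$patient_id, b$patient_id)
    n_dropped <- length(unique(sub$patient_id)) - length(ids)
    if (n_dropped > 0) {
      message(sprintf("metric '%s': %d incomplete pair(s) excluded",
                      m, n_dropped))
    }
    va <- a$value[match(ids, a$patient_id)]
    vb <- b$value[match(ids, b$patient_id)]
    sa <- summarize_metric(va); sb <- summarize_metric(vb)
    base <- data.frame(
      metric = m, n = length(ids), n_dropped = n_dropped,
      mean_a = sa$mean, sd_a = sa$sd, min_a = sa$min, max_a = sa$max,
      mean_b = sb$mean, sd_b = sb$sd, min_b = sb$min, max_b = sb$max,
      stringsAsFactors = FALSE)
    diffs <- va - vb
    if (length(diffs) == 0 || all(diffs == 0)) {
      base$p_value <- NA_real_
      base$significant <- FALSE
      base$tested <- FALSE
    } else {
      wt <- wilcoxon_signed_rank(diffs, ...)
      base$p_value <- wt$p_value
      base$significant <- wt$p_value < alpha
      base$tested <- TRUE
    }
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "cohorts") <- cohorts
  attr(out, "alpha") <- alpha
  out
}
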