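#' Bland-Altman agreement analysis of paired measurements
#'
#' Computes the bias (mean of the paired differences), the sample SD of
#' the differences, and the 95% limits of agreement `bias +/- 1.96 SD` for
#' two methods measuring the same quantity. The half-width `1.96 SD` is
#' reported separately as the agreement interval half-range.
#'
#' @param a,b Paired measurement vectors (same length, no missing values).
#' @param direction `"A_minus_B"` (default) or `"B_minus_A"`.
#' @return An object of class `bland_altman`: `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_halfwidth`, `n_pairs`, `means`,
#'   `differences`.
#' @export
bland_altman <- function(a, b, direction = c("A_minus_B", "B_minus_A")) {
  direction <- match.arg(direction)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2) stop("insufficient data: need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing pairs are not allowed")
  d <- if (direction == "A_minus_B") a - b else b - a
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_lower = bias - 1.96 * sdd,
                 loa_upper = bias + 1.96 * sdd,
                 ci_halfwidth = 1.96 * sdd,
                 n_pairs = length(d),
                 means = (a + b) / 2, differences = d,
                 direction = direction),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (%d pairs, %s)\n", x$n_pairs,
              x$direction))
  cat(sprintf("  bias: %.2f  (SD of differences %.2f)\n", x$bias, x$sd_diff))
  cat(sprintf("  limits of agreement: [%.2f, %.2f]  (half-width %.2f)\n",
              x$loa_lower, x$loa_upper, x$ci_halfwidth))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Two-sample Student's t test (pooled variance)
#'
#' Classic two-sided, pooled-variance two-sample t test with
#' `n_a + n_b - 2` degrees of freedom. If both samples are constant with
#' equal means the degenerate case is reported as `t = 0, p = 1`; constant
#' samples with unequal means raise an error.
#'
#' @param sample_a,sample_b Numeric vectors, each of length at least 2.
#' @return List with `t`, `p`, `df`.
#' @export
students_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 values")
  pooled <- ((length(sample_a) - 1) * stats::var(sample_a) +
               (length(sample_b) - 1) * stats::var(sample_b)) /
    (length(sample_a) + length(sample_b) - 2)
  if (pooled == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, p = 1, df = length(sample_a) + length(sample_b) - 2))
    stop("degenerate variance: both samples constant with unequal means")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param sample_a,sample_b Paired numeric vectors, length at least 3.
#' @return Spearman's rho.
#' @export
spearman <- function(sample_a, sample_b) {
  if (length(sample_a) != length(sample_b)) stop("samples must be paired")
  if (length(sample_a) < 3) stop("need at least 3 pairs")
  if (stats::sd(sample_a) == 0 || stats::sd(sample_b) == 0)
    stop("undefined correlation: constant input")
  stats::cor(sample_a, sample_b, method = "spearman")
}

#' Reference wall-deformation dataset (four-subject phantom study)
#'
#' Paired wall-deformation amplitudes (mm) for four patient-specific
#' elastic aneurysm phantoms, measured at four angular positions
#' (anterior, posterior, left, right) with four repeated probes each: one
#' column from the multi-camera optical system, one from the clinical
#' speckle-tracking echocardiography reference. Shipped as a plain-text
#' CSV transcribed from the published study table.
#'
#' @return Data frame with columns `patient`, `position` (A/P/L/R),
#'   `probe`, `nivbs_mm`, `ref_mm`.
#' @export
wall_deformation_reference <- function() {
  path <- system.file("extdata", "wall_deformation_mm.csv",
                      package = "vesselmotion", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Full agreement report for a paired-measurement table
#'
#' Runs the Bland-Altman analysis, pooled-variance t test and Spearman
#' correlation for a table of paired method measurements, overall and per
#' group.
#'
#' @param pairs Data frame with the two measurement columns and optional
#'   grouping columns.
#' @param col_a,col_b Names of the two measurement columns.
#' @param by Optional name of a grouping column (e.g. `"position"` or
#'   `"patient"`); per-group Bland-Altman results are added.
#' @param direction Difference direction passed to [bland_altman()].
#' @return List with `overall` (a [bland_altman()] object plus `t_test`
#'   and `spearman_rho`) and, when `by` is given, `per_group`.
#' @export
agreement_report <- function(pairs, col_a = "ref_mm", col_b = "nivbs_mm",
                             by = NULL, direction = "A_minus_B") {
  a <- pairs[[col_a]]; b <- pairs[[col_b]]
  overall <- bland_altman(a, b, direction)
  tt <- students_t(a, b)
  rho <- spearman(a, b)
  res <- list(overall = overall, t_test = tt, spearman_rho = rho)
  if (!is.null(by)) {
    res$per_group <- lapply(split(pairs, pairs[[by]]), function(g)
      bland_altman(g[[col_a]], g[[col_b]], direction))
  }
  res
}

#' Write an agreement report as JSON
#'
#' @param report An [agreement_report()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(report, path) {
  ba_fields <- function(x)
    list(bias = x$bias, sd_diff = x$sd_diff, loa_lower = x$loa_lower,
         loa_upper = x$loa_upper, ci_halfwidth = x$ci_halfwidth,
         n_pairs = x$n_pairs)
  out <- list(overall = ba_fields(report$overall),
              t_test = report$t_test,
              spearman_rho = report$spearman_rho)
  if (!is.null(report$per_group))
    out$per_group <- lapply(report$per_group, ba_fields)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
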