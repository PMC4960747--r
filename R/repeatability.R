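#' Test-retest concentration table
#'
#' An n-subjects x k-scans matrix of concentrations (mM) with subject
#' labels, the input to the repeatability statistics. Accepts a data
#' frame whose first column is the subject label and remaining columns
#' are scans, or a plain matrix.
#'
#' @param x Data frame (subject column + scan columns) or numeric matrix.
#' @return A tibble of class `retest_table` with a `subject` column and
#'   one column per scan.
#' @export
#' @examples
#' retest_table(data.frame(subject = 1:3,
#'                         scan1 = c(1, 2, 3), scan2 = c(1.1, 2, 2.9)))
retest_table <- function(x) {
  if (is.matrix(x)) {
    df <- as_tibble(x, .name_repair = ~ paste0("scan", seq_along(.x)))
    df <- dplyr::bind_cols(tibble(subject = seq_len(nrow(x))), df)
  } else {
    df <- as_tibble(x)
    names(df)[1] <- "subject"
  }
  vals <- as.matrix(df[, -1])
  if (nrow(vals) < 2 || ncol(vals) < 2)
    abort("need at least 2 subjects and 2 scans.")
  if (anyNA(vals)) abort("missing cells are not allowed.")
  if (!is.numeric(vals)) abort("scan columns must be numeric.")
  class(df) <- c("retest_table", class(df))
  df
}

retest_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), "subject")])
}

#' One-way random single-measures ICC with exact-F confidence interval
#'
#' The intraclass correlation from a one-way ANOVA with subjects as
#' groups: `ICC(1,1) = (MSB - MSW) / (MSB + (k-1) MSW)`. The two-sided
#' `1 - alpha` confidence interval uses the exact F quantiles:
#' `FL = Fobs / qf(1 - alpha/2, n-1, n(k-1))`, lower bound
#' `(FL - 1)/(FL + k - 1)`, and symmetrically for the upper bound.
#'
#' @param table A [retest_table()].
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return An object of class `icc_oneway` with `icc`, `ci_low`,
#'   `ci_high`, the ANOVA mean squares, F statistic, degrees of freedom
#'   and p value.
#' @export
#' @examples
#' icc_oneway(glu_retest_example())$icc  # 0.961
icc_oneway <- function(table, alpha = 0.05) {
  m <- retest_matrix(table)
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(seq_len(n), times = k)))
  # degenerate (perfect-fit) tables are handled explicitly below
  an <- suppressWarnings(anova(lm(y ~ subject, data = long)))
  msb <- an$`Mean Sq`[1]; msw <- an$`Mean Sq`[2]
  degenerate <- FALSE
  eps <- 1e-12 * max(msb, msw, 1e-300)
  if (msb <= eps && msw <= eps) {
    icc <- 1; ci <- c(NA_real_, NA_real_); fobs <- NA_real_; p <- NA_real_
    degenerate <- TRUE
  } else if (msw <= eps) {
    icc <- 1; ci <- c(NA_real_, 1); fobs <- Inf; p <- 0
    degenerate <- TRUE
  } else {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    fobs <- msb / msw
    fl <- fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- pf(fobs, n - 1, n * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 alpha = alpha, msb = msb, msw = msw, f = fobs,
                 df1 = n - 1, df2 = n * (k - 1), p_value = p,
                 n = n, k = k, degenerate = degenerate),
            class = "icc_oneway")
}

#' @export
print.icc_oneway <- function(x, ...) {
  cat(sprintf(
    "<icc_oneway> ICC %.3f, %d%% CI (%.3f, %.3f), F(%d,%d) = %.2f, p = %.2g\n",
    x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
    x$df1, x$df2, x$f, x$p_value))
  if (x$degenerate) cat("  (degenerate variance structure)\n")
  invisible(x)
}

#' @rdname icc_oneway
#' @param x An `icc_oneway` object.
#' @param ... Unused.
#' @export
tidy.icc_oneway <- function(x, ...) {
  tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
         f = x$f, df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}

#' Coefficient of variation (percent)
#'
#' `100 * SD / mean` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return CoV in percent.
#' @export
#' @examples
#' cov_percent(c(1, 3))  # 70.7
cov_percent <- function(values) {
  if (length(values) < 2) abort("need at least 2 values.")
  m <- mean(values)
  if (m == 0) abort("mean is zero; CoV undefined.")
  100 * sd(values) / m
}

#' Per-subject absolute scan differences
#'
#' For a two-scan table: `|scan1 - scan2|` per subject and the maximum
#' across subjects.
#'
#' @param table A [retest_table()] with exactly two scans.
#' @return List with `per_subject` (tibble: subject, scan values,
#'   `abs_diff`) and `max_abs_diff`.
#' @export
abs_scan_differences <- function(table) {
  m <- retest_matrix(table)
  if (ncol(m) != 2) abort("absolute scan differences require k = 2 scans.")
  d <- abs(m[, 1] - m[, 2])
  per <- dplyr::mutate(as_tibble(table), abs_diff = d)
  list(per_subject = per, max_abs_diff = max(d))
}

#' Repeatability summary
#'
#' Mean, SD (sample, n-1), CoV, ICC block and - for two-scan tables -
#' absolute scan differences, aggregated from one test-retest table.
#'
#' @param table A [retest_table()].
#' @param alpha Significance level for the ICC confidence interval.
#' @return An object of class `retest_summary`.
#' @export
#' @examples
#' retest_summary(glu_retest_example())
retest_summary <- function(table, alpha = 0.05) {
  m <- retest_matrix(table)
  v <- as.vector(m)
  icc <- icc_oneway(table, alpha)
  diffs <- if (ncol(m) == 2) abs_scan_differences(table) else NULL
  structure(list(mean = mean(v), sd = sd(v), cov_percent = cov_percent(v),
                 icc = icc, differences = diffs,
                 n = nrow(m), k = ncol(m)),
            class = "retest_summary")
}

#' @export
print.retest_summary <- function(x, ...) {
  cat(sprintf("<retest_summary> %d subjects x %d scans: %.2f +/- %.2f mM, CoV %.1f%%\n",
              x$n, x$k, x$mean, x$sd, x$cov_percent))
  print(x$icc)
  if (!is.null(x$differences))
    cat(sprintf("  max |scan1 - scan2| = %.2f mM\n",
                x$differences$max_abs_diff))
  invisible(x)
}

#' @rdname retest_summary
#' @param x A `retest_summary` object.
#' @param ... Unused.
#' @export
glance.retest_summary <- function(x, ...) {
  tibble(n = x$n, k = x$k, mean = x$mean, sd = x$sd,
         cov_percent = x$cov_percent, icc = x$icc$icc,
         icc_ci_low = x$icc$ci_low, icc_ci_high = x$icc$ci_high,
         icc_p = x$icc$p_value,
         max_abs_diff = if (is.null(x$differences)) NA_real_ else
           x$differences$max_abs_diff)
}

#' Packaged example test-retest dataset
#'
#' Glutamate concentrations (mM) from a five-subject, two-scan 7T
#' occipital-cortex test-retest study, shipped as the package's worked
#' example for the repeatability statistics.
#'
#' @return A [retest_table()] (5 subjects x 2 scans).
#' @export
#' @examples
#' glance(retest_summary(glu_retest_example()))
glu_retest_example <- function() {
  path <- system.file("extdata", "glu_retest.csv", package = "famousr",
                      mustWork = TRUE)
  retest_table(read.csv(path))
}
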