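#' Two-sample tests on branch-length samples
#'
#' The divergence decision rests on three two-sample comparisons of the two
#' within-clade branch-length samples, reported side by side: Student's t
#' (equal-variance), Welch's t (unequal variance) and the Mann-Whitney U test
#' (non-normality). All alternatives are two-sided: the null is that the two
#' clades did not diverge differentially and the direction is unknown a
#' priori. The sign convention is first sample minus second, so a *less*
#' diverged first clade yields a negative t.
#'
#' @param x,y Numeric branch-length samples (length at least 2, finite).
#' @return An object of class `divergence_test`: a list with `test`,
#'   `statistic` (t value or U), `df` (`NA` for U), `p_value` (two-sided),
#'   `n1`, `n2` and `method` (`"exact"` or `"normal_approx"` for U).
#' @name divergence_tests
NULL

check_sample <- function(v, name) {
  if (!is.numeric(v) || length(v) < 2L)
    stop("sample '", name, "' must be numeric with at least 2 values",
         call. = FALSE)
  if (any(!is.finite(v)))
    stop("sample '", name, "' contains non-finite values", call. = FALSE)
  invisible(v)
}

test_result <- function(test, statistic, df, p_value, n1, n2, method = NA_character_) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = min(1, p_value), n1 = n1, n2 = n2, method = method),
            class = "divergence_test")
}

#' @export
print.divergence_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g%s, p = %s (n1 = %d, n2 = %d%s)\n",
              x$test, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %.4g", x$df),
              format_p(x$p_value), x$n1, x$n2,
              if (is.na(x$method)) "" else paste0(", ", x$method)))
  invisible(x)
}

#' @rdname divergence_tests
#' @export
student_t_test <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 <= 0)
    stop("degenerate samples: pooled variance is zero", call. = FALSE)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  test_result("student_t", t, df, 2 * stats::pt(-abs(t), df), n1, n2)
}

#' @rdname divergence_tests
#' @export
welch_t_test <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 <= 0 && v2 <= 0)
    stop("degenerate samples: both variances are zero", call. = FALSE)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  test_result("welch_t", t, df, 2 * stats::pt(-abs(t), df), n1, n2)
}

#' @rdname divergence_tests
#'
#' @details The U statistic reported is U1, computed from the rank sum of the
#' first sample with midranks for ties. For tie-free samples with
#' `n1 + n2 <= 16` the two-sided p-value is exact: the probability, over all
#' `choose(n1 + n2, n1)` equally likely group assignments, of a U at least as
#' far from its null mean `n1*n2/2` as the observed one. Larger or tied
#' samples use the normal approximation with tie correction and a 0.5
#' continuity correction.
#' @export
mann_whitney_u <- function(x, y) {
  check_sample(x, "x"); check_sample(y, "y")
  n1 <- length(x); n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (N <= 16L && !has_ties) {
    support <- 0:(n1 * n2)
    p <- sum(stats::dwilcox(support[abs(support - mu) >= abs(u1 - mu) - 1e-9],
                            n1, n2))
    return(test_result("mann_whitney_u", u1, NA_real_, p, n1, n2, "exact"))
  }
  tie_tab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) # all values identical
    return(test_result("mann_whitney_u", u1, NA_real_, 1, n1, n2, "normal_approx"))
  z <- u1 - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result("mann_whitney_u", u1, NA_real_, p, n1, n2, "normal_approx")
}

#' Run the three divergence tests
#'
#' Runs Student's t, Welch's t and Mann-Whitney U on the same pair of samples
#' and returns all three in fixed order. A degenerate-sample failure in one
#' test (e.g. zero variance for the t tests) is recorded in that slot while
#' the others still run; only if all three fail is an error raised.
#'
#' @param x,y Numeric branch-length samples.
#' @return Named list `student_t`, `welch_t`, `mann_whitney_u`; each element
#'   is a `divergence_test` or a `divergence_test_error` (list with `test`
#'   and `error` message).
#' @export
run_all_tests <- function(x, y) {
  runners <- list(student_t = student_t_test,
                  welch_t = welch_t_test,
                  mann_whitney_u = mann_whitney_u)
  out <- lapply(names(runners), function(nm) {
    tryCatch(runners[[nm]](x, y),
             error = function(e) structure(
               list(test = nm, error = conditionMessage(e)),
               class = "divergence_test_error"))
  })
  names(out) <- names(runners)
  if (all(vapply(out, inherits, logical(1L), "divergence_test_error")))
    stop("all three tests failed: ",
         paste(vapply(out, `[[`, character(1L), "error"), collapse = "; "),
         call. = FALSE)
  out
}

# Display floor for p-values: below representable precision the report can
# only state a bound.
format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-15) "< 1e-15" else format(p, digits = 6)
}
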