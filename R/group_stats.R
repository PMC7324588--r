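# Two-group comparison of biometric parameters.

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sample two-sided t-test in closed form, the classic
#' Student test (a Welch variant is available via `var_equal = FALSE`). By
#' convention, when the pooled variance is zero the statistic is 0 with
#' p = 1 if the group means are equal, and +/-Inf with p = 0 otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alpha significance level for the `significant` flag.
#' @param parameter name of the compared parameter (metadata).
#' @param var_equal pooled-variance Student test (TRUE, default) or Welch.
#' @return A `t_test_result`: parameter, group means/SDs/sizes, `t`, `df`,
#'   two-sided `p`, `significant` (p < alpha), `alpha`.
#' @export
student_t_test <- function(a, b, alpha = 0.05, parameter = "value",
                           var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("values must be finite")
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0) (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else n1 + n2 - 2
  }
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t <- (m1 - m2) / se
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(parameter = parameter,
                 mean_a = m1, sd_a = sqrt(v1), n_a = n1,
                 mean_b = m2, sd_b = sqrt(v2), n_b = n2,
                 t = t, df = df, p = p,
                 significant = p < alpha, alpha = alpha,
                 var_equal = var_equal),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test on '%s': t = %.4f, df = %.4g, p = %.4g%s\n",
              if (x$var_equal) "Student (pooled)" else "Welch",
              x$parameter, x$t, x$df, x$p,
              if (x$significant) " *" else ""))
  cat(sprintf("  group A: %.3f ± %.3f (n = %d); group B: %.3f ± %.3f (n = %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Compare two cohorts parameter by parameter
#'
#' Runs a Student's t-test per shared biometric parameter (weight, length,
#' total volume, fat volume, fat fraction where available) between two
#' cohorts, flagging significance at `alpha`. No multiple-testing
#' correction is applied across parameters.
#'
#' @param cohort_a,cohort_b `cohort_summary` objects (from
#'   [summarize_cohort()]) or data.frames of per-specimen records.
#' @param alpha significance level.
#' @param var_equal pooled (TRUE) or Welch test.
#' @return A `cohort_comparison`: data.frame with one row per parameter
#'   (group means/SDs, t, df, p, significant) plus the list of
#'   `t_test_result` objects.
#' @export
compare_cohorts <- function(cohort_a, cohort_b, alpha = 0.05, var_equal = TRUE) {
  rec_a <- if (inherits(cohort_a, "cohort_summary")) cohort_a$records else cohort_a
  rec_b <- if (inherits(cohort_b, "cohort_summary")) cohort_b$records else cohort_b
  pars <- intersect(intersect(cohort_parameters, names(rec_a)), names(rec_b))
  pars <- pars[vapply(pars, function(p)
    !all(is.na(rec_a[[p]])) && !all(is.na(rec_b[[p]])), logical(1))]
  if (length(pars) == 0L) stop("cohorts share no comparable parameters")
  tests <- lapply(pars, function(p)
    student_t_test(rec_a[[p]], rec_b[[p]], alpha = alpha, parameter = p,
                   var_equal = var_equal))
  tab <- data.frame(
    parameter = pars,
    mean_a = vapply(tests, `[[`, numeric(1), "mean_a"),
    sd_a = vapply(tests, `[[`, numeric(1), "sd_a"),
    mean_b = vapply(tests, `[[`, numeric(1), "mean_b"),
    sd_b = vapply(tests, `[[`, numeric(1), "sd_b"),
    t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    significant = vapply(tests, `[[`, logical(1), "significant"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, tests = tests, alpha = alpha),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("cohort_comparison (alpha = %g); '*' marks p < alpha\n", x$alpha))
  with(x$table, for (i in seq_along(parameter))
    cat(sprintf("  %-18s %8.3f ± %-7.3f vs %8.3f ± %-7.3f  p = %.4g%s\n",
                parameter[i], mean_a[i], sd_a[i], mean_b[i], sd_b[i], p[i],
                if (significant[i]) " *" else "")))
  invisible(x)
}
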