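#' qPCR relative expression from cycle thresholds
#'
#' Computes `2^(ct_reference - ct_target)`, the 2^(-delta-Ct) relative
#' abundance of a target transcript normalized to a reference gene (e.g.
#' TBP): each PCR cycle is one doubling, so a target crossing threshold one
#' cycle earlier than the reference is twice as abundant. Values above 1
#' mean the target is more abundant than the reference. Vectorized.
#'
#' @param ct_target Cycle threshold(s) of the target gene.
#' @param ct_reference Cycle threshold(s) of the reference gene.
#' @return Relative expression value(s).
#' @export
#' @examples
#' relative_expression(30, 25)  # 2^-5 = 0.03125
relative_expression <- function(ct_target, ct_reference) {
  if (!is.numeric(ct_target) || !is.numeric(ct_reference) ||
      anyNA(ct_target) || anyNA(ct_reference) ||
      !all(is.finite(ct_target)) || !all(is.finite(ct_reference)))
    stop("cycle thresholds must be finite numbers")
  if (any(ct_target < 0 | ct_target > 45) ||
      any(ct_reference < 0 | ct_reference > 45))
    warning("cycle thresholds outside the usual 0-45 range")
  2^(ct_reference - ct_target)
}

#' Group summary for a summary-statistics t-test
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (positive).
#' @param n Group size (>= 2).
#' @return A `group_summary` object.
#' @export
group_summary <- function(mean, sem, n) {
  if (!is.numeric(mean) || !is.finite(mean)) stop("mean must be finite")
  if (!is.numeric(sem) || !is.finite(sem) || sem <= 0)
    stop("sem must be positive")
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  structure(list(mean = as.numeric(mean), sem = as.numeric(sem),
                 n = as.integer(n)), class = "group_summary")
}

#' Two-group t-test from summary statistics
#'
#' Compares group means given only means, standard errors of the mean, and
#' group sizes (the form in which published figures usually report them).
#' Default is the unequal-variance (Welch) test:
#' `t = (mean_b - mean_a) / sqrt(sem_a^2 + sem_b^2)` with
#' Welch-Satterthwaite degrees of freedom. `var_equal = TRUE` gives the
#' classical pooled-variance Student test instead.
#'
#' @param a,b [group_summary()] objects.
#' @param var_equal Use the pooled-variance variant (default `FALSE`).
#' @return A list with `t`, `df`, and the two-sided `p`.
#' @export
#' @examples
#' welch_t_from_summary(group_summary(0.114, 0.059, 8),
#'                      group_summary(1.18, 0.412, 16))
welch_t_from_summary <- function(a, b, var_equal = FALSE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (var_equal) {
    var_a <- a$sem^2 * a$n
    var_b <- b$sem^2 * b$n
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * var_a + (b$n - 1) * var_b) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se <- sqrt(a$sem^2 + b$sem^2)
    df <- (a$sem^2 + b$sem^2)^2 /
      (a$sem^4 / (a$n - 1) + b$sem^4 / (b$n - 1))
  }
  t <- (b$mean - a$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Two-group t-test from raw values
#'
#' Computes each sample's mean and SEM and delegates to
#' [welch_t_from_summary()], so the two entry points are exactly consistent.
#'
#' @param a,b Numeric vectors of length >= 2.
#' @inheritParams welch_t_from_summary
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t_from_values <- function(a, b, var_equal = FALSE) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  sa <- sem(a); sb <- sem(b)
  if (sa == 0 && sb == 0) {
    d <- mean(b) - mean(a)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(a) + length(b) - 2,
                p = if (d == 0) 1 else 0))
  }
  if (sa == 0 || sb == 0) stop("one group has zero variance")
  welch_t_from_summary(group_summary(mean(a), sa, length(a)),
                       group_summary(mean(b), sb, length(b)),
                       var_equal = var_equal)
}
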