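new_stat <- function(statistic, p_value, df, kind, n = NA_integer_) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 kind = kind, n = n),
            class = "qa_stat")
}

#' @export
print.qa_stat <- function(x, ...) {
  cat(sprintf("<qa_stat> %s: statistic %.4g, df %s, p = %.4g\n", x$kind,
              x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Independent two-sample t-test
#'
#' Two-sided pooled-variance (equal-variance) t-test by default; Welch via
#' `var_equal = FALSE`. The degenerate case of two zero-variance samples with
#' equal means returns t = 0, p = 1 by convention.
#'
#' @param sample_a,sample_b numeric samples, each of size >= 2.
#' @param var_equal pool the variances (default TRUE).
#' @return a `qa_stat` with `statistic` (t), `p_value`, `df`.
#' @export
t_test_independent <- function(sample_a, sample_b, var_equal = TRUE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(new_stat(0, 1, length(sample_a) + length(sample_b) - 2,
                      "t-test"))
    }
    return(new_stat(sign(mean(sample_a) - mean(sample_b)) * Inf, 0,
                    length(sample_a) + length(sample_b) - 2, "t-test"))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
  new_stat(unname(tt$statistic), tt$p.value, unname(tt$parameter), "t-test")
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA; the upper-tail p comes from the F
#' distribution. All-identical constant groups return F = 0, p = 1.
#'
#' @param groups list of numeric vectors, >= 2 groups with n >= 2 each.
#' @return a `qa_stat` with `statistic` (F), `p_value`, `df` (between,
#'   within).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  df <- c(length(groups) - 1, length(y) - length(groups))
  if (stats::var(y) == 0) return(new_stat(0, 1, df, "anova"))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  new_stat(unname(ft$statistic), ft$p.value, unname(ft$parameter), "anova")
}

#' Pearson correlation with a two-tailed test
#'
#' Pearson's r plus the two-tailed p value from the t transform with n - 2
#' degrees of freedom. Constant input is an error (r undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `qa_stat` with `statistic` (r), `p_value`, `df`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  new_stat(unname(ct$estimate), ct$p.value, unname(ct$parameter), "pearson",
           n = length(x))
}
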