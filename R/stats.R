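#' Two-sample Student's t-test on cluster size samples
#'
#' Compares two samples of cluster sizes (areas or diameters). The default
#' is the classical pooled-variance Student's t-test; the Welch variant is
#' available by flag and both statistics are always computed. Two-sided and
#' one-sided p-values are reported (the one-sided alternative is
#' `mean(a) > mean(b)`), since "not significantly larger" claims read
#' one-sided while the test is conventionally two-sided.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param variant `"pooled"` (classical) or `"welch"`.
#' @return Object of class `xrf_ttest` with fields `t`, `df`, `p_two`,
#'   `p_one`, `variant`, per-variant sub-results, sample sizes and means.
#' @examples
#' students_t(c(2.1, 2.5, 2.3, 2.2), c(2.8, 3.1, 3.0))
#' @export
students_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    stop("students_t: zero pooled variance")
  }
  both <- lapply(c(pooled = TRUE, welch = FALSE), function(eq) {
    tt <- stats::t.test(a, b, var.equal = eq)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_two = tt$p.value,
         p_one = stats::pt(unname(tt$statistic), unname(tt$parameter),
                           lower.tail = FALSE))
  })
  sel <- both[[variant]]
  structure(list(t = sel$t, df = sel$df, p_two = sel$p_two, p_one = sel$p_one,
                 variant = variant, pooled = both$pooled, welch = both$welch,
                 n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b)),
            class = "xrf_ttest")
}

#' @export
print.xrf_ttest <- function(x, ...) {
  cat(sprintf("<xrf_ttest> %s: t = %.4g, df = %.4g, p(two-sided) = %.4g, p(one-sided) = %.4g\n",
              x$variant, x$t, x$df, x$p_two, x$p_one))
  cat(sprintf("  n = %d vs %d, means %.4g vs %.4g\n",
              x$n_a, x$n_b, x$mean_a, x$mean_b))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.xrf_ttest <- function(x, ...) {
  tibble::tibble(variant = c("pooled", "welch"),
                 t = c(x$pooled$t, x$welch$t),
                 df = c(x$pooled$df, x$welch$df),
                 p_two = c(x$pooled$p_two, x$welch$p_two),
                 p_one = c(x$pooled$p_one, x$welch$p_one))
}

#' @export
glance.xrf_ttest <- function(x, ...) {
  tibble::tibble(variant = x$variant, t = x$t, df = x$df,
                 p_two = x$p_two, p_one = x$p_one,
                 n_a = x$n_a, n_b = x$n_b,
                 mean_a = x$mean_a, mean_b = x$mean_b)
}

#' Distribution summary for violin-style plots
#'
#' Quartiles (linear interpolation), mean, IQR, and the 1.5 x IQR fences
#' used when annotating cluster-size distributions.
#'
#' @param values Numeric vector (n >= 1).
#' @return Tibble with `n`, `mean`, `q25`, `median`, `q75`, `iqr`,
#'   `fence_low`, `fence_high`.
#' @examples
#' distribution_summary(1:100)
#' @export
distribution_summary <- function(values) {
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  tibble::tibble(n = length(values), mean = mean(values),
                 q25 = q[1], median = q[2], q75 = q[3], iqr = iqr,
                 fence_low = q[1] - 1.5 * iqr, fence_high = q[3] + 1.5 * iqr)
}

#' Pairwise size comparisons between elements
#'
#' Runs [students_t()] for every element pair in a long table of cluster
#' sizes, the summary conventionally reported alongside a violin plot.
#'
#' @param sizes Data frame with columns `element` and `size`.
#' @param variant Passed to [students_t()].
#' @return Tibble, one row per ordered pair, with sample sizes, means, t,
#'   df and both p-values.
#' @export
size_comparison_table <- function(sizes, variant = "pooled") {
  els <- unique(sizes$element)
  pairs <- utils::combn(els, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- sizes$size[sizes$element == p[1]]
    b <- sizes$size[sizes$element == p[2]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    g <- glance(students_t(a, b, variant))
    dplyr::bind_cols(tibble::tibble(element_a = p[1], element_b = p[2]), g)
  })
}
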