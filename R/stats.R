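#' @importFrom stats pnorm sd quantile median t.test wilcox.test cor.test
NULL

# Anderson-Darling A^2 for composite normality (mean and variance estimated)
.ad_statistic <- function(x) {
  n <- length(x)
  z <- pnorm((sort(x) - mean(x)) / sd(x))
  # guard the logs against underflow at extreme tails
  z <- pmin(pmax(z, .Machine$double.xmin), 1 - .Machine$double.eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
}

# p-value approximation for the size-corrected statistic
# (D'Agostino & Stephens, case 3: both parameters estimated)
.ad_pvalue <- function(a2, n) {
  a <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  if (a >= 0.6) {
    exp(1.2937 - 5.709 * a + 0.0186 * a^2)
  } else if (a >= 0.34) {
    exp(0.9177 - 4.279 * a - 1.38 * a^2)
  } else if (a > 0.2) {
    1 - exp(-8.318 + 42.796 * a - 59.938 * a^2)
  } else {
    1 - exp(-13.436 + 101.14 * a - 223.73 * a^2)
  }
}

#' Anderson-Darling normality gate
#'
#' Tests a sample for normality with the Anderson-Darling test (mean and
#' variance estimated from the data) and returns the gate decision that
#' drives test selection and summary formatting: `is_normal = (p >= alpha)`.
#' Samples of fewer than 8 values, or constant samples, cannot be gated and
#' default to the nonparametric path with a warning.
#'
#' @param sample numeric vector.
#' @param alpha gate significance level, default 0.05.
#' @return list with `statistic` (A^2), `p`, `is_normal`, `n`.
#' @export
normality_test <- function(sample, alpha = 0.05) {
  x <- sample[!is.na(sample)]
  n <- length(x)
  if (n < 8L) {
    warning("fewer than 8 values: normality cannot be assessed, ",
            "defaulting to the nonparametric path")
    return(list(statistic = NA_real_, p = NA_real_, is_normal = FALSE, n = n))
  }
  if (sd(x) == 0) {
    warning("constant sample: defaulting to the nonparametric path")
    return(list(statistic = NA_real_, p = NA_real_, is_normal = FALSE, n = n))
  }
  a2 <- .ad_statistic(x)
  p <- .ad_pvalue(a2, n)
  list(statistic = a2, p = p, is_normal = p >= alpha, n = n)
}

#' Gate-dependent sample summary string
#'
#' Normally distributed samples are reported as `"mean +/- SD"` (sample SD,
#' n - 1 denominator); others as `"median (Q1;Q3)"`. Quartiles use the
#' linear-interpolation convention on the sorted sample (R type 7).
#'
#' @param sample numeric vector, nonempty.
#' @param normal logical; if `NULL` (default) the gate is applied via
#'   [normality_test()].
#' @param digits decimal places in the formatted string (default 2).
#' @param alpha gate level when `normal` is `NULL`.
#' @return character summary, with attributes `normal` and `values`.
#' @examples
#' summarize_sample(c(1, 2, 3), normal = TRUE)   # "2.00 ± 1.00"
#' summarize_sample(1:9, normal = FALSE)         # "5.00 (3.00;7.00)"
#' @export
summarize_sample <- function(sample, normal = NULL, digits = 2,
                             alpha = 0.05) {
  x <- sample[!is.na(sample)]
  if (length(x) == 0L) stop("cannot summarize an empty sample")
  if (is.null(normal)) {
    normal <- suppressWarnings(normality_test(x, alpha)$is_normal)
  }
  if (normal) {
    v <- c(mean(x), sd(x))
    s <- sprintf("%.*f ± %.*f", digits, v[1L], digits, v[2L])
  } else {
    v <- c(median(x), quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
    s <- sprintf("%.*f (%.*f;%.*f)", digits, v[1L], digits, v[2L],
                 digits, v[3L])
  }
  structure(s, normal = normal, values = v)
}

#' Parse a formatted summary string back to numbers
#'
#' Inverse of [summarize_sample()] at the printed precision.
#'
#' @param s summary string, `"m +/- s"` or `"m (q1;q3)"`.
#' @return named numeric vector: `mean`/`sd` or `median`/`q1`/`q3`.
#' @export
parse_summary <- function(s) {
  s <- trimws(s)
  if (grepl("±", s)) {
    v <- as.numeric(strsplit(s, "±", fixed = TRUE)[[1L]])
    c(mean = v[1L], sd = v[2L])
  } else {
    m <- regmatches(s, regexec(
      "^(-?[0-9.]+) \\((-?[0-9.]+);(-?[0-9.]+)\\)$", s))[[1L]]
    if (length(m) != 4L) stop("unrecognized summary format: ", s)
    c(median = as.numeric(m[2L]), q1 = as.numeric(m[3L]),
      q3 = as.numeric(m[4L]))
  }
}

.stat_result <- function(label, test_used, statistic, p_value, n,
                         normality_p, is_normal, summaries, rho = NA_real_,
                         alpha = 0.05) {
  structure(list(label = label, test_used = test_used,
                 statistic = unname(statistic), p_value = p_value, n = n,
                 normality_p = normality_p, is_normal = is_normal,
                 summaries = summaries, rho = rho, alpha = alpha,
                 significant = is.finite(p_value) && p_value < alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: %s, p = %.4g%s%s\n",
              x$label, x$test_used, x$p_value,
              if (!is.na(x$rho)) sprintf(", rho = %.3f", x$rho) else "",
              if (x$significant) " *" else ""))
  for (nm in names(x$summaries)) {
    cat(sprintf("  %s (n = %d): %s\n", nm,
                x$n[[nm]], x$summaries[[nm]]))
  }
  invisible(x)
}

#' Normality-gated comparison of two independent groups
#'
#' Both samples are gated with [normality_test()]; if both pass, a Welch
#' two-sample t-test is used, otherwise the Mann-Whitney test. Used for
#' between-protocol and between-layer comparisons.
#'
#' @param a,b numeric samples, at least 3 values each.
#' @param label comparison label carried into the result.
#' @param alpha significance level (default 0.05).
#' @return a `stat_result`.
#' @export
compare_independent <- function(a, b, label = "a vs b", alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 values")
  }
  ga <- suppressWarnings(normality_test(a, alpha))
  gb <- suppressWarnings(normality_test(b, alpha))
  normal <- ga$is_normal && gb$is_normal
  ht <- if (normal) {
    t.test(a, b, var.equal = FALSE)
  } else {
    suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  }
  .stat_result(
    label, if (normal) "two_sample_t" else "mann_whitney",
    ht$statistic, ht$p.value, n = list(a = length(a), b = length(b)),
    normality_p = list(a = ga$p, b = gb$p),
    is_normal = list(a = ga$is_normal, b = gb$is_normal),
    summaries = list(a = summarize_sample(a, ga$is_normal),
                     b = summarize_sample(b, gb$is_normal)),
    alpha = alpha)
}

#' Normality-gated paired comparison
#'
#' For quantities measured twice within the same physical specimen (e.g.
#' boundary length before and after residual-stress release). The gate is
#' applied to the paired differences; a paired t-test is used when they pass
#' and the Wilcoxon signed-rank test otherwise.
#'
#' @param a,b numeric samples of equal length, matched by position (or by
#'   names, which must coincide when present).
#' @param label,alpha see [compare_independent()].
#' @return a `stat_result`.
#' @export
compare_paired <- function(a, b, label = "paired", alpha = 0.05) {
  if (length(a) != length(b)) {
    stop("paired samples differ in length (", length(a), " vs ", length(b),
         ")")
  }
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(sort(names(a)), sort(names(b)))) {
    miss <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("specimens not matched across states: ",
         paste(miss, collapse = ", "))
  }
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  d <- b - a
  if (all(d == 0)) {
    # no change at all: nothing to test
    return(.stat_result(label, "wilcoxon_signed_rank", NA_real_, 1,
                        n = list(pairs = length(a)),
                        normality_p = list(differences = NA_real_),
                        is_normal = list(differences = FALSE),
                        summaries = list(differences =
                                           summarize_sample(d, FALSE)),
                        alpha = alpha))
  }
  g <- suppressWarnings(normality_test(d, alpha))
  ht <- if (g$is_normal) {
    t.test(b, a, paired = TRUE)
  } else {
    suppressWarnings(wilcox.test(b, a, paired = TRUE, exact = FALSE,
                                 correct = TRUE))
  }
  .stat_result(
    label, if (g$is_normal) "paired_t" else "wilcoxon_signed_rank",
    ht$statistic, ht$p.value, n = list(pairs = length(a)),
    normality_p = list(differences = g$p),
    is_normal = list(differences = g$is_normal),
    summaries = list(differences = summarize_sample(d, g$is_normal)),
    alpha = alpha)
}

#' Spearman rank correlation
#'
#' Used for relationships such as adventitia percentage vs curvature or
#' opening angle. Ties are handled by average ranks; p-values use the
#' large-sample approximation.
#'
#' @param x,y numeric vectors of equal length, at least 5 complete pairs;
#'   neither may be constant.
#' @param label,alpha see [compare_independent()].
#' @return a `stat_result` with `rho` filled.
#' @export
spearman_correlation <- function(x, y, label = "spearman", alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop("need at least 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  .stat_result(
    label, "spearman", ht$statistic, ht$p.value,
    n = list(pairs = length(x)),
    normality_p = list(), is_normal = list(),
    summaries = list(), rho = unname(ht$estimate), alpha = alpha)
}

#' Decide whether two experimental protocols can be merged
#'
#' The two protocols are merged when none of the six parameters of interest
#' (thickness, opening angle, inner/outer curvature, inner/outer length)
#' differs significantly between them; otherwise they are kept separate and
#' the offending parameters are named.
#'
#' @param per_parameter_results named list of `stat_result`s, one per
#'   parameter; names must cover all six parameters of interest.
#' @return list with `merge` (logical), `offending` (character vector of
#'   significant parameters), `p_values` (named numeric).
#' @export
protocol_merge_decision <- function(per_parameter_results) {
  required <- c("thickness", "opening_angle", "inner_curvature",
                "outer_curvature", "inner_length", "outer_length")
  missing <- setdiff(required, names(per_parameter_results))
  if (length(missing) > 0L) {
    stop("missing protocol comparisons for: ", paste(missing, collapse = ", "))
  }
  res <- per_parameter_results[required]
  p <- vapply(res, function(r) r$p_value, numeric(1))
  sig <- vapply(res, function(r) isTRUE(r$significant), logical(1))
  list(merge = !any(sig), offending = required[sig], p_values = p)
}

#' Holm adjustment across a set of results
#'
#' The primary analysis applies no multiple-testing correction (each
#' comparison is reported at its nominal level); this helper applies the
#' Holm step-down correction across a family of results for users who want
#' family-wise control.
#'
#' @param results list of `stat_result`s.
#' @return the list with `p_value` replaced by Holm-adjusted values and
#'   `significant` recomputed.
#' @export
holm_adjust <- function(results) {
  p <- vapply(results, function(r) r$p_value, numeric(1))
  padj <- stats::p.adjust(p, method = "holm")
  for (i in seq_along(results)) {
    results[[i]]$p_value <- padj[i]
    results[[i]]$significant <- padj[i] < results[[i]]$alpha
  }
  results
}
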