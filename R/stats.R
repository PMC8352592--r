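#' Two-sample t test from raw samples or summary statistics
#'
#' Two-tailed comparison of two groups, accepting either raw sample vectors
#' or `(mean, sd, n)` summaries — the latter is what published figure
#' legends provide.  Welch's unequal-variance test is the default (with very
#' unequal SDs the pooled test overstates significance); the pooled Student
#' variant is also computed and both p values are reported.
#'
#' @param group_a,group_b Either numeric sample vectors, or summaries as a
#'   named vector/list with elements `mean`, `sd`, `n`.
#' @param variant `"welch"` (default) or `"pooled"` — which variant the
#'   headline `t`, `df`, `p` refer to.
#' @return A `two_sample_summary`: per-group `mean`, `sd`, `n`; `t`, `df`,
#'   `p` for the chosen variant; `p_welch` and `p_pooled`; `variant`.
#' @examples
#' two_sample_test(c(mean = 880, sd = 432, n = 29),
#'                 c(mean = 1351, sd = 171, n = 32))
#' @export
two_sample_test <- function(group_a, group_b,
                            variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  sum_a <- as_group_summary(group_a, "group_a")
  sum_b <- as_group_summary(group_b, "group_b")

  welch <- t_from_summary(sum_a, sum_b, pooled = FALSE)
  pooled <- t_from_summary(sum_a, sum_b, pooled = TRUE)
  chosen <- if (variant == "welch") welch else pooled

  structure(list(mean = c(a = sum_a$mean, b = sum_b$mean),
                 sd = c(a = sum_a$sd, b = sum_b$sd),
                 n = c(a = sum_a$n, b = sum_b$n),
                 t = chosen$t, df = chosen$df, p = chosen$p,
                 p_welch = welch$p, p_pooled = pooled$p,
                 variant = variant),
            class = "two_sample_summary")
}

as_group_summary <- function(g, who) {
  if (is.list(g) || !is.null(names(g))) {
    g <- as.list(g)
    check_that(all(c("mean", "sd", "n") %in% names(g)), who,
               "summary input needs mean, sd and n")
    check_that(g$n >= 2, who, "n must be >= 2")
    check_that(g$sd >= 0, who, "sd must be >= 0")
    list(mean = as.numeric(g$mean), sd = as.numeric(g$sd), n = as.numeric(g$n))
  } else {
    check_that(is.numeric(g) && length(g) >= 2, who,
               "raw samples need length >= 2")
    list(mean = mean(g), sd = sd(g), n = length(g))
  }
}

t_from_summary <- function(a, b, pooled) {
  if (pooled) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tt <- (a$mean - b$mean) / se
  p <- if (se == 0) 1 else 2 * pt(-abs(tt), df)
  list(t = tt, df = df, p = max(p, .Machine$double.xmin))
}

#' @export
print.two_sample_summary <- function(x, ...) {
  cat(sprintf(
    "<two_sample_summary %s> %.4g (sd %.4g, n=%d) vs %.4g (sd %.4g, n=%d)\n  t = %.3f, df = %.1f, p = %.3g  (welch %.3g, pooled %.3g)\n",
    x$variant, x$mean[["a"]], x$sd[["a"]], x$n[["a"]],
    x$mean[["b"]], x$sd[["b"]], x$n[["b"]],
    x$t, x$df, x$p, x$p_welch, x$p_pooled))
  invisible(x)
}
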