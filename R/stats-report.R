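#' Violin-plot summary statistics
#'
#' Median and quartiles as drawn on violin plots (red median line, dotted
#' 25/75 percentile lines). Quantiles use linear interpolation (type 7, the
#' R default); quartile conventions differ between tools, so the convention
#' is fixed and documented here.
#'
#' @param values Numeric vector (non-empty).
#' @return Named numeric vector `c(median, q25, q75)`.
#' @examples
#' violin_summary(c(1, 2, 3, 4, 5))
#' @export
violin_summary <- function(values) {
  stopifnot(length(values) >= 1, is.numeric(values))
  q <- quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Compare groups with the test families used for imaging data
#'
#' Three methods:
#' \describe{
#'   \item{`t_with_f`}{Two-sided Student's t-test preceded by an F-test for
#'     equality of variances: the pooled-variance t is used when the F-test
#'     p-value is >= 0.05, otherwise Welch's t. Suited to per-replicate
#'     percentages (n = 3 bar graphs).}
#'   \item{`ks`}{Two-sample Kolmogorov-Smirnov test comparing cumulative
#'     distributions; suited to pooled per-nucleus distributions shown as
#'     violins.}
#'   \item{`anova_bonferroni`}{One-way ANOVA followed by Bonferroni-adjusted
#'     comparisons of selected pairs: each pair's pooled-MSE t-test p-value
#'     is multiplied by the number of selected pairs and capped at 1.}
#' }
#'
#' @param a,b Numeric vectors (two-sample methods).
#' @param method One of `"t_with_f"`, `"ks"`, `"anova_bonferroni"`.
#' @param groups Named list of numeric vectors (`anova_bonferroni`).
#' @param pairs List of length-2 character vectors naming the group pairs to
#'   compare (`anova_bonferroni`); defaults to all pairs.
#' @return For two-sample methods, a list with `method`, `statistic`,
#'   `p_value` and (for `t_with_f`) `ci95_difference`, the 95% CI of
#'   `mean(b) - mean(a)`. For `anova_bonferroni`, a list with `anova`
#'   (`statistic`, `p_value`, `df`) and `pairs`, a tibble with one row per
#'   selected pair (`group_a`, `group_b`, `statistic`, `p_raw`,
#'   `p_adjusted`).
#' @export
compare_groups <- function(a = NULL, b = NULL,
                           method = c("t_with_f", "ks", "anova_bonferroni"),
                           groups = NULL, pairs = NULL) {
  method <- match.arg(method)
  if (method == "anova_bonferroni") {
    return(anova_bonferroni(groups, pairs))
  }
  if (length(a) == 0L || length(b) == 0L) {
    stop_mtoc("empty group supplied", class = "mtoc_input_error")
  }
  if (method == "ks") {
    ks <- suppressWarnings(stats::ks.test(a, b))
    return(list(
      method = "ks", statistic = unname(ks$statistic),
      p_value = ks$p.value
    ))
  }
  t_with_f(a, b)
}

t_with_f <- function(a, b) {
  va <- var(a)
  vb <- var(b)
  if (va == 0 && vb == 0) {
    d <- mean(b) - mean(a)
    return(list(
      method = "t_with_f",
      statistic = if (d == 0) 0 else Inf * sign(d),
      p_value = if (d == 0) 1 else 0,
      f_p_value = 1, equal_variance = TRUE,
      ci95_difference = c(d, d)
    ))
  }
  p_f <- if (va > 0 && vb > 0) stats::var.test(a, b)$p.value else 0
  eq <- p_f >= 0.05
  tt <- stats::t.test(b, a, var.equal = eq)
  list(
    method = "t_with_f", statistic = unname(tt$statistic),
    p_value = tt$p.value, f_p_value = p_f, equal_variance = eq,
    ci95_difference = unname(as.numeric(tt$conf.int))
  )
}

anova_bonferroni <- function(groups, pairs = NULL) {
  if (is.null(groups) || length(groups) < 2L) {
    stop_mtoc("anova_bonferroni needs a named list of >= 2 groups",
      class = "mtoc_input_error"
    )
  }
  if (any(lengths(groups) == 0L)) {
    stop_mtoc("empty group supplied", class = "mtoc_input_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop_mtoc("groups must be named", class = "mtoc_input_error")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1L]]
  mse <- s["Residuals", "Mean Sq"]
  df_res <- s["Residuals", "Df"]
  if (is.null(pairs)) {
    pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  }
  n_pairs <- length(pairs)
  rows <- lapply(pairs, function(p) {
    ga <- groups[[p[1L]]]
    gb <- groups[[p[2L]]]
    se <- sqrt(mse * (1 / length(ga) + 1 / length(gb)))
    t <- (mean(gb) - mean(ga)) / se
    p_raw <- 2 * pt(-abs(t), df_res)
    tibble::tibble(
      group_a = p[1L], group_b = p[2L], statistic = t,
      p_raw = p_raw, p_adjusted = min(1, p_raw * n_pairs)
    )
  })
  list(
    method = "anova_bonferroni",
    anova = list(
      statistic = s["group", "F value"],
      p_value = s["group", "Pr(>F)"],
      df = c(s["group", "Df"], df_res)
    ),
    pairs = dplyr::bind_rows(rows)
  )
}

#' Confidence interval for the difference of group means
#'
#' Pooled-variance t interval on `mean(b) - mean(a)` computed from
#' replicate-level values, matching the 95% CIs of group differences
#' reported alongside n = 3 replicate graphs. With zero pooled variance the
#' interval degenerates to the point difference.
#'
#' @param a,b Numeric vectors of replicate-level values.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
ci_difference <- function(a, b, level = 0.95) {
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) {
    stop_mtoc("empty group supplied", class = "mtoc_input_error")
  }
  d <- mean(b) - mean(a)
  df <- na + nb - 2L
  if (df <= 0L) {
    stop_mtoc("ci_difference needs at least 2 values overall in excess of ",
      "the two means (df > 0)",
      class = "mtoc_input_error"
    )
  }
  sp2 <- ((na - 1) * var_or_zero(a) + (nb - 1) * var_or_zero(b)) / df
  margin <- qt(1 - (1 - level) / 2, df) * sqrt(sp2 * (1 / na + 1 / nb))
  c(d - margin, d + margin)
}

var_or_zero <- function(x) if (length(x) < 2L) 0 else var(x)

#' Dual-luciferase reporter normalization
#'
#' Normalizes Renilla luciferase activity to the firefly transfection
#' control for each measurement and expresses the result as fold activation
#' over a control ratio.
#'
#' @param renilla,firefly Measured activities (vectors or scalars;
#'   `firefly > 0`).
#' @param control_ratio Renilla/firefly ratio of the control condition
#'   (> 0).
#' @return Fold activation, `(renilla / firefly) / control_ratio`.
#' @examples
#' luciferase_normalize(200, 100, 2.0) # 1.0
#' @export
luciferase_normalize <- function(renilla, firefly, control_ratio = 1) {
  if (any(firefly <= 0)) {
    stop_mtoc("firefly activity must be > 0", class = "mtoc_input_error")
  }
  if (any(control_ratio <= 0)) {
    stop_mtoc("control_ratio must be > 0", class = "mtoc_input_error")
  }
  (renilla / firefly) / control_ratio
}
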