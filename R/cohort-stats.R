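#' Two-way ANOVA (Type-III sums of squares)
#'
#' Fits `value ~ A * B` with sum-to-zero contrasts and reports the Type-III
#' sum-of-squares decomposition, which handles the unbalanced cell sizes
#' typical of aging-cohort designs; on balanced designs it coincides with the
#' classical decomposition. Each effect reports SS, df, MS, F against the
#' residual mean square, and the F-distribution p-value.
#'
#' @param table Data frame with the response and two factor columns.
#' @param factor_a,factor_b Column names of the two factors (each must have
#'   at least 2 levels and every cell at least one observation).
#' @param value Column name of the response (default `"value"`).
#' @return Object of class `anova_result`: tibble with columns `effect`
#'   (`factor_a`, `factor_b`, interaction, `Residuals`), `ss`, `df`, `ms`,
#'   `f`, `p`; attributes `mse`, `df_error`, `cell_n`.
#' @export
two_way_anova <- function(table, factor_a, factor_b, value = "value") {
  table <- as.data.frame(table)
  stopifnot(all(c(factor_a, factor_b, value) %in% names(table)))
  a <- factor(table[[factor_a]])
  b <- factor(table[[factor_b]])
  y <- table[[value]]
  if (nlevels(a) < 2L) stop("factor '", factor_a, "' has a single level")
  if (nlevels(b) < 2L) stop("factor '", factor_b, "' has a single level")
  cell_n <- table(a, b)
  if (any(cell_n == 0L)) {
    empty <- which(cell_n == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty cell: %s = %s, %s = %s", factor_a,
                 levels(a)[empty[1L]], factor_b, levels(b)[empty[2L]]))
  }
  dat <- data.frame(y = y, A = a, B = b)
  fit <- stats::lm(y ~ A * B, data = dat,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  if (sum(stats::residuals(fit)^2) <= 1e-12 * max(1, sum(y^2))) {
    stop("zero residual mean square: effects are not testable")
  }
  aov3 <- car::Anova(fit, type = 3)
  rows <- c("A", "B", "A:B", "Residuals")
  ss <- aov3[rows, "Sum Sq"]
  df <- aov3[rows, "Df"]
  ms <- ss / df
  mse <- ms[4L]
  if (!(mse > 0)) stop("zero residual mean square: effects are not testable")
  f <- c(ms[1:3] / mse, NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4L], lower.tail = FALSE), NA)
  out <- tibble::tibble(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b),
               "Residuals"),
    ss = ss, df = df, ms = ms, f = f, p = p
  )
  structure(out, class = c("anova_result", class(out)),
            mse = mse, df_error = df[4L], cell_n = cell_n,
            data = dat, factor_a = factor_a, factor_b = factor_b)
}

#' Fisher's LSD post-hoc comparison
#'
#' Unprotected pairwise t-test using the ANOVA pooled error term:
#' `t = (mean1 - mean2) / sqrt(MSE * (1/n1 + 1/n2))` on the residual degrees
#' of freedom, with no multiplicity correction (which is what LSD means —
#' protection comes from only interpreting it after a significant omnibus
#' F). Comparisons can be between two marginal levels of either factor or
#' between two individual cells (`"levelA/levelB"`).
#'
#' @param anova_result Result of [two_way_anova()].
#' @param level1,level2 Marginal level names of `factor` or `"a/b"` cell
#'   names.
#' @param factor Which factor the levels belong to (`"A"`, `"B"`, or
#'   `"cell"`).
#' @return List: `t`, `df`, `p`, `mean_diff`, `n1`, `n2`.
#' @export
fishers_lsd <- function(anova_result, level1, level2,
                        factor = c("A", "B", "cell")) {
  stopifnot(inherits(anova_result, "anova_result"))
  factor <- match.arg(factor)
  dat <- attr(anova_result, "data")
  mse <- attr(anova_result, "mse")
  df_e <- attr(anova_result, "df_error")
  group <- switch(factor,
    A = as.character(dat$A),
    B = as.character(dat$B),
    cell = paste(dat$A, dat$B, sep = "/")
  )
  pick <- function(lv) {
    v <- dat$y[group == lv]
    if (length(v) == 0L) stop("no observations for level '", lv, "'")
    v
  }
  y1 <- pick(level1)
  y2 <- pick(level2)
  diff <- mean(y1) - mean(y2)
  se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
  t <- diff / se
  list(t = t, df = df_e,
       p = 2 * stats::pt(abs(t), df_e, lower.tail = FALSE),
       mean_diff = diff, n1 = length(y1), n2 = length(y2))
}

#' Signed composite of bidirectional transition percentages
#'
#' Builds the paired predictors used to relate alternation to transition
#' structure: the sum of the bidirectional percentages of the positively
#' paired transitions minus the sum over the negatively paired ones.
#'
#' @param profile A [transition_profile()].
#' @param positive_pairs,negative_pairs Character vectors of unordered pair
#'   keys (`"a:b"`), disjoint; either may be empty.
#' @return Numeric score.
#' @export
composite_transition_score <- function(profile, positive_pairs,
                                       negative_pairs = character(0)) {
  stopifnot(inherits(profile, "transition_profile"))
  if (length(intersect(positive_pairs, negative_pairs)) > 0L) {
    stop("positive and negative pair sets must be disjoint")
  }
  known <- names(profile$bi_percent)
  bad <- setdiff(c(positive_pairs, negative_pairs), known)
  if (length(bad) > 0L) stop("unknown pair key(s): ", paste(bad, collapse = ", "))
  sum(profile$bi_percent[positive_pairs]) - sum(profile$bi_percent[negative_pairs])
}

#' Regress a transition predictor on alternation
#'
#' Ordinary least squares following the plotting convention in which
#' alternation is placed on the x-axis and the transition predictor on the
#' y-axis (R-squared is invariant to which variable is regressed in simple
#' OLS, so the convention does not affect it). Reports slope, intercept,
#' R-squared, the slope-t p-value and n.
#'
#' @param alternation_values Numeric vector (percent alternation per animal).
#' @param predictor_values Numeric vector, same length (n >= 3).
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p`, `n`.
#' @export
regress_alternation <- function(alternation_values, predictor_values) {
  stopifnot(length(alternation_values) == length(predictor_values))
  ok <- stats::complete.cases(alternation_values, predictor_values)
  x <- alternation_values[ok]
  y <- predictor_values[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in alternation or predictor")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared,
         p = sm$coefficients[2L, 4L],
         n = length(x)),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.3f, intercept %.2f, R^2 = %.3f, p = %.4g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p, x$n))
  invisible(x)
}
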