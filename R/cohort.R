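# Epidemiological layer: perceived-stress quartile categories, contingency
# and covariate-adjusted odds ratios, adjusted geometric-mean ratios, and
# cohort-representativeness chi-square tests.

#' Categorize stress scores into quartile groups
#'
#' Scores strictly below the first quartile are `low`, strictly above the
#' third quartile are `high`, everything else (including scores equal to a
#' cutpoint) is `medium`. Quartiles use linear interpolation between order
#' statistics (`type = 7`, the common statistical-package default);
#' `type = 1` gives the nearest-rank alternative. Because of interpolation
#' and ties, category sizes need not be exactly n/4.
#'
#' @param scores numeric vector (n >= 4).
#' @param quantile_type passed to [stats::quantile()] (7 = interpolation,
#'   1 = nearest rank).
#' @return list with `category` (factor levels low/medium/high) and
#'   `cutpoints` (Q1, Q3).
#' @export
categorize_stress <- function(scores, quantile_type = 7) {
  if (length(scores) < 4) stop_input("need at least 4 scores")
  q <- stats::quantile(scores, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  if (q[1] == q[2]) warning("all scores (nearly) identical; everything is 'medium'")
  category <- factor(ifelse(scores < q[1], "low",
                            ifelse(scores > q[2], "high", "medium")),
                     levels = c("low", "medium", "high"))
  list(category = category, cutpoints = stats::setNames(q, c("Q1", "Q3")))
}

#' Odds ratio from a 2x2 contingency table
#'
#' With `a` exposed cases, `b` exposed non-cases, `c` reference cases and
#' `d` reference non-cases: OR = (a d) / (b c), Wald 95% CI =
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)), two-sided p from the
#' Wald z. Counts can be given directly or derived from a cohort table.
#'
#' @param a,b,c,d cell counts (all > 0 unless `continuity` is TRUE).
#' @param continuity add 0.5 to every cell (use for zero cells; off by
#'   default).
#' @return list of class `or_result`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `adjusted = FALSE`, `comparison`.
#' @examples
#' contingency_or(22, 112 - 22, 10, 110 - 10)  # odds ratio 2.44
#' @export
contingency_or <- function(a, b, c, d, continuity = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells == 0) && !continuity)
    stop_input("zero cell in 2x2 table; use continuity = TRUE for the 0.5 correction")
  if (continuity) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  structure(list(odds_ratio = unname(or),
                 ci_low = unname(exp(log(or) - 1.96 * se)),
                 ci_high = unname(exp(log(or) + 1.96 * se)),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 adjusted = FALSE,
                 comparison = "exposed vs reference"),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("%s OR = %.2f (95%% CI %.2f-%.2f), p = %.3g [%s]\n",
              x$comparison, x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
              if (x$adjusted) "adjusted" else "raw"))
  invisible(x)
}

#' Raw odds ratios per exposure level from a cohort table
#'
#' Builds the 2x2 table for each non-reference exposure level against the
#' reference and applies [contingency_or()].
#'
#' @param table cohort data.frame.
#' @param outcome name of the binary outcome column (0/1).
#' @param exposure name of the categorical exposure column.
#' @param reference reference level (default first factor level).
#' @param continuity passed through.
#' @return named list of `or_result`, one per non-reference level.
#' @export
cohort_or <- function(table, outcome, exposure, reference = NULL,
                      continuity = FALSE) {
  x <- factor(table[[exposure]])
  y <- table[[outcome]]
  reference <- reference %||% levels(x)[1]
  out <- list()
  for (lev in setdiff(levels(x), reference)) {
    a <- sum(y == 1 & x == lev); b <- sum(y == 0 & x == lev)
    c_ <- sum(y == 1 & x == reference); d <- sum(y == 0 & x == reference)
    r <- contingency_or(a, b, c_, d, continuity)
    r$comparison <- sprintf("%s vs %s", lev, reference)
    out[[lev]] <- r
  }
  out
}

#' Covariate-adjusted odds ratios from logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS, deviance tolerance 1e-8); the OR
#' per non-reference exposure level is exp(coefficient) with a Wald 95% CI
#' from the observed information. With an empty covariate list and a
#' two-level exposure this reproduces [contingency_or()] exactly (saturated
#' model).
#'
#' @param table cohort data.frame.
#' @param outcome binary outcome column name.
#' @param exposure categorical exposure column name.
#' @param covariates character vector of covariate column names.
#' @param reference exposure reference level.
#' @return named list of `or_result` (with `adjusted = TRUE` when
#'   covariates are present), one per non-reference exposure level.
#' @export
logistic_adjusted_or <- function(table, outcome, exposure,
                                 covariates = character(), reference = NULL) {
  df <- as.data.frame(table)
  df[[exposure]] <- factor(df[[exposure]])
  if (!is.null(reference))
    df[[exposure]] <- stats::relevel(df[[exposure]], reference)
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop_input("logistic model did not converge (possible separation in %s)",
               paste(c(exposure, covariates), collapse = ", "))
  cf <- summary(fit)$coefficients
  lev_terms <- paste0(exposure, levels(df[[exposure]])[-1])
  if (any(is.na(stats::coef(fit)[lev_terms])))
    stop_input("exposure coefficient not estimable (separation or collinearity)")
  out <- list()
  for (k in seq_along(lev_terms)) {
    est <- cf[lev_terms[k], "Estimate"]; se <- cf[lev_terms[k], "Std. Error"]
    out[[levels(df[[exposure]])[-1][k]]] <- structure(
      list(odds_ratio = exp(est),
           ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
           p_value = cf[lev_terms[k], "Pr(>|z|)"],
           adjusted = length(covariates) > 0,
           comparison = sprintf("%s vs %s", levels(df[[exposure]])[-1][k],
                                levels(df[[exposure]])[1])),
      class = "or_result")
  }
  out
}

#' Adjusted geometric-mean ratio of a positive outcome
#'
#' Ordinary least squares on the log-transformed outcome with exposure and
#' covariates; the mean ratio (MR) is exp of the exposure coefficient — the
#' ratio of geometric means adjusted for the covariates — with CI
#' exp(coefficient +/- 1.96 SE) and p from the coefficient's t test.
#' Invariant under multiplicative rescaling of the outcome.
#'
#' @param table cohort data.frame.
#' @param outcome strictly positive outcome column name.
#' @param exposure exposure column (categorical or numeric).
#' @param covariates covariate column names.
#' @param reference exposure reference level (categorical exposure).
#' @return named list of class-`mr_result` lists (one per non-reference
#'   level, or `"slope"` for numeric exposure): `mean_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `covariates`.
#' @export
adjusted_mean_ratio <- function(table, outcome, exposure,
                                covariates = character(), reference = NULL) {
  df <- as.data.frame(table)
  y <- df[[outcome]]
  if (any(!is.finite(y)) || any(y <= 0))
    stop_input("outcome %s must be strictly positive; offending subject(s): %s",
               outcome,
               paste(utils::head(which(!is.finite(y) | y <= 0), 5), collapse = ", "))
  df$.logy <- log(y)
  if (!is.numeric(df[[exposure]])) {
    df[[exposure]] <- factor(df[[exposure]])
    if (!is.null(reference))
      df[[exposure]] <- stats::relevel(df[[exposure]], reference)
  }
  fml <- stats::reformulate(c(exposure, covariates), response = ".logy")
  fit <- stats::lm(fml, data = df)
  cf <- summary(fit)$coefficients
  terms <- if (is.numeric(df[[exposure]])) stats::setNames(exposure, "slope")
  else stats::setNames(paste0(exposure, levels(df[[exposure]])[-1]),
                       levels(df[[exposure]])[-1])
  out <- list()
  for (nm in names(terms)) {
    est <- cf[terms[[nm]], "Estimate"]; se <- cf[terms[[nm]], "Std. Error"]
    out[[nm]] <- structure(
      list(mean_ratio = exp(est), ci_low = exp(est - 1.96 * se),
           ci_high = exp(est + 1.96 * se),
           p_value = cf[terms[[nm]], "Pr(>|t|)"],
           covariates = covariates),
      class = "mr_result")
  }
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("mean ratio = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$mean_ratio, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Chi-square test of equal category distribution in two cohorts
#'
#' Pearson chi-square (no continuity correction) on the category x cohort
#' contingency table, df = (k - 1), asymptotic p. Warns when an expected
#' cell is below 1 but still reports the p-value.
#'
#' @param sub,full data.frames (sub- and full cohort).
#' @param field categorical column present in both.
#' @return list with `statistic`, `df`, `p_value`, `table`.
#' @export
representativeness_chisq <- function(sub, full, field) {
  levs <- sort(unique(c(as.character(sub[[field]]), as.character(full[[field]]))))
  if (length(levs) < 2) stop_input("field %s has a single category", field)
  tab <- rbind(sub = table(factor(sub[[field]], levs)),
               full = table(factor(full[[field]], levs)))
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cells < 1)) warning("expected cell count below 1")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, table = tab)
}
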