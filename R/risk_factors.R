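# Risk-factor analysis for a detected signal: closed-form 2x2 odds
# ratios, logistic regression on sex and age group (all terms entered
# simultaneously -- no stepwise selection), and the Hosmer-Lemeshow
# goodness-of-fit test.

#' Closed-form odds ratio for a 2x2 table
#'
#' OR = (n11 n00)/(n10 n01) with the Wald interval on the log scale,
#' SE = sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00). For a binary exposure this
#' is algebraically identical to the exponentiated logistic-regression
#' coefficient, which the test suite exploits as a cross-module oracle.
#'
#' @param n11 exposed cases; `n10` unexposed cases; `n01` exposed
#'   controls; `n00` unexposed controls.
#' @param n10,n01,n00 see above.
#' @param z normal quantile (1.96 for 95%).
#' @return named numeric vector `c(or, low, high, se_log)`.
#' @export
odds_ratio_2x2 <- function(n11, n10, n01, n00, z = 1.96) {
  cells <- unname(c(n11, n10, n01, n00))
  if (any(cells <= 0))
    return(c(or = NA_real_, low = NA_real_, high = NA_real_,
             se_log = NA_real_))
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  c(or = or, low = exp(log(or) - z * se), high = exp(log(or) + z * se),
    se_log = se)
}

#' Fit a logistic regression risk-factor model
#'
#' Maximum-likelihood logistic regression via [stats::glm()] (IRLS), all
#' supplied terms entered simultaneously. Complete or quasi-complete
#' separation is detected (fitted probabilities collapsing to 0/1 with a
#' diverging coefficient) and reported via a warning and the
#' `separation` field rather than silently returned; a rank-deficient
#' design is an error.
#'
#' @param formula model formula with a binary outcome.
#' @param data data frame of case-control rows.
#' @param z normal quantile for the Wald intervals on the odds-ratio
#'   scale.
#' @return object of class `pv_logistic`: the underlying `glm` fit plus
#'   a coefficient table (estimate, SE, OR = exp(beta), Wald CI,
#'   p-value), log-likelihood, and convergence metadata.
#' @export
fit_logistic <- function(formula, data, z = 1.96) {
  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 50))
  if (anyNA(stats::coef(fit)))
    stop_pv("rank-deficient design: drop aliased terms")
  y <- fit$y
  if (all(y == y[1]))
    stop_pv("outcome must contain both events and non-events")
  co <- summary(fit)$coefficients
  separation <- max(abs(stats::coef(fit))) > 15 &&
    (any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8))
  if (separation)
    warning("possible complete separation: coefficients diverging",
            call. = FALSE)
  tab <- data.frame(term = rownames(co),
                    estimate = co[, 1], se = co[, 2],
                    or = exp(co[, 1]),
                    or_low = exp(co[, 1] - z * co[, 2]),
                    or_high = exp(co[, 1] + z * co[, 2]),
                    p = co[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(glm = fit, coef_table = tab,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, iterations = fit$iter,
                 separation = separation, z = z),
            class = "pv_logistic")
}

#' @export
print.pv_logistic <- function(x, digits = 3, ...) {
  cat("Logistic risk-factor model (",
      length(x$glm$y), " rows, ", sum(x$glm$y), " events; ",
      x$iterations, " IRLS iterations",
      if (!x$converged) ", NOT converged",
      if (x$separation) ", separation suspected", ")\n", sep = "")
  tab <- x$coef_table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pv_logistic <- function(object, ...) stats::coef(object$glm)

#' @export
summary.pv_logistic <- function(object, ...) object$coef_table

#' @export
predict.pv_logistic <- function(object, newdata = NULL,
                                type = "response", ...) {
  stats::predict(object$glm, newdata = newdata, type = type, ...)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Partitions the sample into `g` groups by quantiles of fitted risk
#' (ties kept in one group, assigned to the lower group), then compares
#' observed and expected event counts:
#' statistic = sum over groups of (O - E)^2 / (n_k pbar_k (1 - pbar_k)),
#' referred to a chi-square with g - 2 degrees of freedom. A well-fitting
#' model gives a large p-value.
#'
#' @param fit a `pv_logistic` (or `glm`) fit.
#' @param g number of groups (default 10: deciles of risk).
#' @return object of class `hl_test`: statistic, df, p-value, and the
#'   per-group observed/expected table.
#' @export
hosmer_lemeshow <- function(fit, g = 10) {
  glmfit <- if (inherits(fit, "pv_logistic")) fit$glm else fit
  p <- glmfit$fitted.values
  y <- glmfit$y
  if (length(p) < g) stop_pv("need at least g observations")
  if (length(unique(p)) < 3)
    stop_pv("fewer than 3 distinct fitted values: grouping is degenerate")
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1),
                               type = 7))
  grp <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  nk <- tabulate(grp, nbins = length(br) - 1)
  obs <- tapply(y, grp, sum)
  pbar <- tapply(p, grp, mean)
  keep <- nk > 0
  nk <- nk[keep]; obs <- obs[keep]; pbar <- pbar[keep]
  ek <- nk * pbar
  stat <- sum((obs - ek)^2 / (nk * pbar * (1 - pbar)))
  df <- length(nk) - 2
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 groups = data.frame(n = nk, observed = as.numeric(obs),
                                     expected = as.numeric(ek),
                                     mean_risk = as.numeric(pbar))),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat("Hosmer-Lemeshow goodness-of-fit: chi2 =",
      format(x$statistic, digits = 4), "on", x$df,
      "df, p =", format(x$p.value, digits = 3), "\n")
  invisible(x)
}

#' Univariate and multivariate risk-factor table
#'
#' Builds the conventional risk-factor report for a binary outcome over
#' sex and age group: per-level case/control counts, the univariate
#' closed-form odds ratios against the reference level, and the
#' multivariate (mutually adjusted) logistic odds ratios.
#'
#' @param rows data frame with columns `outcome` (0/1), `sex`
#'   (`"M"`/`"F"`), `age_group` (levels `<=18`, `19-64`, `>=65`); rows
#'   with missing sex or age are dropped first (and counted).
#' @param z normal quantile for intervals.
#' @return list with `table` (the report data frame), `fit` (the
#'   multivariate `pv_logistic`), `hl` (its [hosmer_lemeshow()] result)
#'   and `n_dropped` (rows without both sex and age).
#' @export
risk_factor_table <- function(rows, z = 1.96) {
  need <- c("outcome", "sex", "age_group")
  stopifnot(all(need %in% names(rows)))
  ok <- !is.na(rows$sex) & !is.na(rows$age_group) &
    rows$age_group != "unknown"
  n_dropped <- sum(!ok)
  rows <- rows[ok, , drop = FALSE]
  rows$female <- as.integer(rows$sex == "F")
  rows$age_group <- factor(as.character(rows$age_group),
                           levels = c("<=18", "19-64", ">=65"))
  fit <- fit_logistic(outcome ~ female + age_group, rows, z = z)
  hl <- hosmer_lemeshow(fit)

  cnt <- function(cond) c(cases = sum(rows$outcome == 1 & cond),
                          controls = sum(rows$outcome == 0 & cond))
  uni <- function(cond, ref) {
    e <- cnt(cond); r <- cnt(ref)
    odds_ratio_2x2(e[["cases"]], r[["cases"]], e[["controls"]],
                   r[["controls"]], z = z)
  }
  lv <- levels(rows$age_group)
  blocks <- list(
    female = list(cond = rows$female == 1, ref = rows$female == 0),
    `age 19-64` = list(cond = rows$age_group == lv[2],
                       ref = rows$age_group == lv[1]),
    `age >=65` = list(cond = rows$age_group == lv[3],
                      ref = rows$age_group == lv[1]))
  mv <- fit$coef_table[match(c("female", "age_group19-64", "age_group>=65"),
                             fit$coef_table$term), ]
  tab <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    e <- cnt(b$cond)
    u <- uni(b$cond, b$ref)
    data.frame(variable = names(blocks)[i],
               cases = e[["cases"]], controls = e[["controls"]],
               or_uni = u[["or"]], or_uni_low = u[["low"]],
               or_uni_high = u[["high"]],
               or_multi = mv$or[i], or_multi_low = mv$or_low[i],
               or_multi_high = mv$or_high[i], p_multi = mv$p[i],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, fit = fit, hl = hl, n_dropped = n_dropped)
}
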