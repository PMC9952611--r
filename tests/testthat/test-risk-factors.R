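r2 <- function(x) round_half_up(x, 2)

test_that("closed-form odds ratios reproduce the published marginals", {
  m <- reference_risk_marginals()
  get <- function(v, l, col) m[m$variable == v & m$level == l, col]
  # female vs male
  or_f <- odds_ratio_2x2(get("sex", "female", "cases"),
                         get("sex", "male", "cases"),
                         get("sex", "female", "controls"),
                         get("sex", "male", "controls"))
  expect_equal(r2(or_f[["or"]]), 1.93)
  # age 19-64 and >=65 vs <=18
  or_mid <- odds_ratio_2x2(get("age", "19-64", "cases"),
                           get("age", "le18", "cases"),
                           get("age", "19-64", "controls"),
                           get("age", "le18", "controls"))
  expect_equal(r2(or_mid[["or"]]), 0.77)
  or_old <- odds_ratio_2x2(get("age", "ge65", "cases"),
                           get("age", "le18", "cases"),
                           get("age", "ge65", "controls"),
                           get("age", "le18", "controls"))
  expect_equal(r2(or_old[["or"]]), 1.02)
})

test_that("a symmetric table gives OR 1 with a symmetric interval", {
  or <- odds_ratio_2x2(5, 5, 5, 5)
  expect_equal(or[["or"]], 1)
  expect_equal(or[["low"]] * or[["high"]], 1, tolerance = 1e-12)
  expect_true(all(is.na(odds_ratio_2x2(0, 5, 5, 5)[c("or", "low")])))
})

test_that("single-covariate logistic OR equals the closed-form 2x2 OR", {
  cells <- c(n11 = 60, n10 = 45, n01 = 3377, n00 = 4900)
  rows <- data.frame(
    outcome = rep(c(1, 1, 0, 0), cells),
    x = rep(c(1, 0, 1, 0), cells))
  fit <- fit_logistic(outcome ~ x, rows)
  closed <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
  i <- fit$coef_table$term == "x"
  expect_lt(abs(fit$coef_table$or[i] - closed[["or"]]), 1e-6)
  # Wald SEs agree too: the identity extends to the intervals
  expect_lt(abs(fit$coef_table$se[i] - closed[["se_log"]]), 1e-6)
})

test_that("the intercept-only model recovers event prevalence", {
  rows <- data.frame(outcome = rep(c(1, 0), c(30, 170)))
  fit <- fit_logistic(outcome ~ 1, rows)
  p <- plogis(coef(fit)[[1]])
  expect_equal(p, 0.15, tolerance = 1e-8)
})

test_that("coefficients are recovered within 3 SE on simulated rows", {
  set.seed(2026)
  n <- 20000
  beta <- c(`(Intercept)` = -2.2, female = 0.7, age19_64 = 0.2,
            age65 = -0.3)
  female <- rbinom(n, 1, 0.45)
  age <- sample(c("le18", "19-64", "ge65"), n, TRUE, c(0.1, 0.55, 0.35))
  eta <- beta[1] + beta[2] * female + beta[3] * (age == "19-64") +
    beta[4] * (age == "ge65")
  rows <- data.frame(outcome = rbinom(n, 1, plogis(eta)),
                     female = female,
                     age19_64 = as.integer(age == "19-64"),
                     age65 = as.integer(age == "ge65"))
  fit <- fit_logistic(outcome ~ female + age19_64 + age65, rows)
  expect_true(fit$converged)
  tab <- fit$coef_table
  for (i in seq_along(beta))
    expect_lt(abs(tab$estimate[i] - beta[i]), 3 * tab$se[i],
              label = names(beta)[i])
})

test_that("separation and degenerate outcomes are reported, not silent", {
  rows <- data.frame(outcome = c(rep(1, 20), rep(0, 20)),
                     x = c(rep(1, 20), rep(0, 20)))
  fit <- suppressWarnings(fit_logistic(outcome ~ x, rows))
  expect_true(fit$separation)
  suppressWarnings(
    expect_error(fit_logistic(outcome ~ x,
                              data.frame(outcome = rep(1, 10),
                                         x = rnorm(10))),
                 "events and non-events"))
})

test_that("Hosmer-Lemeshow is zero for a perfectly calibrated grouping", {
  # groups engineered so that O = E exactly with constant within-group risk
  qs <- seq(0.1, 0.9, by = 0.1)
  p <- rep(qs, each = 100)
  y <- unlist(lapply(qs, function(q) rep(c(1, 0), round(c(q, 1 - q) * 100))))
  fake <- list(fitted.values = p, y = y)
  class(fake) <- "glm"
  hl <- hosmer_lemeshow(fake)
  expect_lt(hl$statistic, 1e-9)
  expect_equal(hl$df, nrow(hl$groups) - 2)
})

test_that("Hosmer-Lemeshow detects gross misspecification", {
  set.seed(77)
  n <- 2000
  reject <- logical(50)
  for (i in seq_len(50)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 2.5 * x^2))   # quadratic truth
    fit <- fit_logistic(y ~ x, data.frame(y = y, x = x))  # linear fit
    reject[i] <- hosmer_lemeshow(fit)$p.value < 0.05
  }
  expect_gt(mean(reject), 0.9)
})

test_that("too few distinct fitted values is an error", {
  fake <- list(fitted.values = rep(c(0.2, 0.8), 50),
               y = rbinom(100, 1, 0.5))
  class(fake) <- "glm"
  expect_error(hosmer_lemeshow(fake), "distinct fitted values")
})

test_that("the risk-factor table assembles counts, univariate and adjusted ORs", {
  set.seed(303)
  n <- 4000
  sex <- sample(c("M", "F"), n, TRUE)
  agegrp <- sample(c("<=18", "19-64", ">=65"), n, TRUE, c(0.1, 0.5, 0.4))
  eta <- -3 + 0.7 * (sex == "F")
  rows <- data.frame(outcome = rbinom(n, 1, plogis(eta)), sex = sex,
                     age_group = agegrp)
  rows$sex[1:5] <- NA  # dropped and counted
  rf <- risk_factor_table(rows)
  expect_equal(rf$n_dropped, 5)
  expect_equal(nrow(rf$table), 3)
  expect_equal(sum(rf$table$cases[1], rf$table$controls[1]),
               sum(rows$sex == "F", na.rm = TRUE))
  # univariate female OR close to exp(0.7), multivariate agrees broadly
  expect_equal(log(rf$table$or_uni[1]), 0.7, tolerance = 0.35)
  expect_s3_class(rf$hl, "hl_test")
})
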