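r2 <- function(x) round_half_up(x, 2)

test_that("indices reproduce published reference rows at 2 dp", {
  # piperacillin/tazobactam x hypokalemia vs all other drugs
  f <- dispro(113, 36094, 77255, 64492942)
  expect_equal(r2(f$prr), 2.61)
  expect_equal(r2(f$ror), 2.61)
  expect_equal(r2(f$ror_ci[["low"]]), 2.17)
  expect_equal(r2(f$ror_ci[["high"]]), 3.14)
  expect_equal(r2(f$chi2), 110.45)
  expect_true(all(f$flags))
  # nafcillin x hypokalemia within the penicillin universe
  g <- dispro(24, 1299, 407, 202673)
  expect_equal(r2(g$prr), 9.05)
  expect_equal(r2(g$ror), 9.20)
  expect_equal(r2(g$chi2), 155.08)
})

test_that("zero cells give undefined markers, never errors", {
  expect_true(is.na(prr(c(5, 10, 0, 100))))       # c = 0
  r <- ror_with_ci(c(0, 10, 5, 100))              # a = 0
  expect_true(all(is.na(r)))
  expect_true(is.na(yates_chi2(c(0, 0, 5, 100)))) # zero row margin
  ic <- ic_bcpnn(c(0, 10, 5, 100))                # priors regularize a = 0
  expect_false(anyNA(ic))
  f <- dispro(0, 10, 5, 100)
  expect_false(f$flags[["signal_prr"]])
  expect_false(f$flags[["signal_ror"]])
  expect_true(f$undefined[["ror"]])
})

test_that("degenerate and symmetric tables behave as closed forms say", {
  # equal reporting rates: a/(a+b) == c/(c+d)
  expect_equal(prr(c(10, 90, 100, 900)), 1.0)
  # balanced table: ROR 1, interval straddles 1
  r <- ror_with_ci(c(10, 10, 10, 10))
  expect_equal(r[["ror"]], 1.0)
  expect_lt(r[["low"]], 1); expect_gt(r[["high"]], 1)
  expect_equal(r[["ror"]] / r[["low"]], r[["high"]] / r[["ror"]],
               tolerance = 1e-12)  # multiplicative symmetry
  # perfectly proportional: |ad - bc| = 0 so the Yates statistic clamps
  expect_equal(yates_chi2(c(1, 9, 10, 90)), 0)
})

test_that("Yates chi-square matches the cell-wise oracle on random tables", {
  set.seed(42)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(c(3, 10, 40), 1)) + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    O <- matrix(cells, 2, 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    oracle <- sum(pmax(0, abs(O - E) - 0.5)^2 / E)
    expect_lt(abs(yates_chi2(t) - oracle), 1e-9)
  }
})

test_that("Yates chi-square agrees with stats::chisq.test when uncorrected", {
  for (cells in list(c(12, 88, 30, 400), c(5, 5, 9, 3), c(40, 7, 12, 61))) {
    m <- matrix(cells, 2, 2, byrow = TRUE)
    expect_equal(yates_chi2(cells),
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("ROR/PRR satisfy their exact algebraic relation", {
  set.seed(7)
  for (i in 1:200) {
    cl <- rpois(4, 20) + 1
    t <- contingency_table(cl[1], cl[2], cl[3], cl[4])
    lhs <- ror_with_ci(t)[["ror"]] / prr(t)
    rhs <- ((cl[1] + cl[2]) / cl[2]) / ((cl[3] + cl[4]) / cl[4])
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("E(IC) is monotone in the observed pair count", {
  set.seed(11)
  for (i in 1:100) {
    cl <- rpois(4, 30) + 1
    e1 <- ic_bcpnn(c(cl[1], cl[2], cl[3], cl[4]))[["eic"]]
    e2 <- ic_bcpnn(c(cl[1] + 1, cl[2], cl[3], cl[4]))[["eic"]]
    expect_gte(e2, e1 - 1e-12)
  }
})

test_that("E(IC) vanishes in the exact-independence limit", {
  # a = cx * cy / N with N = 1e8 and balanced 1e4 margins
  ic <- ic_bcpnn(c(1, 9999, 9999, 1e8 - 1 - 2 * 9999))
  expect_lt(abs(ic[["eic"]]), 0.01)
  expect_lt(ic[["ic025"]], ic[["eic"]])
})

test_that("signal criteria apply their frequency and threshold rules", {
  # a = 2: PRR/ROR flags blocked regardless of effect size
  f <- evaluate_signals(a = 2, prr = 50, ror = 50, ror_low = 10,
                        chi2 = 100, ic025 = -1)
  expect_false(f[["signal_prr"]]); expect_false(f[["signal_ror"]])
  # inclusive boundaries: a = 3, PRR = 2, chi2 = 4
  f <- evaluate_signals(3, 2, 2, 1.01, 4, 0.001)
  expect_true(all(f))
  # undefined statistics never signal
  f <- evaluate_signals(10, NA, NA, NA, NA, NA)
  expect_false(any(f))
  # signal_any is the disjunction
  f <- evaluate_signals(10, 1, 1, 0.5, 1, 0.2)
  expect_true(f[["signal_ic"]]); expect_true(f[["signal_any"]])
})

test_that("reference screens flag the published signal patterns", {
  t2 <- dispro_screen_cells(reference_screen("tzp_vs_all"))
  expect_equal(sum(t2$signal_any), 1)
  expect_equal(t2$event[t2$signal_any], "hypokalemia")
  expect_true(all(t2[t2$event == "hypokalemia",
                     c("signal_prr", "signal_ror", "signal_ic")] == TRUE))

  t3 <- dispro_screen_cells(reference_screen("within_pcn"))
  expect_setequal(t3$drug[t3$signal_any],
                  c("piperacillin/tazobactam", "ampicillin",
                    "flucloxacillin", "cloxacillin", "nafcillin"))
})

test_that("empty inputs yield empty screens", {
  expect_equal(nrow(dispro_screen(data.frame(), character(0), list())), 0)
  expect_equal(nrow(dispro_screen_cells(
    data.frame(a = integer(0), b = integer(0), c = integer(0),
               d = integer(0)))), 0)
})

test_that("contingency table construction validates its cells", {
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_table(1.5, 2, 3, 4), "whole")
  t <- contingency_table(1, 2, 3, 4)
  expect_equal(t$N, 10); expect_equal(t$cx, 3); expect_equal(t$cy, 4)
})
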