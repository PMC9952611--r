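# Disproportionality indices on a 2x2 drug-event contingency table.
#
# All arithmetic is carried at full double precision; rounding
# half-away-from-zero to 2 decimals happens only in print/format methods
# and exported report tables.

#' Proportional reporting ratio
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\]: the target event's share of the target
#' drug's pairs relative to its share among comparator pairs.
#'
#' Returns `NA` (an undefined-statistic marker, never an error) when the
#' comparator event count `c` is zero or either row margin is empty.
#'
#' @param t a `contingency_table` (or numeric vector of 4 cells).
#' @return the PRR at full precision, or `NA_real_` when undefined.
#' @export
prr <- function(t) {
  t <- as_contingency(t)
  if (t$a + t$b == 0 || t$c + t$d == 0 || t$c == 0) return(NA_real_)
  (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = (a/b)/(c/d). The interval is computed on the log scale with
#' standard error sqrt(1/a + 1/b + 1/c + 1/d) and is therefore
#' multiplicatively symmetric about the point estimate.
#'
#' Any zero among `a`, `b`, `c`, `d` makes the estimate or its interval
#' undefined; all three components are then returned as `NA` (no
#' continuity correction is applied -- the frequency >= 3 signal rule makes
#' zero-cell corrections moot).
#'
#' @param t a `contingency_table` (or numeric vector of 4 cells).
#' @param z normal quantile for the interval; 1.96 gives two-sided 95%.
#' @return named numeric vector `c(ror, low, high)`.
#' @export
ror_with_ci <- function(t, z = 1.96) {
  t <- as_contingency(t)
  if (t$a == 0 || t$b == 0 || t$c == 0 || t$d == 0)
    return(c(ror = NA_real_, low = NA_real_, high = NA_real_))
  est <- (t$a / t$b) / (t$c / t$d)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  c(ror = est, low = exp(log(est) - z * se), high = exp(log(est) + z * se))
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' chi2 = N * (max(0, |ad - bc| - N/2))^2 / \[(a+b)(c+d)(a+c)(b+d)\],
#' clamped at zero when the continuity correction overshoots the
#' cross-product difference. Undefined (`NA`) when any margin is zero.
#'
#' @param t a `contingency_table` (or numeric vector of 4 cells).
#' @return non-negative chi-square value, or `NA_real_`.
#' @export
yates_chi2 <- function(t) {
  t <- as_contingency(t)
  m <- c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d)
  if (any(m == 0)) return(NA_real_)
  num <- max(0, abs(t$a * t$d - t$b * t$c) - t$N / 2)
  t$N * num^2 / prod(m)
}

#' BCPNN information component (closed-form posterior)
#'
#' The information component IC = log2 of the observed-to-expected joint
#' reporting probability under a Bayesian shrinkage posterior with
#' Beta(1, 1) marginal priors and a dependence-balancing constant
#' gamma = (N+2)^2 / ((cx+1)(cy+1)) chosen so that E(IC) = 0 under exact
#' independence. The posterior expectation and variance are
#'
#'   E(IC) = log2\[ (a+1)(N+2)^2 / ((N+gamma)(cx+1)(cy+1)) \]
#'   V(IC) = (1/ln 2)^2 \[ (N-a+gamma-1)/((a+1)(1+N+gamma))
#'            + (N-cx+1)/((cx+1)(3+N)) + (N-cy+1)/((cy+1)(3+N)) \]
#'
#' and the lower credibility bound is IC025 = E(IC) - z sqrt(V(IC)).
#' The priors regularize the posterior, so the IC is defined even when
#' `a = 0`.
#'
#' @param t a `contingency_table` (or numeric vector of 4 cells).
#' @param z normal quantile; 1.96 gives the 95% lower bound.
#' @return named numeric vector `c(eic, vic, ic025, gamma)` (bits).
#' @export
ic_bcpnn <- function(t, z = 1.96) {
  t <- as_contingency(t)
  if (t$N <= 0) stop_pv("information component requires N > 0")
  a <- t$a; N <- t$N; cx <- t$cx; cy <- t$cy
  gamma <- (N + 2)^2 / ((cx + 1) * (cy + 1))
  eic <- log2((a + 1) * (N + 2)^2 / ((N + gamma) * (cx + 1) * (cy + 1)))
  vic <- (1 / log(2))^2 *
    ((N - a + gamma - 1) / ((a + 1) * (1 + N + gamma)) +
     (N - cx + 1) / ((cx + 1) * (3 + N)) +
     (N - cy + 1) / ((cy + 1) * (3 + N)))
  c(eic = eic, vic = vic, ic025 = eic - z * sqrt(vic), gamma = gamma)
}

#' Evaluate the three signal criteria
#'
#' * PRR signal: a >= 3, PRR >= 2, and Yates chi-square >= 4.
#' * ROR signal: a >= 3, ROR >= 2, chi-square >= 4, and the lower 95%
#'   confidence limit above 1.
#' * IC signal: the lower 95% credibility bound IC025 above 0.
#'
#' An undefined statistic (`NA`) never raises a signal: its flag is
#' `FALSE`. `signal_any` is the disjunction of the three.
#'
#' @param a cell-a count (target drug with target event).
#' @param prr,ror,ror_low,chi2,ic025 the computed statistics (may be `NA`).
#' @return named logical vector
#'   `c(signal_prr, signal_ror, signal_ic, signal_any)`.
#' @export
evaluate_signals <- function(a, prr, ror, ror_low, chi2, ic025) {
  def <- function(x) !is.na(x)
  s_prr <- def(prr) && def(chi2) && a >= 3 && prr >= 2 && chi2 >= 4
  s_ror <- def(ror) && def(ror_low) && def(chi2) &&
    a >= 3 && ror >= 2 && chi2 >= 4 && ror_low > 1
  s_ic <- def(ic025) && ic025 > 0
  c(signal_prr = s_prr, signal_ror = s_ror, signal_ic = s_ic,
    signal_any = s_prr || s_ror || s_ic)
}

#' Fit all disproportionality indices to a 2x2 table
#'
#' The workhorse estimator: computes PRR, ROR with its Wald 95% interval,
#' the Yates-corrected chi-square, and the BCPNN information component
#' with its 95% lower credibility bound, then applies the three signal
#' criteria (see [evaluate_signals()]).
#'
#' @param a a `contingency_table`, a numeric vector of 4 cells, or the
#'   cell-a count when `b`, `c`, `d` are supplied.
#' @param b,c,d remaining cells when `a` is a single count.
#' @param z normal quantile for all intervals (default 1.96, 95%).
#' @return an object of class `dispro`: the table, full-precision
#'   statistics, signal flags, and undefined-statistic markers.
#' @examples
#' fit <- dispro(113, 36094, 77255, 64492942)
#' fit
#' summary(fit)
#' @seealso [dispro_screen()] to scan many drug-event combinations.
#' @export
dispro <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96) {
  t <- if (is.null(b)) as_contingency(a) else contingency_table(a, b, c, d)
  p <- prr(t)
  r <- ror_with_ci(t, z)
  x2 <- yates_chi2(t)
  ic <- ic_bcpnn(t, z)
  flags <- evaluate_signals(t$a, p, r[["ror"]], r[["low"]], x2, ic[["ic025"]])
  structure(
    list(table = t, prr = p,
         ror = r[["ror"]], ror_ci = c(low = r[["low"]], high = r[["high"]]),
         chi2 = x2,
         eic = ic[["eic"]], vic = ic[["vic"]], ic025 = ic[["ic025"]],
         gamma = ic[["gamma"]], z = z, flags = flags,
         undefined = c(prr = is.na(p), ror = is.na(r[["ror"]]),
                       chi2 = is.na(x2))),
    class = "dispro")
}

fmt2 <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", round_half_up(x, 2)))

#' @export
print.dispro <- function(x, ...) {
  t <- x$table
  cat("Disproportionality analysis (pair counts a=", t$a, ", b=", t$b,
      ", c=", t$c, ", d=", t$d, ")\n", sep = "")
  cat("  PRR  ", fmt2(x$prr), "\n", sep = "")
  cat("  ROR  ", fmt2(x$ror), " (", fmt2(x$ror_ci[["low"]]), "-",
      fmt2(x$ror_ci[["high"]]), ")\n", sep = "")
  cat("  chi2 (Yates) ", fmt2(x$chi2), "\n", sep = "")
  cat("  IC025 ", fmt2(x$ic025), " bits\n", sep = "")
  sig <- names(x$flags)[x$flags][names(x$flags)[x$flags] != "signal_any"]
  cat("  signal: ", if (x$flags[["signal_any"]])
    paste(sub("signal_", "", sig), collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' @export
summary.dispro <- function(object, ...) {
  t <- object$table
  df <- data.frame(
    a = t$a, b = t$b, c = t$c, d = t$d,
    prr = object$prr, ror = object$ror,
    ror_low = object$ror_ci[["low"]], ror_high = object$ror_ci[["high"]],
    chi2 = object$chi2, eic = object$eic, ic025 = object$ic025,
    signal_prr = object$flags[["signal_prr"]],
    signal_ror = object$flags[["signal_ror"]],
    signal_ic = object$flags[["signal_ic"]],
    signal_any = object$flags[["signal_any"]],
    row.names = NULL)
  class(df) <- c("summary.dispro", "data.frame")
  df
}

#' @export
as.data.frame.dispro <- function(x, ...) {
  df <- summary(x)
  class(df) <- "data.frame"
  df
}

#' @export
confint.dispro <- function(object, parm = "ror", level = 0.95, ...) {
  if (!identical(parm, "ror"))
    stop_pv("only the ROR interval is available")
  if (abs(level - (2 * stats::pnorm(object$z) - 1)) > 1e-6)
    stop_pv("interval level is fixed by the z supplied to dispro()")
  matrix(object$ror_ci, 1, 2,
         dimnames = list("ror", c("low", "high")))
}
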