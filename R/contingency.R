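#' 2x2 contingency table for disproportionality analysis
#'
#' Constructs the exposure-by-event table underlying every
#' disproportionality index. Cell `a` counts drug-event pairs with the
#' target drug and the target event, `b` the target drug with all other
#' events, `c` comparator drugs with the target event, and `d` comparator
#' drugs with all other events.
#'
#' @param a,b,c,d non-negative integer pair counts.
#' @return an object of class `contingency_table`: a list with the four
#'   cells, the total `N = a + b + c + d`, the drug margin
#'   `cx = a + b`, and the event margin `cy = a + c`.
#' @examples
#' contingency_table(113, 36094, 77255, 64492942)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4 || anyNA(cells) || !is.numeric(cells))
    stop_pv("all four cells must be single non-negative numbers")
  if (any(cells < 0))
    stop_pv("contingency cells must be non-negative")
  if (any(abs(cells - round(cells)) > 1e-8))
    stop_pv("contingency cells must be whole counts")
  cells <- round(cells)
  structure(
    list(a = cells[["a"]], b = cells[["b"]], c = cells[["c"]], d = cells[["d"]],
         N = sum(cells), cx = cells[["a"]] + cells[["b"]],
         cy = cells[["a"]] + cells[["c"]]),
    class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "comparators"),
                              c("target event", "other events")))
  cat("2x2 drug-event contingency table (N =", format(x$N, big.mark = ","), ")\n")
  print(m)
  invisible(x)
}

as_contingency <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.numeric(x) && length(x) == 4)
    return(contingency_table(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop_pv("expected a contingency_table or a numeric vector of 4 cells")
}
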