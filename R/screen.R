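# Screening many drug-event combinations into a signal table.

screen_row <- function(drug, event, fit) {
  s <- as.data.frame(fit)
  cbind(data.frame(drug = drug, event = event, stringsAsFactors = FALSE), s)
}

#' Screen drug-event combinations for disproportionality signals
#'
#' For every combination of a target drug and an event query, builds the
#' 2x2 contingency table from the pair list under the chosen comparator
#' universe and fits all disproportionality indices. Row order is
#' deterministic: drugs in the order given, then events in the order
#' given.
#'
#' @param pairs a drug-event pair data frame from [build_pairs()].
#' @param targets character vector of standardized drug names to screen.
#' @param events a named list of event queries: each element a character
#'   vector of normalized MedDRA preferred terms, named by the disorder
#'   (see [event_queries()]).
#' @param comparator `"all_other_drugs"` or `"drug_list"`.
#' @param drug_list comparator drug names when `comparator = "drug_list"`
#'   (the universe is restricted to these drugs; each screened target must
#'   be among them).
#' @param z normal quantile for intervals.
#' @return a `dispro_screen` data frame: one row per (drug, event) with
#'   cells, statistics at full precision, and the four signal flags.
#' @export
dispro_screen <- function(pairs, targets, events,
                          comparator = c("all_other_drugs", "drug_list"),
                          drug_list = NULL, z = 1.96) {
  comparator <- match.arg(comparator)
  if (length(events) == 0) return(empty_screen())
  if (is.character(events)) events <- list(event = events)
  rows <- vector("list", length(targets) * length(events))
  k <- 0
  for (drug in targets) for (ev in names(events)) {
    k <- k + 1
    t <- build_contingency(pairs, drug, events[[ev]],
                           comparator = comparator, drug_list = drug_list)
    rows[[k]] <- screen_row(drug, ev, dispro(t, z = z))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dispro_screen", "data.frame")
  out
}

#' Screen precomputed 2x2 cell counts
#'
#' Fixtures-mode screening: accepts raw (a, b, c, d) quadruples -- for
#' example the cells of a published signal table -- bypassing the
#' report-level ETL entirely.
#'
#' @param cells a data frame with columns `a`, `b`, `c`, `d` and optional
#'   label columns `drug` and/or `event`.
#' @param z normal quantile for intervals.
#' @return a `dispro_screen` data frame, one row per input row.
#' @export
dispro_screen_cells <- function(cells, z = 1.96) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(cells)))
  if (nrow(cells) == 0) return(empty_screen())
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    fit <- dispro(cells$a[i], cells$b[i], cells$c[i], cells$d[i], z = z)
    screen_row(cells$drug[i] %||% NA_character_,
               if ("event" %in% names(cells)) cells$event[i] else NA_character_,
               fit)
  })
  out <- do.call(rbind, rows)
  if (!"event" %in% names(cells)) out$event <- NULL
  if (!"drug" %in% names(cells)) out$drug <- NULL
  rownames(out) <- NULL
  class(out) <- c("dispro_screen", "data.frame")
  out
}

empty_screen <- function() {
  out <- data.frame(drug = character(), event = character(),
                    a = integer(), b = integer(), c = integer(), d = integer(),
                    prr = numeric(), ror = numeric(), ror_low = numeric(),
                    ror_high = numeric(), chi2 = numeric(), eic = numeric(),
                    ic025 = numeric(), signal_prr = logical(),
                    signal_ror = logical(), signal_ic = logical(),
                    signal_any = logical(), stringsAsFactors = FALSE)
  class(out) <- c("dispro_screen", "data.frame")
  out
}

#' @export
print.dispro_screen <- function(x, digits = 2, ...) {
  if (nrow(x) == 0) {
    cat("dispro_screen: 0 combinations\n")
    return(invisible(x))
  }
  show <- as.data.frame(x)
  for (col in c("prr", "ror", "ror_low", "ror_high", "chi2", "eic", "ic025"))
    if (col %in% names(show)) show[[col]] <- fmt2(show[[col]])
  for (col in c("signal_prr", "signal_ror", "signal_ic", "signal_any"))
    show[[col]] <- ifelse(show[[col]], "*", "")
  show$eic <- NULL
  cat("Disproportionality screen (", nrow(x), " drug-event combinations, ",
      sum(x$signal_any), " signal", if (sum(x$signal_any) != 1) "s", ")\n",
      sep = "")
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write a signal table as TSV
#'
#' Columns mirror a standard published signal table: labels, the four
#' cells, PRR, ROR and its interval, IC025, chi-square, and the signal
#' flags. Statistics are rounded half-away-from-zero to `digits`
#' decimals; cells are written exactly.
#'
#' @param x a `dispro_screen`.
#' @param path output file path.
#' @param digits display rounding for statistics.
#' @return the path, invisibly.
#' @export
write_screen_tsv <- function(x, path, digits = 2) {
  out <- as.data.frame(x)
  for (col in c("prr", "ror", "ror_low", "ror_high", "chi2", "eic", "ic025"))
    if (col %in% names(out)) out[[col]] <- round_half_up(out[[col]], digits)
  write_tsv(out, path)
}
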