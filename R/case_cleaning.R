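# The exclusion cascade applied before any disproportionality counting:
# keep the latest version of each case, drop deletion-listed cases, drop
# reports missing a drug name or reaction row, drop concomitant drug rows.

#' Select the latest version of each case
#'
#' A case may be reported several times (an initial version plus
#' follow-ups). For each case id the record with the greatest
#' (quarter, report id) wins; the quarter label compares
#' lexicographically and ties within a quarter break by larger numeric
#' report id (FAERS ids increase over time). All superseded versions are
#' tallied.
#'
#' @param demo harmonized demo records (from [parse_quarter()]).
#' @return list with `report_ids` (retained, one per case) and
#'   `n_superseded`.
#' @export
select_latest_version <- function(demo) {
  if (nrow(demo) == 0)
    return(list(report_ids = character(0), n_superseded = 0L))
  id_num <- suppressWarnings(as.numeric(demo$report_id))
  id_key <- ifelse(is.na(id_num), -Inf, id_num)
  o <- order(demo$case_id, demo$quarter, id_key)
  d <- demo[o, ]
  last <- !duplicated(d$case_id, fromLast = TRUE)
  list(report_ids = d$report_id[last],
       n_superseded = sum(!last))
}

#' Apply the report-level exclusion cascade
#'
#' Given parsed records restricted to the latest case versions, removes
#' (in order): cases on the deletion list (ids the database provider has
#' flagged as erroneous), reports with no valid reaction row, reports
#' with no usable drug row (every drug blank-named or concomitant), and
#' finally concomitant drug rows from surviving reports. Interacting
#' drugs are retained. Every input report is either retained or counted
#' under exactly one exclusion reason.
#'
#' @param data a `faers_data` object.
#' @param keep report ids retained by [select_latest_version()].
#' @param n_superseded count of superseded versions (for the tally).
#' @param deletion_list character vector of case ids to drop, or `NULL`.
#' @return a `clean_reports` object: `demo` (one row per case, ages
#'   standardized, age groups assigned), `drug` (suspect/interacting rows
#'   only), `reac`, `outc`, and `tally` (named integer exclusion counts).
#' @export
apply_exclusions <- function(data, keep, n_superseded = 0L,
                             deletion_list = NULL) {
  demo <- data$demo[data$demo$report_id %in% keep, , drop = FALSE]
  n_in <- nrow(demo)
  excl <- c(superseded = as.integer(n_superseded), deletion_listed = 0L,
            missing_reaction = 0L, missing_drug = 0L, concomitant_only = 0L)

  if (length(deletion_list)) {
    del <- demo$case_id %in% deletion_list
    excl[["deletion_listed"]] <- sum(del)
    demo <- demo[!del, , drop = FALSE]
  }

  drug <- data$drug[data$drug$report_id %in% demo$report_id, , drop = FALSE]
  reac <- data$reac[data$reac$report_id %in% demo$report_id, , drop = FALSE]
  reac <- reac[nzchar(normalize_term(reac$pt)), , drop = FALSE]

  has_reac <- demo$report_id %in% reac$report_id
  excl[["missing_reaction"]] <- sum(!has_reac)
  demo <- demo[has_reac, , drop = FALSE]

  drug <- drug[drug$report_id %in% demo$report_id, , drop = FALSE]
  named <- nzchar(normalize_term(drug$drugname))
  usable <- named & drug$role_cod != "C"
  has_any_drug <- demo$report_id %in% drug$report_id[named]
  has_usable <- demo$report_id %in% drug$report_id[usable]
  excl[["missing_drug"]] <- sum(!has_any_drug)
  excl[["concomitant_only"]] <- sum(has_any_drug & !has_usable)
  demo <- demo[has_usable, , drop = FALSE]

  drug <- drug[usable & drug$report_id %in% demo$report_id, , drop = FALSE]
  reac <- reac[reac$report_id %in% demo$report_id, , drop = FALSE]
  outc <- data$outc[data$outc$report_id %in% demo$report_id, , drop = FALSE]

  demo$age_years <- as.numeric(standardize_age(demo$age_value, demo$age_unit))
  demo$age_group <- age_group(demo$age_years)
  rownames(demo) <- rownames(drug) <- rownames(reac) <- rownames(outc) <- NULL
  tally <- c(retained = nrow(demo), excl)
  stopifnot(n_in + excl[["superseded"]] ==
              nrow(demo) + sum(excl))
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 tally = tally),
            class = "clean_reports")
}

#' Clean parsed reports end to end
#'
#' Convenience wrapper: [select_latest_version()] then
#' [apply_exclusions()]. Cleaning is idempotent -- cleaning an
#' already-clean set changes nothing.
#'
#' @param data a `faers_data` object from [parse_quarter()].
#' @param deletion_list optional character vector of case ids, or a path
#'   to a plain-text file with one case id per line.
#' @return a `clean_reports` object.
#' @export
clean_cases <- function(data, deletion_list = NULL) {
  stopifnot(inherits(data, "faers_data") || inherits(data, "clean_reports"))
  if (is.character(deletion_list) && length(deletion_list) == 1 &&
      file.exists(deletion_list))
    deletion_list <- trimws(readLines(deletion_list, warn = FALSE))
  sel <- select_latest_version(data$demo)
  apply_exclusions(data, sel$report_ids, sel$n_superseded, deletion_list)
}

#' @export
print.clean_reports <- function(x, ...) {
  cat("clean_reports:", nrow(x$demo), "reports,", nrow(x$drug),
      "suspect/interacting drug rows,", nrow(x$reac), "reaction rows\n")
  cat("exclusions:",
      paste(names(x$tally[-1]), x$tally[-1], sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write the exclusion tally as TSV
#'
#' @param clean a `clean_reports` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_exclusion_tally <- function(clean, path) {
  write_tsv(data.frame(reason = names(clean$tally),
                       n = as.integer(clean$tally)), path)
}
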