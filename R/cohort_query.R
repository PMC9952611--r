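# Drug name standardization, event query expansion, drug-event pairs and
# contingency-table construction.

#' Load a drug dictionary
#'
#' A drug dictionary maps normalized verbatim drug-name synonyms (generic
#' names, brand names, salt forms) to a standardized drug name, with an
#' ATC-class tag per drug. The packaged default covers the twelve
#' penicillin-class drugs of the bundled reference screen; it is a plain
#' YAML file users can copy and edit.
#'
#' @param path YAML file; defaults to the packaged penicillin dictionary.
#' @return object of class `drug_dictionary`: list with `synonyms` (named
#'   character vector: normalized synonym -> standardized name), `drugs`
#'   (standardized names) and `atc_class` (named by drug).
#' @export
drug_dictionary <- function(path = system.file("extdata",
                                               "penicillin_dictionary.yaml",
                                               package = "pvsignal")) {
  raw <- yaml::read_yaml(path)
  drugs <- names(raw)
  syn <- character(0)
  atc <- character(0)
  for (d in drugs) {
    s <- unique(normalize_term(c(d, raw[[d]]$synonyms)))
    if (any(s %in% names(syn)))
      stop_pv("synonym sets must be disjoint across drugs: ",
              paste(intersect(s, names(syn)), collapse = ", "))
    syn[s] <- d
    atc[d] <- raw[[d]]$atc_class %||% NA_character_
  }
  structure(list(synonyms = syn, drugs = drugs, atc_class = atc),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("drug_dictionary:", length(x$drugs), "standardized drugs,",
      length(x$synonyms), "synonyms\n")
  invisible(x)
}

# Strip trailing dosage tokens ("4.5 g", "500mg", "2 x 250 mg tablets")
# from an already-normalized name.
strip_dosage <- function(x) {
  tok <- "(?:[0-9][0-9.,/x]*|mg|g|mcg|ug|ml|l|iu|%|units?|tablets?|capsules?|injection|iv|po)"
  gsub(paste0("(?:\\s+", tok, ")+$"), "", x, perl = TRUE)
}

#' Map a verbatim drug name to its standardized drug
#'
#' Exact dictionary lookup after normalization (lowercase, trim, collapse
#' whitespace) and stripping of trailing dosage tokens (numerals and
#' unit/form words such as "4.5 g" or "500 mg tablets"). No substring or
#' fuzzy matching: anything not in the dictionary maps to `"other"`.
#'
#' @param verbatim character vector of verbatim drug names.
#' @param dictionary a [drug_dictionary()].
#' @return character vector of standardized names (or `"other"`).
#' @export
match_drug <- function(verbatim, dictionary) {
  key <- strip_dosage(normalize_term(verbatim))
  std <- unname(dictionary$synonyms[key])
  std[is.na(std)] <- "other"
  std
}

#' Load the electrolyte-disorder event queries
#'
#' Each of the ten electrolyte disorders is queried by exactly two MedDRA
#' preferred terms: the disorder PT itself and the corresponding
#' laboratory PT (e.g. hypokalemia by "hypokalaemia" and "blood potassium
#' decreased"). Each laboratory "increased"/"decreased" PT belongs to
#' exactly one disorder.
#'
#' @param path TSV with columns `disorder` and `pt`; defaults to the
#'   packaged electrolyte set.
#' @return named list: disorder -> character vector of normalized PTs.
#' @export
event_queries <- function(path = system.file("extdata",
                                             "electrolyte_events.tsv",
                                             package = "pvsignal")) {
  df <- read_tsv(path)
  stopifnot(all(c("disorder", "pt") %in% names(df)))
  df$pt <- normalize_term(df$pt)
  if (anyDuplicated(df$pt))
    stop_pv("each preferred term may belong to exactly one disorder")
  split(df$pt, factor(df$disorder, levels = unique(df$disorder)))
}

#' Build drug-event pairs from cleaned reports
#'
#' The unit of disproportionality counting: every combination of a
#' report's retained (suspect or interacting) drugs with its reaction
#' preferred terms, deduplicated within the report. With a dictionary,
#' drug names are standardized via [match_drug()] (non-matches become
#' `"other"`); without one, normalized verbatim names are used as-is.
#'
#' @param clean a `clean_reports` object from [clean_cases()].
#' @param dictionary optional [drug_dictionary()].
#' @return data frame with columns `report_id`, `drug`, `pt`, one row per
#'   distinct pair.
#' @export
build_pairs <- function(clean, dictionary = NULL) {
  stopifnot(inherits(clean, "clean_reports"))
  drug <- clean$drug
  reac <- clean$reac
  dn <- normalize_term(drug$drugname)
  if (!is.null(dictionary)) dn <- match_drug(drug$drugname, dictionary)
  dr <- unique(data.frame(report_id = drug$report_id, drug = dn,
                          stringsAsFactors = FALSE))
  re <- unique(data.frame(report_id = reac$report_id,
                          pt = normalize_term(reac$pt),
                          stringsAsFactors = FALSE))
  pairs <- merge(dr, re, by = "report_id")
  pairs <- pairs[order(pairs$report_id, pairs$drug, pairs$pt), ]
  rownames(pairs) <- NULL
  pairs
}

#' Build a 2x2 contingency table from drug-event pairs
#'
#' Counts pairs, not reports: `a` pairs with the target drug and a PT in
#' the event query, `b` the target drug's remaining pairs, `c` and `d`
#' the same split over the comparator universe. With
#' `comparator = "drug_list"` the universe is first restricted to pairs
#' whose drug is in `drug_list` (which must include the target).
#'
#' @param pairs data frame from [build_pairs()] (columns `drug`, `pt`).
#' @param target_drug standardized target drug name.
#' @param event_pts character vector of normalized PTs defining the event.
#' @param comparator `"all_other_drugs"` or `"drug_list"`.
#' @param drug_list drugs defining the restricted universe.
#' @return a [contingency_table()].
#' @export
build_contingency <- function(pairs, target_drug, event_pts,
                              comparator = c("all_other_drugs", "drug_list"),
                              drug_list = NULL) {
  comparator <- match.arg(comparator)
  event_pts <- normalize_term(event_pts)
  if (comparator == "drug_list") {
    if (is.null(drug_list)) stop_pv("drug_list comparator needs a drug list")
    if (!target_drug %in% drug_list)
      stop_pv("the comparator drug list must include the target drug")
    pairs <- pairs[pairs$drug %in% drug_list, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop_pv("empty comparator universe")
  if (!any(pairs$drug == target_drug))
    stop_pv("target drug '", target_drug, "' absent from the universe")
  tgt <- pairs$drug == target_drug
  ev <- pairs$pt %in% event_pts
  contingency_table(sum(tgt & ev), sum(tgt & !ev),
                    sum(!tgt & ev), sum(!tgt & !ev))
}
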