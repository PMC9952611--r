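# Report-level characteristics summary (demographics, seriousness,
# reporting source) for the reports mentioning a target drug.

# Seriousness precedence when a report carries several outcome codes:
# fatal (DE) > life-threatening (LT) > hospitalization (HO) > other
# (DS/CA/RI/OT). A report with no outcome row is non-serious.
seriousness_of <- function(codes) {
  if (length(codes) == 0) return("non-serious")
  if ("DE" %in% codes) return("fatal")
  if ("LT" %in% codes) return("life-threatening")
  if ("HO" %in% codes) return("hospitalization")
  "other serious"
}

reporter_type <- function(occp) {
  ifelse(is.na(occp) | !nzchar(occp), "Unknown",
         ifelse(occp %in% c("MD", "PH", "HP", "OT"), "Health professional",
                ifelse(occp == "CN", "Consumer", "Other")))
}

#' Summarize the characteristics of a report set
#'
#' Produces the conventional characteristics table for the reports
#' mentioning a target drug: counts and percentages (of the report
#' total, 1 decimal) for age group, sex, seriousness -- serious reports
#' subdivided by the precedence fatal > life-threatening >
#' hospitalization > other -- reporter type, and the most frequent
#' reporter countries.
#'
#' @param clean a `clean_reports` object.
#' @param target_drug optional standardized drug name: restrict to
#'   reports with at least one matching drug row.
#' @param dictionary optional [drug_dictionary()] used to standardize
#'   drug names before matching the target.
#' @param n_countries number of individual countries to list before
#'   pooling into "Other".
#' @return a `characteristics_table` data frame with columns `section`,
#'   `category`, `n`, `pct`.
#' @export
summarize_characteristics <- function(clean, target_drug = NULL,
                                      dictionary = NULL, n_countries = 4) {
  stopifnot(inherits(clean, "clean_reports"))
  demo <- clean$demo
  if (!is.null(target_drug)) {
    dn <- if (is.null(dictionary)) normalize_term(clean$drug$drugname)
          else match_drug(clean$drug$drugname, dictionary)
    ids <- unique(clean$drug$report_id[dn == target_drug])
    demo <- demo[demo$report_id %in% ids, , drop = FALSE]
  }
  n <- nrow(demo)
  pct <- function(k) round_half_up(100 * k / max(n, 1), 1)
  row <- function(section, category, k)
    data.frame(section = section, category = category, n = k, pct = pct(k),
               stringsAsFactors = FALSE)

  ag <- table(demo$age_group)
  out <- do.call(rbind, lapply(names(ag), function(g)
    row("age", g, as.integer(ag[[g]]))))

  sex <- ifelse(is.na(demo$sex), "unknown",
                ifelse(demo$sex == "M", "male", "female"))
  for (s in c("male", "female", "unknown"))
    out <- rbind(out, row("sex", s, sum(sex == s)))

  codes <- split(clean$outc$outc_cod, clean$outc$report_id)
  ser <- vapply(demo$report_id, function(id)
    seriousness_of(codes[[id]] %||% character(0)), character(1))
  out <- rbind(out, row("seriousness", "serious", sum(ser != "non-serious")))
  for (s in c("hospitalization", "fatal", "life-threatening",
              "other serious"))
    out <- rbind(out, row("seriousness", s, sum(ser == s)))
  out <- rbind(out, row("seriousness", "non-serious",
                        sum(ser == "non-serious")))

  rt <- reporter_type(demo$occp_cod)
  for (s in c("Health professional", "Consumer", "Other", "Unknown"))
    out <- rbind(out, row("reporter", s, sum(rt == s)))

  ctry <- ifelse(is.na(demo$country) | !nzchar(demo$country), "Unknown",
                 demo$country)
  known <- sort(table(ctry[ctry != "Unknown"]), decreasing = TRUE)
  top <- names(known)[seq_len(min(n_countries, length(known)))]
  for (s in top) out <- rbind(out, row("country", s, sum(ctry == s)))
  out <- rbind(out,
               row("country", "Other", sum(!ctry %in% c(top, "Unknown"))),
               row("country", "Unknown", sum(ctry == "Unknown")))
  attr(out, "n_reports") <- n
  class(out) <- c("characteristics_table", "data.frame")
  out
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat("Report characteristics (n =", attr(x, "n_reports"), ")\n")
  df <- as.data.frame(x)
  df$pct <- sprintf("%.1f", df$pct)
  print(df, row.names = FALSE)
  invisible(x)
}
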