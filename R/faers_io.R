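# Parsing of FAERS/LAERS quarterly ASCII extracts.
#
# Both dialects are "$"-delimited with a header row. The legacy (LAERS,
# pre-2012Q3) DEMO key fields are "ISR"/"CASE"; the current (FAERS)
# dialect renames them "primaryid"/"caseid" (and "GNDR_COD" became
# "sex"). Parsing is header-name driven and case-insensitive, so extra
# columns are tolerated and dialect differences are invisible downstream.

ROLE_CODES <- c("PS", "SS", "I", "C")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
AGE_UNITS <- c("DEC", "YR", "MON", "WK", "DY", "HR")

# Harmonized field -> acceptable header names (lowercased), per table.
FIELD_MAP <- list(
  demo = list(report_id = c("primaryid", "isr"),
              case_id = c("caseid", "case"),
              age_value = "age", age_unit = "age_cod",
              sex = c("sex", "gndr_cod"), occp_cod = "occp_cod",
              country = "reporter_country", fda_dt = "fda_dt"),
  drug = list(report_id = c("primaryid", "isr"),
              drugname = "drugname", role_cod = "role_cod"),
  reac = list(report_id = c("primaryid", "isr"), pt = "pt"),
  outc = list(report_id = c("primaryid", "isr"),
              outc_cod = c("outc_cod", "outc_code")))

reject_rows <- function(file, lines, reason) {
  data.frame(file = rep(basename(file), length(lines)),
             line = lines,
             reason = rep_len(if (length(reason)) reason else character(0),
                              length(lines)),
             stringsAsFactors = FALSE)
}

detect_dialect <- function(header_lc) {
  if ("primaryid" %in% header_lc) "current"
  else if ("isr" %in% header_lc) "legacy"
  else NA_character_
}

read_faers_file <- function(file, table, dialect = "auto") {
  if (!file.exists(file)) stop_pv("missing file: ", file)
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0) stop_pv("no header row in ", file)
  header <- tolower(strsplit(lines[[1]], "$", fixed = TRUE)[[1]])
  found <- detect_dialect(header)
  if (is.na(found))
    stop_pv("header of ", basename(file), " matches neither dialect")
  if (dialect != "auto" && found != dialect)
    stop_pv(basename(file), " is in the ", found, " dialect, not ", dialect)
  fmap <- FIELD_MAP[[table]]
  idx <- vapply(fmap, function(cands) {
    j <- match(cands, header)
    j <- j[!is.na(j)]
    if (length(j)) j[[1]] else NA_integer_
  }, integer(1))
  if (is.na(idx[["report_id"]]))
    stop_pv(basename(file), ": no report-id column")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  # trailing empty field is dropped by strsplit; accept n or n-1 fields
  ok <- nf == length(header) | nf == length(header) - 1
  rej <- reject_rows(file, which(!ok) + 1L, "malformed_row")
  parts <- parts[ok]
  get <- function(field) {
    j <- idx[[field]]
    if (is.na(j)) return(rep(NA_character_, length(parts)))
    trimws(vapply(parts, function(p) if (j <= length(p)) p[[j]] else "",
                  character(1)))
  }
  df <- as.data.frame(lapply(stats::setNames(names(fmap), names(fmap)), get),
                      stringsAsFactors = FALSE)
  keep_lines <- which(ok) + 1L
  # mandatory-key screening
  bad <- !nzchar(df$report_id)
  reason <- rep(NA_character_, nrow(df))
  reason[bad] <- "missing_report_id"
  if (table == "drug") {
    badrole <- !bad & !(toupper(df$role_cod) %in% ROLE_CODES)
    reason[badrole] <- "invalid_role_code"
    bad <- bad | badrole
  }
  if (table == "reac") {
    badpt <- !bad & !nzchar(normalize_term(df$pt))
    reason[badpt] <- "missing_pt"
    bad <- bad | badpt
  }
  if (table == "outc") {
    badoc <- !bad & !(toupper(df$outc_cod) %in% OUTCOME_CODES)
    reason[badoc] <- "invalid_outcome_code"
    bad <- bad | badoc
  }
  rej <- rbind(rej, reject_rows(file, keep_lines[bad], reason[bad]))
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  list(records = df, rejects = rej, dialect = found)
}

quarter_from_filename <- function(file) {
  m <- regmatches(basename(file),
                  regexpr("[0-9]{2}q[1-4]", tolower(basename(file))))
  if (length(m)) toupper(m) else NA_character_
}

#' Parse a directory of FAERS/LAERS quarterly ASCII files
#'
#' Reads every `DEMOyyQq`, `DRUGyyQq`, `REACyyQq` and `OUTCyyQq` file
#' (case-insensitive, `.txt`) found under `path`, in either schema
#' dialect, and returns harmonized record tables. Rows whose mandatory
#' keys cannot be parsed (missing report id, blank preferred term,
#' unknown role or outcome code, wrong field count) are routed to a
#' rejects table -- never silently dropped and never fatal. Parsed record
#' count plus reject count equals the input data-row count.
#'
#' @param path directory containing the quarterly files.
#' @param dialect `"legacy"`, `"current"`, or `"auto"` (detect from the
#'   header of each file).
#' @return an object of class `faers_data`: list of data frames `demo`,
#'   `drug`, `reac`, `outc` (harmonized columns; `demo` carries the
#'   quarter label from the filename) and `rejects`
#'   (file, line, reason).
#' @export
parse_quarter <- function(path, dialect = c("auto", "legacy", "current")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(path)) stop_pv("no such directory: ", path)
  all_files <- list.files(path, full.names = TRUE)
  out <- list()
  rejects <- list()
  for (table in c("demo", "drug", "reac", "outc")) {
    files <- all_files[grepl(paste0("^", table, "[0-9]{2}q[1-4].*\\.txt$"),
                             tolower(basename(all_files)))]
    if (length(files) == 0)
      stop_pv("no ", toupper(table), " file found in ", path)
    chunks <- lapply(sort(files), function(f) {
      r <- read_faers_file(f, table, dialect)
      r$records$quarter <- rep(quarter_from_filename(f), nrow(r$records))
      r
    })
    out[[table]] <- do.call(rbind, lapply(chunks, `[[`, "records"))
    rejects[[table]] <- do.call(rbind, lapply(chunks, `[[`, "rejects"))
  }
  demo <- out$demo
  demo$age_value <- suppressWarnings(as.numeric(demo$age_value))
  demo$age_unit <- toupper(demo$age_unit)
  demo$age_unit[!demo$age_unit %in% AGE_UNITS] <- NA_character_
  sex <- toupper(demo$sex)
  demo$sex <- ifelse(sex %in% c("M", "F"), sex, NA_character_)
  out$drug$role_cod <- toupper(out$drug$role_cod)
  out$outc$outc_cod <- toupper(out$outc$outc_cod)
  rej <- do.call(rbind, rejects)
  rownames(rej) <- NULL
  structure(list(demo = demo, drug = out$drug, reac = out$reac,
                 outc = out$outc, rejects = rej),
            class = "faers_data")
}

#' @export
print.faers_data <- function(x, ...) {
  cat("faers_data:", nrow(x$demo), "demo,", nrow(x$drug), "drug,",
      nrow(x$reac), "reac,", nrow(x$outc), "outcome records;",
      nrow(x$rejects), "rejected rows\n")
  invisible(x)
}

#' Standardize reported ages to years
#'
#' Converts (value, unit-code) pairs to years using calendar constants:
#' DEC x10, YR x1, MON /12, WK /52.1775, DY /365.25, HR /8766. A missing
#' unit with a value present is treated as years (the dominant FAERS
#' convention). Negative or absurd results (> 150 years) become missing;
#' the count of such anomalies is attached as attribute `n_anomalous`.
#' Total function: never errors on malformed input.
#'
#' @param age_value numeric vector of reported ages.
#' @param age_unit character vector of unit codes
#'   (DEC/YR/MON/WK/DY/HR or `NA`).
#' @return numeric vector of ages in years (`NA` where unknown), with
#'   attribute `n_anomalous`.
#' @export
standardize_age <- function(age_value, age_unit) {
  factor_by_unit <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                      DY = 1 / 365.25, HR = 1 / 8766)
  age_value <- suppressWarnings(as.numeric(age_value))
  unit <- toupper(as.character(age_unit))
  unit[is.na(unit) | !nzchar(unit)] <- "YR"
  f <- factor_by_unit[unit]
  f[is.na(f)] <- NA_real_
  years <- age_value * f
  anomalous <- !is.na(years) & (years < 0 | years > 150)
  years[anomalous] <- NA_real_
  structure(years, n_anomalous = sum(anomalous))
}

#' Assign the standard age groups
#'
#' Ages are floored to whole years before comparison (so 18.9 is still
#' "<=18"); groups are `<=18`, `19-64`, `>=65`, and `unknown` for
#' missing.
#'
#' @param age_years numeric vector of ages in years.
#' @return factor with levels `<=18`, `19-64`, `>=65`, `unknown`.
#' @export
age_group <- function(age_years) {
  y <- floor(as.numeric(age_years))
  g <- ifelse(is.na(y), "unknown",
              ifelse(y <= 18, "<=18", ifelse(y <= 64, "19-64", ">=65")))
  factor(g, levels = c("<=18", "19-64", ">=65", "unknown"))
}
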