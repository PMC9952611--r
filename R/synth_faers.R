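# Synthetic FAERS-dialect quarterly files with a planted drug-event
# association structure, so every downstream stage is testable without
# any real report data.
#
# Sampling model: each report first draws its drugs (without replacement,
# by the catalog's marginal weights), then its events with odds
# multiplied by the maximum, over the report's drugs, of the planted
# relative reporting ratio lambda(drug, event). lambda = 1 everywhere
# means no association. One random stream per run, seeded once.

#' Configuration for the synthetic report generator
#'
#' @param n_reports number of distinct cases to generate.
#' @param drug_catalog named numeric vector: drug name -> marginal
#'   selection weight (normalized internally).
#' @param event_catalog named numeric vector: MedDRA-PT-like event string
#'   -> baseline weight.
#' @param lambda matrix of relative reporting ratios, drugs x events
#'   (dimnames must match the catalogs); `NULL` means no association
#'   (all 1).
#' @param drugs_per_report,events_per_report named probability vectors
#'   over small positive integers ("1", "2", ...): the distribution of
#'   drugs/events per report.
#' @param p_duplicate_version probability a case emits a follow-up
#'   version (same content, higher report id, age perturbed by one
#'   year so "keep latest" is observable).
#' @param p_concomitant probability a drug record is coded concomitant.
#' @param p_missing_age,p_missing_sex missingness probabilities.
#' @param age_unit_mix named probability vector over the reporting units
#'   DEC/YR/MON/WK/DY.
#' @param dialect `"current"` (primaryid/caseid) or `"legacy"`
#'   (ISR/CASE).
#' @param quarter quarter label used in the file names, e.g. `"13Q1"`.
#' @param seed integer seed; output is a pure function of the config.
#' @return validated object of class `synth_config`.
#' @export
synth_config <- function(n_reports = 1000,
                         drug_catalog = c("piperacillin/tazobactam" = 0.10,
                                          "vancomycin" = 0.18,
                                          "ceftriaxone" = 0.15,
                                          "ciprofloxacin" = 0.14,
                                          "amoxicillin" = 0.16,
                                          "nafcillin" = 0.05,
                                          "furosemide" = 0.12,
                                          "metformin" = 0.10),
                         event_catalog = c("hypokalaemia" = 0.05,
                                           "blood potassium decreased" = 0.02,
                                           "hyponatraemia" = 0.04,
                                           "rash" = 0.22,
                                           "nausea" = 0.25,
                                           "diarrhoea" = 0.18,
                                           "pyrexia" = 0.14,
                                           "renal failure" = 0.10),
                         lambda = NULL,
                         drugs_per_report = c("1" = 0.60, "2" = 0.30,
                                              "3" = 0.10),
                         events_per_report = c("1" = 0.55, "2" = 0.30,
                                               "3" = 0.15),
                         p_duplicate_version = 0.05,
                         p_concomitant = 0.15,
                         p_missing_age = 0.10,
                         p_missing_sex = 0.08,
                         age_unit_mix = c(YR = 0.80, DEC = 0.06, MON = 0.06,
                                          WK = 0.03, DY = 0.05),
                         dialect = c("current", "legacy"),
                         quarter = "13Q1",
                         seed = 1L) {
  dialect <- match.arg(dialect)
  chk_prob <- function(p, what) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
      stop_pv(what, " must be a probability in [0, 1]")
  }
  if (length(drug_catalog) == 0 || length(event_catalog) == 0)
    stop_pv("drug and event catalogs must be non-empty")
  if (is.null(names(drug_catalog)) || is.null(names(event_catalog)))
    stop_pv("catalogs must be named weight vectors")
  if (any(drug_catalog <= 0) || any(event_catalog <= 0))
    stop_pv("catalog weights must be positive")
  if (is.null(lambda)) {
    lambda <- matrix(1, length(drug_catalog), length(event_catalog),
                     dimnames = list(names(drug_catalog),
                                     names(event_catalog)))
  }
  if (!identical(rownames(lambda), names(drug_catalog)) ||
      !identical(colnames(lambda), names(event_catalog)))
    stop_pv("lambda dimnames must match the catalogs")
  if (any(lambda < 0)) stop_pv("lambda must be >= 0")
  for (dist in list(drugs_per_report, events_per_report)) {
    k <- suppressWarnings(as.integer(names(dist)))
    if (anyNA(k) || any(k < 1))
      stop_pv("per-report count distributions need integer names >= 1")
    chk_prob(dist, "per-report count distribution")
  }
  if (max(as.integer(names(drugs_per_report))) > length(drug_catalog) ||
      max(as.integer(names(events_per_report))) > length(event_catalog))
    stop_pv("per-report draws cannot exceed the catalog size")
  chk_prob(c(p_duplicate_version, p_concomitant, p_missing_age,
             p_missing_sex), "rate parameter")
  if (!all(names(age_unit_mix) %in% c("DEC", "YR", "MON", "WK", "DY")))
    stop_pv("age_unit_mix must be over DEC/YR/MON/WK/DY")
  chk_prob(age_unit_mix, "age_unit_mix")
  if (n_reports < 1) stop_pv("n_reports must be a positive integer")
  structure(list(n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog / sum(drug_catalog),
                 event_catalog = event_catalog / sum(event_catalog),
                 lambda = lambda,
                 drugs_per_report = drugs_per_report / sum(drugs_per_report),
                 events_per_report = events_per_report /
                   sum(events_per_report),
                 p_duplicate_version = p_duplicate_version,
                 p_concomitant = p_concomitant,
                 p_missing_age = p_missing_age,
                 p_missing_sex = p_missing_sex,
                 age_unit_mix = age_unit_mix / sum(age_unit_mix),
                 dialect = dialect, quarter = quarter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Weighted sampling without replacement, k items per row, via the
# Gumbel-max trick: one round of max.col per draw rank.
gumbel_topk <- function(logw, n, k_per_row, kmax) {
  m <- length(logw)
  g <- matrix(logw, n, m, byrow = TRUE) - log(-log(matrix(
    stats::runif(n * m), n, m)))
  sel <- matrix(NA_integer_, n, kmax)
  for (r in seq_len(kmax)) {
    j <- max.col(g, ties.method = "first")
    active <- k_per_row >= r
    sel[active, r] <- j[active]
    g[cbind(seq_len(n), j)] <- -Inf
  }
  sel
}

#' Generate a synthetic FAERS quarter
#'
#' Writes DEMO/DRUG/REAC/OUTC files (plus empty THER/RPSR/INDI stubs) in
#' the "$"-delimited dialect selected by the config, and returns the
#' planted ground truth: the exact drug-event pair counts a clean
#' pipeline run should recover (latest case version, concomitant drug
#' rows excluded, pairs deduplicated within report). The same config
#' produces byte-identical files.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `files` (paths written) and `truth`
#'   (a `planted_truth` object; also written as a TSV sidecar).
#' @export
generate_quarter <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_reports
  dn <- names(config$drug_catalog); md <- length(dn)
  en <- names(config$event_catalog); me <- length(en)

  nd <- as.integer(sample(names(config$drugs_per_report), n, TRUE,
                          config$drugs_per_report))
  ne <- as.integer(sample(names(config$events_per_report), n, TRUE,
                          config$events_per_report))
  dsel <- gumbel_topk(log(config$drug_catalog), n, nd, max(nd))

  # event odds multiplied by max over the report's drugs of lambda
  fac <- matrix(1, n, me)
  planted <- which(config$lambda != 1, arr.ind = TRUE)
  for (i in seq_len(nrow(planted))) {
    d <- planted[i, 1]; e <- planted[i, 2]
    rows <- which(rowSums(dsel == d, na.rm = TRUE) > 0)
    fac[rows, e] <- pmax(fac[rows, e], config$lambda[d, e])
  }
  w <- matrix(config$event_catalog, n, me, byrow = TRUE) * fac
  g <- log(w) - log(-log(matrix(stats::runif(n * me), n, me)))
  esel <- matrix(NA_integer_, n, max(ne))
  for (r in seq_len(max(ne))) {
    j <- max.col(g, ties.method = "first")
    active <- ne >= r
    esel[active, r] <- j[active]
    g[cbind(seq_len(n), j)] <- -Inf
  }

  # demographics
  age_true <- round(stats::runif(n, 1, 95))
  unit <- sample(names(config$age_unit_mix), n, TRUE, config$age_unit_mix)
  to_unit <- c(DEC = 0.1, YR = 1, MON = 12, WK = 52.1775, DY = 365.25)
  age_val <- round(age_true * to_unit[unit], 0)
  age_val[unit == "DEC"] <- round(age_true[unit == "DEC"] / 10, 1)
  miss_age <- stats::runif(n) < config$p_missing_age
  sex <- sample(c("M", "F"), n, TRUE)
  miss_sex <- stats::runif(n) < config$p_missing_sex
  occp <- sample(c("MD", "PH", "OT", "CN", ""), n, TRUE,
                 c(0.45, 0.2, 0.1, 0.15, 0.1))
  country <- sample(c("US", "FR", "JP", "GB", "DE"), n, TRUE,
                    c(0.35, 0.2, 0.15, 0.15, 0.15))
  serious <- stats::runif(n) < 0.9
  outc_code <- sample(c("HO", "OT", "DE", "LT"), n, TRUE,
                      c(0.5, 0.25, 0.15, 0.1))

  caseid <- as.character(10000000L + seq_len(n) - 1L)
  pid1 <- paste0(caseid, "1")
  dup <- stats::runif(n) < config$p_duplicate_version
  pid2 <- paste0(caseid, "2")

  # long-format drug rows (base version)
  slot_ok <- !is.na(dsel)
  drug_report <- row(dsel)[slot_ok]
  drug_slot <- col(dsel)[slot_ok]
  drug_id <- dsel[slot_ok]
  o <- order(drug_report, drug_slot)
  drug_report <- drug_report[o]; drug_slot <- drug_slot[o]
  drug_id <- drug_id[o]
  conc <- stats::runif(length(drug_id)) < config$p_concomitant
  role <- ifelse(conc, "C", ifelse(drug_slot == 1, "PS", "SS"))

  ev_ok <- !is.na(esel)
  ev_report <- row(esel)[ev_ok]
  ev_slot <- col(esel)[ev_ok]
  ev_id <- esel[ev_ok]
  o <- order(ev_report, ev_slot)
  ev_report <- ev_report[o]; ev_slot <- ev_slot[o]; ev_id <- ev_id[o]

  # planted truth: pair counts over non-concomitant drug rows x events
  keep <- !conc
  pr <- drug_report[keep]; pd_id <- drug_id[keep]
  reps <- ne[pr]
  exp_idx <- rep(seq_along(pr), reps)
  slot_seq <- sequence(reps)
  pair_drug <- pd_id[exp_idx]
  pair_event <- esel[cbind(pr[exp_idx], slot_seq)]
  counts <- matrix(tabulate(pair_drug + md * (pair_event - 1L), md * me),
                   md, me, dimnames = list(dn, en))

  # assemble file rows (duplicate versions repeat base content, v2 id,
  # age perturbed +1 year)
  age_chr <- ifelse(miss_age, "", as.character(age_val))
  unit_chr <- ifelse(miss_age, "", unit)
  sex_chr <- ifelse(miss_sex, "", sex)
  yy <- substr(config$quarter, 1, 2)
  qn <- as.integer(substr(config$quarter, 4, 4))
  fda_dt <- sprintf("20%s%02d15", yy, qn * 3 - 1)

  legacy <- config$dialect == "legacy"
  demo_head <- if (legacy)
    "ISR$CASE$AGE$AGE_COD$GNDR_COD$OCCP_COD$REPORTER_COUNTRY$FDA_DT"
  else
    "primaryid$caseid$age$age_cod$sex$occp_cod$reporter_country$fda_dt"
  demo_row <- function(pid, age) paste(pid, caseid, age, unit_chr, sex_chr,
                                       occp, country, fda_dt, sep = "$")
  age2 <- ifelse(miss_age, "",
                 as.character(ifelse(unit == "DEC", age_val, age_val + 1)))
  demo_lines <- c(demo_row(pid1, age_chr)[order(as.numeric(pid1))],
                  demo_row(pid2, age2)[dup])

  drug_head <- if (legacy) "ISR$DRUG_SEQ$ROLE_COD$DRUGNAME"
    else "primaryid$caseid$drug_seq$role_cod$drugname"
  drug_row <- function(pid) {
    p <- pid[drug_report]
    if (legacy) paste(p, drug_slot, role, dn[drug_id], sep = "$")
    else paste(p, caseid[drug_report], drug_slot, role, dn[drug_id],
               sep = "$")
  }
  drug_lines <- c(drug_row(pid1), drug_row(pid2)[dup[drug_report]])

  reac_head <- if (legacy) "ISR$PT" else "primaryid$caseid$pt"
  reac_row <- function(pid) {
    p <- pid[ev_report]
    if (legacy) paste(p, en[ev_id], sep = "$")
    else paste(p, caseid[ev_report], en[ev_id], sep = "$")
  }
  reac_lines <- c(reac_row(pid1), reac_row(pid2)[dup[ev_report]])

  outc_head <- if (legacy) "ISR$OUTC_COD" else "primaryid$caseid$outc_cod"
  outc_row <- function(pid) {
    if (legacy) paste(pid, outc_code, sep = "$")
    else paste(pid, caseid, outc_code, sep = "$")
  }
  outc_lines <- c(outc_row(pid1)[serious], outc_row(pid2)[serious & dup])

  q <- config$quarter
  files <- c(demo = file.path(dir, paste0("DEMO", q, ".txt")),
             drug = file.path(dir, paste0("DRUG", q, ".txt")),
             reac = file.path(dir, paste0("REAC", q, ".txt")),
             outc = file.path(dir, paste0("OUTC", q, ".txt")))
  writeLines(c(demo_head, demo_lines), files[["demo"]])
  writeLines(c(drug_head, drug_lines), files[["drug"]])
  writeLines(c(reac_head, reac_lines), files[["reac"]])
  writeLines(c(outc_head, outc_lines), files[["outc"]])
  for (stub in c("THER", "RPSR", "INDI")) {
    f <- file.path(dir, paste0(stub, q, ".txt"))
    writeLines(if (legacy) "ISR" else "primaryid$caseid", f)
    files[[tolower(stub)]] <- f
  }

  tallies <- c(n_reports = n,
               n_demo_records = length(demo_lines),
               n_drug_records = length(drug_lines),
               n_reac_records = length(reac_lines),
               n_outc_records = length(outc_lines),
               n_duplicate_versions = sum(dup),
               n_concomitant_rows = sum(conc),
               n_missing_age = sum(miss_age),
               n_missing_sex = sum(miss_sex),
               n_all_concomitant_reports =
                 sum(tapply(conc, drug_report, all)))
  truth <- structure(list(lambda = config$lambda, pair_counts = counts,
                          drugs = dn, events = en, tallies = tallies),
                     class = "planted_truth")
  truth_path <- file.path(dir, "planted_truth.tsv")
  write_tsv(data.frame(drug = rep(dn, me),
                       event = rep(en, each = md),
                       count = as.integer(counts)), truth_path)
  invisible(list(files = files, truth = truth, truth_path = truth_path))
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", sum(x$pair_counts), "clean drug-event pairs over",
      length(x$drugs), "drugs x", length(x$events), "events\n")
  invisible(x)
}

#' Reporting odds ratio implied by the planted truth
#'
#' Computed directly from the realized clean pair counts: the recovery
#' target for a full pipeline run on the generated files. Any zero cell
#' yields `NA` (flagged, never an error).
#'
#' @param truth a `planted_truth` from [generate_quarter()].
#' @param drug,event catalog names.
#' @return the realized ROR, or `NA_real_` if a cell is zero.
#' @export
planted_ror <- function(truth, drug, event) {
  stopifnot(inherits(truth, "planted_truth"))
  if (!drug %in% truth$drugs) stop_pv("unknown drug: ", drug)
  if (!event %in% truth$events) stop_pv("unknown event: ", event)
  cnt <- truth$pair_counts
  a <- cnt[drug, event]
  b <- sum(cnt[drug, ]) - a
  cc <- sum(cnt[, event]) - a
  d <- sum(cnt) - a - b - cc
  if (a == 0 || b == 0 || cc == 0 || d == 0) return(NA_real_)
  (a / b) / (cc / d)
}
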