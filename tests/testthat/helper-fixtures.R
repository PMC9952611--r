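# Shared fixtures: all built in code at test time.

# Minimal harmonized faers_data built directly from data frames, for
# cleaning-stage tests that do not need file round trips.
make_faers_data <- function(demo, drug, reac,
                            outc = data.frame(report_id = character(0),
                                              outc_cod = character(0))) {
  demo$quarter <- demo$quarter %||% "13Q1"
  demo$age_value <- demo$age_value %||% NA_real_
  demo$age_unit <- demo$age_unit %||% NA_character_
  demo$sex <- demo$sex %||% NA_character_
  demo$occp_cod <- demo$occp_cod %||% NA_character_
  demo$country <- demo$country %||% NA_character_
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 rejects = data.frame()),
            class = "faers_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small two-drug, two-event catalog with exactly one drug and one
# event per report: inclusion probabilities then have a closed form,
# which several oracle computations rely on.
simple_config <- function(n = 5000, lambda_tzp_hypo = 1, seed = 1,
                          p_dup = 0, p_conc = 0, p_miss = 0, ...) {
  dc <- c("piperacillin/tazobactam" = 0.3, "vancomycin" = 0.4,
          "metformin" = 0.3)
  ec <- c("hypokalaemia" = 0.25, "nausea" = 0.45, "rash" = 0.3)
  lam <- matrix(1, 3, 3, dimnames = list(names(dc), names(ec)))
  lam["piperacillin/tazobactam", "hypokalaemia"] <- lambda_tzp_hypo
  synth_config(n_reports = n, drug_catalog = dc, event_catalog = ec,
               lambda = lam,
               drugs_per_report = c("1" = 1),
               events_per_report = c("1" = 1),
               p_duplicate_version = p_dup, p_concomitant = p_conc,
               p_missing_age = p_miss, p_missing_sex = p_miss,
               seed = seed, ...)
}

# Closed-form population cell probabilities for a simple_config run:
# one drug and one event per report, so P(pair d,e) =
# P(drug = d) * P(event = e | drug = d) with event odds scaled by
# lambda(d, e).
simple_true_cells <- function(config, drug, event) {
  pd <- config$drug_catalog
  pe <- config$event_catalog
  lam <- config$lambda
  w <- lam * rep(pe, each = nrow(lam))        # unnormalized event odds
  w <- w / rowSums(w)                         # P(event | drug)
  joint <- pd * w                             # P(drug, event)
  a <- joint[drug, event]
  b <- sum(joint[drug, ]) - a
  cc <- sum(joint[, event]) - a
  d <- 1 - a - b - cc
  c(a = a, b = b, c = cc, d = unname(d))
}

run_clean_pipeline <- function(dir, dialect = "auto") {
  clean_cases(parse_quarter(dir, dialect))
}
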