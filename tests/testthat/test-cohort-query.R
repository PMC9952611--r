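test_that("the packaged dictionary covers the twelve penicillins disjointly", {
  dict <- drug_dictionary()
  expect_setequal(dict$drugs,
    c("piperacillin/tazobactam", "amoxicillin/clavulanic acid",
      "ampicillin/sulbactam", "ampicillin", "amoxicillin", "piperacillin",
      "cloxacillin", "flucloxacillin", "nafcillin", "oxacillin",
      "penicillin g", "penicillin v"))
  expect_false(anyDuplicated(names(dict$synonyms)) > 0)
  expect_setequal(unique(unname(dict$atc_class)),
                  c("J01CR", "J01CA", "J01CF", "J01CE"))
})

test_that("drug matching is exact after normalization and dosage stripping", {
  dict <- drug_dictionary()
  expect_equal(match_drug("PIPERACILLIN/TAZOBACTAM", dict),
               "piperacillin/tazobactam")
  expect_equal(match_drug("  Zosyn   4.5 g ", dict),
               "piperacillin/tazobactam")
  expect_equal(match_drug("amoxicillin 500 mg tablets", dict), "amoxicillin")
  expect_equal(match_drug("vancomycin", dict), "other")
  # no substring matching: a partial token is not a hit
  expect_equal(match_drug("piperacillin/tazobactam extra", dict), "other")
})

test_that("event queries carry the twenty preferred terms, two per disorder", {
  ev <- event_queries()
  expect_equal(length(ev), 10)
  expect_true(all(lengths(ev) == 2))
  expect_setequal(ev$hypokalemia, c("hypokalaemia",
                                    "blood potassium decreased"))
  expect_setequal(ev$hypermagnesemia, c("hypermagnesaemia",
                                        "blood magnesium increased"))
  # each laboratory PT counts toward exactly one disorder
  expect_false(anyDuplicated(unlist(ev)) > 0)
})

test_that("pair building is the deduplicated drug x event product", {
  demo <- data.frame(report_id = "1", case_id = "1", quarter = "13Q1",
                     age_value = 40, age_unit = "YR", sex = "F",
                     occp_cod = "MD", country = "US", fda_dt = "20130101")
  drug <- data.frame(report_id = "1",
                     drugname = c("Drug A", "drug  a", "drug b"),
                     role_cod = "PS")
  reac <- data.frame(report_id = "1",
                     pt = c("rash", "nausea", "pyrexia", "RASH"))
  clean <- clean_cases(make_faers_data(demo, drug, reac))
  pairs <- build_pairs(clean)
  # 2 distinct drugs x 3 distinct events after normalization
  expect_equal(nrow(pairs), 6)
  expect_setequal(unique(pairs$drug), c("drug a", "drug b"))
})

test_that("pair totals recover the generator's planted tally", {
  cfg <- synth_config(n_reports = 800, seed = 31)
  d <- withr::local_tempdir()
  truth <- generate_quarter(cfg, d)$truth
  pairs <- build_pairs(run_clean_pipeline(d))
  expect_equal(nrow(pairs), sum(truth$pair_counts))
  # per-cell recovery, not just the grand total
  tab <- table(pairs$drug, pairs$pt)
  for (dn in truth$drugs) for (en in truth$events) {
    got <- if (dn %in% rownames(tab) && en %in% colnames(tab))
      tab[dn, en] else 0L
    expect_equal(unname(got), truth$pair_counts[dn, en],
                 label = paste(dn, en))
  }
})

test_that("contingency cells match a brute-force recount and conserve totals", {
  set.seed(13)
  pairs <- data.frame(
    report_id = as.character(seq_len(500)),
    drug = sample(c("tzp", "vanco", "cipro"), 500, TRUE),
    pt = sample(c("hypokalaemia", "rash", "nausea"), 500, TRUE))
  t <- build_contingency(pairs, "tzp", "hypokalaemia")
  expect_equal(t$N, 500)
  expect_equal(t$a, sum(pairs$drug == "tzp" & pairs$pt == "hypokalaemia"))
  expect_equal(t$b, sum(pairs$drug == "tzp" & pairs$pt != "hypokalaemia"))
  expect_equal(t$c, sum(pairs$drug != "tzp" & pairs$pt == "hypokalaemia"))
  expect_equal(t$d, sum(pairs$drug != "tzp" & pairs$pt != "hypokalaemia"))
})

test_that("restricting the universe commutes with table construction", {
  set.seed(14)
  pairs <- data.frame(
    report_id = as.character(seq_len(400)),
    drug = sample(c("tzp", "nafcillin", "vanco", "cipro"), 400, TRUE),
    pt = sample(c("hypokalaemia", "rash"), 400, TRUE))
  universe <- c("tzp", "nafcillin")
  t1 <- build_contingency(pairs, "tzp", "hypokalaemia",
                          comparator = "drug_list", drug_list = universe)
  t2 <- build_contingency(pairs[pairs$drug %in% universe, ],
                          "tzp", "hypokalaemia")
  expect_equal(unclass(t1), unclass(t2))
  # universe size = sum over member drugs of their row totals
  expect_equal(t1$N, sum(pairs$drug %in% universe))
})

test_that("contingency construction rejects degenerate universes", {
  pairs <- data.frame(report_id = "1", drug = "vanco", pt = "rash")
  expect_error(build_contingency(pairs, "tzp", "hypokalaemia"),
               "absent from the universe")
  expect_error(build_contingency(pairs, "tzp", "hypokalaemia",
                                 comparator = "drug_list",
                                 drug_list = c("vanco")),
               "include the target")
  expect_error(build_contingency(pairs[0, ], "tzp", "hypokalaemia"),
               "empty comparator universe")
})
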