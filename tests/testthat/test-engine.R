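# db used across blocks: random but fixed synthetic corpus
eng_db <- generate_substance_db(generator_spec(40, seed = 11))

test_that("exposure ratio is 100 * C / OEL with unit reconciliation", {
  s <- substance("71-43-2", "benzene",
                 oels = list(oel_value("eight_hour", 100, "ppm")),
                 molecular_weight = 78.11)
  rec <- list(cas = "71-43-2", concentration = 50, unit = "ppm")
  expect_identical(exposure_ratio(rec, s)$ratio_percent, 50)
  rec$concentration <- 0
  expect_identical(exposure_ratio(rec, s)$ratio_percent, 0)

  # 10 ppm of toluene against an OEL expressed in mg/m3 (37.69 ~ 10 ppm)
  tol <- substance("108-88-3", "toluene",
                   oels = list(oel_value("eight_hour", 37.69, "mg_per_m3")),
                   molecular_weight = 92.14)
  ct <- exposure_ratio(list(cas = "108-88-3", concentration = 10,
                            unit = "ppm"), tol)
  expect_equal(ct$ratio_percent, 100, tolerance = 0.1 / 100)

  # unreconcilable: differing units, no molecular weight
  tol$molecular_weight <- NA_real_
  expect_error(exposure_ratio(list(cas = "108-88-3", concentration = 10,
                                   unit = "ppm"), tol), "108-88-3")
})

test_that("class Hazard Index sums activating substances only", {
  db <- tiny_db()
  # ethylbenzene and benzene share CNS damage; formaldehyde does not
  scn <- mixture_scenario(c("100-41-4", "71-43-2", "50-00-0"),
                          c(100, 1, 0.1), c("ppm", "ppm", "ppm"))
  r <- compute_class_hi(scn, "central_nervous_system_damage", db)
  expect_equal(r$hi_percent, 200)       # both exactly at their OELs
  expect_true(r$risky)
  expect_setequal(r$contributions$cas, c("100-41-4", "71-43-2"))

  # ratios 30, 50, 40 -> HI 120
  scn2 <- mixture_scenario(c("100-41-4", "71-43-2", "50-00-0"),
                           c(30, 0.5, 0.12),  # 30%, 50%, 40% of OELs
                           c("ppm", "ppm", "ppm"))
  r2 <- compute_class_hi(scn2, "ocular_damage", db)  # ethylbenzene + formald.
  expect_equal(r2$hi_percent, 70)
  hi_all <- sum(30, 50, 40)
  expect_equal(compute_class_hi(scn2, "central_nervous_system_damage",
                                db)$hi_percent + 40, hi_all)

  expect_error(compute_class_hi(scn, "spleen_damage", db), "no scenario")
  expect_error(compute_class_hi(scn, "sensitization", db), "non-additive")
})

test_that("risk threshold is strictly greater than 100%", {
  db <- substance_db(list(
    substance("71-43-2", "benzene",
              oels = list(oel_value("eight_hour", 100, "ppm")),
              class_ids = "hepatic_damage")), "synthetic")
  for (case in list(list(conc = 99.999, risky = FALSE),
                    list(conc = 100.0, risky = FALSE),
                    list(conc = 100.001, risky = TRUE))) {
    scn <- mixture_scenario("71-43-2", case$conc, "ppm")
    r <- compute_class_hi(scn, "hepatic_damage", db)
    expect_identical(r$risky, case$risky)
  }
})

test_that("alert detection lists activating substances per alert class", {
  db <- tiny_db()
  scn <- mixture_scenario(c("100-41-4", "71-43-2", "50-00-0"),
                          mode = "qualitative")
  findings <- detect_alerts(scn, db)
  keys <- vapply(findings, `[[`, character(1), "message_key")
  expect_setequal(keys, c("cmr_present", "sensitizer_present"))
  cmr <- findings[[which(keys == "cmr_present")]]
  expect_setequal(cmr$cas_list, c("100-41-4", "71-43-2"))
  expect_false(cmr$informational)
  sens <- findings[[which(keys == "sensitizer_present")]]
  expect_identical(sens$cas_list, "50-00-0")
  expect_match(sens$message, "^One substance")

  # no alert-class substance -> empty
  db2 <- substance_db(list(substance("71-43-2", "benzene",
    oels = list(oel_value("eight_hour", 1, "ppm")),
    class_ids = "hepatic_damage")), "synthetic")
  expect_length(detect_alerts(mixture_scenario("71-43-2", 1, "ppm"), db2), 0L)
})

test_that("ototoxicity activation adds an informational message only", {
  fx <- case_study_fixture()
  findings <- detect_alerts(fx$scenario, fx$db)
  info <- Filter(function(f) f$informational, findings)
  expect_length(info, 1L)
  expect_identical(info[[1]]$class_id, "ototoxicity")
  expect_identical(info[[1]]$message_key, "ototoxicant_present")
  # non-informational findings are all genuinely non-additive classes
  hard <- Filter(function(f) !f$informational, findings)
  for (f in hard) expect_false(tox_class(f$class_id)$additive)
  # the informational note does not flip the alert flag by itself
  rep <- analyze_quantitative(fx$scenario, fx$db)
  expect_true(rep$any_alert)  # true here because of the two real alerts
})

test_that("quantitative analysis ranks alerts first, then decreasing HI", {
  fx <- case_study_fixture()
  rep <- analyze_quantitative(fx$scenario, fx$db)
  add_flags <- vapply(rep$class_results, `[[`, logical(1), "additive")
  # all alert rows precede all additive rows
  expect_true(all(diff(add_flags) >= 0))
  his <- vapply(rep$class_results[add_flags], `[[`, numeric(1), "hi_percent")
  expect_true(all(diff(his) <= 0))
  # alert rows carry no numeric HI
  expect_true(all(is.na(vapply(rep$class_results[!add_flags], `[[`,
                               numeric(1), "hi_percent"))))
  # ties broken alphabetically (four classes tie at 140)
  tied <- vapply(rep$class_results[add_flags], `[[`, character(1),
                 "class_id")[his == max(his)]
  expect_identical(tied, sort(tied))
})

test_that("rank_results ordering contract", {
  mk <- function(id, additive, hi) {
    structure(list(class_id = id, additive = additive, hi_percent = hi,
                   substance_count = NULL))
  }
  ranked <- rank_results(list(mk("b_class", TRUE, 120),
                              mk("a_class", TRUE, 50),
                              mk("alert_x", FALSE, NA_real_)))
  expect_identical(vapply(ranked, `[[`, character(1), "class_id"),
                   c("alert_x", "b_class", "a_class"))
  ranked2 <- rank_results(list(mk("b", TRUE, 50), mk("a", TRUE, 50)))
  expect_identical(vapply(ranked2, `[[`, character(1), "class_id"),
                   c("a", "b"))
  expect_identical(rank_results(list()), list())
})

test_that("single substance below its OEL raises no risk", {
  db <- tiny_db()
  scn <- mixture_scenario("100-41-4", 50, "ppm")
  rep <- analyze_quantitative(scn, db)
  expect_false(rep$any_risk)
  expect_true(rep$any_alert)  # ethylbenzene is in the CMR class here
  add <- Filter(function(r) r$additive, rep$class_results)
  expect_true(all(!vapply(add, `[[`, logical(1), "risky")))
})

test_that("substances without usable OELs are excluded with warnings", {
  db <- substance_db(list(
    substance("71-43-2", "benzene",
              oels = list(oel_value("eight_hour", 1, "ppm")),
              class_ids = "hepatic_damage"),
    substance("50-00-0", "formaldehyde", class_ids = "hepatic_damage")
  ), "synthetic")
  scn <- mixture_scenario(c("71-43-2", "50-00-0"), c(0.5, 1), c("ppm", "ppm"))
  rep <- analyze_quantitative(scn, db)
  expect_match(rep$warnings, "50-00-0.*no usable OEL", all = FALSE)
  hep <- Filter(function(r) r$class_id == "hepatic_damage",
                rep$class_results)[[1]]
  expect_equal(hep$hi_percent, 50)                 # only benzene counts
  expect_setequal(hep$cas_list, c("71-43-2", "50-00-0"))  # still activates
})

test_that("missing concentrations: hard error unless allow_missing", {
  db <- tiny_db()
  scn <- mixture_scenario(c("100-41-4", "71-43-2"), c(10, NA), c("ppm", NA),
                          mode = "quantitative", allow_missing = TRUE)
  expect_error(analyze_quantitative(scn, db), "missing concentration")
  rep <- analyze_quantitative(scn, db, allow_missing = TRUE)
  expect_match(rep$warnings, "71-43-2.*lower bound", all = FALSE)
  cns <- Filter(function(r) r$class_id == "central_nervous_system_damage",
                rep$class_results)[[1]]
  expect_equal(cns$hi_percent, 10)
})

test_that("unknown scenario substances are an error listing the cas", {
  db <- tiny_db()
  scn <- mixture_scenario(c("100-41-4", "9999999-99-5"), c(1, 1),
                          c("ppm", "ppm"))
  expect_error(analyze_quantitative(scn, db), "9999999-99-5")
  expect_error(analyze_qualitative(scn, db), "9999999-99-5")
})

test_that("qualitative analysis counts and flags shared classes", {
  db <- tiny_db()
  scn <- mixture_scenario(c("100-41-4", "71-43-2", "50-00-0"),
                          mode = "qualitative")
  rep <- analyze_qualitative(scn, db)
  res <- stats::setNames(rep$class_results,
                         vapply(rep$class_results, `[[`, character(1),
                                "class_id"))
  expect_identical(res$ocular_damage$substance_count, 2L)
  expect_true(res$ocular_damage$shared)
  expect_identical(res$hematopoietic_system_disruption$substance_count, 1L)
  expect_false(res$hematopoietic_system_disruption$shared)
  # one substance alone: nothing shared
  rep1 <- analyze_qualitative(mixture_scenario("71-43-2"), db)
  expect_true(all(vapply(rep1$class_results, `[[`, integer(1),
                         "substance_count") == 1L))
  expect_false(any(vapply(rep1$class_results, `[[`, logical(1), "shared")))
})

test_that("most-shared additive class ranks first among additive rows", {
  # 15 substances, 13 sharing one class: dominant class leads the ranking
  subs <- lapply(1:15, function(i) {
    substance(hazmix:::cas_from_body(sprintf("90210%02d", i)),
              sprintf("s%02d", i),
              class_ids = c(if (i <= 13) "ocular_damage",
                            if (i <= 10) "upper_airway_damage",
                            if (i <= 2) "lower_airway_damage",
                            if (i == 1) "oxygen_transport_disruption"),
              synthetic = TRUE)
  })
  db <- substance_db(subs, "synthetic")
  scn <- mixture_scenario(names(db$substances), mode = "qualitative")
  rep <- analyze_qualitative(scn, db)
  add <- Filter(function(r) r$additive, rep$class_results)
  expect_identical(add[[1]]$class_id, "ocular_damage")
  expect_identical(add[[1]]$substance_count, 13L)
  expect_identical(add[[2]]$class_id, "upper_airway_damage")
  expect_identical(add[[2]]$substance_count, 10L)
  counts <- vapply(add, `[[`, integer(1), "substance_count")
  expect_true(all(diff(counts) <= 0))
})

test_that("engine HI matches the brute-force oracle on random scenarios", {
  for (seed in 1:25) {
    scn <- generate_scenario(eng_db, n_selected = (seed %% 10) + 1L,
                             regime = c(0, 1.5), seed = seed)
    rep <- analyze_quantitative(scn, eng_db)
    for (r in rep$class_results) {
      if (!r$additive) next
      expect_equal(r$hi_percent, oracle_class_hi(scn, eng_db, r$class_id),
                   tolerance = 1e-9)
    }
  }
})

test_that("homogeneity: scaling concentrations by k scales every HI by k", {
  scn <- generate_scenario(eng_db, 8, c(0.1, 1.2), seed = 5)
  rep <- analyze_quantitative(scn, eng_db)
  for (k in c(0.5, 2, 10)) {
    scn_k <- mixture_scenario(scn$records$cas, scn$records$concentration * k,
                              scn$records$unit)
    rep_k <- analyze_quantitative(scn_k, eng_db)
    for (i in seq_along(rep$class_results)) {
      a <- rep$class_results[[i]]; b <- rep_k$class_results[[i]]
      expect_identical(a$class_id, b$class_id)
      if (a$additive) expect_equal(b$hi_percent, k * a$hi_percent,
                                   tolerance = 1e-12)
    }
  }
})

test_that("monotonicity: adding an activating substance never lowers HI", {
  scn <- generate_scenario(eng_db, 9, c(0.05, 1.0), seed = 8)
  full <- analyze_quantitative(scn, eng_db)
  adds <- Filter(function(r) r$additive, full$class_results)
  full_hi <- stats::setNames(vapply(adds, `[[`, numeric(1), "hi_percent"),
                             vapply(adds, `[[`, character(1), "class_id"))
  for (drop in seq_len(nrow(scn$records))) {
    keep <- scn$records[-drop, ]
    sub <- mixture_scenario(keep$cas, keep$concentration, keep$unit)
    part <- analyze_quantitative(sub, eng_db)
    for (r in Filter(function(r) r$additive, part$class_results)) {
      expect_lte(r$hi_percent, full_hi[[r$class_id]] + 1e-12)
    }
  }
})

test_that("decomposition: HI of a scenario is the sum over any partition", {
  scn <- generate_scenario(eng_db, 8, c(0.1, 1.2), seed = 13)
  rep <- analyze_quantitative(scn, eng_db)
  split_at <- 3
  parts <- list(scn$records[1:split_at, ],
                scn$records[(split_at + 1):nrow(scn$records), ])
  part_hi <- new.env()
  for (p in parts) {
    pr <- analyze_quantitative(mixture_scenario(p$cas, p$concentration,
                                                p$unit), eng_db)
    for (r in Filter(function(r) r$additive, pr$class_results)) {
      part_hi[[r$class_id]] <- (part_hi[[r$class_id]] %||% 0) + r$hi_percent
    }
  }
  for (r in Filter(function(r) r$additive, rep$class_results)) {
    expect_equal(r$hi_percent, part_hi[[r$class_id]], tolerance = 1e-9)
  }
})

test_that("conservation: HI equals the sum of its contributions", {
  for (seed in c(2, 9)) {
    scn <- generate_scenario(eng_db, 10, c(0, 1.5), seed = seed)
    rep <- analyze_quantitative(scn, eng_db)
    for (r in Filter(function(r) r$additive, rep$class_results)) {
      expect_equal(r$hi_percent, sum(r$contributions$ratio_percent),
                   tolerance = 1e-9)
      expect_true(all(diff(r$contributions$ratio_percent) <= 0))
    }
  }
})

test_that("no alert class ever carries a numeric HI", {
  for (seed in 1:10) {
    scn <- generate_scenario(eng_db, 6, c(0, 1.5), seed = seed)
    rep <- analyze_quantitative(scn, eng_db)
    for (r in rep$class_results) {
      if (!r$additive) expect_true(is.na(r$hi_percent))
      if (!r$additive) expect_true(is.na(r$risky))
    }
  }
})

test_that("both modes activate the identical class set", {
  for (seed in 1:10) {
    scn_q <- generate_scenario(eng_db, 7, c(0.1, 1.2), seed = seed)
    scn_l <- mixture_scenario(scn_q$records$cas, mode = "qualitative")
    ids_q <- sort(vapply(analyze_quantitative(scn_q, eng_db)$class_results,
                         `[[`, character(1), "class_id"))
    ids_l <- sort(vapply(analyze_qualitative(scn_l, eng_db)$class_results,
                         `[[`, character(1), "class_id"))
    expect_identical(ids_q, ids_l)
    expect_identical(ids_q, oracle_activated(scn_q, eng_db))
  }
})
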