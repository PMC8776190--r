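# Mixture engine: additive Hazard Index per toxicological class, alert-class
# handling, qualitative shared-class analysis, ranked reports.

.alert_message_keys <- c(
  endocrine_disruption = "endocrine_disruptor_present",
  male_reproductive_damage = "male_reprotoxicant_present",
  female_reproductive_damage = "female_reprotoxicant_present",
  developmental_damage = "developmental_toxicant_present",
  carcinogenicity_mutagenicity = "cmr_present",
  sensitization = "sensitizer_present",
  ototoxicity = "ototoxicant_present"  # informational: class is additive
)

.alert_message_text <- function(message_key, n) {
  word <- if (n == 1L) "One substance" else sprintf("%d substances", n)
  verb <- if (n == 1L) "is" else "are"
  affect <- if (n == 1L) "affects" else "affect"
  switch(message_key,
    cmr_present = sprintf("%s %s carcinogenic and/or mutagenic.", word, verb),
    sensitizer_present = sprintf("%s %s sensitizing.", word, verb),
    developmental_toxicant_present =
      sprintf("%s %s development of the foetus, embryo, and/or child.",
              word, affect),
    endocrine_disruptor_present =
      sprintf("%s %s an endocrine disrupter.", word,
              if (n == 1L) "is" else "are"),
    male_reprotoxicant_present =
      sprintf("%s %s the male reproductive system.", word, affect),
    female_reprotoxicant_present =
      sprintf("%s %s the female reproductive system.", word, affect),
    ototoxicant_present = sprintf("%s %s ototoxic.", word, verb),
    sprintf("%s %s in an alert class.", word, verb)
  )
}

#' Exposure ratio of one substance
#'
#' The per-substance term of the Hazard Index: 100 x C / OEL, where C is
#' the measured atmospheric concentration and OEL the substance's
#' occupational exposure limit selected by [select_oel()]. Measurement and
#' OEL units are reconciled with [convert_concentration()] when they
#' differ (requiring the molecular weight). The ratio is a property of the
#' substance alone: it is identical across every toxicological class the
#' substance activates.
#'
#' @param record List or one-row data frame with `cas`, `concentration`
#'   (>= 0, not `NA`) and `unit`.
#' @param substance The matching `substance` record (with at least one OEL).
#' @return A contribution: list with `cas`, `ratio_percent`, `oel_kind`,
#'   `oel_value`, `oel_unit` and `fallback` (`NA` unless a non-8h OEL was
#'   used).
#' @export
exposure_ratio <- function(record, substance) {
  if (is.na(record$concentration)) {
    stop("substance ", record$cas, ": concentration is missing",
         call. = FALSE)
  }
  sel <- select_oel(substance)
  conc <- convert_concentration(record$concentration, record$unit,
                                sel$oel$unit,
                                molecular_weight = substance$molecular_weight,
                                substance = record$cas)
  list(cas = record$cas,
       ratio_percent = 100 * conc / sel$oel$value,
       oel_kind = sel$oel$kind, oel_value = sel$oel$value,
       oel_unit = sel$oel$unit, fallback = sel$fallback)
}

# Resolve scenario records against the database. Errors on unknown CAS;
# returns per-substance contributions (NULL where the substance is excluded
# from HI sums) plus the warnings generated.
.resolve_contributions <- function(scenario, db, quantitative,
                                   allow_missing = FALSE) {
  recs <- scenario$records
  unknown <- setdiff(recs$cas, names(db$substances))
  if (length(unknown)) {
    stop("substances not in database: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  warnings <- character(0)
  contribs <- stats::setNames(vector("list", nrow(recs)), recs$cas)
  if (quantitative) {
    for (i in seq_len(nrow(recs))) {
      rec <- list(cas = recs$cas[i], concentration = recs$concentration[i],
                  unit = recs$unit[i])
      subst <- db$substances[[rec$cas]]
      if (is.na(rec$concentration)) {
        if (!allow_missing) {
          stop("substance ", rec$cas,
               ": missing concentration in quantitative mode", call. = FALSE)
        }
        warnings <- c(warnings, sprintf(
          "substance %s: no concentration; excluded from Hazard Index sums (indexes are lower bounds)",
          rec$cas))
        next
      }
      if (length(subst$oels) == 0L) {
        warnings <- c(warnings, sprintf(
          "substance %s: no usable OEL; excluded from Hazard Index sums",
          rec$cas))
        next
      }
      ct <- exposure_ratio(rec, subst)
      if (!is.na(ct$fallback)) warnings <- c(warnings, ct$fallback)
      contribs[[rec$cas]] <- ct
    }
  }
  list(contribs = contribs, warnings = warnings)
}

# class_id -> character vector of activating scenario cas, registry order
.activation_map <- function(scenario, db, registry) {
  ids <- class_ids(registry)
  act <- stats::setNames(lapply(ids, function(id) character(0)), ids)
  for (cas in scenario$records$cas) {
    for (id in db$substances[[cas]]$class_ids) {
      act[[id]] <- c(act[[id]], cas)
    }
  }
  act[vapply(act, length, integer(1)) > 0L]
}

#' Hazard Index of one additive toxicological class
#'
#' HI = (C1/OEL1 + C2/OEL2 + ... + Cn/OELn) x 100 over the scenario
#' substances that activate the class; the situation is flagged risky when
#' HI exceeds 100% strictly. Substances that do not activate the class
#' contribute nothing.
#'
#' @param scenario A quantitative `mixture_scenario`.
#' @param class_id An additive class id activated by at least one scenario
#'   substance.
#' @param db A `substance_db` resolving every scenario CAS.
#' @param registry A `tox_registry`.
#' @param allow_missing Drop substances without concentrations instead of
#'   erroring.
#' @return A `class_hi_result`: list with `class_id`, `name`, `additive =
#'   TRUE`, `hi_percent`, `risky` (strictly greater than 100), and
#'   `contributions`, a data frame of per-substance ratios in decreasing
#'   order.
#' @export
compute_class_hi <- function(scenario, class_id, db,
                             registry = tox_registry(),
                             allow_missing = FALSE) {
  cls <- tox_class(class_id, registry)
  if (!cls$additive) {
    stop("class ", class_id, " is non-additive (alert class): ",
         "no Hazard Index is defined", call. = FALSE)
  }
  if (scenario$mode != "quantitative") {
    stop("Hazard Index requires a quantitative scenario", call. = FALSE)
  }
  res <- .resolve_contributions(scenario, db, TRUE, allow_missing)
  act <- .activation_map(scenario, db, registry)
  if (is.null(act[[class_id]])) {
    stop("no scenario substance activates class ", class_id, call. = FALSE)
  }
  .class_hi_result(cls, act[[class_id]], res$contribs)
}

.class_hi_result <- function(cls, activating_cas, contribs) {
  used <- contribs[activating_cas]
  used <- used[!vapply(used, is.null, logical(1))]
  cas <- unname(vapply(used, `[[`, character(1), "cas"))
  ratio <- unname(vapply(used, `[[`, numeric(1), "ratio_percent"))
  ord <- order(-ratio, cas)
  # built by hand: data.frame() is a hot spot across many small classes
  contributions <- structure(
    list(cas = cas[ord], ratio_percent = ratio[ord],
         oel_kind = unname(vapply(used, `[[`, character(1), "oel_kind"))[ord],
         oel_value = unname(vapply(used, `[[`, numeric(1), "oel_value"))[ord],
         oel_unit = unname(vapply(used, `[[`, character(1), "oel_unit"))[ord],
         fallback = unname(vapply(used, `[[`, character(1), "fallback"))[ord]),
    class = "data.frame",
    row.names = if (length(ord)) seq_along(ord) else integer(0))
  hi <- sum(contributions$ratio_percent)
  structure(
    list(class_id = cls$class_id, name = cls$name, additive = TRUE,
         hi_percent = hi, risky = hi > 100,
         cas_list = sort(activating_cas), contributions = contributions),
    class = "class_hi_result"
  )
}

#' Detect alert-class findings in a scenario
#'
#' Produces one finding per non-additive (alert) class activated by at
#' least one scenario substance: additivity is not applicable for these
#' classes, so any exposure triggers a warning instead of a Hazard Index.
#' An additional informational finding (with `informational = TRUE`) is
#' emitted when the ototoxicity class — additive, but singled out in
#' workplace messages because noise co-exposure aggravates it — is
#' activated; it takes no part in alert-class ranking.
#'
#' @param scenario A `mixture_scenario` (either mode).
#' @param db A `substance_db` resolving every scenario CAS.
#' @param registry A `tox_registry`.
#' @return List of findings: `class_id`, `cas_list`, `message_key`,
#'   `informational`, `message`.
#' @export
detect_alerts <- function(scenario, db, registry = tox_registry()) {
  unknown <- setdiff(scenario$records$cas, names(db$substances))
  if (length(unknown)) {
    stop("substances not in database: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  act <- .activation_map(scenario, db, registry)
  alert_ids <- intersect(names(act), class_ids(registry, additive = FALSE))
  findings <- lapply(sort(alert_ids), function(id) {
    key <- unname(.alert_message_keys[id])
    list(class_id = id, cas_list = sort(act[[id]]), message_key = key,
         informational = FALSE,
         message = .alert_message_text(key, length(act[[id]])))
  })
  if (!is.null(act[["ototoxicity"]])) {
    n <- length(act[["ototoxicity"]])
    findings <- c(findings, list(list(
      class_id = "ototoxicity", cas_list = sort(act[["ototoxicity"]]),
      message_key = "ototoxicant_present", informational = TRUE,
      message = .alert_message_text("ototoxicant_present", n)
    )))
  }
  findings
}

#' Rank class results for reporting
#'
#' Stable total order used in every report: alert (non-additive) classes
#' first, then additive classes by decreasing key — Hazard Index in
#' quantitative mode, substance count in qualitative mode — with ties
#' broken alphabetically by class id.
#'
#' @param results List of class results (`class_hi_result`,
#'   `qualitative_class_result`, or alert rows), each carrying `class_id`,
#'   `additive`, and `hi_percent` or `substance_count`.
#' @return The same list, reordered.
#' @export
rank_results <- function(results) {
  if (length(results) == 0L) return(results)
  additive <- vapply(results, `[[`, logical(1), "additive")
  ids <- vapply(results, `[[`, character(1), "class_id")
  key <- vapply(results, function(r) {
    k <- if (!r$additive && is.null(r$substance_count)) NA_real_
         else r$substance_count %||% r$hi_percent
    if (is.null(k) || is.na(k)) -Inf else as.numeric(k)
  }, numeric(1))
  results[order(additive, -key, ids)]
}

#' Quantitative analysis of a mixture
#'
#' The full workplace chemical analysis: alert findings, one Hazard Index
#' per additive class activated by the scenario, risk flags, warnings for
#' excluded substances and OEL fallbacks, all ranked for display (alert
#' classes first with no index, then additive classes by decreasing HI).
#'
#' @param scenario A quantitative `mixture_scenario`.
#' @param db A `substance_db`.
#' @param registry A `tox_registry`.
#' @param allow_missing Drop records without concentrations (with a
#'   warning; indexes become lower bounds) instead of erroring.
#' @return A `hazmix_report`.
#' @export
analyze_quantitative <- function(scenario, db, registry = tox_registry(),
                                 allow_missing = FALSE) {
  stopifnot(inherits(scenario, "mixture_scenario"),
            inherits(db, "substance_db"))
  if (scenario$mode != "quantitative") {
    stop("scenario mode is not quantitative", call. = FALSE)
  }
  res <- .resolve_contributions(scenario, db, TRUE, allow_missing)
  act <- .activation_map(scenario, db, registry)
  alert_ids <- intersect(names(act), class_ids(registry, additive = FALSE))
  additive_ids <- intersect(names(act), class_ids(registry, additive = TRUE))

  class_results <- c(
    lapply(sort(alert_ids), function(id) {
      cls <- tox_class(id, registry)
      structure(list(class_id = id, name = cls$name, additive = FALSE,
                     hi_percent = NA_real_, risky = NA,
                     cas_list = sort(act[[id]])),
                class = "alert_class_result")
    }),
    lapply(additive_ids, function(id) {
      .class_hi_result(tox_class(id, registry), act[[id]], res$contribs)
    })
  )
  class_results <- rank_results(class_results)
  findings <- detect_alerts(scenario, db, registry)
  his <- vapply(class_results, `[[`, numeric(1), "hi_percent")
  any_risk <- any(his > 100, na.rm = TRUE)

  structure(
    list(mode = "quantitative",
         jurisdiction = db$jurisdiction, oel_name = db$oel_name,
         scenario = scenario$records,
         alert_findings = findings,
         class_results = class_results,
         warnings = unique(res$warnings),
         any_risk = any_risk,
         any_alert = any(!vapply(findings, `[[`, logical(1),
                                 "informational"))),
    class = "hazmix_report"
  )
}

#' Qualitative analysis of a mixture
#'
#' Used when atmospheric concentrations are unavailable: no Hazard Index
#' is computed; instead each activated toxicological class is reported
#' with the number of scenario substances activating it, on the principle
#' that risk to an organ grows with the number of substances targeting it.
#' Classes shared by two or more substances are flagged. Alert findings
#' are identical to quantitative mode.
#'
#' @param scenario A `mixture_scenario`; any concentrations present are
#'   ignored.
#' @param db A `substance_db`.
#' @param registry A `tox_registry`.
#' @return A `hazmix_report` with `qualitative_class_result` rows.
#' @export
analyze_qualitative <- function(scenario, db, registry = tox_registry()) {
  stopifnot(inherits(scenario, "mixture_scenario"),
            inherits(db, "substance_db"))
  unknown <- setdiff(scenario$records$cas, names(db$substances))
  if (length(unknown)) {
    stop("substances not in database: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  act <- .activation_map(scenario, db, registry)
  class_results <- lapply(names(act), function(id) {
    cls <- tox_class(id, registry)
    structure(
      list(class_id = id, name = cls$name, additive = cls$additive,
           substance_count = length(act[[id]]),
           cas_list = sort(act[[id]]),
           shared = length(act[[id]]) >= 2L),
      class = "qualitative_class_result"
    )
  })
  class_results <- rank_results(class_results)
  findings <- detect_alerts(scenario, db, registry)
  structure(
    list(mode = "qualitative",
         jurisdiction = db$jurisdiction, oel_name = db$oel_name,
         scenario = scenario$records,
         alert_findings = findings,
         class_results = class_results,
         warnings = character(0),
         any_risk = NA,
         any_alert = any(!vapply(findings, `[[`, logical(1),
                                 "informational"))),
    class = "hazmix_report"
  )
}

#' Analyse a mixture scenario
#'
#' Dispatches on the scenario mode to [analyze_quantitative()] or
#' [analyze_qualitative()].
#'
#' @param scenario A `mixture_scenario`.
#' @param db A `substance_db`.
#' @param registry A `tox_registry`.
#' @param allow_missing Passed to the quantitative analysis.
#' @return A `hazmix_report`.
#' @export
analyze_mixture <- function(scenario, db, registry = tox_registry(),
                            allow_missing = FALSE) {
  if (scenario$mode == "quantitative") {
    analyze_quantitative(scenario, db, registry, allow_missing)
  } else {
    analyze_qualitative(scenario, db, registry)
  }
}
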