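# Report rendering: deterministic plain-text tables for humans, full
# precision JSON for machines, and the JSON -> report inverse.

#' Render an analysis report
#'
#' Text output is a ranked table: alert classes first with "N.A." in the
#' Hazard Index column (additivity not applicable), then additive classes
#' by decreasing HI, risky rows (HI strictly above 100%) marked with `*`.
#' HIs are rounded to one decimal in text; JSON output carries full
#' precision and round-trips through [report_from_json()]. Rendering the
#' same report twice yields identical bytes.
#'
#' @param report A `hazmix_report`.
#' @param format `"text"` or `"json"`.
#' @return A character string (single element; embedded newlines for text).
#' @export
render_report <- function(report, format = c("text", "json")) {
  stopifnot(inherits(report, "hazmix_report"))
  format <- match.arg(format)
  if (format == "json") .render_json(report) else .render_text(report)
}

.render_json <- function(report) {
  cr <- lapply(report$class_results, function(r) {
    out <- list(class_id = r$class_id, name = r$name, additive = r$additive)
    if (report$mode == "quantitative") {
      out$hi_percent <- if (r$additive) .json_num(r$hi_percent) else NA_real_
      out$risky <- if (r$additive) r$risky else NA
      out$cas_list <- as.list(r$cas_list)
      if (r$additive) {
        out$contributions <- lapply(seq_len(nrow(r$contributions)),
          function(i) {
            ct <- r$contributions[i, ]
            list(cas = ct$cas, ratio_percent = .json_num(ct$ratio_percent),
                 oel_kind = ct$oel_kind, oel_value = .json_num(ct$oel_value),
                 oel_unit = ct$oel_unit, fallback = ct$fallback)
          })
      }
    } else {
      out$substance_count <- r$substance_count
      out$shared <- r$shared
      out$cas_list <- as.list(r$cas_list)
    }
    out
  })
  fin <- lapply(report$alert_findings, function(f) {
    list(class_id = f$class_id, cas_list = as.list(f$cas_list),
         message_key = f$message_key, informational = f$informational,
         message = f$message)
  })
  recs <- lapply(seq_len(nrow(report$scenario)), function(i) {
    r <- report$scenario[i, ]
    out <- list(cas = r$cas)
    if (!is.na(r$concentration)) {
      out$concentration <- .json_num(r$concentration)
      out$unit <- r$unit
    }
    out
  })
  obj <- list(
    mode = report$mode,
    jurisdiction = report$jurisdiction,
    oel_name = report$oel_name,
    any_risk = report$any_risk,
    any_alert = report$any_alert,
    scenario = recs,
    alert_findings = fin,
    class_results = cr,
    warnings = as.list(report$warnings)
  )
  .hazmix_json(obj)
}

.render_text <- function(report) {
  lines <- character(0)
  push <- function(...) lines <<- c(lines, sprintf(...))
  push("Mixture analysis report (%s mode)", report$mode)
  push("Database: %s (%s) | substances in scenario: %d",
       report$jurisdiction, report$oel_name, nrow(report$scenario))
  push("")
  if (length(report$alert_findings)) {
    push("Alert messages:")
    for (f in report$alert_findings) {
      push("  ! %s [%s: %s]%s", f$message, f$class_id,
           paste(f$cas_list, collapse = ", "),
           if (f$informational) " (informational)" else "")
    }
  } else {
    push("Alert messages: none")
  }
  if (report$mode == "quantitative") {
    push("Risk from multiple exposures (any Hazard Index > 100%%): %s",
         if (isTRUE(report$any_risk)) "YES" else "no")
  }
  push("")
  if (report$mode == "quantitative") {
    push("  %-36s %8s  %s", "Toxicological class", "HI (%)", "Substances")
    for (r in report$class_results) {
      mark <- if (isTRUE(r$risky)) "*" else " "
      hi <- if (r$additive) sprintf("%.1f", r$hi_percent) else "N.A."
      push("%s %-36s %8s  %s", mark, r$class_id, hi,
           paste(r$cas_list, collapse = ", "))
    }
  } else {
    push("  %-36s %8s %6s  %s", "Toxicological class", "HI (%)", "N",
         "Substances")
    for (r in report$class_results) {
      mark <- if (isTRUE(r$shared)) "+" else " "
      hi <- if (r$additive) ">0%" else "N.A."  # indexes not calculated
      push("%s %-36s %8s %6d  %s", mark, r$class_id, hi,
           r$substance_count, paste(r$cas_list, collapse = ", "))
    }
  }
  if (length(report$warnings)) {
    push("")
    push("Warnings:")
    for (w in report$warnings) push("  - %s", w)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Reconstruct a report from its JSON rendering
#'
#' Inverse of `render_report(report, "json")`: parsing the JSON yields a
#' `hazmix_report` equivalent to the original.
#'
#' @param json JSON string, or path to a JSON file.
#' @return A `hazmix_report`.
#' @export
report_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  lgl_or_na <- function(x) if (is.null(x)) NA else as.logical(x)
  chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  cr <- lapply(raw$class_results, function(r) {
    if (raw$mode == "quantitative") {
      if (isTRUE(r$additive)) {
        contributions <- if (length(r$contributions)) {
          do.call(rbind, lapply(r$contributions, function(ct) {
            data.frame(cas = ct$cas, ratio_percent = as.numeric(ct$ratio_percent),
                       oel_kind = ct$oel_kind,
                       oel_value = as.numeric(ct$oel_value),
                       oel_unit = ct$oel_unit,
                       fallback = chr_or_na(ct$fallback),
                       stringsAsFactors = FALSE)
          }))
        } else {
          data.frame(cas = character(0), ratio_percent = numeric(0),
                     oel_kind = character(0), oel_value = numeric(0),
                     oel_unit = character(0), fallback = character(0))
        }
        structure(list(class_id = r$class_id, name = r$name, additive = TRUE,
                       hi_percent = num_or_na(r$hi_percent),
                       risky = lgl_or_na(r$risky),
                       cas_list = as.character(unlist(r$cas_list)),
                       contributions = contributions),
                  class = "class_hi_result")
      } else {
        structure(list(class_id = r$class_id, name = r$name, additive = FALSE,
                       hi_percent = NA_real_, risky = NA,
                       cas_list = as.character(unlist(r$cas_list))),
                  class = "alert_class_result")
      }
    } else {
      structure(list(class_id = r$class_id, name = r$name,
                     additive = isTRUE(r$additive),
                     substance_count = as.integer(r$substance_count),
                     cas_list = as.character(unlist(r$cas_list)),
                     shared = isTRUE(r$shared)),
                class = "qualitative_class_result")
    }
  })
  fin <- lapply(raw$alert_findings, function(f) {
    list(class_id = f$class_id,
         cas_list = as.character(unlist(f$cas_list)),
         message_key = f$message_key,
         informational = isTRUE(f$informational), message = f$message)
  })
  scenario <- do.call(rbind, lapply(raw$scenario, function(r) {
    data.frame(cas = r$cas, concentration = num_or_na(r$concentration),
               unit = chr_or_na(r$unit), stringsAsFactors = FALSE)
  }))
  structure(
    list(mode = raw$mode, jurisdiction = raw$jurisdiction,
         oel_name = raw$oel_name, scenario = scenario,
         alert_findings = fin, class_results = cr,
         warnings = as.character(unlist(raw$warnings)),
         any_risk = lgl_or_na(raw$any_risk),
         any_alert = isTRUE(raw$any_alert)),
    class = "hazmix_report"
  )
}

#' @export
print.hazmix_report <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}
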