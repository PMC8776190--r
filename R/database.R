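#' Construct an occupational exposure limit value
#'
#' @param kind `"eight_hour"` (full-shift, time-weighted average — the value
#'   used for Hazard Index calculation whenever present), `"short_term"`
#'   (15 min) or `"ceiling"`.
#' @param value Strictly positive concentration magnitude.
#' @param unit `"mg_per_m3"`, `"ppm"` or `"fibers_per_cm3"`; always recorded
#'   explicitly.
#' @return An `oel_value` object.
#' @export
oel_value <- function(kind, value, unit) {
  kind <- match.arg(kind, .oel_kinds)
  unit <- match.arg(unit, .hazmix_units)
  value <- as.numeric(value)
  if (length(value) != 1L || is.na(value) || value <= 0) {
    stop("OEL value must be a single strictly positive number", call. = FALSE)
  }
  structure(list(kind = kind, value = value, unit = unit),
            class = "oel_value")
}

#' Construct a substance record
#'
#' @param cas CAS registry number (primary key). Must pass the check-digit
#'   rule ([validate_cas()]) unless `synthetic = TRUE`.
#' @param name Display name.
#' @param oels List of [oel_value()] entries, at most one per kind; may be
#'   empty (the substance is then usable in qualitative analysis only).
#' @param class_ids Toxicological class ids the substance activates; may be
#'   empty.
#' @param molecular_weight g/mol, `NA` when unknown. Needed only when a
#'   measured concentration and the OEL use different units.
#' @param synthetic `TRUE` for generated fixtures (exempts the CAS checksum).
#' @param evidence_notes Optional free-text provenance metadata (e.g. the
#'   human-within-5x-OEL / animal-within-100x-OEL literature criteria under
#'   which effects were linked); not interpreted.
#' @return A `substance` object.
#' @export
substance <- function(cas, name, oels = list(), class_ids = character(),
                      molecular_weight = NA_real_, synthetic = FALSE,
                      evidence_notes = NA_character_) {
  stopifnot(is.character(cas), length(cas) == 1L, nzchar(cas),
            is.character(name), length(name) == 1L, nzchar(name))
  oels <- lapply(oels, function(o) {
    if (!inherits(o, "oel_value")) o <- do.call(oel_value, o[c("kind", "value", "unit")])
    o
  })
  kinds <- vapply(oels, `[[`, character(1), "kind")
  if (anyDuplicated(kinds)) {
    stop("substance ", cas, ": more than one OEL of the same kind",
         call. = FALSE)
  }
  # canonical kind order, so written output is deterministic
  oels <- oels[order(match(kinds, .oel_kinds))]
  names(oels) <- vapply(oels, `[[`, character(1), "kind")
  structure(
    list(cas = cas, name = name, oels = oels,
         class_ids = sort(unique(as.character(class_ids))),
         molecular_weight = as.numeric(molecular_weight),
         synthetic = isTRUE(synthetic),
         evidence_notes = as.character(evidence_notes)),
    class = "substance"
  )
}

#' Construct a substance database
#'
#' @param substances List of [substance()] records; CAS keys must be unique.
#' @param jurisdiction Tag for the OEL set in force, e.g. `"FR"`, `"QC"`,
#'   `"synthetic"`.
#' @param oel_name Display label of the full-shift 8 h OEL in that
#'   jurisdiction ("VLEP-8h" in France, "VEMP" in Quebec).
#' @return A `substance_db` object; substances are keyed and sorted by CAS.
#' @export
substance_db <- function(substances, jurisdiction, oel_name = "OEL-8h") {
  stopifnot(is.list(substances),
            is.character(jurisdiction), nzchar(jurisdiction))
  stopifnot(all(vapply(substances, inherits, logical(1), "substance")))
  cas <- vapply(substances, `[[`, character(1), "cas")
  if (anyDuplicated(cas)) {
    stop("duplicate cas in database: ",
         paste(unique(cas[duplicated(cas)]), collapse = ", "), call. = FALSE)
  }
  substances <- substances[order(cas)]
  names(substances) <- sort(cas)
  structure(list(jurisdiction = jurisdiction, oel_name = oel_name,
                 substances = substances),
            class = "substance_db")
}

#' Per-record database diagnostics
#'
#' Checks every substance against the registry: CAS check digit (unless the
#' record is flagged synthetic), resolvable class ids, well-formed OELs.
#'
#' @param db A `substance_db`.
#' @param registry A `tox_registry`.
#' @return Character vector of human-readable diagnostics; empty when the
#'   database is fully valid.
#' @export
db_diagnostics <- function(db, registry = tox_registry()) {
  stopifnot(inherits(db, "substance_db"))
  known <- class_ids(registry)
  out <- character(0)
  for (s in db$substances) {
    if (!s$synthetic && !validate_cas(s$cas)) {
      out <- c(out, sprintf("substance %s: invalid CAS check digit", s$cas))
    }
    bad <- setdiff(s$class_ids, known)
    if (length(bad)) {
      out <- c(out, sprintf("substance %s: unknown class_id %s", s$cas,
                            paste(bad, collapse = ", ")))
    }
    for (o in s$oels) {
      if (!is.finite(o$value) || o$value <= 0) {
        out <- c(out, sprintf("substance %s: non-positive %s OEL",
                              s$cas, o$kind))
      }
    }
  }
  out
}

#' Select the OEL used for Hazard Index calculation
#'
#' The full-shift 8 h OEL is always chosen when available. When it is
#' absent the ceiling value is used, then the short-term (15 min) value,
#' each with a machine-readable fallback warning attached — a conservative
#' screening choice, since both bound the 8 h average from above.
#'
#' @param substance A `substance` with at least one OEL.
#' @return List with `oel` (an `oel_value`) and `fallback` (`NA_character_`
#'   when the 8 h value was used, otherwise a warning string).
#' @export
select_oel <- function(substance) {
  oels <- substance$oels
  if (length(oels) == 0L) {
    stop("no usable OEL for substance ", substance$cas, call. = FALSE)
  }
  if (!is.null(oels$eight_hour)) {
    return(list(oel = oels$eight_hour, fallback = NA_character_))
  }
  for (kind in c("ceiling", "short_term")) {
    if (!is.null(oels[[kind]])) {
      return(list(
        oel = oels[[kind]],
        fallback = sprintf("substance %s: no 8 h OEL; %s value used instead",
                           substance$cas, kind)
      ))
    }
  }
  stop("no usable OEL for substance ", substance$cas, call. = FALSE) # unreachable
}

# ---- readers / writers -----------------------------------------------------

#' Read a substance database
#'
#' JSON is the canonical dialect (one file). CSV is a two-file dialect:
#' `substances.csv` (cas, name, molecular_weight, synthetic, evidence_notes,
#' oel_kind, oel_value, oel_unit — one row per OEL, one empty-OEL row for
#' substances without any) and `classes.csv` (cas, class_id), both UTF-8
#' with a header row; `path` is then the directory holding the pair.
#'
#' The database is validated on load: unknown class ids, duplicate CAS keys
#' or failed CAS checksums raise an error naming the offending record.
#'
#' @param path JSON file path, or directory for the CSV dialect.
#' @param format `"json"` or `"csv"`.
#' @param registry Registry used for class-id validation.
#' @return A validated `substance_db`.
#' @seealso [write_substance_db()] — `read` after `write` is the identity.
#' @export
read_substance_db <- function(path, format = c("json", "csv"),
                              registry = tox_registry()) {
  format <- match.arg(format)
  db <- if (format == "json") .read_db_json(path) else .read_db_csv(path)
  diag <- db_diagnostics(db, registry)
  if (length(diag)) {
    stop("invalid substance database:\n  ", paste(diag, collapse = "\n  "),
         call. = FALSE)
  }
  db
}

#' Write a substance database
#'
#' Output is canonical: substances sorted by CAS, object keys in fixed
#' order, so that writing the same database twice is byte-identical and
#' `read_substance_db()` after `write_substance_db()` reconstructs an equal
#' object.
#'
#' @param db A `substance_db`.
#' @param path JSON file path, or directory for the CSV dialect (created if
#'   missing).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_substance_db <- function(db, path, format = c("json", "csv")) {
  stopifnot(inherits(db, "substance_db"))
  format <- match.arg(format)
  if (format == "json") .write_db_json(db, path) else .write_db_csv(db, path)
  invisible(path)
}

.read_db_json <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  for (f in c("jurisdiction", "oel_name", "substances")) {
    if (is.null(raw[[f]])) {
      stop("database JSON missing required field '", f, "'", call. = FALSE)
    }
  }
  subs <- lapply(seq_along(raw$substances), function(i) {
    r <- raw$substances[[i]]
    if (is.null(r$cas) || is.null(r$name)) {
      stop("database record ", i, ": missing cas or name", call. = FALSE)
    }
    oels <- lapply(names(r$oels %||% list()), function(kind) {
      o <- r$oels[[kind]]
      if (is.null(o$value) || is.null(o$unit)) {
        stop("substance ", r$cas, ": OEL '", kind,
             "' missing value or unit", call. = FALSE)
      }
      oel_value(kind, o$value, o$unit)
    })
    substance(
      cas = r$cas, name = r$name, oels = oels,
      class_ids = as.character(unlist(r$class_ids)),
      molecular_weight = r$molecular_weight %||% NA_real_,
      synthetic = isTRUE(r$synthetic),
      evidence_notes = r$evidence_notes %||% NA_character_
    )
  })
  substance_db(subs, jurisdiction = raw$jurisdiction,
               oel_name = raw$oel_name)
}

.write_db_json <- function(db, path) {
  subs <- lapply(db$substances, function(s) {
    rec <- list(cas = s$cas, name = s$name)
    if (!is.na(s$molecular_weight)) {
      rec$molecular_weight <- .json_num(s$molecular_weight)
    }
    rec$synthetic <- s$synthetic
    rec$oels <- lapply(s$oels,
                       function(o) list(value = .json_num(o$value),
                                        unit = o$unit))
    if (length(rec$oels) == 0L) rec$oels <- stats::setNames(list(), character(0))
    rec$class_ids <- s$class_ids
    if (!is.na(s$evidence_notes)) rec$evidence_notes <- s$evidence_notes
    rec
  })
  out <- list(jurisdiction = db$jurisdiction, oel_name = db$oel_name,
              substances = unname(subs))
  writeLines(.hazmix_json(out), path, useBytes = TRUE)
}

.read_db_csv <- function(path) {
  sub_file <- file.path(path, "substances.csv")
  cls_file <- file.path(path, "classes.csv")
  meta_file <- file.path(path, "database.json")
  for (f in c(sub_file, cls_file)) {
    if (!file.exists(f)) stop("CSV dialect file not found: ", f, call. = FALSE)
  }
  st <- utils::read.csv(sub_file, colClasses = "character")
  need <- c("cas", "name", "molecular_weight", "synthetic", "evidence_notes",
            "oel_kind", "oel_value", "oel_unit")
  if (!all(need %in% names(st))) {
    stop("substances.csv must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  links <- utils::read.csv(cls_file, colClasses = "character")
  if (!all(c("cas", "class_id") %in% names(links))) {
    stop("classes.csv must have columns: cas, class_id", call. = FALSE)
  }
  meta <- if (file.exists(meta_file)) {
    jsonlite::fromJSON(meta_file, simplifyVector = FALSE)
  } else {
    list(jurisdiction = "unknown", oel_name = "OEL-8h")
  }
  subs <- lapply(split(st, st$cas), function(rows) {
    r1 <- rows[1L, ]
    has_oel <- nzchar(rows$oel_kind)
    oels <- lapply(which(has_oel), function(i) {
      oel_value(rows$oel_kind[i], as.numeric(rows$oel_value[i]),
                rows$oel_unit[i])
    })
    substance(
      cas = r1$cas, name = r1$name, oels = oels,
      class_ids = links$class_id[links$cas == r1$cas],
      molecular_weight = ifelse(nzchar(r1$molecular_weight),
                                as.numeric(r1$molecular_weight), NA_real_),
      synthetic = identical(r1$synthetic, "TRUE"),
      evidence_notes = ifelse(nzchar(r1$evidence_notes), r1$evidence_notes,
                              NA_character_)
    )
  })
  substance_db(unname(subs), jurisdiction = meta$jurisdiction,
               oel_name = meta$oel_name)
}

.write_db_csv <- function(db, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  rows <- do.call(rbind, c(lapply(db$substances, function(s) {
    base <- data.frame(
      cas = s$cas, name = s$name,
      molecular_weight = ifelse(is.na(s$molecular_weight), "",
                                .num_str(s$molecular_weight)),
      synthetic = as.character(s$synthetic),
      evidence_notes = ifelse(is.na(s$evidence_notes), "", s$evidence_notes),
      stringsAsFactors = FALSE
    )
    if (length(s$oels) == 0L) {
      cbind(base, oel_kind = "", oel_value = "", oel_unit = "")
    } else {
      do.call(rbind, lapply(s$oels, function(o) {
        cbind(base, oel_kind = o$kind,
              oel_value = .num_str(o$value), oel_unit = o$unit)
      }))
    }
  }), list(make.row.names = FALSE)))
  links <- do.call(rbind, c(lapply(db$substances, function(s) {
    if (length(s$class_ids) == 0L) return(NULL)
    data.frame(cas = s$cas, class_id = s$class_ids, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  if (is.null(links)) {
    links <- data.frame(cas = character(0), class_id = character(0))
  }
  utils::write.csv(rows, file.path(path, "substances.csv"), row.names = FALSE)
  utils::write.csv(links, file.path(path, "classes.csv"), row.names = FALSE)
  meta <- jsonlite::toJSON(list(jurisdiction = db$jurisdiction,
                                oel_name = db$oel_name),
                           auto_unbox = TRUE, pretty = 2)
  writeLines(meta, file.path(path, "database.json"), useBytes = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.substance_db <- function(x, ...) {
  cat(sprintf("Substance database [%s, %s]: %d substances\n",
              x$jurisdiction, x$oel_name, length(x$substances)))
  invisible(x)
}

#' @export
print.substance <- function(x, ...) {
  cat(sprintf("%s (%s)%s\n", x$name, x$cas,
              if (x$synthetic) " [synthetic]" else ""))
  for (o in x$oels) {
    cat(sprintf("  OEL %-10s %g %s\n", o$kind, o$value, o$unit))
  }
  cat("  classes:", if (length(x$class_ids)) paste(x$class_ids, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
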