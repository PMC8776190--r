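#' Construct a mixture exposure scenario
#'
#' A scenario is the work situation to assess: the substances present,
#' with, in quantitative mode, the atmospheric concentration measured for
#' each. In qualitative mode (no measurements available) only class
#' activation and sharing are analysed.
#'
#' @param cas Character vector of substance CAS keys (unique).
#' @param concentration Numeric vector of measured concentrations (>= 0),
#'   `NA` where unmeasured; recycled `NA` if omitted.
#' @param unit Concentration units, one of `"ppm"`, `"mg_per_m3"`,
#'   `"fibers_per_cm3"` per record; required wherever `concentration` is
#'   given.
#' @param mode `"quantitative"` or `"qualitative"`. Default: quantitative
#'   when every record carries a concentration, qualitative otherwise.
#' @param allow_missing Permit missing concentrations in quantitative mode;
#'   the analysis then drops those substances from Hazard Index sums with a
#'   warning and the indexes are lower bounds.
#' @return A `mixture_scenario`: list with `records` (data frame `cas`,
#'   `concentration`, `unit`) and `mode`.
#' @export
mixture_scenario <- function(cas, concentration = NULL, unit = NULL,
                             mode = NULL, allow_missing = FALSE) {
  cas <- as.character(cas)
  if (length(cas) == 0L) stop("scenario must list at least one substance",
                              call. = FALSE)
  if (anyDuplicated(cas)) {
    stop("duplicate cas in scenario: ",
         paste(unique(cas[duplicated(cas)]), collapse = ", "), call. = FALSE)
  }
  n <- length(cas)
  concentration <- if (is.null(concentration)) rep(NA_real_, n) else
    as.numeric(concentration)
  unit <- if (is.null(unit)) rep(NA_character_, n) else as.character(unit)
  stopifnot(length(concentration) == n, length(unit) == n)
  has_c <- !is.na(concentration)
  if (any(concentration[has_c] < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (any(has_c & is.na(unit))) {
    stop("every concentration must carry an explicit unit", call. = FALSE)
  }
  bad_unit <- !is.na(unit) & !unit %in% .hazmix_units
  if (any(bad_unit)) {
    stop("unknown concentration unit: ",
         paste(unique(unit[bad_unit]), collapse = ", "), call. = FALSE)
  }
  if (is.null(mode)) {
    mode <- if (all(has_c)) "quantitative" else "qualitative"
  }
  mode <- match.arg(mode, c("quantitative", "qualitative"))
  if (mode == "quantitative" && !allow_missing && !all(has_c)) {
    stop("quantitative scenario with missing concentrations for: ",
         paste(cas[!has_c], collapse = ", "),
         " (use allow_missing = TRUE to drop them with a warning)",
         call. = FALSE)
  }
  structure(
    list(records = data.frame(cas = cas, concentration = concentration,
                              unit = unit, stringsAsFactors = FALSE),
         mode = mode),
    class = "mixture_scenario"
  )
}

#' Read a scenario file
#'
#' CSV: columns `cas`, `concentration`, `unit` (the latter two optional or
#' blank for qualitative records). JSON: object with optional `mode` and
#' `records` array of `{cas, concentration?, unit?}`. Mode is inferred
#' (all concentrations present implies quantitative) unless given here or
#' in the JSON.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guesses from the extension.
#' @param mode Optional explicit mode override.
#' @param allow_missing See [mixture_scenario()].
#' @return A `mixture_scenario`.
#' @export
read_scenario <- function(path, format = NULL, mode = NULL,
                          allow_missing = FALSE) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character")
    if (!"cas" %in% names(df)) {
      stop("scenario CSV must have a 'cas' column", call. = FALSE)
    }
    conc <- if ("concentration" %in% names(df)) {
      suppressWarnings(as.numeric(ifelse(nzchar(df$concentration),
                                         df$concentration, NA)))
    } else NULL
    unit <- if ("unit" %in% names(df)) {
      ifelse(nzchar(df$unit), df$unit, NA_character_)
    } else NULL
    mixture_scenario(df$cas, conc, unit, mode = mode,
                     allow_missing = allow_missing)
  } else {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    recs <- raw$records %||% raw
    cas <- vapply(recs, function(r) as.character(r$cas), character(1))
    conc <- vapply(recs, function(r) as.numeric(r$concentration %||% NA_real_),
                   numeric(1))
    unit <- vapply(recs, function(r) as.character(r$unit %||% NA_character_),
                   character(1))
    mixture_scenario(cas, conc, unit,
                     mode = mode %||% raw$mode %||% NULL,
                     allow_missing = allow_missing)
  }
}

#' Write a scenario to CSV or JSON
#'
#' @param scenario A `mixture_scenario`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path, format = NULL) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- scenario$records
    df$concentration <- ifelse(is.na(df$concentration), "",
                               .num_str(df$concentration))
    df$unit <- ifelse(is.na(df$unit), "", df$unit)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(scenario$records)), function(i) {
      r <- scenario$records[i, ]
      out <- list(cas = r$cas)
      if (!is.na(r$concentration)) {
        out$concentration <- .json_num(r$concentration)
        out$unit <- r$unit
      }
      out
    })
    writeLines(.hazmix_json(list(mode = scenario$mode, records = recs)),
               path, useBytes = TRUE)
  }
  invisible(path)
}

#' @export
print.mixture_scenario <- function(x, ...) {
  cat(sprintf("Mixture scenario (%s): %d substances\n", x$mode,
              nrow(x$records)))
  print(x$records)
  invisible(x)
}
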