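`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force implementations used to cross-check the engine.
# These deliberately share no code with the package internals.

# Sum of 100 * C / OEL over scenario substances activating class_id,
# written as a direct transcription of the Hazard Index definition.
oracle_class_hi <- function(scenario, db, class_id) {
  total <- 0
  for (i in seq_len(nrow(scenario$records))) {
    r <- scenario$records[i, ]
    s <- db$substances[[r$cas]]
    if (!(class_id %in% s$class_ids)) next
    o <- s$oels[["eight_hour"]]
    if (is.null(o)) o <- s$oels[["ceiling"]]
    if (is.null(o)) o <- s$oels[["short_term"]]
    if (is.null(o)) next
    conc <- r$concentration
    if (is.na(conc)) next
    if (r$unit != o$unit) {
      conc <- if (r$unit == "ppm") conc * s$molecular_weight / 24.45
              else conc * 24.45 / s$molecular_weight
    }
    total <- total + 100 * conc / o$value
  }
  total
}

# All class ids activated by >= 1 scenario substance.
oracle_activated <- function(scenario, db) {
  sort(unique(unlist(lapply(scenario$records$cas,
                            function(cas) db$substances[[cas]]$class_ids))))
}

# Check-digit rule computed from scratch on the hyphenless digit string.
oracle_cas_check <- function(cas) {
  if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)) return(FALSE)
  d <- as.integer(strsplit(gsub("-", "", cas), "")[[1]])
  n <- length(d)
  (sum(d[seq_len(n - 1)] * rev(seq_len(n - 1))) %% 10) == d[n]
}

# Small hand-built database: three substances spanning both alert classes,
# a shared additive class, and a fallback-only OEL.
tiny_db <- function() {
  substance_db(list(
    substance("100-41-4", "ethylbenzene",
              oels = list(oel_value("eight_hour", 100, "ppm")),
              class_ids = c("central_nervous_system_damage", "ocular_damage",
                            "carcinogenicity_mutagenicity"),
              molecular_weight = 106.17),
    substance("71-43-2", "benzene",
              oels = list(oel_value("eight_hour", 1, "ppm")),
              class_ids = c("central_nervous_system_damage",
                            "hematopoietic_system_disruption",
                            "carcinogenicity_mutagenicity"),
              molecular_weight = 78.11),
    substance("50-00-0", "formaldehyde",
              oels = list(oel_value("ceiling", 0.3, "ppm")),
              class_ids = c("upper_airway_damage", "ocular_damage",
                            "sensitization"),
              molecular_weight = 30.03)
  ), jurisdiction = "synthetic", oel_name = "OEL-8h")
}
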