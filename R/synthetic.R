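# Synthetic databases and scenarios. The real 700+-substance corpus behind
# national OEL regulations is not redistributable, so generated stand-ins
# (flagged synthetic, with valid CAS check digits drawn from a high
# unassigned-looking range) exercise every engine path.

.with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic database generator
#'
#' @param n_substances Number of substances to generate.
#' @param seed Integer seed; the same spec always yields the identical
#'   database.
#' @param class_density Probability that a substance activates each
#'   additive class, independently. Default 0.15 gives a realistic 2-3
#'   classes per substance across the 18 additive classes.
#' @param alert_density Probability per non-additive (alert) class;
#'   default 0.05, alert memberships being much rarer.
#' @param oel_range Named list of `c(min, max)` OEL magnitudes per unit.
#' @param p_missing_oel Probability a substance has no OEL at all
#'   (qualitative-only entry).
#' @param p_fallback_only Probability that a substance with OELs lacks the
#'   8 h value and lists only a ceiling or short-term one (exercises the
#'   fallback path).
#' @param p_missing_mw Probability the molecular weight is unrecorded.
#' @param concentration_regime Range of target concentration-to-OEL ratios
#'   for generated scenarios; default uniform on [0, 1.5] straddles the
#'   single-substance limit.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_substances, seed = 1L,
                           class_density = 0.15, alert_density = 0.05,
                           oel_range = list(ppm = c(1, 500),
                                            mg_per_m3 = c(0.1, 50)),
                           p_missing_oel = 0.05, p_fallback_only = 0.1,
                           p_missing_mw = 0.1,
                           concentration_regime = c(0, 1.5)) {
  probs <- c(class_density, alert_density, p_missing_oel, p_fallback_only,
             p_missing_mw)
  stopifnot(n_substances >= 1, all(probs >= 0 & probs <= 1),
            all(unlist(oel_range) > 0))
  structure(list(n_substances = as.integer(n_substances),
                 seed = as.integer(seed),
                 class_density = class_density,
                 alert_density = alert_density, oel_range = oel_range,
                 p_missing_oel = p_missing_oel,
                 p_fallback_only = p_fallback_only,
                 p_missing_mw = p_missing_mw,
                 concentration_regime = concentration_regime),
            class = "generator_spec")
}

#' Generate a synthetic substance database
#'
#' Substances carry CAS-shaped identifiers with correct check digits,
#' drawn from a high 7-digit range to avoid colliding with real registry
#' entries, and are flagged `synthetic`. Class memberships are independent
#' Bernoulli draws per class at the spec's densities. The output passes
#' full database validation and is byte-stable under its seed.
#'
#' @param spec A [generator_spec()].
#' @param registry A `tox_registry`.
#' @return A `substance_db` with `jurisdiction = "synthetic"`.
#' @export
generate_substance_db <- function(spec, registry = tox_registry()) {
  stopifnot(inherits(spec, "generator_spec"))
  add_ids <- class_ids(registry, additive = TRUE)
  alert_ids <- class_ids(registry, additive = FALSE)
  .with_seed(spec$seed, {
    n <- spec$n_substances
    bodies <- sprintf("%07d%02d",
                      sample(9000000:9999999, n),
                      sample(0:99, n, replace = TRUE))
    subs <- lapply(seq_len(n), function(i) {
      oels <- list()
      if (stats::runif(1) >= spec$p_missing_oel) {
        unit <- sample(names(spec$oel_range), 1L,
                       prob = c(0.7, 0.3)[seq_along(spec$oel_range)])
        rng <- spec$oel_range[[unit]]
        val <- round(stats::runif(1, rng[1], rng[2]), 3)
        if (stats::runif(1) < spec$p_fallback_only) {
          kind <- sample(c("ceiling", "short_term"), 1L)
          oels <- list(oel_value(kind, val, unit))
        } else {
          oels <- list(oel_value("eight_hour", val, unit))
          if (stats::runif(1) < 0.3) {
            oels <- c(oels, list(oel_value("short_term",
                                           round(val * 3, 3), unit)))
          }
        }
      }
      picks <- c(add_ids[stats::runif(length(add_ids)) < spec$class_density],
                 alert_ids[stats::runif(length(alert_ids)) < spec$alert_density])
      substance(
        cas = cas_from_body(bodies[i]),
        name = sprintf("synthetic substance %04d", i),
        oels = oels,
        class_ids = picks,
        molecular_weight = if (stats::runif(1) < spec$p_missing_mw) NA_real_
                           else round(stats::runif(1, 30, 300), 2),
        synthetic = TRUE,
        evidence_notes = "generated fixture; not a regulatory value"
      )
    })
    substance_db(subs, jurisdiction = "synthetic", oel_name = "OEL-8h")
  })
}

#' Generate an exposure scenario from a database
#'
#' Selects `n_selected` substances without replacement and, when a
#' concentration regime is given, assigns each a concentration such that
#' its concentration-to-OEL ratio is drawn uniformly from the regime (in
#' the unit of the substance's selected OEL, so no conversion noise).
#' Substances without any OEL are not eligible for quantitative selection.
#' With `regime = NULL` a qualitative scenario (no concentrations) is
#' produced and all substances are eligible.
#'
#' @param db A `substance_db`.
#' @param n_selected Number of substances to put in the mixture.
#' @param regime `c(min, max)` ratio range, a single fixed ratio, or
#'   `NULL` for a qualitative scenario.
#' @param seed Integer seed.
#' @return A `mixture_scenario`.
#' @export
generate_scenario <- function(db, n_selected, regime = c(0, 1.5),
                              seed = 1L) {
  stopifnot(inherits(db, "substance_db"))
  eligible <- if (is.null(regime)) {
    names(db$substances)
  } else {
    names(db$substances)[vapply(db$substances,
                                function(s) length(s$oels) > 0L, logical(1))]
  }
  if (n_selected > length(eligible)) {
    stop("n_selected (", n_selected, ") exceeds the ", length(eligible),
         " eligible substances in the database", call. = FALSE)
  }
  .with_seed(seed, {
    cas <- sort(sample(eligible, n_selected))
    if (is.null(regime)) {
      return(mixture_scenario(cas, mode = "qualitative"))
    }
    ratios <- if (length(regime) == 1L) rep(regime, n_selected)
              else stats::runif(n_selected, regime[1], regime[2])
    conc <- numeric(n_selected)
    unit <- character(n_selected)
    for (i in seq_along(cas)) {
      sel <- select_oel(db$substances[[cas[i]]])
      conc[i] <- ratios[i] * sel$oel$value
      unit[i] <- sel$oel$unit
    }
    mixture_scenario(cas, conc, unit, mode = "quantitative")
  })
}

#' Printing-workstation case-study fixture
#'
#' A packaged reconstruction of a four-solvent maintenance-operation
#' co-exposure: methyl ethyl ketone (MEK), methyl isobutyl ketone (MIBK),
#' toluene and trichloroethylene. All four share the central nervous
#' system, ocular, skin and ototoxicity classes; MEK and toluene
#' additionally activate the developmental-damage alert class, MIBK and
#' trichloroethylene the carcinogenicity/mutagenicity alert class, and
#' toluene and trichloroethylene the hepatic class. Concentrations are
#' chosen so that every individual concentration stays below its
#' substance's OEL (ratios 0.45, 0.30, 0.40, 0.25) while the four shared
#' additive classes reach a Hazard Index of 140% — the situation additive
#' screening reveals and single-substance screening misses. The CAS
#' numbers are the real registry entries; OELs and concentrations are
#' synthetic illustrative values, not regulatory ones.
#'
#' @return List with `db` (a `substance_db`) and `scenario` (a
#'   quantitative `mixture_scenario`).
#' @export
case_study_fixture <- function() {
  shared <- c("central_nervous_system_damage", "ocular_damage",
              "skin_damage", "ototoxicity")
  note <- "synthetic illustrative OEL; not a regulatory value"
  db <- substance_db(list(
    substance("78-93-3", "methyl ethyl ketone (MEK)",
              oels = list(oel_value("eight_hour", 200, "ppm"),
                          oel_value("short_term", 300, "ppm")),
              class_ids = c(shared, "developmental_damage"),
              molecular_weight = 72.11, evidence_notes = note),
    substance("108-10-1", "methyl isobutyl ketone (MIBK)",
              oels = list(oel_value("eight_hour", 20, "ppm")),
              class_ids = c(shared, "carcinogenicity_mutagenicity"),
              molecular_weight = 100.16, evidence_notes = note),
    substance("108-88-3", "toluene",
              oels = list(oel_value("eight_hour", 20, "ppm"),
                          oel_value("short_term", 100, "ppm")),
              class_ids = c(shared, "developmental_damage", "hepatic_damage"),
              molecular_weight = 92.14, evidence_notes = note),
    substance("79-01-6", "trichloroethylene",
              oels = list(oel_value("eight_hour", 10, "ppm")),
              class_ids = c(shared, "carcinogenicity_mutagenicity",
                            "hepatic_damage"),
              molecular_weight = 131.39, evidence_notes = note)
  ), jurisdiction = "synthetic", oel_name = "OEL-8h")
  # ratios 0.45, 0.30, 0.40, 0.25 of the respective 8 h OELs
  scenario <- mixture_scenario(
    cas = c("78-93-3", "108-10-1", "108-88-3", "79-01-6"),
    concentration = c(90, 6, 8, 2.5),
    unit = rep("ppm", 4),
    mode = "quantitative"
  )
  list(db = db, scenario = scenario)
}
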