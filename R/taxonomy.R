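#' Built-in registry of the 24 toxicological classes
#'
#' Returns the fixed taxonomy used by the mixture engine: 24 toxicological
#' classes grouping toxic effects by target organ or mode of action. Six
#' classes are non-additive "alert" classes (endocrine disruption, male and
#' female reproductive system damage, developmental damage, carcinogenicity
#' and/or mutagenicity, and sensitization): any exposure to a substance in
#' one of these classes triggers a warning, and no Hazard Index is computed
#' for them.
#'
#' The registry is embedded in the package and identical across calls.
#'
#' @return A `tox_registry` object: a list with element `classes`, a named
#'   list of `tox_class` entries, each a list with fields `class_id`,
#'   `name`, `additive` (logical; `FALSE` marks an alert class) and
#'   `effects` (character vector of associated toxic effects; empty only
#'   for stimulation of basal metabolism).
#' @examples
#' reg <- tox_registry()
#' length(reg$classes)                                  # 24
#' sum(!vapply(reg$classes, `[[`, TRUE, "additive"))    # 6 alert classes
#' @export
tox_registry <- function() {
  .hazmix_registry
}

new_tox_class <- function(class_id, name, additive, effects) {
  stopifnot(nzchar(class_id), nzchar(name), is.logical(additive))
  structure(
    list(class_id = class_id, name = name, additive = additive,
         effects = as.character(effects)),
    class = "tox_class"
  )
}

# The taxonomy, transcribed row by row. Effects are kept verbatim; the
# basal-metabolism class legitimately has none.
.build_registry <- function() {
  cl <- list(
    new_tox_class("ocular_damage", "Ocular damage", TRUE,
      c("Cataract", "Eye irritation", "Corneal edema", "Corneal necrosis")),
    new_tox_class("cardiovascular_damage", "Cardiovascular damage", TRUE,
      c("Cardiac damage", "Vascular system impairment", "Vasoconstriction",
        "Vasodilatation", "Other cardiovascular damage")),
    new_tox_class("upper_airway_damage", "Upper airway damage", TRUE,
      c("Upper airway irritation", "Perforation of the nasal septum",
        "Other upper airway damage")),
    new_tox_class("autonomic_nervous_system_damage",
      "Autonomic nervous system damage", TRUE,
      c("Cholinesterase inhibition", "Muscular stimulation",
        "Other autonomic nervous system damage")),
    new_tox_class("lower_airway_damage", "Lower airway damage", TRUE,
      c("Berylliosis", "Bronchitis", "Bronchopneumonia",
        "Pulmonary emphysema", "Pulmonary fibrosis", "Brazier's disease",
        "Lower airway irritation", "Pulmonary edema", "Pneumoconiosis",
        "Other lower airway damage")),
    new_tox_class("oxygen_transport_disruption",
      "Disruption of oxygen transport", TRUE,
      c("Anemia", "Asphyxia", "Carboxyhemoglobinemia",
        "Blood-forming system disorder", "Hemolysis",
        "Cytochrome oxidase inhibition", "Heme synthesis inhibition",
        "Methemoglobinemia")),
    new_tox_class("central_nervous_system_damage",
      "Central nervous system damage", TRUE,
      c("Central nervous system convulsion",
        "Central nervous system depression",
        "Other central nervous system damage")),
    new_tox_class("peripheral_nervous_system_damage",
      "Peripheral nervous system damage", TRUE,
      c("Peripheral neuropathy", "Other peripheral nervous system damage")),
    new_tox_class("hematopoietic_system_disruption",
      "Hematopoietic system disruption", TRUE,
      c("Agranulocytosis", "Anemia", "Medullar aplasia", "Leukopenia",
        "Neutropenia", "Pancytopenia", "Thrombocytosis", "Thrombopenia",
        "Blood coagulation disorder")),
    new_tox_class("ototoxicity", "Ototoxicity", TRUE,
      c("Cochlear damage", "Auditory nerve damage", "Vestibular damage",
        "Hyperacusis")),
    new_tox_class("metabolic_acidosis", "Metabolic acidosis", TRUE,
      "Metabolic acidosis"),
    new_tox_class("basal_metabolism_stimulation",
      "Stimulation of basal metabolism", TRUE, character(0)),
    new_tox_class("dental_or_bone_damage", "Dental or bone damage", TRUE,
      c("Bone damage", "Skeletal fluorosis", "Dental erosion",
        "Other dental or bone damage")),
    new_tox_class("skin_damage", "Skin damage", TRUE,
      c("Alopecia", "Chloracne", "Skin irritation",
        "Other skin damage (except sensitization)")),
    new_tox_class("endocrine_disruption", "Endocrine disrupter", FALSE,
      c("Antithyroid effect", "Other endocrine disrupter effect")),
    new_tox_class("male_reproductive_damage",
      "Male reproductive system damage", FALSE,
      c("Testicular damage", "Impairment of male fertility",
        "Other male reproductive system damage")),
    new_tox_class("immune_system_damage", "Immune system damage", TRUE,
      "Immune system damage"),
    new_tox_class("female_reproductive_damage",
      "Female reproductive system damage", FALSE,
      c("Ovarian damage", "Impairment of female fertility",
        "Other female reproductive system damage")),
    new_tox_class("hepatic_damage", "Hepatic damage", TRUE,
      c("Liver necrosis", "Other hepatic damage")),
    new_tox_class("spleen_damage", "Spleen damage", TRUE, "Spleen damage"),
    new_tox_class("developmental_damage", "Developmental damage", FALSE,
      c("Embryonic damage", "Fetal damage", "Teratogenic effect",
        "Effect on offspring", "Mutagenic effect on germ cells",
        "Effect on offspring behavior", "Other developmental damage")),
    new_tox_class("carcinogenicity_mutagenicity",
      "Carcinogenicity and/or mutagenicity", FALSE,
      c("Bladder cancer", "Blood vessel cancer", "Laryngeal cancer",
        "Leukemia", "Liver cancer", "Lung cancer", "Mesothelioma",
        "Nasal cancer", "Nasopharyngeal cancer", "Prostate cancer",
        "Renal cancer", "Stomach cancer", "Sinonasal cancer", "Skin cancer",
        "Testicular cancer", "Upper respiratory tract cancer",
        "Mutagenic effect")),
    new_tox_class("kidney_damage", "Kidney damage", TRUE,
      c("Glomerular damage", "Tubular damage", "Bladder damage",
        "Other kidney damage")),
    new_tox_class("sensitization", "Sensitization (skin or respiratory)",
      FALSE,
      c("Asthma", "Respiratory sensitization", "Contact dermatitis",
        "Skin sensitization"))
  )
  names(cl) <- vapply(cl, `[[`, character(1), "class_id")
  stopifnot(!anyDuplicated(names(cl)))
  structure(list(classes = cl), class = "tox_registry")
}

.hazmix_registry <- .build_registry()

#' Look up a toxicological class by id
#'
#' @param class_id Class identifier token, e.g. `"ocular_damage"`.
#' @param registry A `tox_registry`, by default the built-in one.
#' @return The `tox_class` entry.
#' @export
tox_class <- function(class_id, registry = tox_registry()) {
  cls <- registry$classes[[class_id]]
  if (is.null(cls)) {
    stop("unknown toxicological class id: ", class_id, call. = FALSE)
  }
  cls
}

#' Class ids of a registry
#'
#' @param registry A `tox_registry`.
#' @param additive `NULL` for all classes, `TRUE` for additive classes only,
#'   `FALSE` for alert (non-additive) classes only.
#' @return Character vector of class ids, in registry order.
#' @export
class_ids <- function(registry = tox_registry(), additive = NULL) {
  add <- vapply(registry$classes, `[[`, logical(1), "additive")
  ids <- names(registry$classes)
  if (is.null(additive)) ids else ids[add == additive]
}

#' Tabulate the taxonomy
#'
#' @param x A `tox_registry`.
#' @param ... Unused.
#' @return A data frame with one row per class: `class_id`, `name`,
#'   `additive`, `n_effects`.
#' @export
as.data.frame.tox_registry <- function(x, ...) {
  data.frame(
    class_id = names(x$classes),
    name = vapply(x$classes, `[[`, character(1), "name"),
    additive = vapply(x$classes, `[[`, logical(1), "additive"),
    n_effects = vapply(x$classes, function(c) length(c$effects), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.tox_registry <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Toxicological class registry: %d classes (%d alert)\n",
              nrow(df), sum(!df$additive)))
  mark <- ifelse(df$additive, " ", "#")
  cat(sprintf(" %s %-32s %s\n", mark, df$class_id,
              vapply(x$classes, `[[`, character(1), "name")), sep = "")
  invisible(x)
}
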