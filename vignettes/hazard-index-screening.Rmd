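---
title: "Additive Hazard Index screening for chemical mixtures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive Hazard Index screening for chemical mixtures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazmix)
```

## The screening problem

Workers are routinely exposed to several airborne chemicals at once, yet
regulatory compliance is usually judged one substance at a time against its
occupational exposure limit (OEL) — the full-shift, 8 h time-weighted
airborne concentration limit ("VLEP-8h" in France, "VEMP" in Québec).
Substance-by-substance screening misses situations where no single
substance exceeds its limit but several of them stress the same target
organ. Industrial-hygiene bodies (ACGIH, EPA) recommend treating
substances with a similar toxicological effect as dose-additive in the
absence of interaction data, and that default is what this package
implements.

`hazmix` groups toxic effects into 24 toxicological classes by target
organ or mode of action. For each class shared by the substances in a
mixture, it computes the additive **Hazard Index**

$$\mathrm{HI} = \left(\frac{C_1}{\mathrm{OEL}_1} + \frac{C_2}{\mathrm{OEL}_2}
 + \cdots + \frac{C_n}{\mathrm{OEL}_n}\right) \times 100\,\%$$

over the substances activating that class, where $C_i$ is the measured
atmospheric concentration. A class is flagged **risky when HI exceeds
100% strictly**: HI = 100.0 exactly is at the limit, not over it, and the
package keeps that boundary semantics deliberately (the flag flips between
100 and the next representable measurement, which is what a screening
threshold phrased as "greater than 100%" means).

Six of the 24 classes are **non-additive alert classes**: endocrine
disruption, male and female reproductive system damage, developmental
damage, carcinogenicity and/or mutagenicity, and sensitization. Summing
exposure ratios is not meaningful for these mechanisms, and exposure
minimisation rules (any carcinogen exposure must be reduced regardless of
compliance) preempt an index. Any activation of an alert class therefore
produces a warning finding instead of an HI, and alert classes are listed
first in every report with "N.A." in the index column.

One additive class gets special messaging: **ototoxicity**. Reports emit
an informational note whenever it is activated, because noise co-exposure
is a common aggravating factor for ototoxic solvents; the note is marked
`informational` and plays no part in alert ranking or the `any_alert`
flag, since the class itself remains additive and keeps its HI.

## Modes of analysis

* **Quantitative** — every scenario record carries a measured
  concentration; per-class HIs are computed and ranked decreasingly,
  alert classes first. `any_risk` is true iff some HI > 100%.
* **Qualitative** — no measurements available; each activated class is
  reported with the count of activating substances, classes shared by two
  or more substances are flagged, and ranking is by decreasing count.
  Per-substance ratios are rendered as unknown markers (`>0%`), never as
  numbers. Alert detection is identical in both modes, and both modes
  activate exactly the same class set for a given substance list — a
  property the test suite checks.

The `any_risk` and `any_alert` flags are reported separately rather than
merged into one composite banner: whether an alert class alone makes a
situation "risky" is a policy question, so the package exposes both facts
and lets the caller combine them (the command-line interface exits 2 on
either).

## OEL selection and units

The 8 h OEL is always used for the HI when present. When a substance
lists only short-term (15 min) or ceiling values, the package falls back
to **ceiling, then short-term**, attaching a machine-readable warning to
every affected result. This is a design choice, not established
behaviour of any regulatory tool: both fallback values bound the 8 h
average from above, so the resulting ratio over-estimates rather than
under-estimates, which is the right failure direction for a first-level
screen; refusing to compute would hide the substance entirely. A
substance with no OEL at all is excluded from HI sums with a prominent
warning but still counts for class activation and alert findings, since
that qualitative information remains valid.

Concentrations and OELs may be expressed in ppm or mg/m³. When the two
differ the measurement is converted with the standard industrial-hygiene
relation mg/m³ = ppm × MW / 24.45 (molar volume at 25 °C and
101.325 kPa). A missing molecular weight in that situation is a **hard
error** naming the substance: a silently unit-mismatched ratio is the
worst possible failure of a screening tool, being wrong by a factor of
MW/24.45 in whichever direction. Fibre counts (fibers/cm³) have no mass
equivalence and never convert.

Another deliberate hard error: a scenario substance absent from the
database stops the analysis and lists the offending CAS numbers, even if
other substances resolve. Dropping unresolvable substances silently would
turn a wrong-database mistake into an optimistic report.

## Identifiers and the database model

Substances are keyed by CAS registry number, validated with the mod-10
check-digit rule (weights 1..n from the rightmost non-check digit).
Records flagged `synthetic: true` are exempt, which lets generated
fixtures carry CAS-shaped identifiers from a high, unassigned-looking
range without colliding with real registry entries.

The database (`jurisdiction`, `oel_name`, substances with OEL sets and
class links) is canonical in JSON — key-sorted, substances ordered by
CAS, numbers written with the shortest decimal string that parses back to
the identical double — so writing is deterministic byte-for-byte and
`read` after `write` is the exact identity. The flat CSV dialect uses two
files because substance-to-class is many-to-many: `substances.csv` (one
row per OEL) and `classes.csv` (one row per link), plus a small
`database.json` carrying the jurisdiction metadata.

## The synthetic generator

The real curated corpora behind national tools (700+ substances with
literature-reviewed class links) are not redistributable, so the test
fixtures are generated. `generate_substance_db()` draws, per substance:
an 8 h OEL uniform on 1–500 ppm or 0.1–50 mg/m³ (30% of substances also
get a short-term value at 3× the 8 h one); with probability 0.05 no OEL
at all; with probability 0.1 only a ceiling/short-term value, exercising
the fallback path; a molecular weight uniform on 30–300 g/mol, missing
with probability 0.1; and independent class memberships at density 0.15
per additive class and 0.05 per alert class, giving a realistic 2–3
classes per substance. These defaults were chosen once as plausible for
an OEL table and are not tuned to any test outcome. Scenarios draw
concentration-to-OEL ratios uniformly on [0, 1.5], straddling the
single-substance limit so both risky and clean classes occur.

What the generator does *not* emulate: correlated class memberships
(real solvents cluster on CNS/ocular/skin effects), the long-tailed
real OEL distribution, jurisdictional OEL disagreements, and curation
metadata. Passing tests therefore demonstrate the *engine's* arithmetic,
ordering, and invariants on structurally valid inputs — not
toxicological realism of any particular database.

## The packaged case study

`case_study_fixture()` reconstructs a printing-workstation co-exposure:
MEK, MIBK, toluene and trichloroethylene measured during maintenance
work. The four substances share the central-nervous-system, ocular, skin
and ototoxicity classes; MEK and toluene additionally activate the
developmental-damage alert class, MIBK and trichloroethylene the
carcinogenicity/mutagenicity one. The CAS numbers are real; the OELs and
concentrations are **synthetic illustrative values** (so labelled in the
records), chosen so each substance sits at 25–45% of its own limit while
the four shared classes reach HI = 140%. That is the pattern that makes
additive screening worthwhile: single-substance compliance everywhere,
yet four target organs over the additive threshold. A fifth, hepatic
class (toluene + trichloroethylene, HI 65%) shows a shared-but-compliant
row.

## Numerical and ordering choices

* HIs are uncapped; text reports round to one decimal, JSON keeps full
  precision, and `report_from_json()` reconstructs the report object
  exactly.
* Ranking is a stable total order: alert classes before additive ones,
  then decreasing HI (or substance count), ties broken alphabetically by
  class id. Contributions within a class are ordered by decreasing ratio
  with the same alphabetical tie-break.
* Engine sums are plain left-to-right floating-point addition over at
  most a few hundred terms; the test suite checks agreement with an
  independent brute-force sum to 1e-9 relative tolerance, and
  conservation (HI = sum of its contribution rows) to the same tolerance.
* Classes activated by no scenario substance are omitted from reports
  rather than printed as 0% rows.
* Generators consume an explicit seed and restore the caller's RNG
  state, so the same spec is byte-reproducible regardless of session
  history.

Problem sizes in the shipped tests — databases of 25–100 substances
(1000 for the density-convergence check), scenarios of up to 10
substances, 1000 seeded scenarios for the formula-oracle comparison —
were chosen to exercise every path at interactive speed.

## Known limitations

The additivity default can both under-estimate (synergy/potentiation,
e.g. noise–solvent ototoxicity) and over-estimate (infra-additive
mixtures) true mixture toxicity; no interaction modelling is attempted,
and the tool is a first-level screen, not a risk characterisation. The
same OEL is used for a substance in every class it activates, although
the limit was set for its critical effect only — a conservative
simplification. Short-term (15 min) exposure excursions are not assessed;
the short-term OEL appears only as a fallback denominator. The packaged
class links and OELs are illustrative, and any real assessment must load
a curated jurisdictional database.
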