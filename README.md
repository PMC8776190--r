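# hazmix

Screening-level risk assessment of occupational co-exposure to multiple
chemicals, for industrial hygienists, preventers and occupational health
physicians.

Compliance is usually judged one substance at a time against its
occupational exposure limit (OEL) — the full-shift 8 h airborne limit.
That misses mixtures: several substances, each below its own limit, can
jointly stress the same target organ. `hazmix` groups toxic effects into
24 toxicological classes (by target organ or mode of action) and, for
each class shared by the substances in a mixture, computes the additive
**Hazard Index**

    HI = (C1/OEL1 + C2/OEL2 + ... + Cn/OELn) x 100%

where `Ci` is the measured atmospheric concentration of substance *i*.
A class is flagged risky when HI exceeds 100% strictly. Six classes
(endocrine disruption, male/female reproductive system damage,
developmental damage, carcinogenicity and/or mutagenicity,
sensitization) are non-additive **alert classes**: any exposure triggers
a warning instead of an index. Without measurements, a qualitative mode
reports, per activated class, how many substances share it.

The package provides:

* the built-in 24-class taxonomy (`tox_registry()`);
* a substance/OEL database model with canonical JSON and two-file CSV
  dialects, CAS check-digit validation and ppm/mg·m⁻³ conversion
  (`read_substance_db()`, `validate_cas()`, `convert_concentration()`);
* the mixture engine (`analyze_quantitative()`, `analyze_qualitative()`,
  `compute_class_hi()`, `detect_alerts()`) with ranked, machine- and
  human-readable reports (`render_report()`, `report_from_json()`);
* a command-line interface (`cli_analyze()`, `cli_validate_db()`,
  `cli_taxonomy()`; Rscript entry point in `inst/cli/hazmix.R`) with a
  scriptable exit-code contract (0 clean / 2 risk-or-alert / 1 error);
* seeded generators for synthetic databases and scenarios
  (`generate_substance_db()`, `generate_scenario()`) and a packaged
  case-study fixture (`case_study_fixture()`).

## Worked example

Four solvents measured at a printing workstation during maintenance
(packaged fixture; real CAS numbers, synthetic illustrative OELs and
concentrations):

```r
library(hazmix)
fx <- case_study_fixture()
report <- analyze_quantitative(fx$scenario, fx$db)
print(report)
```

```
Mixture analysis report (quantitative mode)
Database: synthetic (OEL-8h) | substances in scenario: 4

Alert messages:
  ! 2 substances are carcinogenic and/or mutagenic. [carcinogenicity_mutagenicity: 108-10-1, 79-01-6]
  ! 2 substances affect development of the foetus, embryo, and/or child. [developmental_damage: 108-88-3, 78-93-3]
  ! 4 substances are ototoxic. [ototoxicity: 108-10-1, 108-88-3, 78-93-3, 79-01-6] (informational)
Risk from multiple exposures (any Hazard Index > 100%): YES

  Toxicological class                    HI (%)  Substances
  carcinogenicity_mutagenicity             N.A.  108-10-1, 79-01-6
  developmental_damage                     N.A.  108-88-3, 78-93-3
* central_nervous_system_damage           140.0  108-10-1, 108-88-3, 78-93-3, 79-01-6
* ocular_damage                           140.0  108-10-1, 108-88-3, 78-93-3, 79-01-6
* ototoxicity                             140.0  108-10-1, 108-88-3, 78-93-3, 79-01-6
* skin_damage                             140.0  108-10-1, 108-88-3, 78-93-3, 79-01-6
  hepatic_damage                           65.0  108-88-3, 79-01-6
```

Reading the output: every substance sits at 25–45% of its own OEL, so
single-substance screening sees no problem — yet the four classes all
four solvents share reach HI = 140% (`*` marks HI > 100%). The two alert
classes head the table with `N.A.` in place of an index, since additivity
is not applied to them. Exit-code-wise this situation is a `2`.

The same analysis from a shell, using the packaged fixture files:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/hazmix.R", package = "hazmix"))')
DB=$(Rscript -e 'cat(system.file("extdata/case_study_db.json", package = "hazmix"))')
SCN=$(Rscript -e 'cat(system.file("extdata/case_study_scenario.csv", package = "hazmix"))')
Rscript "$CLI" analyze --db "$DB" --scenario "$SCN" --format json
```

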