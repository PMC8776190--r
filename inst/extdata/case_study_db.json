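{
  "jurisdiction": "synthetic",
  "oel_name": "OEL-8h",
  "substances": [
    {
      "cas": "108-10-1",
      "name": "methyl isobutyl ketone (MIBK)",
      "molecular_weight": 100.16,
      "synthetic": false,
      "oels": {
        "eight_hour": {
          "value": 20,
          "unit": "ppm"
        }
      },
      "class_ids": ["carcinogenicity_mutagenicity", "central_nervous_system_damage", "ocular_damage", "ototoxicity", "skin_damage"],
      "evidence_notes": "synthetic illustrative OEL; not a regulatory value"
    },
    {
      "cas": "108-88-3",
      "name": "toluene",
      "molecular_weight": 92.14,
      "synthetic": false,
      "oels": {
        "eight_hour": {
          "value": 20,
          "unit": "ppm"
        },
        "short_term": {
          "value": 100,
          "unit": "ppm"
        }
      },
      "class_ids": ["central_nervous_system_damage", "developmental_damage", "hepatic_damage", "ocular_damage", "ototoxicity", "skin_damage"],
      "evidence_notes": "synthetic illustrative OEL; not a regulatory value"
    },
    {
      "cas": "78-93-3",
      "name": "methyl ethyl ketone (MEK)",
      "molecular_weight": 72.11,
      "synthetic": false,
      "oels": {
        "eight_hour": {
          "value": 200,
          "unit": "ppm"
        },
        "short_term": {
          "value": 300,
          "unit": "ppm"
        }
      },
      "class_ids": ["central_nervous_system_damage", "developmental_damage", "ocular_damage", "ototoxicity", "skin_damage"],
      "evidence_notes": "synthetic illustrative OEL; not a regulatory value"
    },
    {
      "cas": "79-01-6",
      "name": "trichloroethylene",
      "molecular_weight": 131.39,
      "synthetic": false,
      "oels": {
        "eight_hour": {
          "value": 10,
          "unit": "ppm"
        }
      },
      "class_ids": ["carcinogenicity_mutagenicity", "central_nervous_system_damage", "hepatic_damage", "ocular_damage", "ototoxicity", "skin_damage"],
      "evidence_notes": "synthetic illustrative OEL; not a regulatory value"
    }
  ]
}
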