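"cas","class_id"
"108-10-1","carcinogenicity_mutagenicity"
"108-10-1","central_nervous_system_damage"
"108-10-1","ocular_damage"
"108-10-1","ototoxicity"
"108-10-1","skin_damage"
"108-88-3","central_nervous_system_damage"
"108-88-3","developmental_damage"
"108-88-3","hepatic_damage"
"108-88-3","ocular_damage"
"108-88-3","ototoxicity"
"108-88-3","skin_damage"
"78-93-3","central_nervous_system_damage"
"78-93-3","developmental_damage"
"78-93-3","ocular_damage"
"78-93-3","ototoxicity"
"78-93-3","skin_damage"
"79-01-6","carcinogenicity_mutagenicity"
"79-01-6","central_nervous_system_damage"
"79-01-6","hepatic_damage"
"79-01-6","ocular_damage"
"79-01-6","ototoxicity"
"79-01-6","skin_damage"
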