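"cas","name","molecular_weight","synthetic","evidence_notes","oel_kind","oel_value","oel_unit"
"108-10-1","methyl isobutyl ketone (MIBK)","100.16","FALSE","synthetic illustrative OEL; not a regulatory value","eight_hour","20","ppm"
"108-88-3","toluene","92.14","FALSE","synthetic illustrative OEL; not a regulatory value","eight_hour","20","ppm"
"108-88-3","toluene","92.14","FALSE","synthetic illustrative OEL; not a regulatory value","short_term","100","ppm"
"78-93-3","methyl ethyl ketone (MEK)","72.11","FALSE","synthetic illustrative OEL; not a regulatory value","eight_hour","200","ppm"
"78-93-3","methyl ethyl ketone (MEK)","72.11","FALSE","synthetic illustrative OEL; not a regulatory value","short_term","300","ppm"
"79-01-6","trichloroethylene","131.39","FALSE","synthetic illustrative OEL; not a regulatory value","eight_hour","10","ppm"
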