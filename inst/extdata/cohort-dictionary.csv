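"column","type","required","description"
"participant_id","character",TRUE,"opaque participant identifier"
"group","character",FALSE,"generator ground-truth group (hc/stage2); optional on real data"
"visit_index","integer",TRUE,"visit number, 0 = first visit with complete battery"
"visit_offset_years","numeric",TRUE,"years since baseline visit, >= 0"
"age","numeric",TRUE,"age in years at visit"
"sex","character",TRUE,"binary sex category, M or F"
"education","numeric",TRUE,"education in years, >= 0"
"jlo","numeric",TRUE,"raw score: JLO"
"hvlt_total","numeric",TRUE,"raw score: HVLT-R Total Recall"
"hvlt_delayed","numeric",TRUE,"raw score: HVLT-R Delayed Recall"
"hvlt_recog","numeric",TRUE,"raw score: HVLT-R Recognition"
"lns","numeric",TRUE,"raw score: LNS"
"cowat","numeric",TRUE,"raw score: COWAT lexical fluency"
"bnt","numeric",TRUE,"raw score: modified BNT"
"semantic_fluency","numeric",TRUE,"raw score: modified semantic fluency"
"sdmt","numeric",TRUE,"raw score: SDMT"
"tmt_a","numeric",TRUE,"raw score: TMT-A (seconds; higher = worse)"
"tmt_b","numeric",TRUE,"raw score: TMT-B (seconds; higher = worse)"
"updrs3","numeric",TRUE,"MDS-UPDRS Part III motor score"
"hoehn_yahr","numeric",TRUE,"Hoehn & Yahr stage"
"scopa_aut","numeric",TRUE,"SCOPA-AUT autonomic score"
"gds15","numeric",TRUE,"GDS-15 depression score"
"quip","numeric",TRUE,"QUIP impulsive-compulsive score"
"stai_state","numeric",TRUE,"STAI state anxiety"
"upsit","numeric",TRUE,"UPSIT smell identification (0-40)"
"ess","numeric",TRUE,"Epworth Sleepiness Scale"
"rbdsq","numeric",TRUE,"RBD Screening Questionnaire"
"moca","numeric",TRUE,"Montreal Cognitive Assessment (0-30)"
"saa_positive","logical",TRUE,"CSF alpha-synuclein seed amplification assay positive (may be missing)"
"dat_deficit","logical",TRUE,"putamen SBR < 75% of age/sex-adjusted reference (may be missing)"
"hyposmia","logical",TRUE,"hyposmia flag"
"functional_impairment","character",TRUE,"ordered functional impairment: none, slight, greater"
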