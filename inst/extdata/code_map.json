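{
  "comment": "Default ICD-10 code map. Charlson categories follow the Quan ICD-10 coding algorithm with the original Charlson weights; the cardiovascular event lists are a minimal illustrative default and should be replaced for real analyses.",
  "cci": {
    "mi": {"codes": ["I21", "I22", "I252"], "weight": 1},
    "chf": {"codes": ["I099", "I110", "I130", "I132", "I255", "I420", "I425", "I426", "I427", "I428", "I429", "I43", "I50", "P290"], "weight": 1},
    "pvd": {"codes": ["I70", "I71", "I731", "I738", "I739", "I771", "I790", "I792", "K551", "K558", "K559", "Z958", "Z959"], "weight": 1},
    "cevd": {"codes": ["G45", "G46", "H340", "I60", "I61", "I62", "I63", "I64", "I65", "I66", "I67", "I68", "I69"], "weight": 1},
    "dementia": {"codes": ["F00", "F01", "F02", "F03", "F051", "G30", "G311"], "weight": 1},
    "cpd": {"codes": ["I278", "I279", "J40", "J41", "J42", "J43", "J44", "J45", "J46", "J47", "J60", "J61", "J62", "J63", "J64", "J65", "J66", "J67", "J684", "J701", "J703"], "weight": 1},
    "rheumatic": {"codes": ["M05", "M06", "M315", "M32", "M33", "M34", "M351", "M353", "M360"], "weight": 1},
    "pud": {"codes": ["K25", "K26", "K27", "K28"], "weight": 1},
    "liver_mild": {"codes": ["B18", "K700", "K701", "K702", "K703", "K709", "K713", "K714", "K715", "K717", "K73", "K74", "K760", "K762", "K763", "K764", "K768", "K769", "Z944"], "weight": 1},
    "diabetes_uncomplicated": {"codes": ["E100", "E101", "E106", "E108", "E109", "E110", "E111", "E116", "E118", "E119", "E120", "E121", "E126", "E128", "E129", "E130", "E131", "E136", "E138", "E139", "E140", "E141", "E146", "E148", "E149"], "weight": 1},
    "diabetes_complicated": {"codes": ["E102", "E103", "E104", "E105", "E107", "E112", "E113", "E114", "E115", "E117", "E122", "E123", "E124", "E125", "E127", "E132", "E133", "E134", "E135", "E137", "E142", "E143", "E144", "E145", "E147"], "weight": 2},
    "hemiplegia": {"codes": ["G041", "G114", "G801", "G802", "G81", "G82", "G830", "G831", "G832", "G833", "G834", "G839"], "weight": 2},
    "renal": {"codes": ["I120", "I131", "N032", "N033", "N034", "N035", "N036", "N037", "N052", "N053", "N054", "N055", "N056", "N057", "N18", "N19", "N250", "Z490", "Z491", "Z492", "Z940", "Z992"], "weight": 2},
    "cancer": {"codes": ["C0", "C1", "C20", "C21", "C22", "C23", "C24", "C25", "C26", "C30", "C31", "C32", "C33", "C34", "C37", "C38", "C39", "C40", "C41", "C43", "C45", "C46", "C47", "C48", "C49", "C50", "C51", "C52", "C53", "C54", "C55", "C56", "C57", "C58", "C60", "C61", "C62", "C63", "C64", "C65", "C66", "C67", "C68", "C69", "C70", "C71", "C72", "C73", "C74", "C75", "C76", "C81", "C82", "C83", "C84", "C85", "C88", "C90", "C91", "C92", "C93", "C94", "C95", "C96", "C97"], "weight": 2},
    "liver_severe": {"codes": ["I850", "I859", "I864", "I982", "K704", "K711", "K721", "K729", "K765", "K766", "K767"], "weight": 3},
    "metastatic_cancer": {"codes": ["C77", "C78", "C79", "C80"], "weight": 6},
    "aids": {"codes": ["B20", "B21", "B22", "B24"], "weight": 6}
  },
  "hierarchy": [
    ["diabetes_complicated", "diabetes_uncomplicated"],
    ["metastatic_cancer", "cancer"],
    ["liver_severe", "liver_mild"]
  ],
  "cv_history_categories": ["mi", "chf", "pvd", "cevd"],
  "cv_events": {
    "unstable_angina": ["I200"],
    "mi": ["I21", "I22"],
    "heart_failure": ["I50"],
    "cerebrovascular": ["I60", "I61", "I62", "I63", "I64"]
  },
  "gi_hemorrhage": ["K250", "K260", "K270", "K280", "K920", "K921", "K922"],
  "treatments": {
    "anemia": ["ESA", "oral_iron", "IV_iron", "RBC_transfusion"],
    "antidiabetic": ["SGLT2i", "GLP", "other_antidiabetic", "insulin"],
    "antihypertensive": ["ARB_ACEi", "other_antihypertensive"],
    "chemotherapy": "chemotherapy",
    "dialysis": "chronic_dialysis",
    "transplant": "kidney_transplant"
  }
}
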