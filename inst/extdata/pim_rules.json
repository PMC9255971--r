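[
  {"rule_id": "BEERS-PPI", "source": "BEERS2019",
   "targets": {"atc": ["A02BC"]},
   "rationale": "proton pump inhibitors: avoid scheduled use beyond 8 weeks (C. difficile, fracture risk)"},
  {"rule_id": "BEERS-BZD", "source": "BEERS2019",
   "targets": {"atc": ["N05BA"]},
   "rationale": "benzodiazepines: increased sensitivity, cognitive impairment, falls"},
  {"rule_id": "BEERS-Z-DRUG", "source": "BEERS2019",
   "targets": {"atc": ["N05CF"]},
   "rationale": "benzodiazepine-receptor agonist hypnotics: falls, fractures"},
  {"rule_id": "BEERS-NSAID", "source": "BEERS2019",
   "targets": {"atc": ["M01AE", "M01AB", "M01AC"]},
   "rationale": "chronic non-COX-selective NSAID use: GI bleeding, renal injury"},
  {"rule_id": "BEERS-FG-ANTIHIST", "source": "BEERS2019",
   "targets": {"atc": ["R06AA", "R06AB", "R06AE"], "generic": ["hydroxyzine"]},
   "rationale": "first-generation antihistamines: highly anticholinergic"},
  {"rule_id": "BEERS-TCA", "source": "BEERS2019",
   "targets": {"generic": ["amitriptyline"]},
   "rationale": "tertiary tricyclic antidepressant: anticholinergic, orthostasis"},
  {"rule_id": "BEERS-ANTIPSYCH", "source": "BEERS2019",
   "targets": {"atc": ["N05AH"]},
   "rationale": "antipsychotics: stroke and mortality risk in older adults"},
  {"rule_id": "BEERS-SU-LONG", "source": "BEERS2019",
   "targets": {"generic": ["glimepiride", "glipizide"]},
   "rationale": "sulfonylureas: prolonged hypoglycemia risk"},
  {"rule_id": "BEERS-DIGOXIN-FIRSTLINE", "source": "BEERS2019",
   "targets": {"generic": ["digoxin"]},
   "rationale": "digoxin as first-line: safer alternatives exist"},
  {"rule_id": "BEERS-AMIODARONE", "source": "BEERS2019",
   "targets": {"generic": ["amiodarone"]},
   "rationale": "amiodarone as first-line for atrial fibrillation"},
  {"rule_id": "BEERS-ALPHA1", "source": "BEERS2019",
   "targets": {"atc": ["C02AC"]},
   "rationale": "central alpha-agonists: CNS effects, bradycardia, orthostasis"},
  {"rule_id": "BEERS-SSRI-FALLS", "source": "BEERS2019",
   "targets": {"atc": ["N06AB"]},
   "predicates": {"ga_flag": "function"},
   "rationale": "SSRIs in patients with functional impairment: fall risk"},
  {"rule_id": "BEERS-OPIOID-COG", "source": "BEERS2019",
   "targets": {"atc": ["N02AA", "N02AX"]},
   "predicates": {"ga_flag": "cognition"},
   "rationale": "opioids with cognitive impairment: delirium risk"},
  {"rule_id": "STOPP-PPI-LONG", "source": "STOPP",
   "targets": {"atc": ["A02BC"]},
   "rationale": "PPI at full dose beyond 8 weeks for uncomplicated disease"},
  {"rule_id": "STOPP-BZD-LONG", "source": "STOPP",
   "targets": {"atc": ["N05BA"]},
   "rationale": "benzodiazepines for more than 4 weeks"},
  {"rule_id": "STOPP-FG-ANTIHIST", "source": "STOPP",
   "targets": {"atc": ["R06AA", "R06AB", "R06AE"]},
   "rationale": "first-generation antihistamines: safer alternatives exist"},
  {"rule_id": "STOPP-NSAID-COMORB", "source": "STOPP",
   "targets": {"atc": ["M01AE", "M01AB", "M01AC"]},
   "predicates": {"ga_flag": "comorbidity"},
   "rationale": "NSAID with significant comorbidity (heart failure, renal disease)"},
  {"rule_id": "STOPP-BB-DM", "source": "STOPP",
   "targets": {"atc": ["C07AB"]},
   "predicates": {"co_medication_atc": "A10B"},
   "rationale": "cardioselective beta-blocker with antidiabetic therapy: masked hypoglycemia"},
  {"rule_id": "STOPP-BB-RATE", "source": "STOPP",
   "targets": {"generic": ["propranolol"]},
   "rationale": "non-selective beta-blocker: bradycardia risk"},
  {"rule_id": "STOPP-LOOP-FIRSTLINE", "source": "STOPP",
   "targets": {"atc": ["C03CA"]},
   "predicates": {"co_medication_atc": "C03A"},
   "rationale": "loop diuretic stacked on thiazide without hypertension indication"},
  {"rule_id": "STOPP-TCA", "source": "STOPP",
   "targets": {"generic": ["amitriptyline"]},
   "rationale": "tricyclic antidepressant with anticholinergic burden"},
  {"rule_id": "STOPP-ANTIPSYCH-HYPNOTIC", "source": "STOPP",
   "targets": {"generic": ["quetiapine"]},
   "predicates": {"ga_flag": "psychological"},
   "rationale": "antipsychotic as hypnotic with psychological impairment"},
  {"rule_id": "STOPP-OPIOID-LAXATIVE", "source": "STOPP",
   "targets": {"atc": ["N02AA"]},
   "rationale": "strong opioid without routine bowel regimen review"},
  {"rule_id": "STOPP-DUAL-ANTIPLT", "source": "STOPP",
   "targets": {"generic": ["clopidogrel"]},
   "predicates": {"co_medication_atc": "B01AA"},
   "rationale": "antiplatelet with vitamin K antagonist: bleeding risk"},
  {"rule_id": "STOPP-GLIB", "source": "STOPP",
   "targets": {"generic": ["glimepiride"]},
   "rationale": "long-acting sulfonylurea: prolonged hypoglycemia"}
]
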