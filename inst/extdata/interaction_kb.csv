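drug_a,drug_b,severity
warfarin,aspirin,D
warfarin,ibuprofen,D
warfarin,naproxen,D
warfarin,acetaminophen,C
warfarin,levothyroxine,C
warfarin,amiodarone,D
warfarin,ciprofloxacin,D
warfarin,fluorouracil,D
warfarin,capecitabine,D
aspirin,ibuprofen,C
aspirin,clopidogrel,C
aspirin,apixaban,D
aspirin,sertraline,C
clopidogrel,omeprazole,D
clopidogrel,esomeprazole,D
apixaban,rivaroxaban,X
lisinopril,furosemide,C
lisinopril,ibuprofen,D
lisinopril,potassium chloride,C
lisinopril,spironolactone,C
losartan,spironolactone,C
losartan,ibuprofen,D
enalapril,allopurinol,C
furosemide,digoxin,C
furosemide,ibuprofen,C
hydrochlorothiazide,digoxin,C
digoxin,amiodarone,D
digoxin,spironolactone,C
amiodarone,simvastatin,D
amiodarone,ciprofloxacin,X
simvastatin,diltiazem,D
atorvastatin,diltiazem,C
metoprolol,diltiazem,C
metoprolol,clonidine,D
metoprolol,glipizide,C
atenolol,insulin glargine,C
metformin,ciprofloxacin,C
insulin glargine,metoprolol,C
levothyroxine,calcium carbonate,C
levothyroxine,ferrous sulfate,C
levothyroxine,omeprazole,C
sertraline,tramadol,D
citalopram,omeprazole,C
citalopram,quetiapine,D
escitalopram,tramadol,D
fluoxetine,tramadol,D
st johns wort,sertraline,X
st johns wort,warfarin,D
fish oil,warfarin,C
lorazepam,morphine,C
alprazolam,oxycodone,C
ondansetron,citalopram,C
cisplatin,furosemide,D
oxaliplatin,ondansetron,C
paclitaxel,carboplatin,C
fluorouracil,allopurinol,C
capecitabine,folic acid,C
gemcitabine,warfarin,D
pemetrexed,ibuprofen,D
doxorubicin,paclitaxel,D
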