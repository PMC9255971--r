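brand,generic
lasix,furosemide
coumadin,warfarin
tylenol,acetaminophen
advil,ibuprofen
motrin,ibuprofen
aleve,naproxen
prilosec,omeprazole
nexium,esomeprazole
protonix,pantoprazole
lipitor,atorvastatin
zocor,simvastatin
crestor,rosuvastatin
glucophage,metformin
synthroid,levothyroxine
ativan,lorazepam
xanax,alprazolam
valium,diazepam
ambien,zolpidem
zoloft,sertraline
lexapro,escitalopram
prozac,fluoxetine
benadryl,diphenhydramine
plavix,clopidogrel
eliquis,apixaban
xarelto,rivaroxaban
norvasc,amlodipine
toprol,metoprolol
lopressor,metoprolol
zestril,lisinopril
cozaar,losartan
neurontin,gabapentin
lyrica,pregabalin
flomax,tamsulosin
colace,docusate
miralax,polyethylene glycol
imodium,loperamide
zofran,ondansetron
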