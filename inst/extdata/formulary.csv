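generic_name,atc_codes,primary_index
atorvastatin,C10AA05,1
simvastatin,C10AA01,1
rosuvastatin,C10AA07,1
pravastatin,C10AA03,1
lisinopril,C09AA03,1
enalapril,C09AA02,1
ramipril,C09AA05,1
losartan,C09CA01,1
valsartan,C09CA03,1
olmesartan,C09CA08,1
metoprolol,C07AB02,1
atenolol,C07AB03,1
bisoprolol,C07AB07,1
carvedilol,C07AG02,1
propranolol,C07AA05,1
furosemide,C03CA01,1
hydrochlorothiazide,C03AA03,1
spironolactone,C03DA01,1
chlorthalidone,C03BA04,1
amlodipine,C08CA01,1
diltiazem,C08DB01,1
digoxin,C01AA05,1
amiodarone,C01BD01,1
isosorbide mononitrate,C01DA14,1
clonidine,C02AC01,1
warfarin,B01AA03,1
apixaban,B01AF02,1
rivaroxaban,B01AF01,1
clopidogrel,B01AC04,1
aspirin,B01AC06;N02BA01,1
omeprazole,A02BC01,1
pantoprazole,A02BC02,1
esomeprazole,A02BC05,1
lansoprazole,A02BC03,1
ranitidine,A02BA02,1
famotidine,A02BA03,1
calcium carbonate,A12AA04;A02AC01,1
metformin,A10BA02,1
glipizide,A10BB07,1
glimepiride,A10BB12,1
insulin glargine,A10AE04,1
sitagliptin,A10BH01,1
empagliflozin,A10BK03,1
cholecalciferol,A11CC05,1
ergocalciferol,A11CC01,1
ascorbic acid,A11GA01,1
thiamine,A11DA01,1
pyridoxine,A11HA02,1
vitamin e,A11HA03,1
cyanocobalamin,B03BA01,1
folic acid,B03BB01,1
ferrous sulfate,B03AA07,1
magnesium oxide,A12CC10,1
potassium chloride,A12BA01,1
zinc sulfate,A12CB01,1
levothyroxine,H03AA01,1
acetaminophen,N02BE01,1
tramadol,N02AX02,1
oxycodone,N02AA05,1
morphine,N02AA01,1
gabapentin,N03AX12,1
pregabalin,N03AX16,1
lorazepam,N05BA06,1
alprazolam,N05BA12,1
diazepam,N05BA01,1
clonazepam,N03AE01,1
zolpidem,N05CF02,1
quetiapine,N05AH04,1
trazodone,N06AX05,1
sertraline,N06AB06,1
citalopram,N06AB04,1
escitalopram,N06AB10,1
fluoxetine,N06AB03,1
duloxetine,N06AX21,1
venlafaxine,N06AX16,1
mirtazapine,N06AX11,1
amitriptyline,N06AA09,1
donepezil,N06DA02,1
ibuprofen,M01AE01,1
naproxen,M01AE02,1
meloxicam,M01AC06,1
celecoxib,M01AH01,1
diclofenac,M01AB05,1
diphenhydramine,R06AA02,1
hydroxyzine,N05BB01,1
loratadine,R06AX13,1
cetirizine,R06AE07,1
chlorpheniramine,R06AB04,1
meclizine,R06AE05,1
albuterol,R03AC02,1
tiotropium,R03BB04,1
fluticasone,R03BA05,1
docusate,A06AA02,1
senna,A06AB06,1
polyethylene glycol,A06AD15,1
loperamide,A07DA03,1
tamsulosin,G04CA02,1
finasteride,G04CB01,1
allopurinol,M04AA01,1
colchicine,M04AC01,1
prednisone,H02AB07,1
dexamethasone,H02AB02,1
ciprofloxacin,J01MA02,1
amoxicillin,J01CA04,1
fish oil,C10AX06,1
glucosamine,M01AX05,1
ginkgo biloba,N06DX02,1
melatonin,N05CH01,1
coenzyme q10,C01EB09,1
saw palmetto,G04CX02,1
st johns wort,N06AX25,1
lactobacillus,A07FA01,1
carboplatin,L01XA02,1
cisplatin,L01XA01,1
oxaliplatin,L01XA03,1
paclitaxel,L01CD01,1
docetaxel,L01CD02,1
gemcitabine,L01BC05,1
fluorouracil,L01BC02,1
capecitabine,L01BC06,1
pemetrexed,L01BA04,1
etoposide,L01CB01,1
irinotecan,L01XX19,1
cyclophosphamide,L01AA01,1
doxorubicin,L01DB01,1
rituximab,L01XC02,1
pembrolizumab,L01XC18,1
nivolumab,L01XC17,1
ondansetron,A04AA01,1
granisetron,A04AA02,1
aprepitant,A04AD12,1
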