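drug_name,rank
imipenem,4
meropenem,4
colistin,4
amikacin,4
linezolid,4
neomycin sulphate,4
tigecycline,4
daptomycin,4
vancomycin,3
gentamicin,3
ceftazidime,3
piperacillin,3
ceftriaxone,2
ciprofloxacin,2
co-amoxiclav,2
levofloxacin,2
erythromycin,2
cefuroxime,2
clindamycin,2
cefotaxime,2
clarithromycin,2
azithromycin,2
norfloxacin,2
moxifloxacin,2
metronidazole,1
co-trimoxazole,1
amoxicillin,1
tobramycin,1
benzylpenicillin,1
doxycycline,1
feneticillin,1
nitrofurantoin,1
cefazoline,1
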