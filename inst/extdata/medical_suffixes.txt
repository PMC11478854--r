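# Medical-glossary suffixes marking clinical-feature terms (one per line).
# Stored without the leading hyphen; matching is on token endings.
osis
emia
aemia
pnea
pnoea
itis
pathy
ectomy
ostomy
otomy
plasty
algia
dynia
megaly
penia
rrhagia
rrhage
rrhea
phagia
phasia
plegia
paresis
trophy
plasia
lysis
uria
derma
graphy
scopy
centesis
malacia
stasis
ptysis
pexy
oedema
edema
cardia
tension
embolism
infarction
ischemia
carcinoma
sarcoma
lymphoma
melanoma
adenoma
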